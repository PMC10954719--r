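#' Count biological 5' read starts (or 3' ends) per position
#'
#' The biological 5' start of a plus-strand read is its BED start; for a
#' minus-strand read it is `end - 1`. Counts are accumulated per
#' (chromosome, strand, position). For collapsed small-RNA reads set
#' `weight = "score"` so each record contributes its multiplicity; the
#' library size is then the summed multiplicity.
#'
#' @param reads BED6-style tibble (one library).
#' @param weight `"none"` (each row counts 1) or `"score"`.
#' @param library_size override the library size used for RPM (defaults to
#'   the total counted reads).
#' @param library_id label carried on the track.
#' @return a `start_track` object: tibble of per-position counts plus the
#'   library size.
#' @export
count_read_starts <- function(reads, weight = c("none", "score"),
                              library_size = NULL, library_id = NULL) {
  .count_termini(reads, side = "five_prime_starts", weight = weight,
                 library_size = library_size, library_id = library_id)
}

#' @rdname count_read_starts
#' @export
count_read_ends <- function(reads, weight = c("none", "score"),
                            library_size = NULL, library_id = NULL) {
  .count_termini(reads, side = "three_prime_ends", weight = weight,
                 library_size = library_size, library_id = library_id)
}

.count_termini <- function(reads, side, weight = c("none", "score"),
                           library_size = NULL, library_id = NULL) {
  weight <- match.arg(weight)
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("reads table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"score" %in% names(reads)) reads$score <- 1
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' (line ",
         which(!reads$strand %in% c("+", "-"))[1], ")", call. = FALSE)
  if (nrow(reads) && any(reads$end <= reads$start))
    stop("malformed BED interval: end <= start at line ",
         which(reads$end <= reads$start)[1], call. = FALSE)
  w <- if (weight == "score") reads$score else rep(1, nrow(reads))
  pos <- if (side == "five_prime_starts") {
    ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  } else {
    ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  }
  counts <- tibble::tibble(chrom = reads$chrom, strand = reads$strand,
                           pos = as.integer(pos), w = w) |>
    dplyr::count(.data$chrom, .data$strand, .data$pos, wt = .data$w,
                 name = "count") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  structure(
    list(counts = counts,
         side = side,
         library_size = library_size %||% sum(w),
         library_id = library_id %||%
           (if ("library" %in% names(reads) && nrow(reads))
             reads$library[1] else NA_character_),
         lookup = stats::setNames(
           counts$count,
           paste(counts$chrom, counts$strand, counts$pos))),
    class = "start_track")
}

#' @export
print.start_track <- function(x, ...) {
  cat(sprintf("<start_track> %s: %d positions, library size %s (%s)\n",
              x$library_id %||% "?", nrow(x$counts),
              format(x$library_size), x$side))
  invisible(x)
}

#' Raw counts and RPM at given positions of a track
#'
#' @param track a `start_track`.
#' @param chrom,strand,pos vectors (recycled) identifying positions.
#' @return numeric vector; positions without reads return 0.
#' @export
track_count <- function(track, chrom, strand, pos) {
  v <- track$lookup[paste(chrom, strand, pos)]
  unname(ifelse(is.na(v), 0, v))
}

#' @rdname track_count
#' @export
track_rpm <- function(track, chrom, strand, pos) {
  if (track$library_size <= 0)
    stop("RPM undefined: track has library size 0", call. = FALSE)
  track_count(track, chrom, strand, pos) * 1e6 / track$library_size
}

#' Counting vector of a genomic locus
#'
#' The 21 RPM values at transcript-direction offsets -10 ... +10 around a
#' locus, the feature vector of the pile-up classifier. Offsets beyond the
#' chromosome bounds contribute 0.
#'
#' @param track a `start_track`.
#' @param chrom,strand,pos locus (0-based position).
#' @return numeric vector of length 21.
#' @export
counting_vector <- function(track, chrom, strand, pos) {
  counting_matrix(track,
                  tibble::tibble(chrom = chrom, strand = strand,
                                 pos = pos))[1, ]
}

#' Counting vectors for many loci at once
#'
#' @param track a `start_track`.
#' @param loci tibble with columns `chrom`, `strand`, `pos`.
#' @return numeric matrix, one row per locus, 21 columns `off_-10` ...
#'   `off_10`.
#' @export
counting_matrix <- function(track, loci) {
  if (track$library_size <= 0)
    stop("RPM undefined: track has library size 0", call. = FALSE)
  offs <- -10:10
  sgn <- ifelse(loci$strand == "+", 1L, -1L)
  m <- vapply(offs, function(o) {
    track_count(track, loci$chrom, loci$strand, loci$pos + sgn * o)
  }, numeric(nrow(loci)))
  m <- matrix(m, nrow = nrow(loci), ncol = 21)
  colnames(m) <- paste0("off_", offs)
  m * 1e6 / track$library_size
}
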