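#' Read / write BED6 tables
#'
#' BED6 with 0-based half-open coordinates; columns chrom, start, end,
#' name, score, strand.
#'
#' @param path file path.
#' @param x BED6-style tibble.
#' @return `read_bed6()` returns a tibble.
#' @export
read_bed6 <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                       col_types = "ciicdc", comment = "#")
  assert_bed6(x)
  x
}

#' @rdname read_bed6
#' @export
write_bed6 <- function(x, path) {
  assert_bed6(x)
  readr::write_tsv(x[, c("chrom", "start", "end", "name", "score",
                         "strand")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Write the truth table / pile-up sites / calls as TSV
#'
#' Plain TSV with a header line; columns as documented on the producing
#' function.
#'
#' @param x a tibble.
#' @param path file path.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read miRNA arm annotations from a GFF3 file
#'
#' Expects MirGeneDB-style records: one feature per mature arm with an ID
#' (or Name) attribute ending in `-5p`/`_5p` or `-3p`/`_3p`. Coordinates
#' are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return tibble with `chrom`, `start`, `end`, `strand`, `arm`
#'   (`"5p"`/`"3p"`) and `name`.
#' @export
read_mirna_arms <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 input", call. = FALSE)
  gr <- rtracklayer::import(path)
  name <- if (!is.null(gr$ID)) gr$ID else gr$Name
  arm <- dplyr::case_when(grepl("[-_]5p$", name) ~ "5p",
                          grepl("[-_]3p$", name) ~ "3p",
                          TRUE ~ NA_character_)
  keep <- !is.na(arm)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    arm = arm[keep],
    name = name[keep])
}

#' Known cleavage loci from annotated miRNA arms
#'
#' Converts mature-arm coordinates into positive training loci for the
#' pile-up classifier. The published convention (`"as_written"`) takes the
#' locus immediately upstream of the 5' end of the 5p arm and the locus
#' immediately downstream of the 3' end of the 3p arm. Because Degradome
#' chemistry captures fragments starting *at* a cut, the alternative
#' `"at_product"` convention takes the 5p 5' end itself and the position
#' after the 3p 3' end.
#'
#' @param arms tibble from [read_mirna_arms()].
#' @param convention `"as_written"` or `"at_product"`.
#' @return tibble of loci (`chrom`, `strand`, `pos`).
#' @export
arm_cleavage_loci <- function(arms, convention = c("as_written",
                                                   "at_product")) {
  convention <- match.arg(convention)
  up1 <- ifelse(arms$strand == "+", 1L, -1L)
  # transcript-oriented 5' start and first-past-3'-end positions
  five_start <- ifelse(arms$strand == "+", arms$start, arms$end - 1L)
  past_three <- ifelse(arms$strand == "+", arms$end, arms$start - 1L)
  pos <- ifelse(arms$arm == "5p",
                if (convention == "as_written") five_start - up1
                else five_start,
                past_three)
  tibble::tibble(chrom = arms$chrom, strand = arms$strand,
                 pos = as.integer(pos)) |>
    dplyr::distinct()
}

#' Export base-pair probabilities as TSV triplets
#'
#' @param structure an `rna_structure` from [rna_ensemble()].
#' @param path file path.
#' @param min_p drop probabilities below this value.
#' @export
write_bp_prob <- function(structure, path, min_p = 1e-6) {
  p <- structure$bp_prob
  if (is.null(p)) stop("no bp_prob; run rna_ensemble()", call. = FALSE)
  idx <- which(upper.tri(p) & p > min_p, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(i = idx[, 1], j = idx[, 2],
                                  p = p[idx]), path)
  invisible(path)
}
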