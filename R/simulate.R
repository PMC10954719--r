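#' Statistical model of one sequencing library
#'
#' Parameters of the read-generating process the downstream analysis
#' assumes: negative-binomially dispersed signal at planted cleavage sites,
#' homogeneous Poisson exonucleolytic background, and +/- 1 nt positional
#' jitter of read 5' ends.
#'
#' @param condition `"control"` or `"knockout"`.
#' @param replicate replicate index.
#' @param signal_depth NB mean read count at a planted Degradome pile-up.
#' @param dispersion NB dispersion (edgeR convention; variance =
#'   mu + dispersion * mu^2).
#' @param background_rate Poisson mean of background read starts per
#'   position per strand.
#' @param srna_mirna_depth,srna_morna_depth NB mean counts of miRNA-like
#'   and moRNA-like small RNA reads per arm.
#' @param jitter probability mass of a +/- 1 nt positional error on each
#'   side (total displaced mass `2 * jitter`).
#' @param read_length Degradome read length (only 5' starts are analyzed).
#' @param library_id label; defaults to `condition_repN`.
#' @return a `library_model` list.
#' @export
library_model <- function(condition = c("control", "knockout"),
                          replicate = 1L,
                          signal_depth = 100, dispersion = 0.1,
                          background_rate = 0.005,
                          srna_mirna_depth = 50, srna_morna_depth = 15,
                          jitter = 0.05, read_length = 50L,
                          library_id = NULL) {
  condition <- match.arg(condition)
  stopifnot(signal_depth >= 0, dispersion >= 0, background_rate >= 0,
            srna_mirna_depth >= 0, srna_morna_depth >= 0,
            jitter >= 0, jitter <= 0.5)
  structure(
    list(condition = condition, replicate = as.integer(replicate),
         signal_depth = signal_depth, dispersion = dispersion,
         background_rate = background_rate,
         srna_mirna_depth = srna_mirna_depth,
         srna_morna_depth = srna_morna_depth,
         jitter = jitter, read_length = as.integer(read_length),
         library_id = library_id %||%
           sprintf("%s_rep%d", condition, replicate)),
    class = "library_model")
}

#' The four-library desk design (2 control vs 2 Drosha-knockout)
#'
#' @param ... overrides passed to every [library_model()].
#' @return list of four `library_model`s.
#' @export
desk_libraries <- function(...) {
  list(library_model("control", 1, ...),
       library_model("control", 2, ...),
       library_model("knockout", 1, ...),
       library_model("knockout", 2, ...))
}

# draw NB counts; dispersion 0 degenerates to Poisson
.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

# genomic BED interval of a read with its biological 5' end at `five`
# (0-based) and given length, on `strand`; arguments recycle
.bio_interval <- function(five, len, strand) {
  m <- max(length(five), length(len), length(strand))
  five <- rep_len(five, m); len <- rep_len(len, m)
  strand <- rep_len(strand, m)
  start <- ifelse(strand == "+", five, five - len + 1L)
  tibble::tibble(start = as.integer(start), end = as.integer(start + len))
}

#' Simulate Degradome-seq read coordinates
#'
#' For every Drosha-dependent planted locus, read 5' starts stack at the
#' 3'-arm cleavage site `D` (mass `1 - 2 * jitter` at `D`, `jitter` at
#' `D +/- 1`), with counts drawn NB around `signal_depth`, multiplied by
#' the locus depletion factor in knockout libraries. Background read starts
#' are homogeneous Poisson per position and strand. Reads are fixed-length
#' intervals on the locus strand.
#'
#' @param truth truth table from [build_genome()].
#' @param models list of [library_model()]s (one library each).
#' @param genome named character vector (for chromosome bounds).
#' @param seed RNG seed.
#' @param decoys optional tibble of Drosha-independent pile-up positions
#'   (`chrom`, `strand`, `pos`) that receive the same NB-dispersed stacks
#'   in every condition (see [build_genome()]).
#' @return BED6-style tibble with additional `library`, `condition` and
#'   `replicate` columns; one row per read.
#' @export
simulate_degradome <- function(truth, models, genome, seed = 1L,
                               decoys = NULL) {
  if (inherits(models, "library_model")) models <- list(models)
  chrom_len <- nchar(genome)
  sites <- tibble::tibble(
    chrom = truth$chrom, strand = truth$strand, pos = truth$D,
    drosha_dependent = truth$drosha_dependent,
    depletion_factor = truth$depletion_factor)
  if (!is.null(decoys) && nrow(decoys)) {
    sites <- bind_rows(sites, tibble::tibble(
      chrom = decoys$chrom, strand = decoys$strand, pos = decoys$pos,
      drosha_dependent = FALSE, depletion_factor = 1))
  }
  with_seed(seed, {
    out <- lapply(models, function(m) {
      reads <- list()
      # planted signal
      if (nrow(sites)) {
        depleted <- m$condition == "knockout" & sites$drosha_dependent
        mu <- m$signal_depth * ifelse(depleted, sites$depletion_factor, 1)
        counts <- .rnb(nrow(sites), mu, m$dispersion)
        for (k in which(counts > 0)) {
          shift <- sample(c(-1L, 0L, 1L), counts[k], replace = TRUE,
                          prob = c(m$jitter, 1 - 2 * m$jitter, m$jitter))
          pos <- sites$pos[k] + shift
          iv <- .bio_interval(pos, m$read_length, sites$strand[k])
          reads[[length(reads) + 1]] <- tibble::tibble(
            chrom = sites$chrom[k], start = iv$start, end = iv$end,
            strand = sites$strand[k])
        }
      }
      # homogeneous Poisson background
      for (chrom in names(genome)) {
        len <- chrom_len[[chrom]]
        for (strand in c("+", "-")) {
          n_bg <- rpois(1, m$background_rate * len)
          if (n_bg > 0) {
            pos <- sample.int(len, n_bg, replace = TRUE) - 1L
            iv <- .bio_interval(pos, m$read_length, strand)
            reads[[length(reads) + 1]] <- tibble::tibble(
              chrom = chrom, start = iv$start, end = iv$end, strand = strand)
          }
        }
      }
      bed <- if (length(reads)) dplyr::bind_rows(reads) else
        empty_bed6()[, c("chrom", "start", "end", "strand")]
      # drop reads whose 5' end falls outside the chromosome, clip the rest
      five_ok <- ifelse(bed$strand == "+",
                        bed$start >= 0 & bed$start < chrom_len[bed$chrom],
                        bed$end - 1 >= 0 & bed$end - 1 < chrom_len[bed$chrom])
      bed <- bed[five_ok, ]
      bed$start <- pmax(bed$start, 0L)
      bed$end <- as.integer(pmin(bed$end, chrom_len[bed$chrom]))
      n_reads <- nrow(bed)
      tibble::tibble(
        chrom = bed$chrom, start = bed$start, end = bed$end,
        name = if (n_reads) sprintf("%s:read%06d", m$library_id,
                                    seq_len(n_reads)) else character(),
        score = rep(1, n_reads), strand = bed$strand,
        library = rep(m$library_id, n_reads),
        condition = rep(m$condition, n_reads),
        replicate = rep(m$replicate, n_reads))
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate collapsed small-RNA-seq read coordinates
#'
#' Emulates the by-products of Drosha cleavage captured by sRNA-seq:
#' miRNA-like reads whose proximal terminus sits exactly at a cleavage site
#' (5p reads start at `S`; 3p reads end at `D - 1`) and moRNA-like reads
#' from the immediately adjacent sequence whose proximal terminus also
#' marks the cut (5p moRNAs end at `S - 1`; 3p moRNAs start at `D`) while
#' their distal termini are exonucleolytically ragged (geometrically
#' dispersed lengths). Identical coordinates are collapsed into one record
#' with the read multiplicity in the BED score.
#'
#' @inheritParams simulate_degradome
#' @param mirna_lengths length range of miRNA-like reads.
#' @param morna_min_length,morna_length_p minimum length and geometric
#'   length parameter of moRNA-like reads.
#' @return collapsed BED6-style tibble (score = multiplicity) with
#'   `library` column.
#' @export
simulate_srna <- function(truth, models, genome, seed = 1L,
                          mirna_lengths = 20:24,
                          morna_min_length = 15, morna_length_p = 0.25) {
  if (inherits(models, "library_model")) models <- list(models)
  chrom_len <- nchar(genome)
  with_seed(seed, {
    out <- lapply(models, function(m) {
      reads <- list()
      emit <- function(chrom, five, len, strand) {
        iv <- .bio_interval(five, len, strand)
        tibble::tibble(chrom = chrom, start = iv$start, end = iv$end,
                       strand = strand)
      }
      for (k in seq_len(nrow(truth))) {
        tr <- truth[k, ]
        sgn <- if (tr$strand == "+") 1L else -1L
        # transcript-direction helper: downstream by d nt
        down <- function(pos, d) pos + sgn * d
        n_mi5 <- .rnb(1, m$srna_mirna_depth, m$dispersion)
        n_mo5 <- .rnb(1, m$srna_morna_depth, m$dispersion)
        n_mi3 <- .rnb(1, m$srna_mirna_depth, m$dispersion)
        n_mo3 <- .rnb(1, m$srna_morna_depth, m$dispersion)
        if (n_mi5 > 0) {  # 5p miRNA-like: 5' end exactly at S
          len <- sample(mirna_lengths, n_mi5, replace = TRUE)
          reads[[length(reads) + 1]] <- emit(tr$chrom, rep(tr$S, n_mi5),
                                             len, tr$strand)
        }
        if (n_mo5 > 0) {  # 5p moRNA-like: 3' end at S - 1, ragged start
          len <- morna_min_length + rgeom(n_mo5, morna_length_p)
          five <- down(tr$S, -len)     # 5' end len nt upstream of S
          reads[[length(reads) + 1]] <- emit(tr$chrom, five, len, tr$strand)
        }
        if (n_mi3 > 0) {  # 3p miRNA-like: 3' end at D - 1 (transcript)
          len <- sample(mirna_lengths, n_mi3, replace = TRUE)
          five <- down(tr$D, -len)
          reads[[length(reads) + 1]] <- emit(tr$chrom, five, len, tr$strand)
        }
        if (n_mo3 > 0) {  # 3p moRNA-like: 5' end exactly at D
          len <- morna_min_length + rgeom(n_mo3, morna_length_p)
          reads[[length(reads) + 1]] <- emit(tr$chrom, rep(tr$D, n_mo3),
                                             len, tr$strand)
        }
      }
      bed <- if (length(reads)) dplyr::bind_rows(reads) else
        empty_bed6()[, c("chrom", "start", "end", "strand")]
      bed <- bed[bed$start >= 0 & bed$end <= chrom_len[bed$chrom], ]
      collapsed <- bed |>
        dplyr::count(.data$chrom, .data$start, .data$end, .data$strand,
                     name = "score") |>
        arrange(.data$chrom, .data$start, .data$end, .data$strand)
      n_u <- nrow(collapsed)
      tibble::tibble(
        chrom = collapsed$chrom, start = collapsed$start,
        end = collapsed$end,
        name = if (n_u) sprintf("%s:uread%06d", m$library_id,
                                seq_len(n_u)) else character(),
        score = as.numeric(collapsed$score), strand = collapsed$strand,
        library = rep(m$library_id, n_u))
    })
    dplyr::bind_rows(out)
  })
}
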