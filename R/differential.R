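#' Per-library raw 5'-start counts at candidate loci
#'
#' Assembles the count matrix for differential pile-up testing: rows are
#' candidate loci, columns are libraries, entries are raw `C5` counts
#' (reads starting at the locus).
#'
#' @param reads combined BED6-style read tibble with `library`,
#'   `condition` and `replicate` columns (as from [simulate_degradome()]).
#' @param loci tibble with `chrom`, `strand`, `pos`.
#' @return a `pileup_counts` object: integer matrix plus library metadata
#'   and library sizes.
#' @export
pileup_counts <- function(reads, loci) {
  stopifnot(all(c("library", "condition") %in% names(reads)))
  libs <- reads |>
    dplyr::distinct(.data$library, .data$condition,
                    .data$replicate) |>
    arrange(.data$condition, .data$replicate)
  tracks <- lapply(libs$library, function(l) {
    count_read_starts(reads[reads$library == l, ], library_id = l)
  })
  counts <- vapply(tracks, function(t) {
    track_count(t, loci$chrom, loci$strand, loci$pos)
  }, numeric(nrow(loci)))
  counts <- matrix(as.integer(counts), nrow = nrow(loci),
                   dimnames = list(paste(loci$chrom, loci$strand, loci$pos),
                                   libs$library))
  structure(
    list(counts = counts,
         loci = loci,
         lib_sizes = vapply(tracks, function(t) t$library_size, numeric(1)),
         meta = libs),
    class = "pileup_counts")
}

#' @export
print.pileup_counts <- function(x, ...) {
  cat(sprintf("<pileup_counts> %d loci x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-library scaling factors (edgeR),
#' rescaled to geometric mean 1. Library depth itself is absorbed by the
#' library sizes, not the factors.
#'
#' @param counts non-negative integer matrix (loci x libraries).
#' @param lib_sizes library sizes; default column sums.
#' @param trim_m,trim_a trim fractions for the M and A values.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        trim_m = 0.30, trim_a = 0.05) {
  if (any(colSums(counts) == 0))
    stop("library with all-zero counts: TMM undefined", call. = FALSE)
  f <- edgeR::calcNormFactors(counts, lib.size = lib_sizes, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(f, colnames(counts))
}

#' Differential pile-up test between knockout and control
#'
#' Negative-binomial testing of condition-dependent depletion, following
#' the Degradome analysis convention: TMM normalization, empirical-Bayes
#' dispersion estimation, then either a quasi-likelihood F-test
#' (`method = "qlf"`, the default) or a likelihood-ratio test
#' (`method = "lrt"`), with Benjamini-Hochberg FDR across tested loci.
#' `log2FC` is knockout minus control, so Drosha-dependent loss is
#' negative. Loci with zero counts in all libraries are excluded before
#' the FDR adjustment.
#'
#' @param x a [pileup_counts()] object, or a counts matrix.
#' @param conditions for a plain matrix: `"control"`/`"knockout"` per
#'   column (>= 2 replicates each).
#' @param lib_sizes for a plain matrix: library sizes per column.
#' @param method `"qlf"` or `"lrt"`.
#' @param lfc_cut,fdr_cut,two_sided dependence gate, see
#'   [call_dependent()].
#' @return tibble with one row per tested locus: `log2FC`, `p_value`,
#'   `fdr` and the `dependent` flag.
#' @export
test_differential <- function(x, conditions = NULL, lib_sizes = NULL,
                              method = c("qlf", "lrt"),
                              lfc_cut = -1.5, fdr_cut = 0.05,
                              two_sided = FALSE) {
  method <- match.arg(method)
  if (inherits(x, "pileup_counts")) {
    counts <- x$counts
    conditions <- x$meta$condition
    lib_sizes <- x$lib_sizes
    loci <- x$loci
  } else {
    counts <- x
    stopifnot(!is.null(conditions))
    lib_sizes <- lib_sizes %||% colSums(counts)
    loci <- tibble::tibble(locus = rownames(counts) %||%
                             as.character(seq_len(nrow(counts))))
  }
  conditions <- factor(conditions, levels = c("control", "knockout"))
  if (anyNA(conditions))
    stop("conditions must be 'control' or 'knockout'", call. = FALSE)
  if (any(table(conditions) < 2))
    stop("need at least 2 replicates per condition to estimate dispersion",
         call. = FALSE)
  keep <- rowSums(counts) > 0
  y <- edgeR::DGEList(counts = counts[keep, , drop = FALSE],
                      lib.size = lib_sizes, group = conditions)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  design <- stats::model.matrix(~conditions)
  y <- edgeR::estimateDisp(y, design)
  res <- if (method == "qlf") {
    fit <- edgeR::glmQLFit(y, design)
    edgeR::glmQLFTest(fit, coef = 2)
  } else {
    fit <- edgeR::glmFit(y, design)
    edgeR::glmLRT(fit, coef = 2)
  }
  tab <- res$table
  out <- loci[keep, , drop = FALSE]
  out$log2FC <- tab$logFC
  out$p_value <- tab$PValue
  out$fdr <- p.adjust(tab$PValue, method = "BH")
  call_dependent(out, lfc_cut = lfc_cut, fdr_cut = fdr_cut,
                 two_sided = two_sided)
}

#' Apply the condition-dependence gate
#'
#' A locus is condition-dependent when `log2FC < lfc_cut` (one-sided, loss
#' only; set `two_sided = TRUE` for `|log2FC| > |lfc_cut|`) and
#' `fdr < fdr_cut`.
#'
#' @param results tibble with `log2FC` and `fdr` columns.
#' @param lfc_cut log2 fold-change threshold (default -1.5).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param two_sided gate on magnitude rather than loss only.
#' @return `results` with a `dependent` logical column.
#' @export
call_dependent <- function(results, lfc_cut = -1.5, fdr_cut = 0.05,
                           two_sided = FALSE) {
  results$dependent <- if (two_sided) {
    abs(results$log2FC) > abs(lfc_cut) & results$fdr < fdr_cut
  } else {
    results$log2FC < lfc_cut & results$fdr < fdr_cut
  }
  results
}

#' Intersect two dependent-site lists
#'
#' Exact (chromosome, strand, position) intersection of the loci flagged
#' `dependent` in two differential results (e.g. Drosha- and
#' Dicer-dependent sites).
#'
#' @param results_a,results_b tibbles with `chrom`, `strand`, `pos` and
#'   `dependent` columns.
#' @return tibble of loci dependent in both.
#' @export
intersect_dependent <- function(results_a, results_b) {
  a <- results_a[results_a$dependent, c("chrom", "strand", "pos")]
  b <- results_b[results_b$dependent, c("chrom", "strand", "pos")]
  dplyr::inner_join(a, b, by = c("chrom", "strand", "pos"))
}
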