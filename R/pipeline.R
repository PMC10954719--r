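#' Desk-scale run configuration
#'
#' The default configuration reproduces the desk-preset synthetic world:
#' a 100 kb genome with 200 planted Drosha-substrate hairpins (120
#' miRNA-class, 80 mRNA-class), two control and two knockout Degradome
#' libraries, one collapsed sRNA library, and 100 consensus iterations
#' (vote fractions, not absolute counts, define acceptance). Unknown keys
#' are rejected.
#'
#' @param seed global seed; per-stage substreams are derived from it.
#' @param ... overrides of the defaults listed below.
#' @return a `run_config` list echoed verbatim into the run object.
#' @export
desk_config <- function(seed = 1L, ...) {
  config <- list(
    seed = as.integer(seed),
    n_mirna_like = 120,
    n_mrna_like = 80,
    genome_length = 100000,
    spacing = 200,
    depletion_factor = 0.1,
    signal_depth = 100,
    dispersion = 0.1,
    background_rate = 0.005,
    srna_mirna_depth = 50,
    srna_morna_depth = 15,
    jitter = 0.05,
    n_iterations = 100,
    accept_fraction = 0.9,
    n_negatives = 1000,
    cv_folds = 10,
    n_decoy_sites = 600,
    rpm_min = 1.0,
    scan_window = c(25, 100),
    flank = 15,
    annotate_flank = 25,
    max_shift = 2,
    overhang_range = c(0, 4),
    lfc_cut = -1.5,
    fdr_cut = 0.05,
    differential_method = "qlf",
    backend = "toy")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config[names(dots)] <- dots
  structure(config, class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> pile-up consensus -> differential -> stem-loop
#' reconstruction -> feature analysis as one reproducible run. Every stage
#' draws from an independent substream of the global seed, so reruns are
#' bit-identical and stages can be reproduced in isolation.
#'
#' @param config a [desk_config()].
#' @param keep_reads retain the simulated read tables in the result
#'   (larger object).
#' @return a `drosha_run` object bundling the truth table, classifier,
#'   pile-up sites, differential results, stem-loop calls, feature table
#'   and a per-stage count report. Use [glance()] for a one-row summary.
#' @export
run_pipeline <- function(config = desk_config(), keep_reads = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- simulate ---------------------------------------------------------
  world <- build_genome(config$n_mirna_like, config$n_mrna_like,
                        config$genome_length,
                        seed = stage_seed(seed, "genome"),
                        spacing = config$spacing,
                        depletion_factor = config$depletion_factor,
                        n_decoy_sites = config$n_decoy_sites)
  truth <- world$truth
  libs <- desk_libraries(signal_depth = config$signal_depth,
                         dispersion = config$dispersion,
                         background_rate = config$background_rate,
                         srna_mirna_depth = config$srna_mirna_depth,
                         srna_morna_depth = config$srna_morna_depth,
                         jitter = config$jitter)
  degradome <- simulate_degradome(truth, libs, world$genome,
                                  seed = stage_seed(seed, "degradome"),
                                  decoys = world$decoys)
  srna <- simulate_srna(truth, libs[[1]], world$genome,
                        seed = stage_seed(seed, "srna"))
  chrom_sizes <- nchar(world$genome)

  # --- pile-up consensus ------------------------------------------------
  control_ids <- vapply(libs, function(m)
    if (m$condition == "control") m$library_id else NA_character_,
    character(1))
  control_ids <- control_ids[!is.na(control_ids)]
  tracks <- lapply(control_ids, function(l)
    count_read_starts(degradome[degradome$library == l, ],
                      library_id = l))
  positives <- tibble::tibble(chrom = truth$chrom, strand = truth$strand,
                              pos = truth$D)
  classifier <- train_pileup_classifier(
    tracks[[1]], positives, chrom_sizes,
    n_negatives = config$n_negatives, cv_folds = config$cv_folds,
    seed = stage_seed(seed, "train"))
  pileups <- consensus_pileup(
    tracks, positives, chrom_sizes,
    n_iterations = config$n_iterations,
    accept_fraction = config$accept_fraction,
    n_negatives = config$n_negatives, cv_folds = config$cv_folds,
    seed = stage_seed(seed, "consensus"))
  accepted <- pileups[pileups$accepted, c("chrom", "strand", "pos")]

  # --- differential -----------------------------------------------------
  counts <- pileup_counts(degradome, accepted)
  differential <- test_differential(counts,
                                    method = config$differential_method,
                                    lfc_cut = config$lfc_cut,
                                    fdr_cut = config$fdr_cut)
  anchors <- differential[differential$dependent,
                          c("chrom", "strand", "pos")]

  # --- stem-loop reconstruction ----------------------------------------
  calls <- call_stemloops(anchors, srna, world$genome,
                          rpm_min = config$rpm_min,
                          window = config$scan_window,
                          flank = config$flank,
                          max_shift = config$max_shift,
                          overhang_range = config$overhang_range)

  # --- features & classification ---------------------------------------
  resolved <- calls[calls$resolved, ]
  features <- if (nrow(resolved)) {
    f <- stemloop_features(resolved, world$genome)
    cls <- classify_calls(resolved, truth_annotation(truth))
    f$class <- cls$class
    f$context <- cls$context
    f
  } else tibble::tibble()

  report <- tibble::tibble(
    n_planted = nrow(truth),
    n_candidates = nrow(pileups),
    n_accepted_pileups = nrow(accepted),
    n_dependent = nrow(anchors),
    n_resolved = sum(calls$resolved),
    n_unresolved = sum(!calls$resolved),
    sensitivity = classifier$metrics$sensitivity,
    specificity = classifier$metrics$specificity,
    auc = classifier$metrics$auc,
    n_mirna_class = sum(features$class == "miRNA"),
    n_non_mirna_class = sum(features$class == "non-miRNA"))

  structure(
    list(config = config, truth = truth, genome = world$genome,
         classifier = classifier, pileups = pileups,
         differential = differential, calls = calls,
         features = features, report = report,
         reads = if (keep_reads) list(degradome = degradome, srna = srna)
                 else NULL),
    class = "drosha_run")
}

#' @export
print.drosha_run <- function(x, ...) {
  r <- x$report
  cat("<drosha_run>\n")
  cat(sprintf("  planted hairpins:     %d\n", r$n_planted))
  cat(sprintf("  candidate loci:       %d\n", r$n_candidates))
  cat(sprintf("  accepted pile-ups:    %d\n", r$n_accepted_pileups))
  cat(sprintf("  Drosha-dependent:     %d\n", r$n_dependent))
  cat(sprintf("  resolved stem-loops:  %d (+%d unresolved)\n",
              r$n_resolved, r$n_unresolved))
  cat(sprintf("  classifier:           sens %.3f spec %.3f auc %.3f\n",
              r$sensitivity, r$specificity, r$auc))
  cat(sprintf("  classes:              %d miRNA / %d non-miRNA\n",
              r$n_mirna_class, r$n_non_mirna_class))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object a `drosha_run`.
#' @param ... unused.
#' @method glance drosha_run
#' @export
glance.drosha_run <- function(x, ...) {
  x$report
}

#' Annotation tibble for a synthetic truth table
#'
#' Represents each planted hairpin's product span as an annotation
#' feature: miRNA-class hairpins as `miRNA`, mRNA-class hairpins as `CDS`
#' (exonic stem-loops).
#'
#' @param truth truth table from [build_genome()].
#' @return tibble with `chrom`, `start`, `end`, `strand`, `type`.
#' @export
truth_annotation <- function(truth) {
  pstart <- ifelse(truth$strand == "+", truth$S, truth$D + 1L)
  pend <- ifelse(truth$strand == "+", truth$D, truth$S + 1L)
  tibble::tibble(
    chrom = truth$chrom, start = as.integer(pstart),
    end = as.integer(pend), strand = truth$strand,
    type = ifelse(truth$class_label == "miRNA-like", "miRNA", "CDS"))
}

#' Classify stem-loop calls against an annotation
#'
#' A call is miRNA-class when its product span overlaps an annotated
#' miRNA hairpin on the same strand; otherwise non-miRNA. Genomic context
#' is assigned by the highest-priority overlapping feature
#' (miRNA > CDS > five_utr > three_utr > intron > lncRNA_exon >
#' intergenic).
#'
#' @param calls resolved calls from [call_stemloops()].
#' @param annotation tibble with `chrom`, `start`, `end`, `strand`,
#'   `type` (0-based half-open).
#' @return tibble with `class` and `context` per call.
#' @export
classify_calls <- function(calls, annotation) {
  bad <- setdiff(unique(calls$chrom), unique(annotation$chrom))
  if (length(bad) && nrow(annotation))
    stop("contig(s) absent from the annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  priority <- c("miRNA", "CDS", "five_utr", "three_utr", "intron",
                "lncRNA_exon")
  # product span in genomic half-open coordinates, both orientations:
  # transcript-wise the product runs from its five-site f to the position
  # before the three-junction t
  f <- ifelse(calls$orientation == "upstream", calls$S, calls$D)
  t <- ifelse(calls$orientation == "upstream", calls$D, calls$S)
  lo <- ifelse(calls$strand == "+", f, t + 1L)
  hi <- ifelse(calls$strand == "+", t, f + 1L)
  out <- lapply(seq_len(nrow(calls)), function(i) {
    ov <- annotation[annotation$chrom == calls$chrom[i] &
                       annotation$strand == calls$strand[i] &
                       annotation$start < hi[i] &
                       annotation$end > lo[i], ]
    ctx <- if (!nrow(ov)) "intergenic" else {
      hits <- priority[priority %in% ov$type]
      if (length(hits)) hits[1] else "intergenic"
    }
    tibble::tibble(class = if (ctx == "miRNA") "miRNA" else "non-miRNA",
                   context = ctx)
  })
  bind_rows(out)
}
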