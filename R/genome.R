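#' Random spec generators for the two substrate classes
#'
#' `mirna_like_spec()` draws a canonical miRNA substrate: a ~35 +/- 1 bp
#' upper stem, an 11-14 nt terminal loop, at most one small symmetric
#' internal loop, G-C-rich pairing and the full motif complement.
#' `mrna_like_spec()` draws a suboptimal (mRNA-type) substrate: a ~26 bp
#' stem, variable loop, 1-3 asymmetric internal loops, weaker pairing and
#' no miRNA motifs.
#'
#' @return a [hairpin_spec()].
#' @export
mirna_like_spec <- function() {
  n_loops <- rbinom(1, 1, 0.3)
  il <- list()
  if (n_loops) {
    sz <- sample(1:2, 1)
    il <- list(c(sample(5:25, 1), sz, sz))
  }
  hairpin_spec(stem_length = sample(34:36, 1),
               loop_length = sample(11:14, 1),
               lower_stem_length = 13,
               internal_loops = il,
               overhang = 2,
               motif_flags = c("basal_UG", "apical_UGU", "CNNC"),
               gc_bias = c(0.60, 0.32, 0.08))
}

#' @rdname mirna_like_spec
#' @export
mrna_like_spec <- function() {
  stem <- sample(24:28, 1)
  n_loops <- sample(1:3, 1)
  il <- list()
  pos <- 3
  for (k in seq_len(n_loops)) {
    pos <- pos + sample(0:4, 1)
    s5 <- sample(0:3, 1)
    s3 <- sample(0:3, 1)
    if (s5 == s3) s3 <- s3 + 1          # keep them asymmetric
    span <- max(s5, s3)
    if (pos + span - 1 > stem - 2) break
    il <- c(il, list(c(pos, s5, s3)))
    pos <- pos + span + 2
  }
  hairpin_spec(stem_length = stem,
               loop_length = sample(4:16, 1),
               lower_stem_length = 13,
               internal_loops = il,
               overhang = 2,
               motif_flags = character(),
               gc_bias = c(0.38, 0.48, 0.14))
}

#' Build a toy genome with planted Drosha-substrate hairpins
#'
#' Generates an i.i.d.-uniform background sequence and embeds
#' `n_mirna_like` miRNA-class and `n_mrna_like` mRNA-class hairpins
#' (designed by [design_hairpin()]) at non-overlapping positions on random
#' strands, with at least `spacing` nt between planted regions. Every
#' planted hairpin is checked for discoverability: the cleavage-site pair
#' must satisfy 25 <= |D - S| <= 100 and the sequence must refold with the
#' planted duplex end.
#'
#' @param n_mirna_like,n_mrna_like number of hairpins per class.
#' @param genome_length total length in nt.
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @param spacing minimum gap between planted regions.
#' @param chrom chromosome name.
#' @param depletion_factor mean-depth multiplier for Drosha-dependent loci
#'   in knockout libraries.
#' @param n_decoy_sites Drosha-independent cleavage sites planted as plain
#'   pile-up positions (no hairpin, no knockout depletion). Degradome
#'   libraries are dominated by such sites — in the original data only
#'   about a quarter of pile-up sites were Drosha-dependent — and they
#'   anchor the TMM normalization of the differential test.
#' @param mirna_spec_fn,mrna_spec_fn spec generators, by default
#'   [mirna_like_spec()] and [mrna_like_spec()].
#' @return list with `genome` (named character vector, DNA), `truth`,
#'   a tibble with one row per planted hairpin: locus id, coordinates
#'   (0-based), strand, genomic cleavage sites `S` and `D` (positions of
#'   the first nucleotide of the excised product and of the downstream
#'   fragment, in biological orientation), planted structure and class,
#'   and `decoys`, the Drosha-independent cleavage positions.
#' @export
build_genome <- function(n_mirna_like, n_mrna_like, genome_length,
                         seed = 1L, spacing = 200,
                         chrom = "chrS", depletion_factor = 0.1,
                         n_decoy_sites = 0,
                         mirna_spec_fn = mirna_like_spec,
                         mrna_spec_fn = mrna_like_spec) {
  with_seed(seed, {
    n <- n_mirna_like + n_mrna_like
    classes <- sample(rep(c("miRNA-like", "mRNA-like"),
                          c(n_mirna_like, n_mrna_like)))
    designs <- lapply(classes, function(cl) {
      for (attempt in 1:20) {
        spec <- if (cl == "miRNA-like") mirna_spec_fn() else mrna_spec_fn()
        hp <- tryCatch(design_hairpin(spec), error = function(e) NULL)
        if (!is.null(hp) && hp$D - hp$S >= 25 && hp$D - hp$S <= 100)
          return(hp)
      }
      stop("could not design a discoverable hairpin after 20 attempts",
           call. = FALSE)
    })
    lens <- vapply(designs, function(h) nchar(h$sequence), integer(1))
    need <- sum(lens) + max(n - 1, 0) * spacing
    if (need > genome_length)
      stop("genome_length too small: need at least ", need,
           " nt to place ", n, " loci with ", spacing, " nt spacing",
           call. = FALSE)

    genome_chr <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    starts <- integer(0)
    if (n > 0) {
      extra <- genome_length - need
      parts <- floor(diff(c(0, sort(runif(n)), 1)) * extra)
      gaps <- parts[seq_len(n)] + c(0, rep(spacing, n - 1))
      starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
    }
    strands <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character()

    rows <- vector("list", n)
    for (k in seq_len(n)) {
      hp <- designs[[k]]
      len <- lens[k]
      g0 <- starts[k]
      dna <- chartr("U", "T", hp$sequence)
      if (strands[k] == "-") dna <- revcomp_dna(dna)
      genome_chr[(g0 + 1):(g0 + len)] <- strsplit(dna, "")[[1]]
      loc <- function(off) {
        if (strands[k] == "+") g0 + off else g0 + len - 1L - off
      }
      rows[[k]] <- tibble::tibble(
        locus_id = sprintf("hp%03d", k),
        chrom = chrom, strand = strands[k],
        region_start = g0, region_end = g0 + len,
        S = loc(hp$S), D = loc(hp$D),
        span = hp$D - hp$S,
        overhang = hp$overhang,
        n_pairs = hp$n_pairs,
        S_local = hp$S, D_local = hp$D,
        dot_bracket = hp$dot_bracket,
        sequence = hp$sequence,
        class_label = classes[k],
        drosha_dependent = TRUE,
        depletion_factor = depletion_factor)
    }
    truth <- if (n > 0) dplyr::bind_rows(rows) else tibble::tibble(
      locus_id = character(), chrom = character(), strand = character(),
      region_start = integer(), region_end = integer(),
      S = integer(), D = integer(), span = integer(), overhang = integer(),
      n_pairs = integer(), S_local = integer(), D_local = integer(),
      dot_bracket = character(), sequence = character(),
      class_label = character(), drosha_dependent = logical(),
      depletion_factor = numeric())
    genome <- stats::setNames(paste(genome_chr, collapse = ""), chrom)
    # Drosha-independent decoy pile-up sites, clear of planted regions
    decoys <- tibble::tibble(site_id = character(), chrom = character(),
                             strand = character(), pos = integer())
    if (n_decoy_sites > 0) {
      forbidden <- unlist(lapply(seq_len(n), function(k) {
        (starts[k] - 150):(starts[k] + lens[k] + 150)
      }))
      free <- setdiff(seq_len(genome_length) - 1L, forbidden)
      if (length(free) < n_decoy_sites)
        stop("not enough genome left for ", n_decoy_sites, " decoy sites",
             call. = FALSE)
      pos <- sample(free, n_decoy_sites)
      decoys <- tibble::tibble(
        site_id = sprintf("decoy%04d", seq_len(n_decoy_sites)),
        chrom = chrom,
        strand = sample(c("+", "-"), n_decoy_sites, replace = TRUE),
        pos = as.integer(pos))
    }
    list(genome = genome, truth = truth, decoys = decoys)
  })
}

#' Write / read a genome as FASTA
#'
#' Thin wrappers over Biostrings for the package's named-character genome
#' representation.
#'
#' @param genome named character vector of DNA sequences.
#' @param path file path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA output", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA input", call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
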