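#' Find small-RNA terminus stacks around a Degradome anchor
#'
#' Scans both 25-100 nt windows (upstream and downstream in transcript
#' direction) around a Degradome pile-up site `D` for positions where
#' collapsed sRNA-seq read 5' starts or 3' ends stack above `rpm_min`.
#' A start stack at position `p` implies a cleavage site at `p` (the first
#' nucleotide of a cleavage product); an end stack at `p` implies a
#' cleavage site one nt further downstream (the cut lies between the
#' moRNA-like 3' end and the next product).
#'
#' @param start_track,end_track `start_track` objects built from the same
#'   collapsed sRNA library with [count_read_starts()] and
#'   [count_read_ends()] (`weight = "score"`).
#' @param chrom,strand,D anchor locus (0-based).
#' @param rpm_min minimum stacked depth in reads per million.
#' @param window implied-site distance range, closed interval.
#' @return tibble of qualifying stacks: `site` (genomic position of the
#'   implied cleavage site), `delta` (signed transcript offset from `D`),
#'   `side`, `rpm` and raw `count`.
#' @export
find_terminus_stacks <- function(start_track, end_track, chrom, strand, D,
                                 rpm_min = 1.0, window = c(25, 100)) {
  sgn <- if (strand == "+") 1L else -1L
  # implied-site transcript offsets delta in the two windows
  deltas <- c(-(window[2]:window[1]), window[1]:window[2])
  # start stacks: implied site == read start position
  start_pos <- D + sgn * deltas
  start_rpm <- track_rpm(start_track, chrom, strand, start_pos)
  start_cnt <- track_count(start_track, chrom, strand, start_pos)
  # end stacks at transcript offset delta - 1 imply a site at delta
  end_pos <- D + sgn * (deltas - 1L)
  end_rpm <- track_rpm(end_track, chrom, strand, end_pos)
  end_cnt <- track_count(end_track, chrom, strand, end_pos)
  rpm <- start_rpm + end_rpm
  keep <- rpm > rpm_min
  tibble::tibble(
    chrom = chrom, strand = strand, D = D,
    site = start_pos[keep],
    delta = deltas[keep],
    side = ifelse(deltas[keep] < 0, "upstream", "downstream"),
    rpm = rpm[keep],
    count = start_cnt[keep] + end_cnt[keep])
}

#' Compute the 3' overhang at a duplex end
#'
#' Given a folded window and the product's boundary indices, returns the
#' signed 3' overhang: `three_end_idx - partner(five_idx)`. When
#' `five_idx` itself is unpaired the duplex end is located by sliding up to
#' `max_shift` nt inward with compensation. RNase III (Drosha) cleavage
#' leaves an overhang of 2; callers apply the 2 +/- 2 acceptance window.
#'
#' @param structure an `rna_structure`.
#' @param five_idx 1-based window index of the product's 5'-most
#'   nucleotide.
#' @param three_end_idx 1-based window index of the product's 3'-most
#'   nucleotide.
#' @param max_shift maximum inward slide when `five_idx` is unpaired.
#' @return signed overhang in nt.
#' @export
compute_overhang <- function(structure, five_idx, three_end_idx,
                             max_shift = 2) {
  pt <- structure$pair_table
  n <- length(pt)
  stopifnot(five_idx >= 1, three_end_idx <= n, five_idx < three_end_idx)
  for (k in 0:max_shift) {
    idx <- five_idx + k
    if (idx <= n && !is.na(pt[idx]))
      return((three_end_idx - pt[idx]) - k)
  }
  rlang::abort(
    sprintf("no paired position within %d nt of the product 5' end",
            max_shift),
    class = "droshascan_no_duplex")
}

#' Reconstruct one candidate stem-loop
#'
#' Folds the window between a terminus stack and its Degradome anchor with
#' `flank` nt on each side and tests the RNase III overhang geometry.
#' For an upstream stack (canonical orientation) the excised product runs
#' from the stack site `S` to `D - 1` and the folded window is
#' `[S - flank, D + flank]`; for a downstream stack (single 5'-arm
#' cleavage, inverse orientation) the product runs from `D` to `site - 1`
#' and the window is `[D - flank, site - 1 + flank]` (transcript
#' coordinates). The call is accepted when the computed overhang lies in
#' `overhang_range`.
#'
#' @param genome named character vector.
#' @param stack one-row tibble from [find_terminus_stacks()].
#' @param flank flank length in nt.
#' @param params folding model parameters.
#' @param max_shift see [compute_overhang()].
#' @param overhang_range closed acceptance interval (2 +/- 2 by default).
#' @return one-row tibble describing the call.
#' @export
reconstruct_stemloop <- function(genome, stack, flank = 15,
                                 params = fold_params(), max_shift = 2,
                                 overhang_range = c(0, 4)) {
  chrom <- stack$chrom; strand <- stack$strand
  D <- stack$D; delta <- stack$delta
  sgn <- if (strand == "+") 1L else -1L
  if (delta < 0) {           # canonical: hairpin 5' of D
    lo <- delta - flank; hi <- flank
    five_off <- delta; three_end_off <- -1L
    orientation <- "upstream"
  } else {                   # inverse: hairpin 3' of D
    lo <- -flank; hi <- delta - 1L + flank
    five_off <- 0L; three_end_off <- delta - 1L
    orientation <- "downstream"
  }
  # transcript offsets [lo, hi] inclusive -> genomic half-open interval
  len <- nchar(genome[[chrom]])
  lo_ok <- if (strand == "+") max(lo, -D) else max(lo, D - (len - 1L))
  hi_ok <- if (strand == "+") min(hi, len - 1L - D) else min(hi, D)
  clipped <- lo_ok != lo || hi_ok != hi
  if (clipped) {
    warning("stem-loop window truncated at chromosome boundary",
            call. = FALSE)
    lo <- lo_ok; hi <- hi_ok
  }
  g <- sort(c(D + sgn * lo, D + sgn * hi))
  g_start <- g[1]; g_end <- g[2] + 1L
  seq <- extract_rna(genome, chrom, g_start, g_end, strand)
  five_idx <- five_off - lo + 1L
  three_end_idx <- three_end_off - lo + 1L
  st <- rna_fold(seq, params = params)
  overhang <- tryCatch(
    compute_overhang(st, five_idx, three_end_idx, max_shift = max_shift),
    droshascan_no_duplex = function(e) NA_integer_)
  accepted <- !is.na(overhang) &&
    overhang >= overhang_range[1] && overhang <= overhang_range[2]
  tibble::tibble(
    chrom = chrom, strand = strand, D = D,
    S = stack$site, delta = delta, orientation = orientation,
    window_start = g_start, window_end = g_end,
    five_idx = five_idx, three_end_idx = three_end_idx,
    sequence = seq, dot_bracket = st$dot_bracket, mfe = st$mfe,
    overhang = as.integer(overhang),
    srna_rpm = stack$rpm,
    clipped = clipped,
    accepted = accepted,
    reason = if (accepted) NA_character_ else if (is.na(overhang))
      "no duplex at product 5' end" else "overhang outside 2 +/- 2")
}

#' Call Drosha-cleaved stem-loops for a set of Degradome anchors
#'
#' For every anchor, evaluates every qualifying sRNA terminus stack in both
#' orientations with [reconstruct_stemloop()] and retains, among accepted
#' candidates, the one with the highest supporting sRNA depth; ties are
#' broken by overhang closest to 2, then by the shorter hairpin, then by
#' the most-upstream site. Anchors with no accepted candidate are reported
#' unresolved.
#'
#' @param anchors tibble with `chrom`, `strand`, `pos` (accepted pile-up
#'   loci, e.g. Drosha-dependent sites).
#' @param srna_reads collapsed sRNA BED6 tibble (one library; score =
#'   multiplicity).
#' @param genome named character vector.
#' @param rpm_min,window see [find_terminus_stacks()].
#' @param flank,params,max_shift,overhang_range see
#'   [reconstruct_stemloop()].
#' @return tibble with one row per anchor: the best accepted call, or an
#'   unresolved row with the rejection reason. `resolved` flags success.
#' @export
call_stemloops <- function(anchors, srna_reads, genome, rpm_min = 1.0,
                           window = c(25, 100), flank = 15,
                           params = fold_params(), max_shift = 2,
                           overhang_range = c(0, 4)) {
  start_track <- count_read_starts(srna_reads, weight = "score")
  end_track <- count_read_ends(srna_reads, weight = "score")
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    stacks <- find_terminus_stacks(start_track, end_track,
                                   a$chrom, a$strand, a$pos,
                                   rpm_min = rpm_min, window = window)
    unresolved <- tibble::tibble(
      chrom = a$chrom, strand = a$strand, D = a$pos,
      S = NA_integer_, delta = NA_integer_,
      orientation = NA_character_,
      window_start = NA_integer_, window_end = NA_integer_,
      five_idx = NA_integer_, three_end_idx = NA_integer_,
      sequence = NA_character_, dot_bracket = NA_character_,
      mfe = NA_real_, overhang = NA_integer_, srna_rpm = NA_real_,
      clipped = NA, accepted = FALSE, resolved = FALSE,
      reason = "no terminus stack above RPM threshold")
    if (!nrow(stacks)) return(unresolved)
    cands <- dplyr::bind_rows(lapply(seq_len(nrow(stacks)), function(j) {
      reconstruct_stemloop(genome, stacks[j, ], flank = flank,
                           params = params, max_shift = max_shift,
                           overhang_range = overhang_range)
    }))
    acc <- cands[cands$accepted, ]
    if (!nrow(acc)) {
      unresolved$reason <- "no candidate passed the overhang test"
      return(unresolved)
    }
    best <- acc |>
      arrange(desc(.data$srna_rpm), abs(.data$overhang - 2),
              abs(.data$delta), .data$delta) |>
      dplyr::slice(1)
    best$resolved <- TRUE
    best
  })
  bind_rows(rows)
}
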