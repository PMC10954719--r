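#' Specify a Drosha-substrate hairpin to plant
#'
#' Describes the geometry of a stem-loop the way Drosha sees it: a basal
#' (lower) stem of `lower_stem_length` base pairs below the cleavage site,
#' an upper stem of `stem_length` rungs carrying the excised product,
#' a terminal loop, and optional internal loops. The Drosha cut sits at the
#' lower/upper stem junction and leaves a 3' overhang of `overhang` nt.
#'
#' Internal loops are given as a list of `c(position, size5, size3)`:
#' `position` is the rung of the upper stem (1 = first rung above the
#' cleavage site) where the loop starts; the loop replaces
#' `max(size5, size3)` rungs with `size5` unpaired nt on the 5' arm and
#' `size3` on the 3' arm. A symmetric loop has `size5 == size3`; a bulge
#' has one side of size 0.
#'
#' @param stem_length rungs (base pairs before loop removal) in the upper
#'   stem. Canonical miRNA substrates have ~35; non-miRNA substrates ~26.
#' @param loop_length unpaired nt in the terminal loop (>= 3).
#' @param lower_stem_length base pairs basal of the cleavage site.
#' @param internal_loops list of `c(position, size5, size3)` triples.
#' @param overhang planted 3' overhang in nt (canonical RNase III: 2).
#' @param motif_flags subset of `c("basal_UG", "apical_UGU", "CNNC")` to
#'   plant at their canonical windows.
#' @param gc_bias length-3 probability vector for drawing each planted pair
#'   as G-C, A-U or G-U.
#' @param flank_ss single-stranded flank length emitted on each side.
#' @return a `hairpin_spec` list.
#' @export
hairpin_spec <- function(stem_length = 35, loop_length = 11,
                         lower_stem_length = 13, internal_loops = list(),
                         overhang = 2,
                         motif_flags = c("basal_UG", "apical_UGU", "CNNC"),
                         gc_bias = c(0.55, 0.35, 0.10), flank_ss = 25) {
  spec <- structure(
    list(stem_length = as.integer(stem_length),
         loop_length = as.integer(loop_length),
         lower_stem_length = as.integer(lower_stem_length),
         internal_loops = internal_loops,
         overhang = as.integer(overhang),
         motif_flags = motif_flags,
         gc_bias = gc_bias / sum(gc_bias),
         flank_ss = as.integer(flank_ss)),
    class = "hairpin_spec")
  validate_hairpin_spec(spec)
  spec
}

validate_hairpin_spec <- function(spec) {
  with(spec, {
    if (loop_length < 3)
      stop("infeasible hairpin spec: loop_length must be >= 3", call. = FALSE)
    if (lower_stem_length < 0 || stem_length < lower_stem_length)
      stop("infeasible hairpin spec: need stem_length >= lower_stem_length >= 0",
           call. = FALSE)
    if (overhang < 0)
      stop("infeasible hairpin spec: overhang must be >= 0", call. = FALSE)
    if (overhang > lower_stem_length + flank_ss - 1)
      stop("infeasible hairpin spec: overhang extends past the emitted region",
           call. = FALSE)
    if (length(internal_loops)) {
      il <- do.call(rbind, internal_loops)
      if (ncol(il) != 3 || any(il[, 2] + il[, 3] < 1) || any(il[, 2] < 0))
        stop("internal loops must be c(position, size5, size3) with size5+size3 >= 1",
             call. = FALSE)
      span <- pmax(il[, 2], il[, 3])
      # keep >= 2 pairs at the stem ends and between loops so planted
      # helices survive the lone-pair ban
      if (any(il[, 1] < 3) || any(il[, 1] + span - 1 > stem_length - 2))
        stop("infeasible hairpin spec: internal loop larger than the stem allows",
             call. = FALSE)
      o <- order(il[, 1])
      il <- il[o, , drop = FALSE]
      if (nrow(il) > 1 &&
          any(il[-1, 1] - (il[-nrow(il), 1] + span[o][-nrow(il)]) < 2))
        stop("infeasible hairpin spec: internal loops too close together",
             call. = FALSE)
    }
    if (length(gc_bias) != 3 || any(gc_bias < 0))
      stop("gc_bias must be three non-negative probabilities", call. = FALSE)
  })
  invisible(spec)
}

# set sequence position to a base; if planted-paired, keep the partner
# Watson-Crick complementary
.plant_base <- function(seq_chr, pt, pos, base) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seq_chr[pos] <- base
  if (!is.na(pt[pos])) seq_chr[pt[pos]] <- comp[[base]]
  seq_chr
}

#' Design the sequence and structure of a planted hairpin
#'
#' Realizes a [hairpin_spec()] as an RNA sequence plus its planted
#' dot-bracket, with cleavage offsets: `S` is the 0-based offset of the
#' first nucleotide of the excised product (the 5'-arm cut lies between
#' `S - 1` and `S`), `D` the offset of the first nucleotide of the
#' downstream fragment. `S` and `D - 1` bound a duplex end with the planted
#' 3' overhang. Unpaired regions are drawn from A/C so they cannot pair
#' with each other, and requested sequence motifs are written into their
#' canonical windows.
#'
#' @param spec a [hairpin_spec()].
#' @param check_fold verify with [rna_fold()] that the minimum-free-energy
#'   structure reproduces the planted duplex end (error if not).
#' @return list with `sequence` (RNA), `dot_bracket`, `pair_table`, `S`,
#'   `D` (0-based offsets), `overhang`, `n_pairs` and the spec.
#' @examples
#' hp <- design_hairpin(hairpin_spec(stem_length = 30, loop_length = 6))
#' substr(hp$dot_bracket, hp$S + 1, hp$S + 1)
#' @export
design_hairpin <- function(spec, check_fold = TRUE) {
  validate_hairpin_spec(spec)
  L <- spec$lower_stem_length
  K <- L + spec$stem_length          # rungs before loop removal
  fl <- spec$flank_ss

  # walk the 5' and 3' strands rung by rung, inserting internal loops
  il <- if (length(spec$internal_loops))
    do.call(rbind, spec$internal_loops) else matrix(0L, 0, 3)
  if (nrow(il)) il <- il[order(il[, 1]), , drop = FALSE]
  five_types <- character(0)   # per 5'-strand nt: "pair" or "loop"
  three_types <- character(0)
  rung <- 1L
  li <- 1L
  while (rung <= K) {
    upper_pos <- rung - L        # rung position within the upper stem
    if (li <= nrow(il) && upper_pos == il[li, 1]) {
      s5 <- il[li, 2]; s3 <- il[li, 3]
      five_types <- c(five_types, rep("loop", s5))
      three_types <- c(three_types, rep("loop", s3))
      rung <- rung + max(s5, s3)
      li <- li + 1L
    } else {
      five_types <- c(five_types, "pair")
      three_types <- c(three_types, "pair")
      rung <- rung + 1L
    }
  }
  n5 <- length(five_types)
  n3 <- length(three_types)
  n <- fl + n5 + spec$loop_length + n3 + fl
  # local 0-based layout: [flank][5' strand][loop][3' strand][flank]
  five_idx <- fl + seq_len(n5)                   # 1-based local positions
  loop_idx <- fl + n5 + seq_len(spec$loop_length)
  three_idx <- fl + n5 + spec$loop_length + seq_len(n3)

  pt <- rep(NA_integer_, n)
  p5 <- five_idx[five_types == "pair"]           # basal -> apical
  p3 <- rev(three_idx[rev(three_types) == "pair"])  # matched to p5 order
  # p3 must be apical -> basal along the 3' strand; rev(three_types) walks
  # basal -> apical on the 3' strand, so flip to pair with p5
  pt[p5] <- p3
  pt[p3] <- p5

  seq_chr <- sample(c("A", "C"), n, replace = TRUE)
  # terminal-loop filler is C-only: C pairs neither itself nor the
  # planted U/G/U, and a planted G cannot recruit a stacking neighbour,
  # so the lone-pair ban keeps the loop open under the built-in model
  seq_chr[loop_idx] <- "C"
  pair_kind <- sample(c("GC", "AU", "GU"), length(p5), replace = TRUE,
                      prob = spec$gc_bias)
  flip <- runif(length(p5)) < 0.5
  left <- substr(pair_kind, 1, 2)
  b5 <- ifelse(flip, substr(pair_kind, 2, 2), substr(pair_kind, 1, 1))
  b3 <- ifelse(flip, substr(pair_kind, 1, 1), substr(pair_kind, 2, 2))
  seq_chr[p5] <- b5
  seq_chr[p3] <- b3

  S <- fl + L          # 0-based offset of first product nt
  partner_S <- pt[S + 1] - 1L                    # 0-based
  D <- partner_S + spec$overhang + 1L

  if ("basal_UG" %in% spec$motif_flags && S - 14 >= 0) {
    seq_chr <- .plant_base(seq_chr, pt, S - 14 + 1, "U")
    seq_chr <- .plant_base(seq_chr, pt, S - 13 + 1, "G")
  }
  if ("apical_UGU" %in% spec$motif_flags && spec$loop_length >= 3) {
    for (k in 1:3)
      seq_chr <- .plant_base(seq_chr, pt, loop_idx[k], c("U", "G", "U")[k])
  }
  if ("CNNC" %in% spec$motif_flags && D + 19 <= n - 1) {
    seq_chr <- .plant_base(seq_chr, pt, D + 16 + 1, "C")
    seq_chr <- .plant_base(seq_chr, pt, D + 19 + 1, "C")
  }

  out <- list(sequence = paste(seq_chr, collapse = ""),
              dot_bracket = pairs_to_dotbracket(pt),
              pair_table = pt,
              S = S, D = D, overhang = spec$overhang,
              n_pairs = length(p5), spec = spec)
  if (check_fold) {
    st <- rna_fold(out$sequence)
    got <- st$pair_table[S + 1]
    if (is.na(got) || got - 1L != D - 1L - spec$overhang)
      stop("designed hairpin does not refold with the planted duplex end; ",
           "try a stronger gc_bias or longer stem", call. = FALSE)
  }
  out
}
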