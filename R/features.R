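#' Per-position structural categories of a folded window
#'
#' Labels every position of a secondary structure: `P` paired, `F`
#' flanking single-stranded RNA (outside the outermost pair), `T`
#' terminal (hairpin) loop, `I` symmetric internal loop, `B` asymmetric
#' internal loop or bulge. Unpaired positions of a multibranch loop (not
#' expected in hairpin windows) are labelled `B` with a warning.
#'
#' @param pair_table 1-based partner indices (NA = unpaired), as in
#'   [parse_dotbracket()].
#' @return list: `categories` (character vector) and `loops`, a tibble of
#'   internal loops with `size5`, `size3`, `pos5` (window index of the
#'   first interior position on the 5' side) and `symmetric`.
#' @export
annotate_structure <- function(pair_table) {
  n <- length(pair_table)
  cat <- rep("F", n)
  cat[!is.na(pair_table)] <- "P"
  loops <- list()
  warned <- FALSE
  # walk every pair that closes a loop (innermost pair of its helix run)
  for (p in seq_len(n)) {
    q <- pair_table[p]
    if (is.na(q) || q <= p) next
    # children: pairs directly enclosed by (p, q)
    kids <- list()
    u <- p + 1L
    while (u < q) {
      if (!is.na(pair_table[u]) && pair_table[u] > u) {
        kids[[length(kids) + 1]] <- c(u, pair_table[u])
        u <- pair_table[u] + 1L
      } else {
        u <- u + 1L
      }
    }
    if (!length(kids)) {               # hairpin loop
      if (q - p > 1) cat[(p + 1):(q - 1)] <- "T"
    } else if (length(kids) == 1) {
      k <- kids[[1]]
      size5 <- k[1] - p - 1L
      size3 <- q - k[2] - 1L
      if (size5 + size3 >= 1) {        # internal loop or bulge
        lab <- if (size5 == size3) "I" else "B"
        if (size5 > 0) cat[(p + 1):(k[1] - 1)] <- lab
        if (size3 > 0) cat[(k[2] + 1):(q - 1)] <- lab
        loops[[length(loops) + 1]] <- tibble::tibble(
          size5 = size5, size3 = size3, pos5 = p + 1L,
          symmetric = size5 == size3)
      }
    } else {                           # multibranch: unexpected in hairpins
      if (!warned) {
        warning("multibranch loop in stem-loop window; unpaired positions ",
                "labelled B", call. = FALSE)
        warned <- TRUE
      }
      for (u in (p + 1):(q - 1))
        if (is.na(pair_table[u]) && cat[u] == "F") cat[u] <- "B"
    }
  }
  list(categories = cat,
       loops = if (length(loops)) bind_rows(loops) else
         tibble::tibble(size5 = integer(), size3 = integer(),
                        pos5 = integer(), symmetric = logical()))
}

# anchored coordinate helpers: position +1 is the first nucleotide of the
# upper stem (product side); the cleavage site lies between -1 and +1;
# anchored 0 is never used
.anchor5 <- function(w, five_idx) ifelse(w >= five_idx,
                                         w - five_idx + 1L, w - five_idx)
.anchor3 <- function(w, three_end_idx) ifelse(w <= three_end_idx,
                                              three_end_idx - w + 1L,
                                              three_end_idx - w)

# 5-bp window bin of an anchored position (bin 1 = anchored 1..5)
.anchored_bin <- function(a) {
  ifelse(a >= 1, (a - 1L) %/% 5L + 1L, -((-a - 1L) %/% 5L + 1L))
}

#' Cleavage-anchored structural annotation of a stem-loop call
#'
#' Refolds the call window extended to `flank` nt (default 25) on each
#' side, constraining every base pair of the original 15-nt-flank
#' structure to remain paired, then labels each position with
#' [annotate_structure()] categories and reports cleavage-anchored
#' coordinates for both arms (5'-arm anchor: the product's first
#' nucleotide; 3'-arm anchor: the product's last nucleotide; positive
#' positions run apical, negative basal, no position 0).
#'
#' @param call one-row tibble from [call_stemloops()] (resolved).
#' @param genome named character vector.
#' @param flank extended flank in nt.
#' @param params folding model parameters.
#' @return tibble with one row per window position: `window_idx`, `base`,
#'   `category`, `arm` (assignment by hairpin apex), `anchored_5p`,
#'   `anchored_3p` and `anchored` (the coordinate on the position's own
#'   arm). Internal loops are attached as attribute `"loops"`.
#' @export
annotate_positions <- function(call, genome, flank = 25,
                               params = fold_params()) {
  stopifnot(nrow(call) == 1, isTRUE(call$resolved) || isTRUE(call$accepted))
  extra <- flank - 15L
  sgn <- if (call$strand == "+") 1L else -1L
  len <- nchar(genome[[call$chrom]])
  g_start <- max(call$window_start - extra, 0L)
  g_end <- min(call$window_end + extra, len)
  seq <- extract_rna(genome, call$chrom, g_start, g_end, call$strand)
  # offset of the old window inside the new one, in transcript direction
  off <- if (call$strand == "+") call$window_start - g_start
         else g_end - call$window_end
  pt15 <- parse_dotbracket(call$dot_bracket)
  paired <- which(!is.na(pt15) & pt15 > seq_along(pt15))
  fp <- if (length(paired)) cbind(paired + off, pt15[paired] + off) else NULL
  st <- tryCatch(
    rna_fold(seq, constraint = fold_constraint(forced_pairs = fp),
             params = params),
    error = function(e) {
      warning("constrained refold infeasible; falling back to an ",
              "unconstrained fold: ", conditionMessage(e), call. = FALSE)
      rna_fold(seq, params = params)
    })
  ann <- annotate_structure(st$pair_table)
  five_idx <- call$five_idx + off
  three_end_idx <- call$three_end_idx + off
  n <- nchar(seq)
  # hairpin apex: centre of the first terminal loop, else window centre
  t_run <- which(ann$categories == "T")
  apex <- if (length(t_run)) mean(range(t_run)) else (n + 1) / 2
  w <- seq_len(n)
  out <- tibble::tibble(
    window_idx = w,
    base = strsplit(seq, "")[[1]],
    category = ann$categories,
    arm = ifelse(w <= apex, "5p", "3p"),
    anchored_5p = .anchor5(w, five_idx),
    anchored_3p = .anchor3(w, three_end_idx))
  out$anchored <- ifelse(out$arm == "5p", out$anchored_5p, out$anchored_3p)
  loops <- ann$loops
  if (nrow(loops)) {
    loops$anchored_pos5 <- .anchor5(loops$pos5, five_idx)
    loops$bin <- .anchored_bin(loops$anchored_pos5)
  } else {
    loops$anchored_pos5 <- integer()
    loops$bin <- integer()
  }
  attr(out, "loops") <- loops
  attr(out, "structure") <- st
  out
}

#' Catalog internal loops of an annotated stem-loop
#'
#' One record per maximal unpaired run between stem pairs: the unpaired
#' sizes on each arm, the cleavage-anchored position of the first interior
#' nucleotide on the 5' arm closest to the cut, whether the loop is
#' symmetric, and its 5-bp window bin.
#'
#' @param annotation output of [annotate_positions()].
#' @return tibble with `size5`, `size3`, `anchored_pos5`, `bin`,
#'   `symmetric`.
#' @export
catalog_internal_loops <- function(annotation) {
  loops <- attr(annotation, "loops")
  loops[, c("size5", "size3", "anchored_pos5", "bin", "symmetric")]
}

#' Thermodynamic and structural features of stem-loop calls
#'
#' Computes, per resolved call: MFE of the 15-nt-flank window; the
#' stem-loop `length` (product span plus both flanks); base-pairing
#' frequency (pairs / length); maximum base-pair stacking (longest
#' uninterrupted helix / length); ensemble diversity and mean positional
#' entropy of the window; G-C / A-U / G-U pair composition of the lower
#' (anchored <= -1 on the 5' arm) and upper (>= +1) stem; and internal
#' loop counts.
#'
#' @param calls tibble from [call_stemloops()].
#' @param genome named character vector.
#' @param params folding model parameters.
#' @param temperature_scale Boltzmann temperature for ensemble statistics.
#' @return tibble with one feature row per resolved call.
#' @export
stemloop_features <- function(calls, genome, params = fold_params(),
                              temperature_scale = 1) {
  calls <- calls[calls$resolved %||% calls$accepted, ]
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    st <- rna_ensemble(call$sequence, params = params,
                       temperature_scale = temperature_scale)
    pt <- st$pair_table
    n <- nchar(call$sequence)
    pairs5 <- which(!is.na(pt) & pt > seq_along(pt))
    n_pairs <- length(pairs5)
    comp <- bp_composition(call, structure = st)
    # longest chain of stacked pairs (i,j),(i+1,j-1),...
    max_stack <- 0L
    run <- 0L
    for (p in seq_len(n)) {
      q <- pt[p]
      if (!is.na(q) && q > p) {
        run <- if (p > 1 && !is.na(pt[p - 1]) && pt[p - 1] == q + 1)
          run + 1L else 1L
        max_stack <- max(max_stack, run)
      } else if (is.na(q)) run <- 0L
    }
    ann <- annotate_positions(call, genome, params = params)
    loops <- catalog_internal_loops(ann)
    tibble::tibble(
      chrom = call$chrom, strand = call$strand, D = call$D, S = call$S,
      orientation = call$orientation,
      length = n,
      mfe = st$mfe,
      n_pairs = n_pairs,
      bp_frequency = n_pairs / n,
      max_stack = max_stack / n,
      ensemble_diversity = st$ensemble_diversity,
      mean_entropy = mean(st$positional_entropy),
      overhang = call$overhang,
      lower_gc = comp$lower[["GC"]], lower_au = comp$lower[["AU"]],
      lower_gu = comp$lower[["GU"]],
      upper_gc = comp$upper[["GC"]], upper_au = comp$upper[["AU"]],
      upper_gu = comp$upper[["GU"]],
      n_internal_loops = nrow(loops),
      n_asymmetric_loops = sum(!loops$symmetric))
  })
  bind_rows(rows)
}

#' Base-pair composition of the lower and upper stem
#'
#' Classifies every pair of the folded call window as G-C, A-U or G-U
#' (orientation-agnostic) and assigns it to the lower or upper stem by the
#' anchored sign of its 5'-side nucleotide (lower: anchored <= -1, i.e.
#' basal of the cleavage site). Each triplet is normalized to that stem's
#' pair count; stems without pairs return NA.
#'
#' @param call one-row tibble from [call_stemloops()].
#' @param structure optional pre-computed `rna_structure` of the window.
#' @return list with named numeric triplets `lower` and `upper`.
#' @export
bp_composition <- function(call, structure = NULL) {
  st <- structure %||% rna_fold(call$sequence)
  pt <- st$pair_table
  bases <- strsplit(st$sequence, "")[[1]]
  p5 <- which(!is.na(pt) & pt > seq_along(pt))
  kind <- vapply(p5, function(p) {
    pair <- paste(sort(c(bases[p], bases[pt[p]])), collapse = "")
    c(CG = "GC", AU = "AU", GU = "GU")[[pair]]
  }, character(1))
  region <- ifelse(.anchor5(p5, call$five_idx) <= -1, "lower", "upper")
  triplet <- function(k) {
    if (!length(k)) return(c(GC = NA_real_, AU = NA_real_, GU = NA_real_))
    tab <- table(factor(k, levels = c("GC", "AU", "GU")))
    as.numeric(tab / sum(tab)) |> stats::setNames(c("GC", "AU", "GU"))
  }
  list(lower = triplet(kind[region == "lower"]),
       upper = triplet(kind[region == "upper"]))
}

#' Position frequency and information-bits matrix
#'
#' For items aligned on anchored coordinates, computes per-position symbol
#' frequencies and the information content
#' `bits = log2(A) + sum(f * log2(f))` (with `0 * log 0 = 0`), `A` the
#' alphabet size. Positions covered by fewer than `min_count` items are
#' masked (bits = NA).
#'
#' @param items tibble with columns `item`, `position`, `symbol`.
#' @param alphabet character vector of allowed symbols, e.g.
#'   `c("A","C","G","U")` or `c("P","F","I","B","T")`.
#' @param min_count minimum coverage per position.
#' @return tibble with one row per position: coverage `n`, `bits` and one
#'   frequency column per symbol.
#' @export
information_matrix <- function(items, alphabet, min_count = 5) {
  if (!nrow(items)) stop("no items to align", call. = FALSE)
  bad <- setdiff(unique(items$symbol), alphabet)
  if (length(bad))
    stop("symbol(s) outside alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- items |>
    group_by(.data$position) |>
    summarise(n = n(),
              freqs = list(table(factor(.data$symbol,
                                        levels = alphabet)) / n()),
              .groups = "drop")
  fr <- do.call(rbind, lapply(out$freqs, as.numeric))
  colnames(fr) <- paste0("f_", alphabet)
  plogp <- function(f) ifelse(f > 0, f * log2(f), 0)
  bits <- log2(length(alphabet)) + rowSums(plogp(fr))
  out$freqs <- NULL
  out$bits <- ifelse(out$n >= min_count, bits, NA_real_)
  dplyr::bind_cols(out, tibble::as_tibble(fr)) |>
    arrange(.data$position)
}

#' Canonical motif windows
#'
#' Default anchored windows for the pri-miRNA processing motifs, following
#' their canonical literature positions: the basal UG with U at anchored
#' -14 of the 5' arm (+/- 1 nt); the apical UGU/GUG within the terminal
#' loop; the CNNC starting 16-18 nt 3' of the 3'-arm cleavage site; the
#' mGHG on the 3' strand opposite anchored -7..-5 with a mismatched
#' central H.
#'
#' @param basal_ug_pos,basal_ug_shift anchored U position and search
#'   half-width.
#' @param cnnc_offsets downstream offsets (nt from the cut, first C).
#' @param mghg_window anchored 5'-arm positions the triplet faces.
#' @return list of windows.
#' @export
motif_windows <- function(basal_ug_pos = -14, basal_ug_shift = 1,
                          cnnc_offsets = 16:18,
                          mghg_window = c(-7, -5)) {
  list(basal_ug_pos = basal_ug_pos, basal_ug_shift = basal_ug_shift,
       cnnc_offsets = cnnc_offsets, mghg_window = mghg_window)
}

# transcript-direction character accessor around a genomic anchor
.txn_base <- function(genome, chrom, strand, anchor, offset) {
  sgn <- if (strand == "+") 1L else -1L
  pos <- anchor + sgn * offset
  len <- nchar(genome[[chrom]])
  vapply(pos, function(p) {
    if (p < 0 || p >= len) return(NA_character_)
    extract_rna(genome, chrom, p, p + 1, strand)
  }, character(1))
}

#' Scan a stem-loop call for pri-miRNA processing motifs
#'
#' Tests the four canonical Drosha-guiding motifs (basal UG, apical
#' UGU/GUG, CNNC, mGHG) in their configured windows. For downstream
#' (inverse) calls the anchoring uses the inferred product boundaries.
#'
#' @param call one-row resolved call from [call_stemloops()].
#' @param genome named character vector.
#' @param annotation optional [annotate_positions()] output (computed on
#'   demand for the terminal loop).
#' @param windows see [motif_windows()].
#' @return tibble with one row per motif: `present` and a match `detail`.
#' @export
scan_motifs <- function(call, genome, annotation = NULL,
                        windows = motif_windows()) {
  stopifnot(nrow(call) == 1)
  # product boundaries in genomic space, transcript-oriented
  five_site <- if (call$orientation == "upstream") call$S else call$D
  three_junction <- if (call$orientation == "upstream") call$D else call$S
  # basal UG: U at anchored basal_ug_pos (+/- shift) followed by G
  w <- windows$basal_ug_pos + (-windows$basal_ug_shift):windows$basal_ug_shift
  basal_hit <- NA_integer_
  for (a in w) {
    b1 <- .txn_base(genome, call$chrom, call$strand, five_site, a)
    b2 <- .txn_base(genome, call$chrom, call$strand, five_site, a + 1)
    if (!is.na(b1) && !is.na(b2) && b1 == "U" && b2 == "G") {
      basal_hit <- a
      break
    }
  }
  # apical UGU: UGU or GUG anywhere in the terminal loop
  if (is.null(annotation)) annotation <- annotate_positions(call, genome)
  loop_seq <- paste(annotation$base[annotation$category == "T"],
                    collapse = "")
  ugu <- grepl("UGU|GUG", loop_seq)
  # CNNC: C at offset o (16-18 nt 3' of the 3'-arm cut; offset 1 = first
  # downstream nucleotide) and another C three further
  cnnc_hit <- NA_integer_
  for (o in windows$cnnc_offsets) {
    b1 <- .txn_base(genome, call$chrom, call$strand, three_junction, o - 1)
    b2 <- .txn_base(genome, call$chrom, call$strand, three_junction, o + 2)
    if (!is.na(b1) && !is.na(b2) && b1 == "C" && b2 == "C") {
      cnnc_hit <- o
      break
    }
  }
  # mGHG: triplet on the 3' strand facing anchored -7..-5, read 5'->3'
  # as G H G with the central H mismatched
  pt <- parse_dotbracket(call$dot_bracket)
  bases <- strsplit(call$sequence, "")[[1]]
  a_idx <- function(a) call$five_idx + a   # window index of anchored a < 0
  mghg <- FALSE
  i7 <- a_idx(windows$mghg_window[1])
  i5 <- a_idx(windows$mghg_window[2])
  if (i7 >= 1 && i5 >= 1 && !is.na(pt[i7]) && !is.na(pt[i5]) &&
      pt[i5] + 2 == pt[i7]) {
    t5 <- pt[i5]
    trip <- bases[t5:(t5 + 2)]
    mid_pairs_center <- !is.na(pt[i5 + 1]) && pt[i5 + 1] == t5 + 1 &&
      paste(sort(c(bases[i5 + 1], bases[t5 + 1])), collapse = "") %in%
        c("AU", "CG")
    mghg <- trip[1] == "G" && trip[3] == "G" && trip[2] != "G" &&
      !mid_pairs_center
  }
  tibble::tibble(
    motif = c("basal_UG", "apical_UGU", "CNNC", "mGHG"),
    present = c(!is.na(basal_hit), ugu, !is.na(cnnc_hit), mghg),
    detail = c(
      if (is.na(basal_hit)) NA_character_ else
        sprintf("UG at anchored %d", basal_hit),
      if (ugu) "UGU/GUG in terminal loop" else NA_character_,
      if (is.na(cnnc_hit)) NA_character_ else
        sprintf("CNNC at offset %d", cnnc_hit),
      if (mghg) "mGHG opposite lower stem" else NA_character_))
}

#' Welch comparisons of stem-loop features between groups
#'
#' Two-tailed unequal-variance (Welch) t-tests per feature between two
#' groups, with no multiplicity correction (features are reported
#' individually). Degenerate features with zero variance in both groups
#' give p = 1 when the means agree and an error otherwise.
#'
#' @param features feature tibble (e.g. from [stemloop_features()]).
#' @param group name of the grouping column (two levels).
#' @param vars feature columns to test; default every numeric column.
#' @return tibble with one row per feature: group means, Welch `statistic`,
#'   `df` and `p_value`.
#' @export
compare_groups <- function(features, group, vars = NULL) {
  g <- factor(features[[group]])
  if (nlevels(g) != 2)
    stop("grouping column must have exactly two levels", call. = FALSE)
  if (any(table(g) < 2))
    stop("need at least 2 observations per group", call. = FALSE)
  if (is.null(vars)) {
    vars <- names(features)[vapply(features, is.numeric, logical(1))]
    vars <- setdiff(vars, group)
  }
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- features[[v]][g == lv[1]]
    y <- features[[v]][g == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      return(tibble::tibble(feature = v, mean_1 = mean(x), mean_2 = mean(y),
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y))
        return(tibble::tibble(feature = v, mean_1 = mean(x),
                              mean_2 = mean(y), statistic = 0, df = Inf,
                              p_value = 1))
      stop("degenerate zero-variance feature with unequal means: ", v,
           call. = FALSE)
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(feature = v, mean_1 = mean(x), mean_2 = mean(y),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  out <- bind_rows(rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  out
}
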