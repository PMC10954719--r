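#' @useDynLib droshascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

# canonical pairs of the built-in model: Watson-Crick plus G-U wobble
.can_pair <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

#' Encode an RNA (or DNA) sequence string
#'
#' Accepts upper/lower case and T for U; anything outside ACGU(T) errors.
#'
#' @param seq single character string.
#' @return integer vector, 0-based codes A=0, C=1, G=2, U=3.
#' @keywords internal
encode_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- chartr("acgutT", "ACGUUU", seq)
  codes <- match(strsplit(s, "")[[1]], RNA_ALPHABET) - 1L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("invalid nucleotide at position ", bad, " of sequence", call. = FALSE)
  }
  codes
}

#' Parameters of the built-in stacking energy model
#'
#' The toy model scores a structure as the sum of contributions of adjacent
#' stacked pairs: `e_gc_gc` when both pairs are G-C, `e_mixed` when exactly
#' one is, `e_other` otherwise. Unpaired bases are free, hairpin loops must
#' contain at least `min_loop` unpaired bases, and `no_lp = TRUE` (the
#' default, mirroring the production folder's \code{--noLP}) forbids
#' isolated base pairs.
#'
#' @param e_gc_gc,e_mixed,e_other stack energies in model units.
#' @param min_loop minimum hairpin-loop size in nt.
#' @param no_lp forbid lone pairs?
#' @return a `fold_params` list.
#' @export
fold_params <- function(e_gc_gc = -3, e_mixed = -2, e_other = -1,
                        min_loop = 3, no_lp = TRUE) {
  stopifnot(min_loop >= 0)
  structure(
    list(energies = c(e_gc_gc, e_mixed, e_other),
         min_loop = as.integer(min_loop), no_lp = isTRUE(no_lp)),
    class = "fold_params")
}

#' Folding constraints
#'
#' @param forced_pairs two-column matrix (or NULL) of 1-based position pairs
#'   that must pair with each other.
#' @param forbidden_positions 1-based positions forced to stay unpaired.
#' @return a `fold_constraint` list.
#' @export
fold_constraint <- function(forced_pairs = NULL, forbidden_positions = integer()) {
  if (!is.null(forced_pairs)) {
    forced_pairs <- matrix(as.integer(forced_pairs), ncol = 2)
    forced_pairs[] <- t(apply(forced_pairs, 1, sort))
  }
  structure(list(forced_pairs = forced_pairs,
                 forbidden_positions = as.integer(forbidden_positions)),
            class = "fold_constraint")
}

# Build the allowed-pair matrix and must-pair vector for the DP.
.fold_inputs <- function(codes, constraint, params) {
  n <- length(codes)
  allowed <- matrix(FALSE, n, n)
  if (n >= 2) {
    idx <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) j - i - 1 >= params$min_loop),
                 arr.ind = TRUE)
    if (nrow(idx)) {
      ok <- .can_pair[cbind(codes[idx[, 1]] + 1L, codes[idx[, 2]] + 1L)]
      allowed[idx[ok, , drop = FALSE]] <- TRUE
    }
  }
  mustpair <- rep(FALSE, n)
  if (!is.null(constraint)) {
    fp <- constraint$forced_pairs
    if (!is.null(fp) && nrow(fp)) {
      if (any(fp < 1 | fp > n)) stop("forced pair out of range", call. = FALSE)
      # forced pairs must nest
      for (a in seq_len(nrow(fp))) for (b in seq_len(nrow(fp))) {
        if (a < b) {
          i <- fp[a, 1]; j <- fp[a, 2]; k <- fp[b, 1]; l <- fp[b, 2]
          nested <- (j < k) || (l < i) || (i < k && l < j) || (k < i && j < l)
          if (!nested) stop("forced pairs cross: (", i, ",", j, ") and (",
                            k, ",", l, ")", call. = FALSE)
        }
      }
      for (a in seq_len(nrow(fp))) {
        i <- fp[a, 1]; j <- fp[a, 2]
        if (!allowed[i, j])
          stop("forced pair (", i, ",", j,
               ") is not pairable under the model", call. = FALSE)
        allowed[i, -j] <- FALSE
        allowed[-i, j] <- FALSE
        allowed[-j, i] <- FALSE
        allowed[j, -i] <- FALSE
        mustpair[c(i, j)] <- TRUE
      }
    }
    fb <- constraint$forbidden_positions
    if (length(fb)) {
      if (any(fb < 1 | fb > n)) stop("forbidden position out of range",
                                     call. = FALSE)
      if (any(mustpair[fb])) stop("position both forced and forbidden",
                                  call. = FALSE)
      allowed[fb, ] <- FALSE
      allowed[, fb] <- FALSE
    }
  }
  list(allowed = allowed, mustpair = mustpair)
}

#' Fold a sequence to its minimum-free-energy structure
#'
#' Dynamic program over the built-in stacking model (see [fold_params()]),
#' honoring constraints. The traceback is deterministic: the stacking branch
#' is preferred and splits are taken at the smallest feasible position.
#'
#' @param seq RNA (or DNA) sequence string.
#' @param constraint optional [fold_constraint()].
#' @param params model parameters, [fold_params()].
#' @return an `rna_structure` object with fields `sequence`, `dot_bracket`,
#'   `pair_table` (1-based partner index, NA when unpaired) and `mfe`.
#' @examples
#' rna_fold("GGGAAACCC")
#' @export
rna_fold <- function(seq, constraint = NULL, params = fold_params()) {
  codes <- encode_rna(seq)
  inp <- .fold_inputs(codes, constraint, params)
  res <- mfe_cpp(codes, inp$allowed, inp$mustpair, params$no_lp,
                 params$energies)
  pt <- res$pairs + 1L
  pt[pt == 0L] <- NA_integer_
  structure(
    list(sequence = chartr("T", "U", toupper(seq)),
         dot_bracket = pairs_to_dotbracket(pt),
         pair_table = pt,
         mfe = res$energy,
         backend_id = "toy"),
    class = "rna_structure")
}

#' Ensemble statistics over the Boltzmann distribution of structures
#'
#' McCaskill-style inside-outside dynamic program over the built-in model.
#' Returns base-pair probabilities \eqn{p_{ij}}, positional entropy
#' \eqn{H_i = -\sum_j p_{ij} \ln p_{ij} - q_i \ln q_i} with
#' \eqn{q_i = 1 - \sum_j p_{ij}} (natural log), and the ensemble diversity
#' \eqn{\sum_{i<j} 2 p_{ij} (1 - p_{ij})}, the expected base-pair distance
#' between two independent draws from the ensemble.
#'
#' @inheritParams rna_fold
#' @param temperature_scale Boltzmann temperature in model energy units.
#' @return an `rna_structure` object additionally carrying `bp_prob`,
#'   `positional_entropy`, `ensemble_diversity` and the partition function
#'   `Z`.
#' @export
rna_ensemble <- function(seq, constraint = NULL, params = fold_params(),
                         temperature_scale = 1) {
  stopifnot(temperature_scale > 0)
  st <- rna_fold(seq, constraint, params)
  codes <- encode_rna(seq)
  inp <- .fold_inputs(codes, constraint, params)
  res <- pf_cpp(codes, inp$allowed, inp$mustpair, params$no_lp,
                params$energies, temperature_scale)
  p <- res$bp_prob
  q <- pmax(1 - rowSums(p), 0)
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  st$bp_prob <- p
  st$positional_entropy <- -(rowSums(plogp(p)) + plogp(q))
  st$ensemble_diversity <- sum(2 * p[upper.tri(p)] * (1 - p[upper.tri(p)]))
  st$Z <- res$Z
  st
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db string over the alphabet `(`, `)`, `.`.
#' @return integer vector of 1-based partner indices, NA when unpaired.
#' @examples
#' parse_dotbracket("((..))")
#' @export
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1)
  ch <- strsplit(db, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid dot-bracket character at index ", bad[1], call. = FALSE)
  pt <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced bracket at index ", i, call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack))
    stop("unbalanced bracket at index ", stack[length(stack)], call. = FALSE)
  pt
}

#' Render a pair table as a dot-bracket string
#'
#' @param pt pair table as returned by [parse_dotbracket()].
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pt) {
  ch <- rep(".", length(pt))
  paired <- which(!is.na(pt))
  ch[paired[pt[paired] > paired]] <- "("
  ch[paired[pt[paired] < paired]] <- ")"
  paste(ch, collapse = "")
}

#' Exhaustively enumerate nested structures (test oracle)
#'
#' Brute-force enumeration of every nested secondary structure respecting
#' the minimum hairpin loop and (optionally) the lone-pair ban, with exact
#' model energies. Independent of the dynamic-programming engine; intended
#' as a ground-truth oracle on short sequences.
#'
#' @inheritParams rna_fold
#' @param max_len guard against combinatorial explosion.
#' @return tibble with columns `dot_bracket` and `energy`.
#' @export
enumerate_structures <- function(seq, params = fold_params(), max_len = 20) {
  codes <- encode_rna(seq)
  n <- length(codes)
  if (n > max_len)
    stop("sequence longer than max_len = ", max_len, call. = FALSE)
  pairable <- function(i, j) {
    j - i - 1 >= params$min_loop && .can_pair[codes[i] + 1, codes[j] + 1]
  }
  # all pair sets on [i, j], each as a 2-column matrix
  rec <- function(i, j) {
    if (j - i + 1 <= params$min_loop) return(list(matrix(0L, 0, 2)))
    out <- rec(i, j - 1)                      # j unpaired
    ks <- if (j - params$min_loop - 1 >= i) i:(j - params$min_loop - 1)
          else integer()
    for (k in ks) {
      if (pairable(k, j)) {
        left <- if (k - 1 >= i) rec(i, k - 1) else list(matrix(0L, 0, 2))
        inner <- rec(k + 1, j - 1)
        for (L in left) for (Iin in inner)
          out <- c(out, list(rbind(L, Iin, c(k, j))))
      }
    }
    out
  }
  sets <- rec(1L, n)
  if (params$no_lp) {
    lone_free <- vapply(sets, function(ps) {
      if (!nrow(ps)) return(TRUE)
      key <- paste(ps[, 1], ps[, 2])
      has_nb <- paste(ps[, 1] + 1, ps[, 2] - 1) %in% key |
        paste(ps[, 1] - 1, ps[, 2] + 1) %in% key
      all(has_nb)
    }, logical(1))
    sets <- sets[lone_free]
  }
  seq_chr <- RNA_ALPHABET[codes + 1]
  energy_of <- function(ps) {
    if (nrow(ps) < 2) return(0)
    key <- paste(ps[, 1], ps[, 2])
    stacked <- paste(ps[, 1] + 1, ps[, 2] - 1) %in% key
    e <- 0
    for (r in which(stacked)) {
      g1 <- all(sort(seq_chr[c(ps[r, 1], ps[r, 2])]) == c("C", "G"))
      g2 <- all(sort(seq_chr[c(ps[r, 1] + 1, ps[r, 2] - 1)]) == c("C", "G"))
      e <- e + if (g1 && g2) params$energies[1]
        else if (g1 || g2) params$energies[2] else params$energies[3]
    }
    e
  }
  db <- vapply(sets, function(ps) {
    pt <- rep(NA_integer_, n)
    if (nrow(ps)) {
      pt[ps[, 1]] <- ps[, 2]
      pt[ps[, 2]] <- ps[, 1]
    }
    pairs_to_dotbracket(pt)
  }, character(1))
  tibble::tibble(dot_bracket = db,
                 energy = vapply(sets, energy_of, numeric(1)))
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("MFE: %g (backend: %s)\n", x$mfe, x$backend_id))
  if (!is.null(x$ensemble_diversity))
    cat(sprintf("ensemble diversity: %.4f\n", x$ensemble_diversity))
  invisible(x)
}

#' Tidy an RNA structure into a per-position tibble
#'
#' @param x an `rna_structure`.
#' @param ... unused.
#' @return tibble with one row per position: base, partner, paired flag and,
#'   when ensemble statistics are present, pairing probability and entropy.
#' @method tidy rna_structure
#' @export
tidy.rna_structure <- function(x, ...) {
  n <- nchar(x$sequence)
  out <- tibble::tibble(
    position = seq_len(n),
    base = strsplit(x$sequence, "")[[1]],
    partner = x$pair_table,
    paired = !is.na(x$pair_table))
  if (!is.null(x$bp_prob)) {
    out$p_paired <- rowSums(x$bp_prob)
    out$entropy <- x$positional_entropy
  }
  out
}

#' @rdname tidy.rna_structure
#' @method glance rna_structure
#' @export
glance.rna_structure <- function(x, ...) {
  tibble::tibble(
    length = nchar(x$sequence),
    n_pairs = sum(!is.na(x$pair_table)) / 2,
    mfe = x$mfe,
    ensemble_diversity = x$ensemble_diversity %||% NA_real_,
    backend = x$backend_id)
}

#' Plot the positional pairing profile of a folded RNA
#'
#' Line plot of per-position pairing probability and positional entropy
#' (requires [rna_ensemble()] output).
#'
#' @param object an `rna_structure` from [rna_ensemble()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rna_structure
#' @export
autoplot.rna_structure <- function(object, ...) {
  if (is.null(object$bp_prob))
    stop("run rna_ensemble() first to compute the pairing profile",
         call. = FALSE)
  df <- tidy.rna_structure(object)
  df_long <- tidyr::pivot_longer(df, c("p_paired", "entropy"),
                                 names_to = "metric")
  ggplot2::ggplot(df_long,
                  ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
}
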