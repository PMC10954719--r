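# Independent reference implementations used as oracles.

# Boltzmann-ensemble statistics computed from exhaustive enumeration
# (droshascan::enumerate_structures is itself recursive enumeration,
# independent of the C++ dynamic programs it checks).
enum_ensemble <- function(seq, params = fold_params(), kT = 1) {
  enum <- enumerate_structures(seq, params)
  w <- exp(-enum$energy / kT)
  Z <- sum(w)
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (r in seq_len(nrow(enum))) {
    pt <- parse_dotbracket(enum$dot_bracket[r])
    for (i in which(!is.na(pt))) {
      if (pt[i] > i) P[i, pt[i]] <- P[i, pt[i]] + w[r]
    }
  }
  P <- (P + t(P)) / Z
  q <- pmax(1 - rowSums(P), 0)
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  list(Z = Z,
       mfe = min(enum$energy),
       bp_prob = P,
       entropy = -(rowSums(plogp(P)) + plogp(q)),
       diversity = sum(2 * P[upper.tri(P)] * (1 - P[upper.tri(P)])),
       n_structures = nrow(enum))
}

# brute-force AUC by pair counting
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# closed-form Welch t-test
welch_reference <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# step-up Benjamini-Hochberg by hand
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# random RNA sequence
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# a small clean synthetic world shared by several tests
small_world <- function(n_mi = 12, n_mr = 8, len = 25000, seed = 42,
                        n_decoy = 0) {
  build_genome(n_mi, n_mr, len, seed = seed, n_decoy_sites = n_decoy)
}
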