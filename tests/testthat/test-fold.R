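test_that("dot-bracket parsing round-trips and rejects malformed input", {
  expect_equal(parse_dotbracket("((..))"), c(6L, 5L, NA, NA, 2L, 1L))
  expect_true(all(is.na(parse_dotbracket("...."))))
  expect_error(parse_dotbracket("((.)"), "unbalanced bracket at index 1")
  expect_error(parse_dotbracket("().)"), "unbalanced bracket at index 4")
  expect_error(parse_dotbracket("(.x)"), "invalid dot-bracket character at index 3")
  for (db in c("((((...))))", ".(...).", "((..))((...))")) {
    expect_equal(pairs_to_dotbracket(parse_dotbracket(db)), db)
  }
})

test_that("MFE folding reproduces hand-checkable cases", {
  # no complementary pairs at all
  st <- rna_fold("AAAAAA")
  expect_equal(st$dot_bracket, "......")
  expect_equal(st$mfe, 0)
  # unique stable hairpin: three stacked G-C pairs
  st <- rna_fold("GGGAAACCC")
  expect_equal(st$dot_bracket, "(((...)))")
  expect_equal(st$mfe, -6)  # two G-C/G-C stacks at -3 each
  # lone pair is banned by default ...
  expect_equal(rna_fold("GAAAC")$dot_bracket, ".....")
  # ... but allowed (at energy 0) when noLP is off
  enum <- enumerate_structures("GAAAC", fold_params(no_lp = FALSE))
  expect_setequal(enum$dot_bracket, c(".....", "(...)"))
  expect_equal(enum$energy, c(0, 0))
})

test_that("enumeration oracle counts structures consistently", {
  expect_equal(enumerate_structures("AAAA")$dot_bracket, "....")
  # independent recursion for the structure count: s(i,j) with memoization
  count_rec <- function(seq, min_loop = 3) {
    codes <- strsplit(seq, "")[[1]]
    pairable <- function(a, b) {
      paste(sort(c(codes[a], codes[b])), collapse = "") %in%
        c("AU", "CG", "GU") && b - a - 1 >= min_loop
    }
    memo <- new.env()
    cnt <- function(i, j) {
      if (j - i < min_loop) return(1)
      key <- paste(i, j)
      if (!is.null(memo[[key]])) return(memo[[key]])
      total <- cnt(i, j - 1)
      ks <- if (j - min_loop - 1 >= i) i:(j - min_loop - 1) else integer()
      for (k in ks) {
        if (pairable(k, j)) {
          left <- if (k - 1 >= i) cnt(i, k - 1) else 1
          total <- total + left * cnt(k + 1, j - 1)
        }
      }
      memo[[key]] <- total
      total
    }
    cnt(1, nchar(seq))
  }
  for (seq in c("GGAAACC", "GCAUGCAUGC", "AUAUAUAUAU")) {
    enum <- enumerate_structures(seq, fold_params(no_lp = FALSE))
    expect_equal(nrow(enum), count_rec(seq))
  }
  expect_error(enumerate_structures(strrep("A", 25)), "max_len")
})

test_that("ensemble statistics match closed forms on degenerate ensembles", {
  # only one attainable state: everything unpaired
  st <- rna_ensemble("AAAAAA")
  expect_equal(st$positional_entropy, rep(0, 6))
  expect_equal(st$ensemble_diversity, 0)
  expect_equal(st$Z, 1)
  # two equally weighted states differing by one pair: p = 1/2,
  # H = ln 2 at the paired positions, diversity = 2 * p * (1 - p) = 1/2
  st <- rna_ensemble("GAAAC", params = fold_params(no_lp = FALSE))
  expect_equal(st$bp_prob[1, 5], 0.5)
  expect_equal(st$ensemble_diversity, 0.5)
  expect_equal(st$positional_entropy[1], log(2))
  expect_equal(st$positional_entropy[5], log(2))
  expect_equal(st$positional_entropy[3], 0)
})

test_that("dynamic programs agree with exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    seq <- random_rna(sample(5:12, 1))
    for (no_lp in c(TRUE, FALSE)) {
      params <- fold_params(no_lp = no_lp)
      ref <- enum_ensemble(seq, params)
      st <- rna_ensemble(seq, params = params)
      expect_equal(st$Z, ref$Z, tolerance = 1e-12)
      expect_equal(st$mfe, ref$mfe, tolerance = 1e-12)
      expect_equal(st$bp_prob, ref$bp_prob, tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(st$positional_entropy, ref$entropy, tolerance = 1e-9)
      expect_equal(st$ensemble_diversity, ref$diversity, tolerance = 1e-9)
    }
  }
})

test_that("temperature scaling reweights the ensemble correctly", {
  seq <- "GGCAAAGCC"
  for (kT in c(0.5, 2)) {
    ref <- enum_ensemble(seq, kT = kT)
    st <- rna_ensemble(seq, temperature_scale = kT)
    expect_equal(st$Z, ref$Z, tolerance = 1e-12)
    expect_equal(st$bp_prob, ref$bp_prob, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("constraints are honored by MFE and partition function", {
  # forced pair appears in the MFE structure
  st <- rna_fold("GGGAAACCC", fold_constraint(forced_pairs = rbind(c(2, 8))))
  expect_equal(st$pair_table[2], 8L)
  # forbidden positions stay unpaired and the rest refolds
  st <- rna_fold("GGGAAACCC",
                 fold_constraint(forbidden_positions = c(1, 9)))
  expect_true(all(is.na(st$pair_table[c(1, 9)])))
  expect_equal(st$pair_table[2], 8L)
  # when the forced helix is the only completion its pairs have p = 1
  cc <- fold_constraint(forced_pairs = rbind(c(1, 9), c(2, 8), c(3, 7)))
  en <- rna_ensemble("GGGAAACCC", cc)
  expect_equal(en$bp_prob[1, 9], 1)
  expect_equal(en$bp_prob[2, 8], 1)
  # constrained Z equals the enumeration restricted to the constraint
  enum <- enumerate_structures("GGGAAACCC")
  keep <- vapply(enum$dot_bracket, function(db) {
    pt <- parse_dotbracket(db)
    identical(pt[1], 9L) && identical(pt[2], 8L) && identical(pt[3], 7L)
  }, logical(1))
  expect_equal(en$Z, sum(exp(-enum$energy[keep])), tolerance = 1e-12)
  # crossing forced pairs are rejected
  expect_error(
    rna_fold("GGGAAACCC",
             fold_constraint(forced_pairs = rbind(c(1, 6), c(3, 9)))),
    "cross")
  # unsatisfiable pair (non-complementary bases)
  expect_error(rna_fold("AAAAAAAAA",
                        fold_constraint(forced_pairs = rbind(c(1, 9)))),
               "not pairable")
})

test_that("tidy and glance summarize structures", {
  st <- rna_ensemble("GGGAAACCC")
  td <- tidy(st)
  expect_equal(nrow(td), 9)
  expect_true(all(c("p_paired", "entropy") %in% names(td)))
  gl <- glance(st)
  expect_equal(gl$n_pairs, 3)
  expect_equal(gl$mfe, -6)
})
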