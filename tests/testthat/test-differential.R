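null_counts <- function(n, mu = 100, size = 10, cols = 4) {
  matrix(rnbinom(n * cols, mu = mu, size = size), n, cols,
         dimnames = list(NULL, paste0("lib", seq_len(cols))))
}
conds <- c("control", "control", "knockout", "knockout")

test_that("TMM factors behave on composition-free designs", {
  set.seed(61)
  x <- null_counts(500)
  # identical columns: no composition difference, all factors 1
  same <- cbind(x[, 1], x[, 1], x[, 1], x[, 1])
  colnames(same) <- colnames(x)
  expect_equal(unname(tmm_factors(same)), rep(1, 4))
  # doubling one library's depth is absorbed by the library size
  doubled <- cbind(x[, 1], 2L * x[, 1])
  colnames(doubled) <- c("a", "b")
  f <- tmm_factors(doubled)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-8)
  # geometric-mean-1 constraint always holds
  f2 <- tmm_factors(x)
  expect_equal(prod(f2), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(x[, 1], 0L * x[, 1])), "all-zero")
})

test_that("differential gate and intersection logic", {
  res <- tibble::tibble(chrom = "c", strand = "+", pos = 1:4,
                        log2FC = c(-2.0, -1.0, -2.0, 1.9),
                        fdr = c(0.01, 0.001, 0.2, 0.01))
  out <- call_dependent(res)
  expect_equal(out$dependent, c(TRUE, FALSE, FALSE, FALSE))
  out2 <- call_dependent(res, two_sided = TRUE)
  expect_equal(out2$dependent, c(TRUE, FALSE, FALSE, TRUE))
  a <- tibble::tibble(chrom = "c", strand = "+", pos = c(1, 2),
                      dependent = TRUE)
  b <- tibble::tibble(chrom = "c", strand = "+", pos = c(2, 3),
                      dependent = TRUE)
  expect_equal(intersect_dependent(a, b)$pos, 2)
})

test_that("BH adjustment in results matches the step-up construction", {
  set.seed(63)
  x <- null_counts(300)
  res <- test_differential(x, conditions = conds)
  expect_equal(res$fdr, bh_reference(res$p_value), tolerance = 1e-12)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("type-I error is calibrated on all-null data", {
  set.seed(65)
  res <- test_differential(null_counts(2000), conditions = conds,
                           lib_sizes = rep(1e6, 4))
  tI <- mean(res$p_value < 0.05)
  expect_gte(tI, 0.03)
  expect_lte(tI, 0.07)
  expect_lte(mean(res$dependent), 0.05)
})

test_that("planted depletion is estimated and gated correctly", {
  set.seed(67)
  n_null <- 1000; n_dep <- 60
  counts <- rbind(null_counts(n_null),
                  cbind(matrix(rnbinom(n_dep * 2, mu = 500, size = 10),
                               n_dep, 2),
                        matrix(rnbinom(n_dep * 2, mu = 50, size = 10),
                               n_dep, 2)))
  colnames(counts) <- paste0("lib", 1:4)
  res <- test_differential(counts, conditions = conds,
                           lib_sizes = rep(1e6, 4))
  dep <- res[(n_null + 1):(n_null + n_dep), ]
  expect_lt(abs(median(dep$log2FC) - (-log2(10))), 0.25)
  expect_gte(mean(dep$dependent), 0.9)
})

test_that("scaling one library leaves fold changes essentially unchanged", {
  set.seed(69)
  n <- 400
  counts <- rbind(null_counts(n),
                  cbind(matrix(rnbinom(40 * 2, mu = 400, size = 10), 40, 2),
                        matrix(rnbinom(40 * 2, mu = 40, size = 10), 40, 2)))
  colnames(counts) <- paste0("lib", 1:4)
  ls <- rep(1e6, 4)
  res1 <- test_differential(counts, conditions = conds, lib_sizes = ls)
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 3L
  ls2 <- ls; ls2[1] <- ls2[1] * 3
  res2 <- test_differential(counts2, conditions = conds, lib_sizes = ls2)
  expect_lt(median(abs(res1$log2FC - res2$log2FC)), 0.05)
})

test_that("tightening the FDR cut never adds dependent sites", {
  set.seed(71)
  counts <- rbind(null_counts(300),
                  cbind(matrix(rnbinom(30 * 2, mu = 300, size = 10), 30, 2),
                        matrix(rnbinom(30 * 2, mu = 30, size = 10), 30, 2)))
  colnames(counts) <- paste0("lib", 1:4)
  res <- test_differential(counts, conditions = conds,
                           lib_sizes = rep(1e6, 4))
  d05 <- call_dependent(res, fdr_cut = 0.05)$dependent
  d01 <- call_dependent(res, fdr_cut = 0.01)$dependent
  expect_true(all(d05 | !d01))
})

test_that("replicate and zero-row preconditions are enforced", {
  set.seed(73)
  x <- null_counts(50)
  expect_error(test_differential(x[, 1:2],
                                 conditions = c("control", "knockout")),
               "at least 2 replicates")
  expect_error(test_differential(x, conditions = c("a", "a", "b", "b")),
               "control")
  # all-zero rows are excluded before BH: multiplicity = tested loci
  x[1:10, ] <- 0L
  res <- test_differential(x, conditions = conds)
  expect_equal(nrow(res), 40)
})

test_that("pileup count matrices assemble raw C5 counts per library", {
  gb <- build_genome(3, 2, 25000, seed = 75, n_decoy_sites = 40)
  libs <- desk_libraries(background_rate = 0)
  reads <- simulate_degradome(gb$truth, libs, gb$genome, seed = 77,
                              decoys = gb$decoys)
  loci <- dplyr::bind_rows(
    tibble::tibble(chrom = gb$truth$chrom, strand = gb$truth$strand,
                   pos = gb$truth$D, planted = TRUE),
    tibble::tibble(chrom = gb$decoys$chrom, strand = gb$decoys$strand,
                   pos = gb$decoys$pos, planted = FALSE))
  pc <- pileup_counts(reads, loci)
  expect_equal(dim(pc$counts), c(45, 4))
  expect_equal(pc$meta$condition, rep(c("control", "knockout"), each = 2))
  # counts at D match an independently built track
  tr <- count_read_starts(reads[reads$library == pc$meta$library[1], ])
  expect_equal(unname(pc$counts[, 1]),
               track_count(tr, loci$chrom, loci$strand, loci$pos))
  # Drosha-dependent loci are depleted in the knockout; decoys are not
  res <- test_differential(pc)
  expect_true(all(res$dependent[res$planted]))
  expect_false(any(res$dependent[!res$planted]))
})
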