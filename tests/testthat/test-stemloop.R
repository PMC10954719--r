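# helper: build a one-locus world with clean sRNA evidence
clean_world <- function(seed = 81, n_mi = 6, n_mr = 4) {
  gb <- small_world(n_mi, n_mr, 30000, seed = seed)
  srna <- simulate_srna(gb$truth,
                        library_model("control", 1),
                        gb$genome, seed = seed + 1)
  list(gb = gb, srna = srna,
       starts = count_read_starts(srna, weight = "score"),
       ends = count_read_ends(srna, weight = "score"))
}

test_that("terminus stacks respect the RPM threshold and window", {
  w <- clean_world()
  tr <- w$gb$truth[1, ]
  stacks <- find_terminus_stacks(w$starts, w$ends, tr$chrom, tr$strand,
                                 tr$D)
  expect_true(nrow(stacks) >= 1)
  # the dominant upstream stack implies the planted S
  up <- stacks[stacks$side == "upstream", ]
  expect_equal(up$site[which.max(up$rpm)], tr$S)
  expect_true(all(abs(stacks$delta) >= 25 & abs(stacks$delta) <= 100))
  # an absurd threshold silences everything
  expect_equal(nrow(find_terminus_stacks(w$starts, w$ends, tr$chrom,
                                         tr$strand, tr$D,
                                         rpm_min = 1e9)), 0)
})

test_that("end stacks imply a cleavage site one nt downstream", {
  # single read ending (biological 3') at position 119 -> implied site 120
  reads <- tibble::tibble(chrom = "chr1", start = 100, end = 120,
                          name = "r", score = 40, strand = "+")
  starts <- count_read_starts(reads, weight = "score",
                              library_size = 1e6)
  ends <- count_read_ends(reads, weight = "score", library_size = 1e6)
  stacks <- find_terminus_stacks(starts, ends, "chr1", "+", D = 60)
  # the read start itself also qualifies as a stack (implied site 100);
  # the end stack implies the site one nt past the 3' end
  expect_setequal(stacks$site, c(100, 120))
  end_stack <- stacks[stacks$site == 120, ]
  expect_equal(end_stack$delta, 60)
  expect_equal(end_stack$side, "downstream")
  expect_equal(end_stack$rpm, 40)
})

test_that("overhang computation handles paired, slid and absent duplexes", {
  # perfect hairpin: partner(five) = three_end - 2 -> overhang 2
  st <- list(pair_table = parse_dotbracket("((((....)))).."))
  class(st) <- "rna_structure"
  # five_idx 1 pairs 12; with three_end 14 the overhang is 2
  expect_equal(compute_overhang(st, 1, 14), 2)
  # blunt duplex: three_end = partner -> overhang 0
  expect_equal(compute_overhang(st, 1, 12), 0)
  # overhang 5 is computed (gating is the caller's job)
  st5 <- list(pair_table = parse_dotbracket("((((....)))).....")) |>
    structure(class = "rna_structure")
  expect_equal(compute_overhang(st5, 1, 17), 5)
  # unpaired five_idx slides inward with compensation
  stu <- list(pair_table = parse_dotbracket(".(((....)))..")) |>
    structure(class = "rna_structure")
  # five_idx 1 unpaired, slide to 2 (partner 11): (13 - 11) - 1 = 1
  expect_equal(compute_overhang(stu, 1, 13), 1)
  # nothing paired within max_shift -> typed error
  expect_error(compute_overhang(stu, 1, 13, max_shift = 0),
               class = "droshascan_no_duplex")
})

test_that("planted hairpins reconstruct with exact geometry", {
  w <- clean_world(seed = 91)
  anchors <- tibble::tibble(chrom = w$gb$truth$chrom,
                            strand = w$gb$truth$strand,
                            pos = w$gb$truth$D)
  calls <- call_stemloops(anchors, w$srna, w$gb$genome)
  expect_true(all(calls$resolved))
  expect_equal(calls$S, w$gb$truth$S)
  expect_equal(calls$D, w$gb$truth$D)
  expect_equal(calls$overhang, w$gb$truth$overhang)
  expect_true(all(calls$orientation == "upstream"))
  # window arithmetic: length = span + 2 * flank + 1 (inclusive ends)
  expect_equal(nchar(calls$sequence), w$gb$truth$span + 31L)
})

test_that("orientation symmetry: minus-strand hairpins anchor identically", {
  w <- clean_world(seed = 93)
  tr <- w$gb$truth
  expect_true(all(c("+", "-") %in% tr$strand))
  anchors <- tibble::tibble(chrom = tr$chrom, strand = tr$strand,
                            pos = tr$D)
  calls <- call_stemloops(anchors, w$srna, w$gb$genome)
  for (s in c("+", "-")) {
    sel <- calls$strand == s
    expect_true(all(calls$resolved[sel]))
    expect_equal(calls$overhang[sel], tr$overhang[sel])
  }
})

test_that("unstructured windows are rejected for lack of a duplex", {
  set.seed(95)
  # an A/C-only genome cannot pair at all
  genome <- c(chrU = paste(sample(c("A", "C"), 2000, TRUE), collapse = ""))
  stack <- tibble::tibble(chrom = "chrU", strand = "+", D = 1000,
                          site = 940, delta = -60, side = "upstream",
                          rpm = 50, count = 50)
  call <- reconstruct_stemloop(genome, stack)
  expect_false(call$accepted)
  expect_match(call$reason, "no duplex")
})

test_that("the accepted overhang set is exactly 0..4", {
  # synthetic duplexes with planted overhang 0..6: gate passes only 0..4
  set.seed(97)
  for (ov in 0:6) {
    hp <- design_hairpin(hairpin_spec(stem_length = 20, loop_length = 6,
                                      lower_stem_length = 8, overhang = ov,
                                      motif_flags = character(),
                                      gc_bias = c(0.8, 0.2, 0)))
    genome <- c(chrT = chartr("U", "T", hp$sequence))
    stack <- tibble::tibble(chrom = "chrT", strand = "+", D = hp$D,
                            site = hp$S, delta = hp$S - hp$D,
                            side = "upstream", rpm = 10, count = 10)
    call <- reconstruct_stemloop(genome, stack)
    expect_equal(call$overhang, ov)
    expect_equal(call$accepted, ov <= 4)
  }
})

test_that("the deepest stack wins; ties break toward canonical geometry", {
  w <- clean_world(seed = 99, n_mi = 3, n_mr = 0)
  tr <- w$gb$truth[1, ]
  sgn <- if (tr$strand == "+") 1L else -1L
  # add a decoy stack 10 nt upstream of S with lower depth: real S wins
  decoy_site <- tr$S - sgn * 10L
  decoy <- tibble::tibble(chrom = tr$chrom,
                          start = ifelse(tr$strand == "+", decoy_site,
                                         decoy_site - 21L),
                          end = ifelse(tr$strand == "+", decoy_site + 22L,
                                       decoy_site + 1L),
                          name = "decoy", score = 3, strand = tr$strand)
  srna2 <- dplyr::bind_rows(w$srna, decoy)
  anchors <- tibble::tibble(chrom = tr$chrom, strand = tr$strand,
                            pos = tr$D)
  call <- call_stemloops(anchors, srna2, w$gb$genome)
  expect_equal(call$S, tr$S)
})

test_that("anchors without sRNA support are reported unresolved", {
  gb <- small_world(2, 0, 20000, seed = 101)
  # one stray read far from every anchor: no qualifying stack
  stray <- tibble::tibble(chrom = gb$truth$chrom[1], start = 10L,
                          end = 32L, name = "stray", score = 5,
                          strand = "+")
  anchors <- tibble::tibble(chrom = gb$truth$chrom,
                            strand = gb$truth$strand, pos = gb$truth$D)
  calls <- call_stemloops(anchors, stray, gb$genome)
  expect_true(all(!calls$resolved))
  expect_match(calls$reason[1], "no terminus stack")
})
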