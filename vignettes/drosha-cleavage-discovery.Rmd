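---
title: "Discovering Drosha cleavage sites from Degradome and small-RNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Drosha cleavage sites from Degradome and small-RNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droshascan)
```

## The model and its assumptions

Drosha, the nuclear RNase III enzyme of the microprocessor, cleaves
stem-loops in primary transcripts. Each cleavage event cuts both strands
of the stem with a 2-nt offset, so the released hairpin carries a 3'
2-nt overhang, and the downstream fragment carries a 5' monophosphate.
Degradome sequencing captures polyadenylated 5'P fragments: read 5'
starts therefore stack homogeneously at the 3'-arm cut (`D`).
Small-RNA sequencing captures the processed products: miRNA-like reads
whose 5' end sits exactly at the 5'-arm cut (`S`) and moRNA-like reads
from the adjacent sequence whose proximal terminus marks the cut while
the distal terminus is ragged (exonucleolytic trimming). The pipeline
assumes exactly this generative picture, and the synthetic-data module
simulates it explicitly so every stage can be validated against planted
ground truth.

The stages and their contracts:

1. `count_read_starts()` / `counting_vector()` build per-position
   5'-start counts `C5` (RPM-normalized) and the 21-feature vector at
   offsets −10…+10 around a locus, on the locus strand.
2. `train_pileup_classifier()` fits a cross-validated lasso/elastic-net
   logistic model (`glmnet::cv.glmnet`, `type.measure = "class"`,
   10 folds) on known cleavage sites versus 1000 genomic negatives;
   metrics are computed on the *prevalidated* held-out fold scores, and
   the model counts as trained only when sensitivity, specificity and
   AUC all exceed 0.9. `consensus_pileup()` repeats draw–train–classify
   `n_iterations` times and accepts a locus only with more than
   `accept_fraction` positive classifications in *every* control
   replicate (strictly greater, matching the ">900 of 1000" rule;
   the desk preset scales to 100 iterations — acceptance is defined on
   vote fractions, not absolute counts).
3. `test_differential()` hands the per-locus count matrix to edgeR —
   the toolchain the original analysis used — with TMM normalization,
   `estimateDisp()`, and `glmQLFit()/glmQLFTest()` by default
   (`method = "lrt"` switches to the likelihood-ratio test). The
   dependence gate is one-sided, `log2FC < -1.5` (knockout minus
   control, so loss is negative) and `FDR < 0.05`; a `two_sided` flag
   covers the magnitude variant used for gene-level expression.
4. `call_stemloops()` pairs each dependent anchor `D` with sRNA terminus
   stacks whose implied cleavage site lies 25–100 nt away (closed
   interval; start stacks imply a site at the start, end stacks one nt
   further downstream) and exceeds 1 RPM. The window from `S − 15` to
   `D + 15` (inclusive ends) is folded and the candidate is accepted
   when the product termini bound a duplex end with a 3' overhang of
   2 ± 2 nt. Both orientations are always scanned: upstream (canonical)
   and downstream (the single-5'-arm-cleavage, inverse case, where the
   hairpin lies 3' of the pile-up). Among accepted candidates the one
   with the deepest sRNA support wins; ties break by overhang closest
   to 2, then the shorter hairpin, then the most-upstream site.
5. `stemloop_features()`, `annotate_positions()`, `scan_motifs()` and
   `compare_groups()` compute the per-substrate feature set (see below).

## The built-in folding model

The production analysis used an external thermodynamic folder; this
package instead ships a deliberately small stacking model so that every
downstream statistic is exactly verifiable:

* allowed pairs: Watson–Crick plus G·U wobble;
* energy: the sum over adjacent stacked pairs — −3 for two G-C pairs,
  −2 when exactly one of the two pairs is G-C, −1 otherwise; unpaired
  bases are free;
* hairpin loops hold at least `min_loop = 3` unpaired bases; lone pairs
  are forbidden by default (mirroring the production folder's `--noLP`);
* `temperature_scale` (default 1, model units) sets the Boltzmann
  weight `exp(-E/kT)`.

`rna_fold()` computes the MFE structure with a dynamic program over the
grammar (pair-with-outward-stack, validated pair, interval), and
`rna_ensemble()` runs the matching inside–outside pass for base-pair
probabilities, from which positional entropy
\(H_i = -\sum_j p_{ij}\ln p_{ij} - q_i \ln q_i\) (natural log — the
choice is arbitrary and documented so the enumeration oracle agrees) and
ensemble diversity \(\sum_{i<j} 2 p_{ij}(1-p_{ij})\) follow.
`enumerate_structures()` is an independent brute-force enumerator
(sequences up to 20 nt); the test suite checks DP-versus-enumeration
agreement to 1e−9 on random panels, with and without the lone-pair ban
and at different temperatures.

Numerical choices: energies are small integers, so partition sums stay
within double range for windows up to a few hundred nt (an overflow
guard errors with advice to shorten the window). MFE ties are broken by
a deterministic traceback (stacking branch first, then the hairpin
branch, then the smallest split point) rather than by a global
lexicographic rule; co-optimal structures are therefore reproducible but
not lexicographically minimal. Geometry downstream (the overhang test)
uses the MFE structure; the production pipeline's settings listed an MEA
decoder among its options but never states which structure feeds the
overhang test, so the MFE structure was chosen and is flagged here.

Constraints (`fold_constraint()`) force pairs or forbid positions; the
cleavage-anchored structural annotation refolds each call with 25-nt
flanks while forcing every 15-nt-flank pair to stay paired, which is the
published procedure for extending the window without losing the stem
(the constrained refold is always feasible because the forced pairs come
from a valid structure; a fallback to an unconstrained fold warns if a
user supplies impossible constraints).

## The synthetic world

`build_genome()` plants two substrate classes on an i.i.d.-uniform
background genome (both strands, ≥ 200 nt apart):

* **miRNA-like** (canonical): upper stem 35 ± 1 bp, terminal loop
  11–14 nt, lower stem 13 bp (the distance Drosha cuts from the basal
  junction), at most one small symmetric internal loop, G-C-rich
  pairing (60/32/8% G-C/A-U/G-U), planted basal UG (U at anchored −14),
  apical UGU and CNNC (first C 17 nt past the 3'-arm cut) motifs,
  3' overhang 2.
* **mRNA-like** (suboptimal): stem 24–28 bp (~26), variable loop
  (4–16 nt), 1–3 asymmetric internal loops, weaker pairing
  (38/48/14%), no motifs.

Values not fixed by the biology above (flank length 25 nt, loop-length
ranges, the gc-bias triplets) were chosen once as representative of
murine pri-miRNA substrates and are configurable but not tuned.
Unpaired filler sequence is drawn from {A, C} — two letters that cannot
pair with each other under the model — and terminal-loop filler from C
alone so that a planted U/G/U triplet cannot recruit a stacked pair and
the loop provably stays open. Every planted hairpin is checked at
generation time to refold with the planted duplex end and to keep
25 ≤ D − S ≤ 100 so it is discoverable by the scan.

`simulate_degradome()` draws NB counts (mean `signal_depth = 100`,
dispersion 0.1) at each cleavage site, jitters read starts by ±1 nt with
probability 0.05 per side, multiplies knockout means by the depletion
factor 0.1 (comfortably beyond the log2FC < −1.5 gate), and adds
homogeneous Poisson background (0.005 starts per position per strand).
The background model is an assumption — the original study never models
background degradation — chosen for the analytic tractability of
false-positive checks. Degradome reads are fixed 50-mers; only 5'
starts are analyzed. `simulate_srna()` emits miRNA-like reads
(20–24 nt, proximal terminus exact) and moRNA-like reads (length
15 + geometric, ragged distal terminus) on both arms and collapses
identical coordinates with the multiplicity in the BED score; terminus
RPM and library size both count multiplicities.

Two deliberate world-structure decisions deserve emphasis:

* **Decoy sites.** Most pile-up sites in the real data are *not*
  Drosha-dependent (roughly a quarter were). The desk preset therefore
  plants 600 Drosha-independent decoy cleavage sites alongside the 200
  hairpins. Without them every tested locus would be depleted in the
  knockout and TMM — which assumes most features unchanged — would
  normalize the depletion away; the decoys are the biological anchor
  that makes the differential contrast identifiable, exactly as the
  non-dependent pile-ups are in real libraries.
* **Depleted fraction in the calibration world.** For the differential
  calibration check, 100 depleted loci sit among 2000 nulls (~5%); at
  much higher depleted fractions the trimmed M-value window becomes
  contaminated and TMM partially absorbs the effect — a known property
  of TMM, not of this implementation.

What a green synthetic test does **not** establish: the generator has no
sequencing errors, no alignment ambiguity, no transcript-boundary
effects, no position-dependent background, and its hairpins fold
unambiguously under the toy model; real libraries are messier in all of
these ways, so green tests validate the procedure's logic, not its
field performance.

## Feature definitions

For a call with product from `S` to `D − 1` (span `D − S`):

* `length` = span + 30 + 1 — the folded window with 15-nt flanks,
  inclusive ends;
* `bp_frequency` = pairs / length, `max_stack` = longest run of
  consecutively stacked pairs / length;
* lower vs upper stem assignment of each pair by the anchored sign of
  its 5'-side nucleotide (anchored +1 = first product nucleotide; the
  cut lies between −1 and +1; 0 is never used), compositions normalized
  within each stem;
* structural categories P/F/I/B/T from the constrained 25-nt-flank
  refold; symmetric internal loops are I, asymmetric loops and bulges B,
  and (rare, warned) multibranch-loop positions fall back to B;
* internal loops are cataloged by the anchored position of their first
  5'-arm interior nucleotide and binned into 5-bp windows
  (`bin = (pos − 1) %/% 5 + 1` for positive anchored positions);
* information bits per aligned anchored position:
  `log2(A) + sum(f log2 f)` with a minimum-coverage mask (default 5);
* motif windows follow the canonical literature positions: basal UG with
  U at anchored −14 (±1 nt), apical UGU/GUG inside the terminal loop,
  CNNC starting 16–18 nt past the 3'-arm cut, and mGHG read 5'→3' on the
  3' strand opposite anchored −7…−5 with a mismatched central base. The
  mid-stem motif mentioned in passing in the source literature has no
  operational definition and is excluded by default.
* `compare_groups()` runs two-tailed Welch t-tests per feature with no
  multiplicity correction, matching per-feature reporting.

For downstream-orientation (inverse) calls the anchoring uses the
inferred product boundary (the pile-up site is then the *5'*-arm cut);
this case is flagged in the `orientation` column.

## Open design points and their resolutions

* *Positive-locus convention.* The published wording places training
  positives immediately upstream of the 5p arm's 5' end and downstream
  of the 3p arm's 3' end. For a 5'P-capture protocol, a fragment starts
  *at* a cut, so both conventions are implemented
  (`arm_cleavage_loci(convention = "as_written" | "at_product")`),
  default as written. In synthetic mode the truth table's pile-up loci
  are the planted Degradome stack positions themselves (only the
  polyA-bearing downstream fragment produces a stack), which keeps
  training self-consistent.
* *Unpaired S.* When the product's 5' nucleotide is unpaired in the MFE
  structure, the duplex end is located by sliding up to `max_shift = 2`
  nt inward with compensation; candidates with no duplex within reach
  are rejected with a typed condition.
* *Window truncation.* Windows crossing a chromosome end are truncated
  with a warning rather than dropped.
* *Candidate universe.* Scoring every genomic position is wasteful;
  candidates are positions with nonzero 5'-start coverage in any
  replicate (a zero-coverage position cannot be a pile-up). Configurable
  via the `candidates` argument.
* *Differential engine.* edgeR stands behind the module (the original
  toolchain); quasi-likelihood F-tests by default, LRT as an option.
  P-values are engine-specific; the (log2FC, FDR) gate is the contract.

## Known limitations

The toy energy model has no loop penalties, dangles or full
nearest-neighbour parameters, so absolute MFE values are in model units
and only comparative statements carry over to thermodynamic reality; a
production folding backend can be swapped in behind the same
`rna_structure` contract (`backend_id` records the origin). Consensus
classification refits `cv.glmnet` per iteration and replicate, which is
the runtime bottleneck at full scale. No attempt is made to quantify
mature miRNA abundance, to model clustered hairpins jointly, or to run
gene-level expression pipelines.
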