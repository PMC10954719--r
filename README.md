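# droshascan

Discovery and characterization of Drosha cleavage sites from
Degradome-seq and small-RNA-seq read coordinates.

## The problem

The nuclear RNase III enzyme Drosha initiates microRNA biogenesis by
cleaving stem-loops in primary transcripts, leaving a 5'-monophosphate on
the downstream fragment and a signature 3' 2-nt overhang on the released
duplex. Degradome sequencing (PARE) captures polyA fragments bearing a
5' monophosphate, so read 5' starts stack precisely at cleavage sites —
but only on the 3' arm of the stem-loop. Small-RNA-seq captures the
by-products of processing (miRNAs and miRNA-offset RNAs, moRNAs) whose
proximal termini mark the cut on the opposite arm.

`droshascan` implements the full computational route from read
coordinates to characterized substrates, for people analyzing
Degradome/PARE experiments with matched knockout conditions:

1. **Pile-up detection.** Per-position 5'-start counts \(C5\) feed a
   21-feature counting vector
   \(C_i = (C5_{i-10}, \ldots, C5_i, \ldots, C5_{i+10})\) (RPM).
   A cross-validated elastic-net logistic model is trained on known
   cleavage sites against 1000 resampled genomic negatives, re-trained
   over many iterations, and a locus is accepted when it is positively
   classified in more than 90% of iterations in **every** control
   replicate. The model must reach sensitivity, specificity and AUC all
   > 0.9 on held-out folds.
2. **Condition dependence.** Raw counts at candidate loci are
   TMM-normalized and tested with edgeR's negative-binomial
   quasi-likelihood machinery; a site is Drosha-dependent when
   `log2FC < -1.5` (knockout vs control) and `FDR < 0.05`.
3. **Stem-loop reconstruction.** For each dependent anchor `D`, sRNA
   terminus stacks (> 1 RPM) 25–100 nt away propose the opposite-arm cut
   `S`; the window `S-15 .. D+15` is folded and the call is accepted when
   the two cuts bound a duplex end with a 3' overhang of 2 ± 2 nt
   (both upstream and inverse, downstream orientations are scanned).
4. **Substrate features.** MFE, length, base-pairing frequency, maximum
   stacking, lower/upper-stem pair composition, ensemble diversity and
   positional entropy (from the built-in partition function),
   cleavage-anchored P/F/I/B/T structural annotation under a constrained
   25-nt-flank refold, internal-loop catalogs, information-bits matrices,
   and scans for the basal UG, apical UGU, CNNC and mGHG motifs, with
   Welch t comparisons between substrate classes.

Folding uses a fully self-contained stacking energy model (G-C/G-C
stacks −3, mixed −2, other −1; lone pairs banned; hairpin loops ≥ 3 nt)
whose MFE, partition function, base-pair probabilities, positional
entropy and ensemble diversity are exactly verifiable against exhaustive
enumeration — see the methods vignette.

A first-class synthetic-data generator (`build_genome()`,
`simulate_degradome()`, `simulate_srna()`) plants ground-truth hairpins
— canonical miRNA-like substrates (~35 bp stems, motifs planted) and
suboptimal mRNA-like ones (~26 bp stems, asymmetric loops) — so the
whole pipeline is testable end to end with a machine-readable truth
table.

## Worked example

```r
library(droshascan)

run <- run_pipeline(desk_config(seed = 1, n_mirna_like = 14,
                                n_mrna_like = 8, genome_length = 35000,
                                n_decoy_sites = 60, n_iterations = 8,
                                n_negatives = 300))
run
#> <drosha_run>
#>   planted hairpins:     22
#>   candidate loci:       955
#>   accepted pile-ups:    63
#>   Drosha-dependent:     19
#>   resolved stem-loops:  19 (+0 unresolved)
#>   classifier:           sens 1.000 spec 0.997 auc 0.997
#>   classes:              12 miRNA / 7 non-miRNA
```

Twenty-two hairpins were planted (plus 60 Drosha-independent decoy
cleavage sites). The consensus classifier accepted 63 pile-up loci; the
differential gate kept 19 as Drosha-dependent (three planted loci missed
the strict every-replicate vote rule at this small scale); all 19 were
resolved into stem-loops with exact cleavage pairs, and classification
against the planted annotation recovered the miRNA / non-miRNA split.

Single pieces compose with pipes:

```r
st <- rna_ensemble("GGGAAACCC")
st
#> GGGAAACCC
#> (((...)))
#> MFE: -6 (backend: toy)
#> ensemble diversity: 0.9147
glance(run$classifier)    # held-out sensitivity/specificity/AUC
run$features |> compare_groups("class", c("mfe", "bp_frequency"))
```

## Acceptance script

`scripts/acceptance.R` regenerates the desk-preset synthetic dataset,
trains the pile-up classifier and reports its held-out sensitivity,
specificity and AUC, and computes the 3' overhang of a canonical
synthetic Drosha substrate:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
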