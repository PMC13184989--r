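# selscape

Enrichment and sequence–activity landscape analysis for **single-step in
vitro selections** of catalytic DNA (deoxyribozyme) libraries.

## The problem

A self-phosphorylating deoxyribozyme is mutagenised at a defined set of
positions — here a 47-nt catalytic core with 14 variable positions: ten
fully random (N) bulge positions and two base pairs (16–42 and 17–40)
encoded by R-Y or Y-R degeneracy, an encoded space of
4¹⁰ × 8 × 8 = 67,108,864 genotypes. One round of selection with a
phosphate-donor substrate enriches reactive genotypes; deep sequencing
turns enrichment into numbers. Running parallel selections with two similar
substrates (4-MUP, diFMUP) measures *substrate specificity* per genotype.

`selscape` is the downstream pipeline for this kind of experiment, for
people analysing selection sequencing data or studying sequence–fitness
landscape modelling:

* **Library model** — exact combinatorics of IUPAC templates with
  paired-position constraints (`library_size()`, `pairing_fraction()`,
  orientation sublibraries, enumeration and uniform sampling).
* **Read processing** — merged FASTA/FASTQ reads → oriented, scaffold-matched,
  variable-position-extracted genotype tables normalised to counts per
  million: CPM = count × 10⁶ / total reads (`process_reads()`).
* **Specificity scoring** — inner merge of two arms and the score
  s = log₂(CPM_A / CPM_B) (`merge_common()`).
* **Mutation effects** — per-position stratification of scores, effect
  ranking by the range of per-base medians, permutation-null calibration
  (`rank_positions_by_effect()`).
* **Sequence→activity models** — one-hot encoded multilayer-perceptron
  regression of CPM and specificity (defaults reproduce the reference
  model: layers [200, 200, 200], α = 0.001, lr 0.01, batch 100, early
  stopping, ≤ 200 epochs), 80/20 split, nested downsampling learning
  curves, 3-fold CV grid search, Spearman/R²/MAE, and positional-frequency
  baselines (`fit_network()`, `learning_curve()`, `baseline_positional()`).
* **Selection simulator** — a seeded generator with a ground-truth
  genotype→reacted-fraction landscape per substrate, single-round
  enrichment and multinomial read sampling, plus four registered benchmark
  scenarios for parameter-recovery testing (`make_benchmark()`).
* **Pipeline** — `run_pipeline()` orchestrates
  simulate → process-reads → enrich → mutscan → train → report from one
  JSON config with derived per-stage seeds; a CLI lives at
  `inst/cli/selscape.R`.

## Worked example

Simulate a benchmark whose two substrates differ only at positions
20, 21, 33 and 34, then recover that from the sequencing tables alone:

```r
library(selscape)

spec <- aurora_bulge_spec()
spec
#> library_spec: 47-nt core, 14 variable positions, 2 pair constraint(s)
#>   positions: 16, 17, 20, 21, 22, 23, 33, 34, 35, 36, 37, 40, 41, 42
#>   encoded genotypes: 67,108,864
pairing_fraction(spec)
#> [1] 0.5625

sim <- make_benchmark("specificity-planted", seed = 101,
                      n_distinct = 2e4, depth = 2e5)
sim$post_counts[["4MUP"]]
#> genotype_counts [4MUP]: 18493 unique genotypes, 200000 reads
#>              genotype count   cpm
#>     1: TATGTGGGGTGCAA    71   355
#>     2: TTTTCAACTCTAAA    69   345
#>     3: TTTTATAGTGGATA    67   335
#>    ---

m <- merge_common(sim$post_counts[["4MUP"]], sim$post_counts[["diFMUP"]])
attr(m, "n_common")
#> [1] 16315

eff <- rank_positions_by_effect(m, spec, min_cpm = 10, min_n = 10)
unique(eff[, c("position", "effect_range", "rank")])[1:5, ]
#>    position effect_range  rank
#> 1:       34   2.23849500     1
#> 2:       20   2.14055594     2
#> 3:       21   1.32192809     3
#> 4:       33   0.88981708     4
#> 5:       35   0.08246216     5

run <- specificity_regression(m, split_plan(fractions = 1, seed = 2),
                              network_config(hidden_layer_sizes = c(64, 64),
                                             max_iter = 80),
                              seed = 3, spec = spec)
run$metrics
#> rho = 0.841, R^2 = 0.702, MAE = 0.6681 (n = 3263)
```

Reading the output: the four planted positions occupy exactly the top four
effect ranks, with a sharp drop to rank 5 (0.082) — the per-position
stratification of log₂ CPM ratios recovers where specificity is encoded.
The held-out R² of 0.70 says a network trained on 13k genotypes predicts
the specificity scores of unseen genotypes well in this (deliberately
learnable) scenario; the `"imbalanced"` scenario shows the opposite regime,
where score regression is much harder than CPM regression.

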