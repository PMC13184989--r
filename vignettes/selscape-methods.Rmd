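---
title: "Methods: modelling single-step selections of self-phosphorylating DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling single-step selections of self-phosphorylating DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selscape)
```

## The experiment this package models

A self-phosphorylating deoxyribozyme (a catalytic single-stranded DNA that
transfers a phosphate from a small-molecule substrate onto its own 5'
hydroxyl) is mutagenised at a defined set of positions and subjected to a
*single-step selection*: the library is incubated with one substrate,
reacted (5'-phosphorylated) molecules are tagged by ligation, purified,
amplified and sequenced. Because only one round is performed, enrichment is
read out directly from sequence counts: a genotype's post-selection
abundance is proportional to its pre-selection abundance times its reacted
fraction. Running parallel selections with two chemically similar substrates
(here labelled 4-MUP and diFMUP) turns the same readout into a
*specificity* measurement.

`selscape` implements the full downstream analysis:

1. **Library combinatorics** (`aurora_bulge_spec()`, `library_size()`,
   `pairing_fraction()`): the 47-nt core with 14 variable positions — ten
   fully random N positions and two base pairs (16–42, 17–40) encoded by
   R-Y or Y-R degeneracy. The encoded space is
   $4^{10} \times 8 \times 8 = 67{,}108{,}864$ genotypes, and per
   constrained pair 6 of the 8 encoded duplets can pair (Watson–Crick plus
   G-T/T-G wobbles), giving a pairing fraction of $(6/8)^2 = 0.5625$.
2. **Read processing** (`process_reads()`): merged amplicon reads are
   oriented against the fixed scaffold, matched at the 33 fixed positions,
   and the 14 variable positions are extracted; unique genotypes are counted
   and normalised to counts per million, $\mathrm{CPM} = c \times 10^6 / N$.
3. **Specificity scoring** (`merge_common()`): arms are inner-joined on
   genotype and each common genotype gets
   $s = \log_2(\mathrm{CPM_A}/\mathrm{CPM_B})$.
4. **Mutation effects** (`rank_positions_by_effect()`): scores are
   stratified by the base at each variable position; the effect statistic is
   the range of per-base median scores, calibrated against a permutation
   null.
5. **Sequence–activity models** (`fit_network()`, `learning_curve()`):
   one-hot encoded genotypes (position-major, base order A,C,G,T; 56
   features) are regressed on CPM or score with a feed-forward network,
   using an 80/20 split, nested training-set downsampling, and 3-fold CV
   grid search; evaluation reports Spearman rho, $R^2$ about the test-set
   mean, and MAE.

## The reference model and its hyperparameters

The regressor is a multilayer perceptron with ReLU hidden units, linear
output, squared-error loss with L2 penalty, and minibatch Adam — the
semantics of the scikit-learn `MLPRegressor` the original analysis used.
The default configuration is the published final model: hidden layers
`[200, 200, 200]`, `alpha = 0.001`, constant learning rate `0.01`, batch
size 100, early stopping on, `max_iter = 200`. Free details the reference
does not pin down follow the common defaults: a 10% internal validation
split scored by $R^2$, patience of 10 epochs, improvement tolerance `1e-4`,
Glorot-uniform initialisation.

No multilayer NN regressor exists in the supported R dependency stack, so
the engine is implemented in-package in base R matrix code (BLAS-backed).
Two implementation choices worth knowing:

* **Target centring.** The target is centred internally (the offset is
  added back at prediction). Raw CPM targets have means far from zero, and
  at desk-scale data sizes (hundreds of Adam steps per epoch rather than the
  thousands available at full scale) an uncentred output bias wastes a large
  share of the step budget; a constant target is returned exactly as a
  degenerate fit.
* **Early stopping restores the best weights**, and on noisy targets it
  stops early by design: longer training visibly overfits counting noise
  (this is observable in the acceptance tests, where the best validation
  epoch is reached within a few epochs at 10× coverage).

The positional-frequency baselines (`baseline_positional()`) are the
"simpler models" contrast: a main-effects model of per-position nucleotide
identities, and a variant adding duplet terms at the constrained pairs. They
are fitted by least squares on the one-hot design rather than by raw
per-base means: the two encoded base pairs make positions correlated, and
marginal means are biased exactly there, which would handicap the baseline
even on perfectly additive data. With independent positions the two
estimators coincide.

## The synthetic-data generator

Because the study's sequencing data are not redistributed, the package
ships a seeded selection simulator (`make_benchmark()`) whose outputs have
the statistical shape the analysis assumes: a ground-truth genotype →
reacted-fraction landscape per substrate, one deterministic selection step
(post ∝ pre × reacted fraction), and multinomial read sampling. Defaults:
pools of 1e5 distinct genotypes, 1e6 reads per arm (10× mean coverage, so
many low-count and few high-count genotypes), Dirichlet concentration 100
for synthesis skew (±10% around equimolar — the heavy abundance skew in
sequenced selections comes from selection itself, not synthesis), and a
small non-specific background reaction where a scenario calls for it
(nonspecific ligation is always present in the real assay).

The landscape is `p = bg + (1 - bg) · link(intercept + score)` with
`score` a sum of additive per-position/base effects, optional pairwise
(duplet) epistatic terms, an optional bonus per satisfied base pair, and an
optional *rugged* component: idiosyncratic per-genotype deviations that are
part of the deterministic ground truth but not a smooth function of
sequence (activity cliffs).

Four registered scenarios:

* **additive** — both substrates share one landscape whose reacted fraction
  is an exact sum of positive, lognormal per-position effect cells
  (identity link). This is the regime where the main-effects baseline is
  correctly specified, so network and baseline must tie; it also bounds
  what additivity can deliver: a sum of 14 positive per-position terms has
  relative sd at most ≈ 0.46 (the all-mass-on-one-base profile), which
  caps the achievable $R^2$ against *sampled* CPM at 10× coverage at about
  0.68. This is why parameter-recovery checks score models against the
  sequence-determined expected CPM (`expected_cpm(..., equimolar = TRUE)`)
  rather than against the noisy draw — see "Evaluation targets" below.
* **epistatic** — adds positive pairwise duplet cells at six random
  position pairs carrying most of the signal variance; a main-effects model
  necessarily misses it, the network must not.
* **specificity-planted** — logistic landscapes identical between
  substrates except at positions 20, 21, 33 and 34, where the second
  substrate's effects are shifted. The mutation-effect ranking must
  recover exactly this set.
* **imbalanced** — arm A is a heavy-tailed logistic landscape over a
  sizeable background (a continuum of enriched genotypes whose raw CPM is
  predictable), while arm B reacts appreciably only through rugged
  per-genotype cliffs (sd 5 on the logit) over a very low background, so B
  has few enriched genotypes and they are unlearnable from sequence. Among
  the genotypes common to both arms, arm-B counts sit near 1 read and the
  log2 CPM-ratio is dominated by counting noise and cliffs: the score
  distribution skews heavily positive and score regression is much harder
  than CPM regression — the two imbalance mechanisms the real two-substrate
  data display. This scenario was designed (and iterated during
  development, before freezing) specifically to exhibit that qualitative
  structure; its parameters are not calibrated to any measured dataset.

What the generator does **not** emulate: sequencing errors and quality
variation, PCR amplification bias, reaction-time kinetics, ligation
efficiency differences, and real secondary-structure constraints. A green
test therefore establishes that the pipeline recovers a known ground truth
under the stated statistical structure — not that the biology of any real
selection matches that structure.

## Evaluation targets for parameter recovery

At 10× coverage the Poisson noise floor means even a perfect model cannot
push $R^2$ against sampled CPM much beyond the signal share
$\mathrm{Var_s}/(\mathrm{Var_s} + \overline{\mathrm{CPM}})$. Recovery
criteria are therefore evaluated in two deliberate ways:

* *Parameter recovery* (the "noiseless"/"noisy" contrast): the model —
  trained either on the true expected CPM or on a sampled table — is scored
  against the **true expected CPM under an equimolar pool** on held-out
  genotypes. This measures how much of the landscape the model recovered,
  independent of irreducible noise in the evaluation target, and excludes
  the pool's synthesis skew, which no sequence model can predict.
* *Model-class comparisons* (network vs baseline) are scored on the
  **observed** targets both models were trained on, mirroring how the
  corresponding real-data comparison is made.

## Numerical and interface choices

* Log base 2 for the specificity score, recorded in output metadata;
  arm-exclusive genotypes get no score (a display-only half-minimum
  pseudocount exists solely for scatter exports).
* Ranked outputs break count ties lexicographically by genotype, so "most
  abundant sequence" is deterministic.
* Read processing defaults to an exact scaffold match (mismatch budget 0)
  and drops reads with ambiguous bases at variable positions; FASTQ
  qualities are parsed but not filtered on unless a mean-Q threshold is
  given. These are conservative guesses — the reference pipeline's pattern
  matching implies exact matching but does not state a quality filter.
* High-abundance analyses default to CPM ≥ 10; mutation-effect strata
  require ≥ 10 rows per base. Effect ranking uses the range of per-base
  median scores (robust to the heavy CPM tail); CPM-weighted means are
  reported alongside.
* Downsampling fractions default to geometric halvings
  {1, 1/2, 1/4, 1/8, 1/16, 1/32}, bracketing the ~12.5% regime where
  predictive power typically degrades; the exact fractions and the CV grid
  of the original study are not published, so these are declared
  substitutes (the published final configuration is always a grid point).
* Enumeration of genotype spaces refuses to materialise more than 1e7
  genotypes; sampling is the intended route above that.
* All randomness flows from explicit integer seeds; pipeline stages derive
  sub-seeds from one global seed keyed by stage name (`derive_seed()`), so
  stages can be rerun in isolation.
* Pre-selection abundance defaults to the equimolar expectation
  `1e6 / pool size` when no round-0 sequencing is supplied; the choice is
  recorded in the enrichment summary.
* The true 47-nt core sequence is not redistributed; the default
  `reference_core` is a synthetic placeholder (clearly documented as such),
  and every numeric result above is independent of the fixed bases.

## Known limitations

* The MLP engine is single-threaded R; it is sized for desk-scale data
  (up to ~1e5 rows, 56 features), not for production deep learning.
* `enumerate_genotypes()` sorts the materialised space, so truncated
  enumeration of spaces above the safety bound is refused rather than
  streamed.
* The rugged landscape component is defined only over the simulated pool's
  genotypes; unseen genotypes fall back to the smooth part of the
  landscape.
* Orientation handling assumes full-length merged reads; indels are not
  modelled (primer clipping is anchored, mismatch-only).
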