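---
title: "Models and methods: chiasma scoring, Poisson tests, and the gamma interference model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiasma)
```

This vignette is the package's account of its science: the models it fits,
the assumptions they carry, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## 1. Chiasma scoring from bivalent shapes

At metaphase I, a homolog pair connected by a single chiasma appears as a
rod, by two (one per arm) as a ring, and an unconnected pair as two
univalents. The scoring rule is therefore `univalent_pair → 0`, `rod → 1`,
`ring → 2`. The rule saturates at two: a bivalent carrying three or more
crossovers still looks like a ring, so shape scoring underestimates the true
crossover number. In a double-haploid mapping estimate rice carries about
28.3 crossovers per cell against a shape-scored frequency near 20.7, which is
why the package keeps the simulator's true per-bivalent event counts
(`n_class1`, `n_class2`) next to the shape class: the size of the
underestimate is itself measurable from simulated data.

Per-cell chiasma frequency is the sum of the per-bivalent scores; the
bivalent count is the number of rods plus rings (univalent pairs are not
bivalents). Genotypes are summarised as sample mean ± SD with n, matching
how cytological tables are conventionally printed (one decimal).

## 2. Poisson goodness of fit

If residual crossovers in a ZMM-pathway mutant are placed without
interference, per-cell totals should be Poisson. `poisson_gof()` estimates
the mean λ̂ by the sample mean, computes expected frequencies over integer
categories `0, 1, …, max` with an open upper tail, pools adjacent categories
inward from both tails until every expected frequency reaches
`min_expected`, and refers `Σ (obs − exp)²/exp` to chi-square with
`categories − 2` df (one lost to the total, one to λ̂).

Two conventions needed a decision:

* **Pooling threshold.** The default is `min_expected = 1`, not the
  textbook 5, to preserve resolution at cytological sample sizes (n ≈ 130
  cells); the threshold is an argument, so the conservative convention is one
  keystroke away. With `min_expected = 1` the test's type-I error is
  verified by simulation to sit within binomial error of the nominal 5%
  (a test in the suite).
* **Degrees of freedom.** Published chi-square values for such data
  sometimes come with dfs that cannot be reverse-engineered without the raw
  per-cell tables (different binnings give different dfs). `force_df` lets a
  user reproduce a p-value at a stated df; the statistic itself is
  unaffected. No attempt is made to reproduce any particular published
  chi-square numerically — raw per-cell distributions are generally printed
  only as figures.

## 3. Two-sample comparisons from summary statistics

Genotype contrasts are computed from `(mean, SD, n)` with the classical
pooled-variance t (df = n₁ + n₂ − 2), because that is the convention behind
printed statistics of the form t[249] = 19.9. The Welch variant is available
(`welch = TRUE`). A caveat the package cannot remove: recomputing t from
*rounded* printed summaries reproduces the printed t only to about one part
in a hundred — from (6.5, 2.1, 130) vs (2.1, 1.3, 121) the pooled t is
19.79, while the value computed from the unrounded raw counts was printed as
19.9. The arithmetic helpers `retention_percent()`, `class1_fraction()` and
`fold_change()` cover the standard derived quantities (percent of chiasmata
retained in a mutant, share of crossovers formed by the interference-
sensitive pathway, focus-count fold changes); all are scale-invariant ratios.

## 4. The gamma interference model

Distances between adjacent class I crossover markers on one chromosome,
expressed as percentages of SC length, are modelled as gamma:
*x* ~ Gamma(ν, θ) with shape ν the interference parameter. ν = 1 is
exponential gaps — a Poisson placement, no interference; ν ≈ 8 means gap CV
≈ 0.35, strongly regularised spacing. The model's key assumptions: gaps are
i.i.d. across and within chromosomes (so pooling across cells is licit), and
marker foci are a complete, exact readout of class I event positions.

### Estimators

* **MLE (default).** For gamma data the shape MLE solves
  `log ν − ψ(ν) = log x̄ − mean(log x)`; the package solves this by Newton
  iteration on log ν from the standard closed-form initialiser, then sets
  θ̂ = x̄/ν̂. The SE comes from the inverse observed Fisher information,
  `se(ν̂)² = ν̂ / (n (ν̂ ψ′(ν̂) − 1))`; a seeded nonparametric bootstrap is
  available because published SEs for such fits rarely state their method.
  Convergence is monotone and fast (< 20 iterations at double precision);
  near-constant gaps drive ν̂ → large with a correspondingly large SE rather
  than failing.
* **Method of moments.** ν̂ = (x̄/s)², the squared inverse CV. Less
  efficient, but independent of the likelihood machinery — the test suite
  requires MLE and MoM to agree within 10% at n = 5,000 across
  ν ∈ {1, 2, 4, 8.39, 12}, and requires the MLE to agree with an external
  gamma fitter to 4 decimals.
* **Binned least squares.** The traditional cytology procedure fits the
  gamma density to the relative-frequency histogram. Because bin widths for
  published fits are typically unstated, the default estimator is the MLE on
  raw distances and the binned fit is provided for fidelity and comparison
  (equal-width bins over the data range, integrated bin probabilities,
  Nelder–Mead on log-parameters with multistart from the MoM estimate).
  Consistency with the MLE within 15% on simulated data is part of the test
  suite.

### Distance extraction and the finite-window caveat

`interfocus_distances()` uses only interior gaps — consecutive focus pairs on
the same chromosome; the segments before the first and after the last focus
are excluded, and chromosomes with fewer than two foci contribute nothing.
End segments are excluded outright rather than treated as censored
observations, because under a stationary renewal placement the interior gaps
themselves are exactly gamma.

That exactness, however, holds for the unbounded process. On a chromosome of
finite relative length *T*, a gap is observed only if both endpoints fall
inside the window, which under-samples long gaps (the observable density is
proportional to f(x)(T − x)). On long windows the bias vanishes — the suite
verifies by Kolmogorov–Smirnov that gaps extracted from a long simulated SC
match Gamma(ν, 1/(νμ)) — but on short chromosomes carrying ~2 foci the
observed gaps run short and ν̂ lands above the generative shape (a dedicated
test pins the bias direction). Real short-chromosome inter-focus data share
this property, so a fitted ν from such data is an operational interference
measure tied to the chromosome's length, not a pure renewal parameter.
Published shape estimates from short-chromosome distances are treated
throughout as generative targets for recovery experiments, not as exactly
reproducible statistics. Parameter recovery itself is tight: at n = 5,000
unwindowed gaps the MLE recovers shapes across ν ∈ {1, …, 12} within 5%.

## 5. Colocalization

`coloc_fractions()` scores a focus of channel A as colocalized when any
channel B focus on the same cell and chromosome lies within a distance
tolerance, and reports both directions. Threshold matching (not optimal
bipartite assignment) was chosen: it is simpler, monotone in the tolerance,
and sufficient for fraction statistics; one-to-one matching matters only for
count-preserving analyses, which are out of scope. Whether published
colocalization fractions were scored by eye or by an explicit distance
criterion is usually unstated, so the tolerance — default 0.01, i.e. 1% of
SC length, roughly the resolution at which two immunofluorescence foci stop
being separable — is the single most consequential free parameter and is
carried in every result and printed in every report header. An empty channel
raises an error rather than returning 0: the fraction is undefined, and
silent zeros would masquerade as perfect anti-colocalization.

`fraction_outside_reference()` covers centromere-exclusion statistics: the
fraction of foci farther than the tolerance from a per-chromosome reference
position. For uniformly placed foci and an interior point reference the
expected fraction is 1 − 2·tolerance, which the suite checks by Monte Carlo.

## 6. The synthetic-data generator

Each cell carries 12 bivalents with relative SC lengths proportional to the
rice karyotype (normalised to mean 1, chromosome 9 shortest). Per bivalent,
two independent point processes are drawn:

* **Class I** (interference-sensitive): a gamma renewal process with shape
  `class1_nu` and density `class1_mu` events per unit SC. The first event is
  drawn from the equilibrium residual-life distribution — sampled exactly as
  U × (length-biased gap), with the length-biased Gamma(ν, β) being
  Gamma(ν + 1, β) — so the process is stationary and interior gaps are
  exactly gamma. An "ordinary" (origin-started) renewal is available for
  comparison; its interior gaps are also gamma, only the first-event law
  differs. Class I event positions are emitted as the `bright` focus
  channel, emulating prominent recombination-protein foci at class I sites.
* **Class II** (interference-free): homogeneous Poisson with rate
  `class2_rate` per unit SC. Whether residual mutant crossovers are
  spatially Poisson *along* chromosomes is not established by per-cell count
  data; the generator assumes spatial uniformity and flags that assumption
  here.

The shape class of each bivalent is `min(total events, 2)` mapped to
univalent-pair / rod / ring — scoring is pathway-agnostic, as chiasmata are
cytologically. No obligate-chiasma constraint is imposed: bivalents with
zero events become univalent pairs, which is exactly the mutant phenotype
logic.

**Genotype calibration.** Defaults are the published study conditions:

| genotype | class I | class II | rationale |
|---|---|---|---|
| WT | ν = 8.39, μ = 2.0/unit | 4 events/cell | ~2.0 bright foci per bivalent (≈24/cell); 28.3 total − 24.3 class I |
| hei10 | knocked out | scored mean 6.5 | published per-cell chiasma mean |
| mer3 | knocked out | scored mean 5.8 | ~28% of 20.7 retained |
| mer3hei10 | knocked out | scored mean 2.1 | published per-cell chiasma mean |
| zep1 | ν = 8.39, μ = 36.2/12 per unit | 4 events/cell | 36.2 bright foci/cell (~1.5× WT) |
| pair3 | μ = 1.2/12 per unit | 0 | ~1.2 residual bright spots/cell; a coarse emulation |

For class-II-only genotypes the event rate is not set to the printed chiasma
mean directly: because scoring caps each bivalent at 2, the scored mean falls
slightly below the event mean. The generator inverts the closed form
`E[score] = Σᵢ (2 − 2e^{−rLᵢ} − rLᵢe^{−rLᵢ})` (`calibrate_class2_rate()`), so
the *scored* chiasma mean matches the printed value in expectation — for the
6.5-chiasma genotype this puts the event rate at ≈6.8 events/cell. For WT no
such inversion exists (the class I count distribution has no closed form);
its parameters are fixed at the printed focus density and the scored mean is
emergent, ≈21.8 per cell, a little above the printed 20.7 because
per-bivalent capping reproduces only part of the real multi-crossover
undercount. No acceptance check asserts the WT scored mean tightly; what the
WT simulation must and does reproduce is the strong underdispersion that
makes Poisson goodness of fit fail decisively.

**Dual-channel generator.** `simulate_dual_channel()` gives both antibodies
the same underlying foci, then applies per-channel dropout, Gaussian jitter
(clamped to [0, 1]), and optional Poisson background. With tolerance 0.01
and small jitter, the directional fractions are ≈ (1 − dropout of the other
channel); the defaults (2.5% / 6.9%) therefore reproduce the published
93.1% / 97.5% asymmetric pair. Jitter SD defaults to 0.002 (0.2% of SC
length), well inside the matching tolerance, as co-registered
immunofluorescence channels are.

**What the generator does not emulate.** No 3D nucleus geometry or image
formation; no SC polymerisation or stage-resolved focus turnover (faint ~300
foci populations at leptotene are not modelled — the bright channel exists
only where class I events exist); no obligate chiasma; no inter-bivalent
correlation in event numbers. Passing tests on this generator therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to microscopy artefacts such as focus fusion,
segmentation error, or SC tracing error in real images.

## 7. Problem sizes and determinism

Every stochastic routine is driven by an explicit seed (`sim_config()`
refuses to run without one), and seeded runs are byte-identical — the
pipeline writes a config-echoing report header so each run is
self-describing. The test suite's simulation scales were chosen to make each
check statistically decisive while keeping the whole suite around three
minutes: 5,000 gaps for parameter-recovery checks (MLE SE ≈ 2% of ν at
ν = 8.39), 500 replicates of 130-cell populations for the type-I-error
calibration of the Poisson test (binomial SE ≈ 1%), 250 cells for the
wild-type rejection check, and ~19,000 base foci (800 cells) for
colocalization fractions (MC SE < 0.2%).

## 8. Known limitations

* The gamma model is fitted to pooled distances for one chromosome class;
  per-cell fits are deliberately not offered (n per cell is 1–2 gaps).
* Finite-window bias (section 4) means generative and fitted ν coincide only
  on long chromosomes; comparisons of ν̂ across genotypes remain valid when
  chromosome lengths are comparable.
* Shape-based chiasma scoring saturates at 2 per bivalent by construction;
  interpretations that need true crossover counts should use the simulator's
  event counts or independent genetic estimates.
* The colocalization tolerance is a modelling choice, not a measured quantity;
  conclusions should be checked for stability across a small tolerance range
  (the fractions are monotone in it, so this is a two-run check).
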