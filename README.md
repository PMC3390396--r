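# chiasma

Quantitative analysis of meiotic recombination cytology, built around the
statistics used to characterise crossover formation in rice pollen mother
cells (PMCs): chiasma counts read off metaphase I bivalent shapes, Poisson
tests of their per-cell distributions, genotype contrasts, gamma-model
estimation of crossover interference from inter-focus distances on the
synaptonemal complex (SC), and dual-channel focus colocalization fractions.
It is aimed at plant meiosis groups who score bivalent shapes and
immunofluorescence foci and want the downstream statistics reproducible,
tested, and scriptable — plus a seeded synthetic-data generator so every
analysis can be exercised against known ground truth.

## The statistics in brief

**Chiasma scoring.** At metaphase I a rod-shaped bivalent is scored as one
chiasma, a ring-shaped bivalent as two, and a pair of univalents as zero.
Per-cell totals give the chiasma frequency; the per-cell distribution is
tested against a Poisson law by a chi-square goodness-of-fit test with the
mean estimated from the data (df = categories − 2 after tail pooling).
Genotypes reported as mean ± SD are compared with the classical
pooled-variance two-sample t test (df = n₁ + n₂ − 2).

**Crossover interference.** Distances *x* between adjacent class I crossover
markers (prominent recombination-protein foci), expressed as percentages of
SC length, are modelled as a gamma renewal process:

&nbsp;&nbsp;&nbsp;&nbsp;*x* ~ Gamma(ν, θ),&nbsp;&nbsp; E[*x*] = νθ,&nbsp;&nbsp; CV = 1/√ν

The shape ν is the interference parameter: ν = 1 corresponds to exponential
gaps (a Poisson process, no interference); larger ν means gaps of more
uniform length, i.e. stronger interference. `fit_interference()` estimates ν
by maximum likelihood (default, with Fisher-information or bootstrap SE), by
the method of moments (ν̂ = (mean/sd)², an independent cross-check), or by
least squares on binned relative frequencies (the traditional cytology
procedure).

**Colocalization.** A focus in channel A is colocalized when a channel B
focus lies on the same chromosome within a distance tolerance (default 1% of
SC length). The two directional fractions are reported separately because
antibody dropout makes them asymmetric.

**Simulation.** Class I crossovers are placed by a stationary gamma renewal
process (equilibrium first event, so interior gaps are exactly gamma); class
II crossovers by a homogeneous Poisson process. Genotype presets knock out
pathways (`hei10`, `mer3hei10`: no class I) and are calibrated to published
per-cell chiasma means and bright-focus counts.

## Worked example

```r
library(chiasma)

# simulate a wild-type-like and a class-II-only mutant population
wt  <- simulate_meiosis(sim_config("WT",    n_cells = 130, seed = 1))
mut <- simulate_meiosis(sim_config("hei10", n_cells = 130, seed = 2))

summarize_genotype(chiasma_counts(mut$cells))
#> $mean
#> [1] 6.561538
#> $sd
#> [1] 2.375599
#> $n
#> [1] 130

poisson_gof(chiasma_counts(mut$cells)$chiasma_count)
#> Poisson goodness of fit: chi2[10] = 4.25, p = 0.9354 (lambda-hat = 6.56, n = 130)

poisson_gof(chiasma_counts(wt$cells)$chiasma_count)
#> Poisson goodness of fit: chi2[12] = 222, p = 9.311e-41 (lambda-hat = 21.6, n = 130)

pooled_t_test(6.5, 2.1, 130, 2.1, 1.3, 121)
#> Two-sample t (pooled): t[249] = 19.79, two-sided p = 5.315e-53

# interference on the shortest chromosome's bright foci, pooled over cells
short <- wt$foci[wt$foci$channel == "bright" & wt$foci$bivalent_id == "chr09", ]
fit <- fit_interference(interfocus_distances(short))
fit
#> Gamma interference model fit (mle)
#>   nu (shape, interference strength): 11.59 (SE 2.02)
#>   scale: 4.52   n = 64 gaps   logLik = -263.9
#>   (nu = 1 corresponds to no interference)
```

The mutant population is Poisson-consistent (p = 0.94) while the wild-type
population, whose crossovers are mostly interference-placed, is strongly
underdispersed and rejected (p ≈ 10⁻⁴⁰) — the qualitative signature that
separates the two crossover pathways. The fitted ν ≫ 1 on the short
chromosome confirms strong interference among bright foci; on short
chromosomes the window truncation of observed gaps inflates ν̂ relative to
the generative value (see the vignette).

An end-to-end run with a consolidated report:

```r
cfg <- read_run_config(system.file("extdata", "demo_run.cfg", package = "chiasma"))
run_pipeline(cfg, "demo_out")
```

or from a shell via the wrapper `inst/scripts/chiasma-pipeline.R`
(subcommands `simulate`, `chiasma`, `gof`, `ttest`, `interference`, `coloc`,
`validate`, `all`).

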