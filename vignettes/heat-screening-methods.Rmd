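---
title: "Methods: heat-tolerance screening and marker diversity in peaheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-tolerance screening and marker diversity in peaheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaheat)
library(dplyr)
```

peaheat implements a complete desk-scale pipeline for screening pea
(*Pisum sativum*) germplasm panels for heat tolerance in staggered-sowing
field trials, and for characterising the screened accessions with small SNP
marker panels. This vignette documents the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## The screening model

Late sowing pushes the reproductive phase of a cool-season legume into early
summer heat. The design compares each accession under a normal sowing (NS,
1 March) and two late sowings (LS1, 16 March; LS2, 31 March). Heat tolerance
is scored from yield, specifically from the average grain weight per plant
$W$ measured on up to five mature plants per replicate:

$$LR_1 = \left(1 - \frac{W_{LS1}}{W_{NS}}\right) \times 100\%, \qquad
  LR_2 = \left(1 - \frac{W_{LS2}}{W_{NS}}\right) \times 100\%.$$

The two loss rates index a nine-level standard built from 20-point bands.
Writing $b(x) \in \{0,\dots,4\}$ for the band index of a loss rate
($[0,20] \mapsto 0$, $(20,40] \mapsto 1$, ...), the level is

$$\mathrm{level} = b(LR_1) + b(LR_2) + 1,$$

which reproduces the nine tabulated band combinations exactly: level 1 is
both losses at most 20%, level 9 both above 80%, and the even levels are the
asymmetric adjacent-band combinations. Levels 1–3 are heat-tolerant (HT),
7–9 heat-sensitive (HS), 4–6 intermediate. An accession whose loss rates
differ by more than 40 points is excluded as affected by systematic error.

Three numerical choices deserve note.

* **Clamping.** A late-sown yield *gain* gives a negative loss rate. The
  standard's domain starts at zero loss, so `loss_rates()` clamps to
  $[0, 100]$ before classification; a gain is "no loss" (level band 0).
* **Boundaries.** Bands are closed above, exactly as tabulated: a loss of
  20.0 sits in band 0, 20.0001 in band 1. Ties at 20/40/60/80 therefore go
  to the lower band.
* **Coverage.** The tabulated rules only list band combinations differing by
  at most one. A narrow sliver of pairs (band indices two apart but loss
  difference still $\le 40$, e.g. $LR_1 = 15$, $LR_2 = 50$) is not excluded
  and not covered by any printed row; the band-sum formula extends the
  standard continuously there. The test suite checks exact agreement with a
  literal transcription of the nine rules on an exhaustive 0.5-point grid
  and confines the extension to that sliver.

Iterative screening (`screen_iterative()`) repeats the trial on the previous
round's HT and HS accessions. The final round's HT/HS sets are the
*extremely* tolerant/sensitive accessions; the consistency set contains the
accessions with the same extreme category in every round in which they were
classified.

Per-stage companions are the field survival rate,
$FSR = \sum_r \text{survivors}_r / (\text{sown} \times n_\text{reps}) \times
100\%$ (the pooled-replicate form; with three replicates it matches the
conventional tabulated formula, with one it reduces to the plain fraction),
and the grain filling rate, hundred-grain weight divided by calendar days
from first flowering to maturity (g/day). `compare_gfr()` runs a one-way
ANOVA of GFR between HT and HS per stage.

## The normality check on level counts

`ks_normality()` applies the classical one-sample Kolmogorov–Smirnov test to
per-accession levels against a normal with the sample mean and standard
deviation, reporting the plain asymptotic two-sided p-value (no
estimated-parameter correction) — the SPSS-style output users of this
workflow expect. Two caveats are documented deliberately:

* estimating the parameters from the sample makes the test conservative;
* rounding into nine discrete levels is genuine lack-of-fit relative to a
  continuous normal, so at large $n$ (a few hundred accessions) the test
  *correctly* rejects even when the level histogram looks normal.

The calibration test therefore runs at final-round scale ($n = 50$, levels
from a rounded $\mathcal{N}(5, 1.8^2)$), where discretization is mild; the
measured null rejection rate at $\alpha = 0.05$ is about 6% over 500
replicates. For large rounds the statistic is still exact (it matches a
brute-force ECDF scan); only the continuous-null p-value should be read
with care.

## The synthetic trial generator

`sim_panel()` and `sim_trial()` generate the study conditions the screening
stage assumes, with one mandatory seed making everything bit-reproducible.

* NS grain weight per plant is log-normal (median 25 g, log-sd 0.6),
  spanning roughly 0–60+ g — positive and right-skewed, like field yields.
* Loss under late sowing is Gaussian on the percent scale around a stage-
  and class-dependent target, truncated to $[0, 100]$ with a truncation
  counter surfaced as a warning. The target is
  $\text{effect} \times (\text{stage}_\text{frac} + \mathbb{1}[\text{HS}])$
  with stage fractions 0.25 (LS1) and 1/3 (LS2): the latent HS class loses
  `effect` percentage points more than HT at both stages, loss grows from
  LS1 to LS2, and a zero effect collapses all losses to zero (latent classes
  become unrecoverable, which the tests exploit as a null case). We chose
  the truncated-Gaussian form over a logistic transform because the effect
  and noise parameters then keep their percentage-point meaning exactly.
* Survival out of 10 sown seeds is binomial with stage probabilities
  0.618/0.474/0.285 (NS/LS1/LS2) — the season-average survival rates of the
  first screening year — so survival decreases with later sowing.
* Phenology: sowing dates are fixed at 1/16/31 March; flowering follows at
  about 60/55/50 days and maturity 35/30/26 days later (Gaussian jitter,
  ordered by construction), reflecting heat-accelerated development.
* Round 1 uses one replicate per stage (completely randomized design),
  rounds 2–3 three replicates (randomized block design).

The defaults (`effect = 60`, `noise_sd = 5`) are the conditions under which
the screening stage is expected to recover at least 90% of latent labels;
the tests measure ~97% per class at $n = 200$ averaged over 20 seeds. The
generator does **not** emulate: spatial field heterogeneity or block
effects, genotype-specific phenology/escape effects, year-to-year climate
differences, continuous tolerance gradations (the latent class is binary by
default), or correlated measurement error — so passing tests demonstrate
correctness of the pipeline's logic under its own assumptions, not field
validity.

Field-scale variance components of per-plant grain weight are not available
to fit against; the plant-level log-sd default (0.10) is a plausible
measurement-plus-microenvironment spread, chosen once.

## Thermal summaries

`sim_temperatures()` draws a daily series from 1 March to 31 July: linear
warming trend (default 0.12 °C/day from 8 °C) plus optional sinusoidal bump
and iid Gaussian noise; with a positive trend any late-sowing window is, in
expectation, warmer than the normal-sowing window 15 days earlier.
`heat_stress_days()` counts days *strictly* above each threshold (16, 20,
22, 30 °C by default) in a growth window; `thermal_units()` accumulates
growing degree-days $\sum \max(0, T - T_\text{base})$ with base 0 °C by
default — the reference the workflow cites gives no formula, so the simplest
defensible definition is used and the base is configurable. Sub-windows:
vegetative $[$sowing, flowering$)$, reproductive $[$flowering, maturity$]$.

## Marker diversity statistics

All indices are computed from plug-in allele frequencies over both copies of
non-missing calls (no imputation, no call-rate filter by default) and are
$k$-allele general, since small SNaPshot panels do contain tri-allelic loci:

* `NG`, `Na` — distinct observed genotypes and alleles;
* `MAF` — major allele frequency;
* `GD` $= 1 - \sum_a p_a^2$ — gene diversity (expected heterozygosity under
  random mating);
* `He` — **observed** heterozygosity, the fraction of heterozygous calls.
  In a predominantly selfing crop this is far below GD, which is why panel
  means of He near 0.15 coexist with GD means above 0.3; a bias-corrected
  expected heterozygosity ($\frac{n}{n-1} GD$) is emitted separately as
  `He_exp`;
* `PIC` $= 1 - \sum_a p_a^2 - \sum_{a<b} 2 p_a^2 p_b^2$ (Botstein) with the
  conventional informativeness classes: high ($\ge 0.5$), moderate
  ($[0.25, 0.5)$), slight ($< 0.25$).

Invariants tested: $PIC \le GD$ everywhere; biallelic caps $GD \le 0.5$,
$PIC \le 0.375$; removing missing calls never changes `Na`. Whether a
bias-corrected frequency estimator should enter GD/PIC is unstated in the
tools this mirrors; plain plug-in estimators are used.

## Genotype simulation

`sim_genotypes()` plants the structure the downstream stages must recover.
Per-group allele frequencies follow the Balding–Nichols construction: a
marker's ancestral frequency vector $p$ (kept away from fixation) and group
frequencies drawn $\mathrm{Dirichlet}\!\left(p \frac{1-F_{ST}}{F_{ST}}\right)$,
so `fst` controls between-group dispersion and the $F_{ST} \to 0$ limit
collapses group differences. Neutral markers are differentiated by the
latent genetic subpopulation (itself correlated with sowing type, echoing
the geography of spring- vs winter-sown material); heat-tolerance-related
markers by the latent tolerance class. Genotypes are two independent draws
per accession (within-group random mating); a configurable fraction of
markers is tri-allelic; calls go missing completely at random at
`missing_rate`. Realized frequencies converge to the generator parameters
(tested at 3 standard errors).

## Population structure

* **Distances.** Individual-level trees and ordinations use the
  allele-sharing distance $d = 1 - \text{shared}/(2m)$ over
  pairwise-complete markers. Group-level comparisons use Nei's (1972)
  standard distance $D = -\ln(J_{XY} / \sqrt{J_X J_Y})$; groups fixed for
  different alleles give $J_{XY} = 0$, an infinite distance that is flagged
  rather than silently capped. The exact distance dialect behind "Nei's
  genetic distance" in the tool this mirrors is unstated; both options are
  exposed and the choice documented here.
* **UPGMA** is implemented directly (size-weighted average linkage) so the
  tie-break is fully specified: among minimum-distance pairs, the pair whose
  smallest original leaf indices are lexicographically least joins first.
  Output is an `ape` tree, ultrametric to 1e-9, and equal (as a cophenetic
  matrix) to average-linkage `hclust` on tie-free inputs — the independent
  oracle in the tests.
* **PCoA** double-centers $-d^2/2$ (Gower) and eigendecomposes; coordinates
  are eigenvectors scaled by $\sqrt{\lambda}$ over positive eigenvalues and
  contribution rates are percentages of the positive-eigenvalue total.
  Euclidean inputs are reconstructed to 1e-8; an all-zero matrix is flagged
  degenerate instead of dividing by a zero eigenvalue sum.
* **Admixture clustering** is a Gibbs sampler over the admixture model with
  uncorrelated allele frequencies: cluster-of-origin indicators per allele
  copy, cluster allele frequencies with a $\mathrm{Dirichlet}(\lambda = 1)$
  prior, and per-accession admixture proportions with a
  $\mathrm{Dirichlet}(\alpha = 1)$ prior. Deviations from the reference
  implementation are deliberate and documented: $\alpha$ is fixed rather
  than Metropolis-updated (adequate for K selection and assignment at this
  scale), and there is no linkage model, correlated-frequencies prior, or
  location prior. Missing calls are skipped. The sampler is compiled (Rcpp)
  and uses R's RNG, so a seed fixes the trace bit-for-bit. The run-level
  likelihood estimate is $\widehat{L} = \overline{\ln L} -
  \mathrm{var}(\ln L)/2$ from the post-burn-in trace (the deviance-style
  estimator conventionally fed to delta-K); the plain mean is also kept.
  Label switching is handled by reporting clusters in canonical order (by
  the first accession exceeding 0.5 membership). At $K = 1$ the sampler's
  mean log-likelihood matches the analytic pooled-frequency multinomial
  log-likelihood within Monte-Carlo error (tested).
* **Evanno delta-K**: $\Delta K = |L''(K)| / \mathrm{sd}(\widehat{L}_K)$
  over interior K of a contiguous range with replicate runs; zero spread or
  an all-zero second difference is flagged rather than silently resolved.

Desk-scale MCMC defaults are 2000 burn-in + 8000 recorded sweeps; the
conventional field-scale setting (10000/100000, K = 1–10, 10 runs) is a
configuration choice away. The scaled lengths are not a compromise of
correctness: on planted two-subpopulation panels (120 accessions, 40
markers, $F_{ST} = 0.15$) the delta-K peak at $K = 2$ exceeds the runner-up
by two orders of magnitude, and the acceptance experiment (5 replicate
panels x K = 1..5 x 5 runs) selects $K = 2$ as the modal choice.

## Primer design-rule validation

`validate_primers()` checks SNaPshot primers against the printed design
constraints: length 15–30 nt, GC 40–60%, Tm 58–60 °C, effective (tailed)
length ≤ 38 nt for peripheral primers, tailed length ≥ 36 nt for extension
primers, inter-primer complementary runs ≤ 4 nt, no 3'-terminal
complementary overlap, and bounded self-complementarity. Interpretations
where the source rules are qualitative: Tm uses the basic GC formula
($64.9 + 41(GC - 16.4)/L$) for ≥ 14 nt and the Wallace rule below, both
labelled, because no Tm method is named and thermodynamic tables would
overreach the validation purpose; self-complementary runs ≥ 4 warn and
≥ 6 fail (configurable); adjacent-locus length spacing of 4–6 nt is a
warning, not a failure, because it is phrased as customary practice. Both
complementarity scans are exhaustive and tested against quadratic brute
force.

## Pipeline and reproducibility

`run_pipeline()` chains every stage from one YAML-able config with a
mandatory master seed; all stage seeds derive from it, so a rerun is
bit-identical for deterministic stages and trace-identical for the MCMC.
Stage outputs are delimited tables (plus Newick), and the markdown report
only restates numbers present in those tables. Problem sizes in the default
config (120 accessions, 46 + 20 markers, K = 1–4, 3 runs per K, 1000/4000
MCMC) were chosen so a full run completes in a few minutes on one core;
every test fixture is generated in code at run time.

## Known limitations

* The screening classifier assumes the NS stage yields a usable positive
  mean grain weight; accessions without it are ledgered as unscoreable, not
  imputed.
* The KS p-value's continuous null is a poor reference at large $n$ for
  nine-level data (see above).
* The admixture sampler's fixed $\alpha$ slightly biases Q toward the prior
  for strongly admixed individuals; K selection and hard assignments are
  insensitive to this at the simulated effect sizes.
* Nei distances between small groups use plug-in frequencies; no
  bias-corrected identity estimator is applied.
* The generator's binary latent tolerance class makes the level histogram
  bimodal at large effect sizes, unlike the approximately normal histograms
  of real first-round screenings; a continuous tolerance score would sit
  between, and the binary default was chosen to make recovery tests sharp.
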