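---
title: "Power and polygenic-score accuracy under cross-study genetic heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and polygenic-score accuracy under cross-study genetic heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagwaspower)
```

## The problem

Large-scale GWAS results are usually produced by a fixed-effects
meta-analysis of summary statistics from many cohorts. When the effects of
causal variants are not identical across cohorts — because phenotypes are
measured differently, because gene–environment interaction differs between
populations, or because cohorts differ in ancestry — the meta-analysis
averages heterogeneous signals. Both the power to detect associated loci
and the out-of-sample accuracy of a polygenic score (PGS) built from the
meta-analytic effect estimates are attenuated, and the attenuation is
invisible if power is computed under the usual single-population
assumptions. `metagwaspower` quantifies this attenuation from design
parameters alone: per-study sample sizes, per-study SNP heritabilities, and
the cross-study genetic correlation (CGR) of causal-SNP effects.

## The model

The genome is abstracted as $S$ independent haplotype blocks, each tagged
by one SNP; $M \le S$ of them tag causal blocks that jointly account for
the full SNP heritability, each with equal theoretical $R^2$. Genotypes and
phenotypes are standardized. Causal effects follow a random-effects model:
for SNP $k$, the standardized effects $(b_{1k}, \dots, b_{Ck}, b_{hk})$ in
the $C$ discovery studies and the hold-out sample $h$ are jointly Gaussian
with $\mathrm{Var}(b_{ck}) = h^2_c / M$ and
$\mathrm{Cor}(b_{ck}, b_{dk}) = \rho_{cd}$, the CGR.

Under the sample-size-weighted fixed-effects meta-analysis
($w_c = \sqrt{N_c/N_T}$ on study $Z$ scores), the $Z$ statistic of a causal
SNP is marginally normal with mean zero and variance

$$\sigma^2 \;=\; 1 + \frac{1}{M N_T} \sum_{c,d} N_c N_d\, \rho_{cd}
\sqrt{h^2_c h^2_d},$$

so heterogeneity acts through excess variance rather than a mean shift.
Power per causal SNP at the two-sided level $\alpha$ is
$\beta = 2\Phi(-t/\sigma)$ with $t = \Phi^{-1}(1 - \alpha/2)$; because the
random effects are jointly Gaussian, this marginal tail is exact and no
integration over the effect distribution is needed. Expected counts follow
from independence of blocks, e.g.
$E[\#\mathrm{hits}] = \beta M + \alpha(S - M)$.

For the PGS (all $S$ SNPs, effect-size weights $w_c = N_c/N_T$), the
hold-out $R^2$ is $\mathrm{Cov}(\hat S, y)^2 / \mathrm{Var}(\hat S)$ with

$$\mathrm{Cov}(\hat S, y) = \sum_c \frac{N_c}{N_T}\rho_{ch}
\sqrt{h^2_c h^2_h}, \qquad
\mathrm{Var}(\hat S) = \frac{S}{N_T} + \frac{1}{N_T^2}\sum_{c,d}
N_c N_d \rho_{cd}\sqrt{h^2_c h^2_d}.$$

For one discovery study this reduces to
$R^2 = \rho^2 h^4 / (S/N + h^2)$: $R^2$ is quadratic in the CGR, and its
large-sample ceiling is $\rho^2 h^2$ — with imperfect CGR the hold-out
heritability can never be fully captured. Two consequences worth noting:

* Power is far less sensitive to CGR than $R^2$ is (for two studies the
  CGR enters $\sigma^2$ linearly), but when baseline power per SNP is low
  a small absolute loss is a large relative loss in expected hits.
* The quadratic ceiling is a *single-study* statement. Splitting a fixed
  total $N$ over more studies raises hold-out $R^2$ when CGR $< 1$,
  because study-specific effect components average out across studies
  while the shared component accumulates; with 50 studies at CGR 0.2 the
  $R^2$ can exceed $\rho^2 h^2$ several-fold. For the same reason the
  sometimes-quoted bound $R^2 \le \rho^2 h^2_h$ must not be applied to
  multi-study designs.

`attenuation()` reports the relative loss in expected hits and in $R^2$
against the same design with every correlation set to 1 — the benchmark a
naive power calculation implicitly assumes.

## Parameters and defaults

* `alpha` defaults to the genome-wide $5\times10^{-8}$ (two-sided; false
  positives are counted two-sided as $\alpha(S-M)$, consistently).
* Equal designs keep the per-study size $N_T/C$ fractional. Rounding to
  integers shifts expected hits in the second decimal for published
  designs, which matters when comparing against values printed to two
  decimals.
* The bordered $(C{+}1)\times(C{+}1)$ correlation matrix must be positive
  semidefinite; the check tolerates eigenvalues down to $-10^{-8}$ and
  reports the offending eigenvalue. Constant-correlation designs are PSD
  for $\rho \ge -1/C$.
* Tail probabilities are computed on the normal-quantile scale and count
  aggregation uses `log1p`/`expm1`, so $\beta$ down to $10^{-300}$ and
  $M$ up to $10^6$ survive without underflow.

## What the reproduction catalog shows

`run_reproduction()` recomputes 80 published reference cells: ten
large-scale GWAS designs (height, BMI, years of education, self-rated
health — expected hits and PGS $R^2$ under the estimated CGR and under
CGR $=1$, plus attenuation) and 21 in-text contour-figure values. All
figure values, all $R^2$ cells and all but two attenuation cells
reproduce at printed precision. The hit-count columns agree to roughly
0.01–0.1% in relative terms but not to the two printed decimals: the
published inputs ($h^2$, CGR) carry three significant digits, which
cannot pin a hit count to $\pm 0.005$, and the near-zero cells are
inconsistent with the displayed count formula itself (expected hits are
bounded below by $\alpha(S-M) = 0.0115$, so a printed `0.00` is
unreachable, and a printed `0.01` would need a per-SNP power several
times smaller than the Gaussian tail gives). These cells are flagged
`known_discrepant` in the catalog, with both values reported, rather
than silently matched.

## The simulator

`simulate_scenario()` generates the multi-study world explicitly:
allele-count genotypes at independent SNPs, correlated per-study causal
effects, phenotypes with noise variance $1-h^2$, per-study marginal
regressions, the fixed-effects meta-analysis, and a hold-out PGS. It is
the empirical check on every closed form above. Design choices:

* **Standardization** uses within-study sample moments, as in GWAS
  practice; population moments are available as a switch for oracle
  checks.
* **MAF–effect coupling**: raw-effect variance $\propto [2f(1-f)]^s$.
  $s=-1$ is the equal-$R^2$ assumption of the theory; $s=0$ (equal raw
  variance) violates it and is the default stress test, combined with
  allele frequencies drawn $\mathrm{Uniform}(0.05, 0.5)$ and redrawn per
  study.
* **Causal overlap**: instead of imposing an effect correlation directly,
  a scenario can share only a fraction $q$ of causal loci between studies
  (effect correlation $\rho_e$ at shared loci, independent effects at
  private loci), which implies a genome-wide CGR of $q\rho_e$. Empirical
  power is measured over the union of the discovery studies' causal loci.
* **Relaxed threshold**: validation runs at $\alpha = 5\times10^{-4}$.
  Empirical power at $5\times10^{-8}$ would need enormous samples; the
  theory is a statement about $\sigma^2$ and holds at any $\alpha$, so the
  same threshold is used on both sides of the comparison.
* **Random numbers**: the genotype core uses a self-contained
  xoshiro256++ generator; every (replicate, study) pair gets a substream
  seed derived from the scenario seed by fixed integer offsets, so results
  are bit-reproducible across platforms and adding scenarios to a grid
  never perturbs existing ones. Effect and frequency draws use R's RNG,
  seeded per replicate from the same master seed.
* **Strict equal-$R^2$ variant**: `effect_model = "fixed_magnitude"`
  draws effects of constant magnitude $\sqrt{h^2/M}$ with random signs,
  sign-coupled across studies through a latent Gaussian with correlation
  $\sin(\pi\rho/2)$ so the sign correlation hits the target CGR — a
  sensitivity analysis for the Gaussian-effects assumption.

### The default validation grids

The default grids (`default_validation_grid()`) are a spanning selection
rather than a full factorial, chosen so the whole validation runs in a few
minutes on one CPU: six baseline cells covering
$S \in \{1000, 2000\}$, $M/S \in \{0.1, 1\}$, $C \in \{2, 5\}$,
$n_c \in \{2000, 10000\}$, $h^2 \in \{0.2, 0.5\}$,
$\rho \in \{0.3, 0.7, 1.0\}$ under the equal-$R^2$ violation, and four
overlap cells with $q\rho_e \in \{0.3, 0.5, 0.6, 0.8\}$, each with 200
replicates.

The overlap cells keep the per-SNP signal $n h^2 / M$ moderate ($\le 1$).
This is where the single-variance closed form is an accurate summary of
the shared/private mixture: a genome that mixes shared causal loci
(higher meta-analysis $Z$ variance) with study-private loci (lower
variance) is summarized by one effective variance, and because power is
nonlinear in the variance this summary degrades as per-SNP signal grows.
At $n h^2/M \approx 5$ the mixture and the effective-CGR prediction can
differ by ten percentage points; at $n h^2/M \le 1$ they agree to about
one point, which is the regime of realistic polygenic architectures
(per-SNP $R^2$ of order $10^{-4}$ implies $n h^2/M \ll 1$ at any
feasible per-study $n$).

What passing validation does and does not show: the simulator draws
independent SNPs, Hardy–Weinberg genotypes, Gaussian (or fixed-magnitude)
effects and homogeneous within-study populations. Agreement therefore
validates the algebra of the closed forms and their robustness to the
equal-$R^2$ and shared-loci assumptions — not LD structure, case-control
ascertainment, imputation error, or within-study stratification, all of
which are outside the model on both sides of the comparison.

## Worked example

The 79-cohort height meta-analysis design ($N_T = 253{,}288$,
$h^2 = 0.449$, CGR $= 0.965$, $S = 250$k, $M = 20$k):

```{r}
cfg <- calculator_config(
  mode = "scalar", n_total = 253288, n_studies = 79, h2 = 0.449,
  cgr = 0.965, cgr_holdout = 0.965, s_total = 250000, m_causal = 20000)
run_calculator(cfg)
```

Even at a CGR of 0.965, heterogeneity costs this design about 8% of its
expected discoveries and 6% of its polygenic-score $R^2$ — a part of the
gap between SNP heritability and what genome-wide-significant hits explain
("hiding heritability") that larger samples cannot recover.

```{r, eval = FALSE}
# empirical check of the closed forms (about two minutes each)
validate_grid(default_validation_grid("baseline"))
validate_grid(default_validation_grid("overlap"))
```

## Known limitations

* Quantitative traits only; no liability-scale conversion for binary
  outcomes.
* LD enters only through the "effective number of independent SNPs"
  abstraction; $S$ must be supplied (literature values range from 60k to
  several million) and results scale with it.
* Heritabilities and CGRs are inputs, not estimates: the package does not
  implement GREML or LD-score estimation.
* The fixed-effects meta-analysis is the object of study;
  heterogeneity-aware meta-analysis statistics are out of scope.
* With three-significant-digit inputs, expected hit counts are determined
  only to ~0.1% relative precision; treat more decimals as spurious.
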