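---
title: "Bi-directional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instruments, with the
variant–exposure associations $\hat\gamma_j \pm \sigma_{X_j}$ and the
variant–outcome associations $\hat\Gamma_j \pm \sigma_{Y_j}$ taken from two
independent GWAS. Under the instrumental-variable assumptions (relevance, no
confounding of the variant–outcome path, and no horizontal pleiotropy), each
variant provides a Wald ratio estimate $\hat\beta_j = \hat\Gamma_j /
\hat\gamma_j$ of the same causal effect $\beta$. Because pleiotropy is never
verifiable from summary data alone, practice is to report a battery of
estimators whose validity rests on different relaxations of the third
assumption, and to treat agreement across them as the evidential unit.

`bimr` implements the full workflow bi-directionally: reading and validating
summary statistics, selecting and harmonizing instruments (in both the
exposure-to-outcome and outcome-to-exposure directions), the estimator
battery with heterogeneity and pleiotropy diagnostics, binary-outcome power
calculations, random-effects meta-analysis across study populations, and a
calibrated synthetic-data generator used to validate every component.

## Input data and harmonization

`readSummaryStats()` expects one row per variant with the canonical columns
`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (renameable via `column_map`).
Malformed rows are rejected with per-line reasons recorded in an attribute;
structurally broken files (missing columns, duplicated variant ids) are
errors.

Harmonization (`harmonizePanels()`) proceeds per instrument:

* **Selection**: variants with `pvalue < p_threshold` (default `5e-8`, the
  conventional genome-wide threshold; the inequality is strict so a variant
  at exactly the threshold is not selected) minus an explicit `blacklist`
  of variants known to act through other phenotypes.
* **Allele alignment** (`alignAlleles()`): effect/other alleles are matched
  directly or after flipping (with `beta` negated and `eaf` reflected).
  Strand-ambiguous palindromic variants (A/T, C/G) are oriented by allele
  frequency, and dropped whenever either panel's frequency lies within
  `palindromic_eaf_window = 0.08` of 0.5 (i.e. in `[0.42, 0.58]`), where
  frequency cannot distinguish strands reliably.
* **Proxy substitution** (`findProxy()`): an instrument absent from the
  outcome panel is replaced by the most correlated variant in the supplied
  `LDReference` with `r^2 > r2_min` (default `0.8`, strict), the customary
  proxy floor; the proxy's outcome association is re-signed by the sign of
  the LD correlation.

Every decision (kept, flipped, proxied, dropped and why) is recorded in the
audit log accessible via `auditLog()`.

## The estimator battery

With harmonized $(\hat\gamma_j, \sigma_{X_j}, \hat\Gamma_j, \sigma_{Y_j})$,
$j = 1, \dots, J$:

* **Wald ratio** (`waldRatio()`): $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$
  with first-order standard error $\sigma_{Y_j}/|\hat\gamma_j|$. The
  first-order form ignores uncertainty in $\hat\gamma_j$; it is accurate when
  instruments are strong, which the selection threshold enforces.
* **IVW, multiplicative random effects** (`ivwRandomEffects()`): weighted
  least squares of $\hat\Gamma_j$ on $\hat\gamma_j$ through the origin with
  weights $1/\sigma_{Y_j}^2$. The standard error is inflated by
  $\sqrt{\max(1, Q/(J-1))}$, where $Q$ is Cochran's heterogeneity statistic
  (`cochranQ()`, $J-1$ df): heterogeneity widens the interval but, unlike an
  additive random-effects model, does not re-weight the instruments.
* **MR-Egger** (`mrEgger()`): the same weighted regression with a free
  intercept, after re-signing so all $\hat\gamma_j \ge 0$. The intercept
  estimates the average directional pleiotropy; the slope is consistent for
  $\beta$ under the weaker InSiDE assumption (instrument strength
  independent of direct effects). Both tests use an overdispersion factor
  $\max(1, \hat\sigma)$ on $J-2$ df.
* **Weighted median** (`weightedMedian()`): the median of the ratio
  estimates under weights $\hat\gamma_j^2/\sigma_{Y_j}^2$, by interpolation
  of the weighted CDF at 0.5; consistent when instruments carrying at least
  half the weight are valid. The standard error is a parametric bootstrap
  (`n_boot = 1000` by default — the bootstrap SE's own Monte-Carlo error is
  then a few percent, adequate for a sensitivity analysis).
* **Mode-based estimate** (`modeBasedEstimate()`): the mode of a weighted
  Gaussian kernel density of the ratios, bandwidth $\phi \cdot 0.9 \cdot
  \min(\mathrm{sd}, \mathrm{mad}) \cdot J^{-1/5}$ with `phi = 1` (the
  standard normal-reference rule); consistent when the largest group of
  instruments sharing an estimate is valid.
* **MR-PRESSO** (`mrPresso()`): a global pleiotropy test from the weighted
  residual sum of squares about leave-one-out IVW fits, calibrated by a
  parametric bootstrap (`n_sim = 5000` default, so the smallest resolvable
  p-value is 2e-4); per-variant outlier tests are Bonferroni-adjusted, and
  when outliers are flagged the outlier-corrected IVW is reported together
  with a distortion test against random removals of the same size.
* **Robust regression** (`mrRobust()`): MM-estimation of the origin
  regression (Huber weights, Tukey biweight with the standard 95%-efficiency
  tuning constant 4.685), smoothly down-weighting outlying instruments.
* **MR-RAPS** (`mrRaps()`): a robust adjusted profile score that models the
  error in $\hat\gamma_j$ explicitly (profile variance $\sigma_{Y_j}^2 +
  \beta^2\sigma_{X_j}^2 + \tau^2$) and scores residuals through a Huber
  $\psi$ with tuning constant 1.345 (95% Gaussian efficiency). The
  overdispersion $\tau^2 \ge 0$ absorbs balanced pleiotropy. The standard
  error uses the expected information under the fitted model rather than an
  empirical sandwich: with $J \approx 10$ instruments the empirical variance
  of the score is too noisy and an estimated sandwich materially
  under-covers, while the model-based form attains nominal coverage in the
  package's simulation suite.

`runEstimatorSuite()` runs all of the above plus the diagnostics and returns
a single long-format table; `highlightRules()` applies the reporting
conventions (prefer the outlier-corrected estimate when the global PRESSO
test is significant at 0.01; prefer the weighted median under significant
heterogeneity at 0.05). `multivariableIVW()` estimates direct effects of
multiple exposures jointly by weighted multiple regression.

## Power and design

`mrPowerBinary()` implements the standard binary-outcome approximation: with
case fraction $K$, total $N$, instrument strength $R^2$ and odds ratio OR,

$$b = K\left(\frac{\mathrm{OR}}{1 + K(\mathrm{OR} - 1)} - 1\right), \qquad
v = \frac{K(1-K) - b^2}{N R^2},$$

and power is the tail probability of a non-central $\chi^2_1$ with
non-centrality $b^2/v$. `minDetectableOR()` inverts this on a 0.01 OR grid
(the granularity at which such bounds are conventionally reported),
returning the smallest protective and risk ORs with power at or above the
target (defaults: $\alpha = 0.05$, power 0.80).

## Meta-analysis

`metaFromCI()` converts published ORs with 95% CIs to log scale with
$se = (\ln \mathrm{upper} - \ln \mathrm{lower}) / (2 \times 1.959964)$;
because published values are rounded to two decimals, reconstructed
intervals reproduce the inputs at that precision. `dlRandomEffects()` pools
by DerSimonian–Laird, and `eggerAsymmetry()` regresses standardized effects
on precision as a small-study (publication-bias) test on $k - 2$ df.

## The synthetic generator

`simulateTwoSample()` draws the summary statistics of a two-sample design
directly from their asymptotic distributions — no individual-level data are
simulated. Defaults mirror a vitamin-C-to-cancer study shape:

* `n_snps = 10` independent instruments with frequencies uniform on
  `maf_range = c(0.1, 0.9)`;
* true effects scaled so the realized variance explained is exactly
  `target_r2 = 0.0187` (the scaling is exact, not in expectation, so fixture
  checks are deterministic);
* exposure panel of `n_exposure = 52018` with
  $\sigma_{X_j}^2 = (1 - R^2) / (n_X \cdot 2 f_j (1 - f_j))$;
* binary outcome panel of `n_outcome = 456348` with case fraction
  `case_fraction` and
  $\sigma_{Y_j}^2 = 1 / (n_Y \cdot K(1-K) \cdot 2 f_j (1 - f_j))$,
  the standard logistic-score approximation;
* optional pleiotropy: `balanced` (zero-mean direct effects) or
  `directional` (non-zero mean) in a configurable fraction of instruments;
* optional LD blocks (`ld_block`) that add correlated proxy variants to the
  outcome panel, with a matching `LDReference`, so proxy substitution can be
  exercised end to end.

What the generator deliberately does **not** emulate: realistic genome-wide
LD (blocks are exchangeable with a single correlation), sample overlap
between the two GWAS, winner's curse from instrument discovery in the same
sample, population stratification, or effect heterogeneity across strata.
Conclusions about those failure modes cannot be drawn from it.

`makeVitaminCFixture()` returns a deterministic 11-variant exposure panel
whose variance explained is exactly 0.0187 and which reduces to 10
instruments after blacklisting a variant with a known pleiotropic pathway —
the instrument design the defaults are built around.

## Pipeline

`mrAnalysisConfig()` + `runDirection()` run one direction of a
bi-directional analysis over many outcome panels, with per-pair failure
isolation, per-outcome instrument exclusion lists for sensitivity re-runs,
optional multivariable adjustment, and deterministic TSV/JSON outputs keyed
by seed. `readAnalysisConfig()` reads the same configuration from YAML with
paths resolved relative to the file.

## Limitations

* **MR-Egger calibration.** The Egger intercept test assumes the NO
  Measurement Error (NOME) condition and correctly specified weights. With
  noisy instrument–exposure estimates, a non-zero causal effect, or additive
  pleiotropy atop heteroscedastic outcome SEs, the intercept test is
  anti-conservative; its size is nominal in the package's tests only under
  designs where those violations vanish. Treat significant intercepts as a
  prompt for the outlier-robust estimators, not as proof of pleiotropy.
* **MR-PRESSO masking.** With few instruments and very precise outcome SEs,
  a gross outlier drags every leave-one-out fit far enough that all
  instruments exceed the per-variant threshold, leaving nothing to correct
  with. The test's sensitivity checks therefore use panels large enough that
  a single outlier cannot dominate the fit.
* **First-order Wald SEs** ignore uncertainty in $\hat\gamma_j$ and are
  anti-conservative for weak instruments; MR-RAPS is the estimator in the
  battery that accounts for it.
* **Power formula** is an approximation around the null; it degenerates when
  $b^2 \ge K(1-K)$ (extreme ORs at extreme case fractions), where the
  function stops rather than extrapolate.
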