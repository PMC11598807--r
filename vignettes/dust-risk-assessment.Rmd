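---
title: "Source apportionment and probabilistic health risk for flame retardants in vehicle dust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source apportionment and probabilistic health risk for flame retardants in vehicle dust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustrisk)
```

## The problem

Vehicles are small, poorly ventilated, hot environments densely packed with
flame-retarded materials: polyurethane-foam (PUF) seats, PVC upholstery and
floor mats, electronics, and hydraulic fluids. Two chemical families
dominate the resulting dust burden — organophosphate esters (OPEs, e.g.
TDCiPP, TBOEP, TPhP) and polybrominated diphenyl ethers (PBDEs, congeners
BDE-28 through BDE-209). Because these additives are blended rather than
chemically bound, they migrate into settled dust, and people who spend long
hours in vehicles (professional drivers above all) ingest, inhale and
absorb them.

`dustrisk` implements the full analysis chain for such data:

1. **Data handling** — samples × congeners concentration tables (ng g⁻¹)
   with below-detection-limit (MDL) censoring and half-MDL substitution.
2. **Descriptive source analysis** — normality screening, Spearman
   correlation, KMO sampling adequacy, Bartlett's sphericity, and PCA with
   varimax rotation.
3. **Positive matrix factorization (PMF)** — uncertainty-weighted
   nonnegative factorization for quantitative source apportionment.
4. **Exposure and risk** — three-route average daily doses (ADD), hazard
   quotients/index (HQ/HI), and carcinogenic risk (CR).
5. **Probabilistic assessment** — distribution fitting, seeded Monte Carlo
   propagation, percentile reporting, and contribution-to-variance
   sensitivity analysis.
6. A synthetic-data generator with *planted* source structure, so that
   every stage can be validated against known ground truth.

## Censoring and summary statistics

Concentrations reported below a congener's MDL are replaced by MDL/2, the
standard convention for left-censored environmental data. A value exactly
equal to the MDL is treated as observed: only explicitly flagged cells are
censored. Summaries use the sample (n−1) standard deviation; a
single-observation "sample" (a literature mean treated as one observation)
reports SD 0 with a warning rather than NA, so such rows can still flow
through the exposure equations.

## PMF: model, weights, optimizer

The receptor model is $X = GF + E$ with $X$ the $n \times m$ data matrix,
$G \ge 0$ the $n \times p$ source contributions, $F \ge 0$ the $p \times m$
source profiles. The fit minimises the uncertainty-weighted objective

$$Q = \sum_{i,j} \left(\frac{x_{ij} - (GF)_{ij}}{\sigma_{ij}}\right)^2 ,$$

with per-cell uncertainties built from the measurement error model used
throughout receptor modelling:

* $\sigma_{ij} = \tfrac{5}{6}\,\mathrm{MDL}_j$ when $c_{ij} \le \mathrm{MDL}_j$;
* $\sigma_{ij} = \sqrt{(\mathrm{EF}\cdot c_{ij})^2 + (0.5\,\mathrm{MDL}_j)^2}$ otherwise,

where EF is the *error fraction*, default 0.1 (the conventional 10%
relative measurement error; it is a tunable argument of
`build_uncertainty()`). The rule is deliberately discontinuous at
$c = \mathrm{MDL}$ — the below-MDL branch is the larger — and the equality
case takes the below-MDL branch; this is asserted, not hidden, in the test
suite.

The optimizer is the weighted multiplicative update scheme (Lee–Seung form
with $1/\sigma^2$ weights), which is monotone nonincreasing in $Q$ and
keeps $G, F$ strictly nonnegative. Numerical choices:

* **Initialisation** — strictly positive uniform draws, rescaled so the
  initial model matches the data column means; per-restart seeds come from
  a seeded master stream, so a fit is fully reproducible given `seed`.
* **Restarts** — 20 by default; the restart with minimal $Q$ wins. The
  best $Q$ is nonincreasing in the number of restarts at a fixed master
  seed.
* **Convergence** — relative $\Delta Q < 10^{-8}$ or 5000 sweeps.
* **Identifiability** — the factorization has an inherent diagonal
  rescaling ambiguity ($Q(GD, D^{-1}F) = Q(G, F)$); for reporting, rows of
  $F$ are normalised to sum to 1 with $G$ absorbing the scale. Factor
  count $p$ is a user decision: in this domain the number of sources is
  chosen by interpretability, not automatically.

`species_contributions()` reports, for each congener, the percentage of
modelled mass per factor (rows sum to 100); `match_factors()` aligns
estimated and reference profiles by exhaustive cosine-similarity matching
(practical to $p \le 8$), which the validation tests use to measure
recovery of planted sources.

## PCA diagnostics

PCA runs on the correlation matrix of (internally standardised) columns.
Retained loadings $\lambda_k = v_k\sqrt{e_k}$ are rotated with
normalised-Kaiser varimax (criterion change $<10^{-10}$, up to 1000
sweeps); communalities are invariant under the rotation to $10^{-8}$, a
tested property. Sign indeterminacy is resolved by making each factor's
largest-magnitude loading positive. The number of retained factors `k` is
caller-specified with the eigenvalue ≥ 1 count returned as a suggestion
only, because substantive source interpretation can justify retaining a
factor with an eigenvalue slightly below 1. Congener exclusion (e.g.
variables with low communalities that depress the KMO) is an explicit
argument, never automatic.

KMO is computed from anti-image partial correlations via the inverse
correlation matrix; Bartlett's sphericity uses
$\chi^2 = -(n-1-(2m+5)/6)\ln\det R$ with $m(m-1)/2$ degrees of freedom.
Both are verified against independent small-matrix oracles (cofactor-based
partial correlations; direct closed-form evaluation). The normality screen
uses Shapiro–Wilk — the standard choice below n = 5000 — and motivates the
rank-based (Spearman) correlation used throughout, since dust
concentrations are strongly right-skewed. Spearman p-values use the
t approximation $t = r\sqrt{(n-2)/(1-r^2)}$.

## Exposure model and calibration

Average daily doses (mg kg⁻¹ day⁻¹) for a concentration $C$ (mg kg⁻¹,
numerically ng g⁻¹ / 1000):

$$\mathrm{ADD_{ing}} = \frac{C\,R_{ing}\,ET\,EF\,ED}{BW\,AT}\,CF_{ing},\qquad
\mathrm{ADD_{inh}} = \frac{C\,R_{inh}\,ET\,EF\,ED}{PEF\,BW\,AT}\,CF_{inh},$$
$$\mathrm{ADD_{der}} = \frac{C\,SA\,DA\,AF\,ET\,EF\,ED}{BW\,AT}\,CF_{der}.$$

The conversion constants make the equations dimensionally exact:
$CF_{ing} = 10^{-3}$ (g dust → kg), $CF_{der} = 10^{-6}$ (mg dust → kg),
and $CF_{inh} = 10^{-3}$. The inhalation constant deserves a note: without
it, reproducing the package's reference dose table would require an
implausible inhalation rate of 0.017 m³ day⁻¹; with it, the calibrated
rate is 17.1 m³ day⁻¹, squarely in the range used for adults. $ET$ is a
unitless fraction of the day; $EF \cdot ED / AT$ is dimensionless with
$AT = ED \times 365$ days for noncancer endpoints and $70 \times 365$ for
lifetime cancer risk.

Default parameter sets (all overridable via `exposure_params()`):

| parameter | occupational | nonoccupational | unit | note |
|---|---|---|---|---|
| `et` | 1/3 | 0.0502 | day fraction | 8 h driving vs ≈72 min commuting |
| `ef` | 350 | 350 | days yr⁻¹ | |
| `ed` | 10 | 10 | yr | cancels for noncancer (AT = ED·365) |
| `bw` | 70 | 70 | kg | adult |
| `r_ing` | 0.041834 | 0.041834 | g day⁻¹ | calibrated |
| `r_inh` | 17.108 | 17.108 | m³ day⁻¹ | calibrated |
| `pef` | 1.39 × 10⁹ | 1.39 × 10⁹ | m³ kg⁻¹ | particulate emission factor |
| `sa`, `da` | 5700, 0.07 | 5700, 0.07 | cm², mg cm⁻² | exposed skin, adherence |

"Calibrated" means: the lumped route coefficients were back-computed, once
and before any testing, so that the model reproduces the package's
reference ADD table (`reference_add_table()`) from the reference
concentration summary (`reference_concentrations()`) — the ingestion
coefficient is 1.910 × 10⁻⁷ day⁻¹ occupationally, constant across
congeners to <1% by construction of the reference tables themselves.
Congener-specific dermal uptake fractions (0.0096–0.027) were
back-computed the same way and live in `default_panel()`. Within printed
3-significant-figure rounding, the calibrated model reproduces every
reference per-congener dose to better than 1%.

One known defect of the reference ADD table is handled explicitly: its
per-congener *nonoccupational dermal* PBDE cells duplicate the
occupational values and contradict their own printed family total; the
family totals are treated as authoritative, and the per-congener cells of
that column are excluded from consistency checks.

Toxicity defaults: RfDs for six OPEs (TnBP 0.024, TBOEP 0.015, TCEP 0.022,
TCiPP 0.08, TDCiPP 0.015, TPhP 0.07 mg kg⁻¹ day⁻¹) and four PBDEs (BDE-47
and BDE-99 1 × 10⁻⁴, BDE-153 2 × 10⁻⁴, BDE-209 7 × 10⁻³); slope factors
for TnBP (0.009), TEHP (0.0032), TCEP (0.02), TDCiPP (0.07) and BDE-209
(7 × 10⁻⁴ (mg kg⁻¹ day⁻¹)⁻¹). These are documented defaults in the range
of US EPA IRIS/PPRTV assessments — verify against the current IRIS record
before regulatory use. The package's risk conclusions are *band* checks
(HI < 1; CR against the 10⁻⁶/10⁻⁴ bands) and are insensitive to these
choices by more than two orders of magnitude. Congeners without an RfD or
SF are skipped with a warning, never silently zeroed.

## Probabilistic assessment

`fit_best_distribution()` fits candidate families (normal, lognormal,
gamma, Weibull, uniform) by maximum likelihood and selects by the smallest
Anderson–Darling statistic; a chi-square statistic on equal-probability
bins ($k = \lceil 1+\log_2 n\rceil$) is reported as a secondary diagnostic
but never arbitrates, since two selectors need an explicit tie-break rule
and AD is the more powerful tail-sensitive test. Families requiring
positive support are skipped (with a warning) for samples containing
nonpositive values; constant samples short-circuit to a point mass.

`monte_carlo_risk()` draws all inputs independently per iteration
(concentrations per congener, exposure factors), evaluates the dose and
risk equations, and accumulates HI and CR draws. Conventions:

* **Independence** — no dependence structure is imposed between inputs;
  nothing in the summary-level source data identifies a copula.
* **Concentration defaults** — lognormal, moment-matched to a summary
  mean and SD (`default_concentration_dists()`), the natural model for
  concentrations spanning orders of magnitude when raw samples are
  unavailable.
* **Exposure-factor defaults** (`default_param_dists()`) — body weight
  normal (SD 10 kg, truncated at 0); time-in-vehicle, ingestion rate,
  inhalation rate triangular ±50% around their point values; exposure
  frequency triangular (250, 350, 365); duration and the remaining
  geometry factors held at point values.
* **Truncation** — physically nonnegative quantities are resampled at 0;
  the resample count is retained as an attribute.
* **Averaging time follows the drawn duration** (`at = ed × 365`), so the
  point-mass case reproduces the deterministic pipeline *bit-exactly* (a
  tested oracle equivalence — including floating-point accumulation
  order).
* **Percentiles** — empirical quantiles with the standard
  linear-interpolation convention (R type 7), reported at the 10th, 50th
  and 90th levels by default; 10,000 iterations by default.

Sensitivity analysis reports, per input, the Spearman rank correlation
with the output and the signed contribution-to-variance
$\mathrm{sign}(\rho_v)\,\rho_v^2 / \sum_w \rho_w^2 \times 100$ — the
convention of the commercial risk tools this estimator mirrors. The
"squared-correlation, sign restored" reading is the only defined estimator
behind the loose phrase "contribution by squaring"; it makes absolute
contributions sum to 100, keeps signs interpretable (body weight, a
denominator, comes out negative), and is invariant to monotone rescaling
of any input because it is rank-based.

## What the synthetic generator emulates — and what it does not

`gen_concentrations()` plants $p$ nonnegative source profiles (rows
normalised to 1), draws heavy-tailed per-sample contributions, applies
multiplicative lognormal noise (mean 1, relative scale `noise_cv`;
additive Gaussian truncated at 0 is available), and censors cells below
the panel MDLs. This emulates the features that matter for validating the
pipeline: nonnegativity, a low-rank source structure, right-skewed
marginals spanning orders of magnitude, and MDL censoring. It does *not*
emulate between-study heterogeneity of literature-compiled data,
correlated measurement error across congeners, or matrix effects — so a
passing recovery test demonstrates the estimator works under the stated
noise model, not that real vehicle-dust compilations satisfy that model.

The validation suite's problem sizes are chosen to exercise the estimators
meaningfully while keeping the default test run fast: profile recovery at
n = 200 samples, m = 8 congeners, p = 3 sources, 10% noise, 20 restarts
(mean matched cosine similarity ≥ 0.95 required); Monte Carlo checks at
10,000 iterations; percentile-convergence and stability experiments over
10 seeds. The cross-seed stability check of the 90th percentile (≤ 2%
relative at 10,000 iterations) runs on a moderate-variability bed
(lognormal concentrations, CV 0.5): with the very heavy reference tails
(CV up to 2.8) the *statistical sampling error* of an empirical 90th
percentile at that iteration count is itself ≈ 2.4%, so a tighter band
there would measure the tails, not the engine. The heavy-tailed reference
conditions are exercised separately by the HI < 1 band check across
seeds.

## Degenerate inputs and edge behaviour

* Constant columns: error in the normality screen; `NA` with a warning in
  Spearman; a singularity error (with advice to drop congeners) in KMO.
* All-censored or all-zero congener columns: `fit_pmf()` refuses with
  advice to exclude them.
* Zero modelled mass for a congener: its species-contribution row is `NA`
  with a warning.
* `p = 1` factor: every congener is 100% attributed to it.
* Single sample: SD 0 with a warning (see above).
* A reported value exactly at the MDL: observed for censoring purposes,
  below-MDL branch for the PMF uncertainty — the two rules serve
  different masters (substitution vs error model) and both follow the
  receptor-modelling convention.

## Known limitations

* The PMF optimizer is a multiplicative-update weighted NMF; it does not
  implement rotational exploration (Fpeak) or bootstrap/displacement error
  estimation found in dedicated receptor-modelling software.
* Exposure scenarios are adult-only; no bioaccessibility adjustment (100%
  absorption is assumed) and no age stratification.
* RfD/SF defaults are shipped for convenience and must be re-verified
  for any regulatory application.
* Monte Carlo inputs are independent; correlated exposure factors (e.g.
  body weight vs inhalation rate) would require a dependence model the
  summary-level data cannot identify.
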