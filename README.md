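# dustrisk

Source apportionment and probabilistic health-risk assessment for
organophosphate ester (OPE) and polybrominated diphenyl ether (PBDE) flame
retardants in vehicle dust.

Vehicle interiors concentrate flame-retarded materials — polyurethane-foam
seats, PVC trim and floor mats, electronics, hydraulic fluids — and their
additives accumulate in settled dust at concentrations spanning five to six
orders of magnitude. `dustrisk` is for exposure scientists and
environmental epidemiologists who need to go from a samples × congeners
concentration table to (a) an attribution of that mixture to emitting
sources and (b) a defensible noncancer and cancer risk characterization
for people who sit in those vehicles, occupationally or not.

## What it computes

**Source apportionment.** Spearman correlation with normality screening,
KMO / Bartlett adequacy diagnostics, varimax-rotated PCA, and
uncertainty-weighted positive matrix factorization (PMF): the receptor
model *X = GF + E* fitted by minimising

> Q = Σᵢⱼ [(xᵢⱼ − (GF)ᵢⱼ)/σᵢⱼ]²,  G, F ≥ 0,

with cell uncertainties σᵢⱼ = (5/6)·MDL below the detection limit and
√((EF·c)² + (0.5·MDL)²) above it. Multiplicative (Lee–Seung, 1/σ²-weighted)
updates, multi-restart, seed-reproducible; planted-source recovery is part
of the test suite.

**Exposure and risk.** Three-route average daily doses for a dust
concentration C (mg kg⁻¹):

> ADD_ing = C·R_ing·ET·EF·ED·CF/(BW·AT),
> ADD_inh = C·R_inh·ET·EF·ED·CF/(PEF·BW·AT),
> ADD_der = C·SA·DA·AF·ET·EF·ED·CF/(BW·AT),

then hazard quotients HQ = ADD/RfD, hazard index HI = Σ HQ, and
carcinogenic risk CR = ADD × SF against the 10⁻⁶ / 10⁻⁴ bands. Calibrated
default parameter sets for occupational (8 h day⁻¹ in vehicle) and
nonoccupational (≈72 min day⁻¹) adults reproduce the packaged reference
dose table from the packaged concentration summary; every parameter is
overridable.

**Probabilistic assessment.** Maximum-likelihood distribution fitting with
Anderson–Darling selection (chi-square reported as a secondary
diagnostic), 10,000-iteration seeded Monte Carlo propagation of HI and CR,
percentile summaries, and signed contribution-to-variance sensitivity
analysis from rank correlations.

**Synthetic data.** A generator that plants known nonnegative source
profiles, heavy-tailed contributions, multiplicative noise and MDL
censoring, so every stage is testable against ground truth.

## Worked example

```r
library(dustrisk)
ref <- reference_concentrations()      # per-congener means/SD/MDL, ng g^-1
prm <- default_exposure_params("occupational")
at  <- add_table(ref, params = prm)    # ADDs, mg kg^-1 day^-1
family_sums(at)
#>   family    ingestion   inhalation       dermal
#> 1   PBDE 3.122421e-06 9.186424e-13 2.872293e-07
#> 2    OPE 1.493779e-05 4.394824e-12 2.469471e-06
route_contributions(at)                # rounded
#>   family ingestion inhalation dermal
#> 1   PBDE     91.58          0   8.42
#> 2    OPE     85.81          0  14.19
```

Ingestion dominates (92% of the PBDE dose after rounding, dermal 8%);
inhalation is ~6 orders of magnitude smaller. Deterministic risk:

```r
attr(hq_table(at), "hi")               # hazard index, occupational
#> [1] 0.00308
cr_table(at, params = prm)[, c("congener", "cr", "band")]
#> TDCiPP 9.26e-08, TCEP 3.70e-09, BDE-209 3.17e-10, ... all "negligible"
```

HI ≪ 1 and every CR < 10⁻⁶: no indication of noncancer or cancer concern
at these exposure levels. Propagating input variability:

```r
rd <- monte_carlo_risk(default_concentration_dists(ref),
                       default_param_dists(prm), params = prm,
                       n_iter = 10000, seed = 1)
percentile_summary(rd)
#>   level           hi           cr
#> 1    10 0.0008403566 7.693529e-09
#> 2    50 0.0020487823 3.551418e-08
#> 3    90 0.0055663850 2.009851e-07
head(sensitivity_contributions(rd, "hi"), 5)
#>    input       rho contribution
#> 1 BDE-47 0.4269350     25.16910
#> 2 BDE-99 0.3729347     19.20481
#> 3 TDCiPP 0.3337733     15.38323
#> 4     et 0.2914063     11.72579
#> 5  r_ing 0.2592188      9.27849
```

Even the 90th-percentile hazard index stays below one, and the
concentration inputs (BDE-47, BDE-99, TDCiPP) dominate the output
variance, followed by time spent in the vehicle; body weight contributes
negatively (it sits in the denominator).

The whole chain — synthetic generation, PCA, PMF, deterministic risk,
Monte Carlo — can also be driven from one configuration via
`run_pipeline(pipeline_config(...))`, which writes a CSV/JSON report
bundle with a seed manifest.

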