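# dlgrowth

Mechanistic, diffusion-limited tumor growth modelling for preclinical
(xenograft) drug studies, for pharmacometricians and modellers who fit
longitudinal tumor-volume data and want a growth law whose parameters mean
something physiological.

Empirical growth laws (exponential, Gompertz, exponential-linear, ...) fit
xenograft volume series well but say nothing about what is happening inside
the tumor. dlgrowth implements a growth law of the same mathematical shape
derived from spherical nutrient diffusion: a tumor of radius *R* develops a
necrotic core of radius *R*<sub>n</sub> once *R* exceeds a critical radius
*R*<sub>c</sub>, with the core size set by the steady-state diffusion
balance

&nbsp;&nbsp;&nbsp;&nbsp;*R*² − 3*R*<sub>n</sub>² + 2*R*<sub>n</sub>³/*R* = *R*<sub>c</sub>²,

so the growing fraction *G* = 1 − (*R*<sub>n</sub>/*R*)³ is determined
algebraically from the current volume. The volume rate equation is

&nbsp;&nbsp;&nbsp;&nbsp;dV/dt = λ·G·V − λ<sub>n</sub>·(1−G)·V − k·c(t)·G·V,

with net proliferation rate λ, necrotic loss rate λ<sub>n</sub>, drug
potency k, and single-exponential plasma kinetics c(t) (bolus mg/kg doses,
12-h default half-life as for irinotecan). Because the model is spatial at
heart it *predicts* the growth fraction — comparable with Ki-67 endpoint
histology via the cross-section relation (1−G)^(2/3) — and extends to
spatially limited drug penetration: a quasi-steady reaction–diffusion
profile in the proliferating shell with penetration parameter ρ, whose
shell-integrated kill replaces k·c·G.

The package also provides the classical comparator laws under the same
dosing interface, SAEM nonlinear mixed-effects population fitting with
log-normal random effects and importance-sampling AIC, visual predictive
checks, a synthetic-cohort generator emulating a three-protocol CDX
efficacy study (95 mice, 68/18/9 across weekly 50 mg/kg schedules), CSV
I/O, and a command-line interface.

## Worked example

```r
library(dlgrowth)

p <- dl_params(lambda_net = 0.12, lambda_nec = 0.05, k_drug = 5.7e-3,
               R_c = 0.41, V0 = 0.25)
sch <- dose_schedule(c(1, 8, 15), 50)          # weekly 50 mg/kg
sim <- simulate_dl(p, sch, t_grid = seq(0, 30, by = 5))
round(as.data.frame(sim), 4)
#>   time      V      R    R_n      G    conc
#> 1    0 0.2500 0.3908 0.0000 1.0000  0.0000
#> 2    5 0.3704 0.4455 0.1101 0.9849  0.1953
#> 3   10 0.5421 0.5058 0.1992 0.9390  3.1252
#> 4   15 0.8966 0.5982 0.3112 0.8593 50.0031
#> 5   20 1.1989 0.6590 0.3795 0.8090  0.0488
#> 6   25 1.8001 0.7546 0.4831 0.7376  0.0000
#> 7   30 2.5555 0.8481 0.5819 0.6770  0.0000
```

The tumor starts fully proliferating (G = 1, pure exponential growth),
crosses the critical volume V<sub>c</sub> = 4π/3·0.41³ ≈ 0.289 cm³ on day
~1, and by day 30 has grown to 2.56 cm³ with a necrotic core at 69% of its
radius (G = 0.68). The `conc` column shows the sawtooth plasma
concentration at the output times; treatment-induced shrinkage raises G
again (the core regains nutrient access) — the mechanistic signature that
empirical laws cannot produce.

Drug penetration: the fraction of the applied concentration reaching the
necrotic boundary of a shell with R = 0.6, R<sub>n</sub> = 0.3 cm is

```r
penetration_ratio(0.6, 0.3, rho = c(0, 2, 5, 10))
#> [1] 1.0000 0.7358 0.2339 0.0225
```

— uniform at ρ = 0, surface-confined at large ρ;
`simulate_spatial()` runs the full trajectory with the shell-integrated
kill.

Population fitting on a synthetic cohort:

```r
coh <- generate_cohort(design_az_cdx(40), dl_population_default(), "dl", seed = 1)
fit <- fit_population(coh, "dl", saem_control(n_burn = 200, n_smooth = 100),
                      seed = 2)
information_criteria(fit, coh)
```

## Command line

```sh
Rscript inst/cli/dlgrowth.R synth --preset az_cdx --n 95 --seed 1 --out-dir run1
Rscript inst/cli/dlgrowth.R fit --volumes run1/volumes.csv --doses run1/doses.csv \
    --model dl --n-runs 3 --out-dir run1
Rscript inst/cli/dlgrowth.R vpc --model dl --n-sim 1000 --out-dir run1
```

Every run directory gets a `run.json` (config, seed, package version) for
bit-for-bit reproducibility.

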