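# cdtk — two-phase toxicokinetics of dietary cadmium in ant colonies

`cdtk` analyses time-course data from a destructive-sampling feeding
experiment: ant colonies from two habitat types (forest and city) are fed
cadmium-laced food (100 mg·kg⁻¹) for 21 days and then clean food
(1 mg·kg⁻¹) for 21 more, and whole colonies are removed and assayed at 13
sampling days. The package is for ecotoxicologists who want to estimate
uptake and elimination kinetics from such designs, test whether kinetics
differ between groups, and validate the whole workflow on simulated data.

## The model

Internal concentration follows a one-compartment first-order balance. During
the contamination phase (t ≤ t_C):

    C_I(t) = C_I0 · e^(−kE1·t) + C_Eu · (kA1/kE1) · (1 − e^(−kE1·t))

and during decontamination (t > t_C) the same form restarts from the
predicted switch concentration C_ItC with the clean-food concentration C_Ed
and its own rate pair (kA2, kE2), so the curve is continuous at t_C.
kA is the assimilation rate constant and kE the elimination rate constant
(both day⁻¹); the phase plateau is C_E·kA/kE. Each phase is fitted by
Gauss–Newton nonlinear least squares; a pooled model (one rate pair) is
compared against a habitat-indexed model (one pair per habitat, fitted as a
single joint regression) with AIC and the extra-sum-of-squares F-test.
A linear model contrasts day-0 against day-42 concentrations with habitat
and their interaction.

## Worked example

```r
library(cdtk)

sch <- exposure_schedule(C_I0 = 2)           # C_Eu = 100, C_Ed = 1, t_C = 21
sim <- generate_dataset(simulation_config(seed = 42))
obs <- sim$observations                       # 104 colonies, 13 days

f0 <- fit_phase(obs, "contamination", sch, "pooled")
f1 <- fit_phase(obs, "contamination", sch, "by_habitat")
compare_nested(f0, f1)
```

prints (seed 42):

```
Nested model comparison (contamination phase):
  F(2, 44) = 104.753, p = 1.854e-17
  AIC null = 344.09, AIC alternative = 264.03 (delta = -80.06)
  preferred: by_habitat
```

The habitat-indexed model wins decisively because the generator's default
truth gives forest colonies a ~88 mg·kg⁻¹ plateau and city colonies a
~69.5 mg·kg⁻¹ plateau:

```r
steady_state(default_truth()$forest$contamination, 100)   # 88.03
steady_state(default_truth()$city$contamination, 100)     # 69.53
print(f1)
```

```
Toxicokinetic fit: contamination phase, by_habitat model (n = 48, p = 4)
          estimate      se ci_low ci_high
kA_city     1.1980 0.10270 0.9910  1.4050
kE_city     1.6900 0.15130 1.3860  1.9950
kA_forest   0.5817 0.02833 0.5246  0.6389
kE_forest   0.6594 0.03525 0.5883  0.7304
RSS = 558.7, adjusted R2 = 0.925, AIC = 264.03 (converged in 6 iter)
```

Estimates (truth: city 1.262/1.815, forest 0.581/0.66) carry asymptotic 95%
confidence intervals from the Jacobian at the optimum. The endpoint
contrast asks whether colonies returned to their initial concentration by
day 42:

```r
test_term(obs, "time_point")
#> time_point: F(1, 13) = 209.860, p = 2.12e-09
```

A full report bundle (parameter table, comparison/endpoint JSON, prediction
curves, run log) comes from the pipeline or the CLI:

```r
run_pipeline(list(simulate = list()), out_dir = "out", seed = 42)
```

```sh
Rscript -e 'cdtk::cdtk_cli()' run --config config.json --out out --seed 42
```

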