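# neoperem

Population pharmacokinetics and dosing simulation of meropenem in
critically ill neonates and children on extracorporeal membrane oxygenation
(ECMO), with or without continuous renal replacement therapy (CRRT).

Beta-lactam dosing in neonatal ECMO is hard: body weight spans an order of
magnitude, the circuit and renal-replacement therapy change drug
disposition, and routine therapeutic drug monitoring (TDM) yields only a
handful of sparse concentrations per patient. This package implements a
complete, tested workflow for that setting, aimed at pharmacometricians and
intensive-care researchers:

* **Final covariate model** — one-compartment kinetics with

  `CL = CLp (BW/7.88) exp(eta_CL)`,
  `V = Vp (BW/7.88) (1 + theta_CRRT)^CRRT exp(eta_V)`,

  log-normal inter-individual variability and proportional residual error,
  with the published estimates packaged as a fixture
  (`CLp = 1.09 L/h`, `Vp = 3.98 L`, `theta_CRRT = 1.04`,
  `omega2_CL = 0.0887`, `omega2_V = 0.916`, `sigma2 = 0.17`), and
  closed-form infusion kinetics verified against numeric ODE integration.
* **Monte Carlo dosing evaluation** — probability of target attainment
  (PTA) for 40% and 100% fT>MIC across the standard regimens (20/40 mg/kg
  q8h as 0.5 h or 3 h infusions; 60/120 mg/kg/day continuous), MIC
  0.5–16 mg/L, on and off CRRT (`pta()`, `run_table3()`).
* **Estimation** — Laplace nonlinear mixed-effects fitting with forward
  stepwise covariate modeling at the ΔOFV > 3.84 criterion
  (`fit_model()`, `scm()`).
* **Validation** — nonparametric bootstrap, normalized prediction
  distribution errors (NPDE) and conditional-weighted-residual diagnostics
  (`bootstrap_model()`, `npde()`, `gof()`).
* **Synthetic TDM generator** — cohorts and sparse NONMEM-style datasets
  emulating the study population (45 subjects, median weight 7.88 kg,
  38/45 ECMO, 31/45 CRRT, ~152 concentrations), so the whole pipeline is
  runnable and testable without any clinical data
  (`generate_cohort()`, `generate_tdm()`).

## Worked example

```r
library(neoperem)

pop <- final_model()
ind <- individual_params(pop, subject_covariates(bw = 7.88, crrt_on = 0))
ind
#> Individual PK parameters: CL = 1.09 L/h, V = 3.98 L, ke = 0.2739 1/h

# steady-state trough of 20 mg/kg infused over 0.5 h every 8 h
reg <- build_regimen("short_q8h", 20, bw = 7.88, horizon = 168)
conc_at(ind, reg, 168)
#> [1] 5.342222

# PTA at MIC 4 mg/L for the 40% fT>MIC target, 10,000 subjects
cfg <- simulation_config(n_subjects = 10000, bw = 7.88, crrt_on = 0, seed = 1)
pta(pop, reg, mic_grid = 4, targets = 0.4, cfg = cfg)
#>              regimen crrt mic target   pta     n seed
#> 1 20 mg/kg 0.5 h q8h    0   4    0.4 89.01 10000    1
```

The typical patient keeps its trough (5.3 mg/L) above an MIC of 4 mg/L for
the whole dosing interval, but once inter-individual variability and
residual noise are simulated, about 11% of subjects fail the 40% fT>MIC
target at that MIC — which is why the intermittent regimens stop being
reliable in the MIC "grey zone" while continuous infusion at 120 mg/kg/day
holds PTA near 100% up to 4 mg/L.

An end-to-end synthetic analysis:

```r
dat <- generate_tdm(generate_cohort(cohort_spec(seed = 1)),
                    design_spec(), pop, seed = 2)
fit <- fit_model(dat, final_structure())
fit            # estimates with RSEs, OFV
npde(dat, as_population_parameters(fit), n_sim = 500, seed = 3)
```

A thin command-line wrapper with `generate`, `fit`, `pta`, `table3`,
`bootstrap` and `npde` subcommands is installed at
`system.file("cli", "neoperem", package = "neoperem")`.

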