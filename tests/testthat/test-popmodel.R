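test_that("covariate model reproduces the published typical values", {
  pop <- final_model()
  # typical subject at the reference weight, off CRRT
  ind <- individual_params(pop, subject_covariates(bw = 7.88, crrt_on = 0))
  expect_equal(ind$cl, 1.09, tolerance = 1e-12)
  expect_equal(ind$v, 3.98, tolerance = 1e-12)
  expect_equal(ind$ke, 1.09 / 3.98, tolerance = 1e-12)
  # CRRT doubles the volume via the (1 + theta) multiplier
  ind1 <- individual_params(pop, subject_covariates(bw = 7.88, crrt_on = 1))
  expect_equal(ind1$v, 3.98 * (1 + 1.04), tolerance = 1e-12)
  expect_equal(ind1$cl, ind$cl)
  # identity at reference covariates holds for any parameter set
  p2 <- population_parameters(0.7, 2.5, 0.3, 0.1, 0.2, 0.05, bw_ref = 5)
  i2 <- individual_params(p2, subject_covariates(bw = 5, crrt_on = 0))
  expect_equal(i2$cl, 0.7)
  expect_equal(i2$v, 2.5)
  # body-weight scaling is proportional and random effects act log-normally
  i3 <- individual_params(p2, subject_covariates(bw = 10), 0.2, -0.1)
  expect_equal(i3$cl, 0.7 * 2 * exp(0.2))
  expect_equal(i3$v, 2.5 * 2 * exp(-0.1))
})

test_that("constructors reject invalid parameters and covariates", {
  expect_error(population_parameters(-1, 4), "clp")
  expect_error(population_parameters(1, 4, theta_crrt = -1.2), "theta_crrt")
  expect_error(population_parameters(1, 4, omega2_cl = -0.1), "omega2_cl")
  expect_error(subject_covariates(bw = 0), "bw")
  expect_error(subject_covariates(bw = 5, crrt_on = 2), "crrt_on")
  expect_error(subject_covariates(5, 0, extras = list(pna = NaN)), "finite")
  pop <- final_model()
  expect_error(individual_params(pop, subject_covariates(5), eta_cl = Inf),
               "finite")
  expect_error(dose_event(-1, 10, 1), "start")
  expect_error(dose_event(0, 10, 0), "duration")
  expect_error(regimen(list(dose_event(8, 10, 1), dose_event(0, 10, 1))),
               "sorted")
})

test_that("closed-form kinetics match steady-state limits and the ODE oracle", {
  pop <- final_model()
  ind <- individual_params(pop, subject_covariates(7.88))
  # no doses, no drug
  expect_equal(conc_at(ind, regimen(), c(0, 5, 100)), c(0, 0, 0))
  # continuous infusion approaches Css = R / CL
  cont <- build_regimen("continuous", 120, bw = 7.88, horizon = 168)
  expect_equal(conc_at(ind, cont, 168), 39.4 / 1.09, tolerance = 1e-3)
  # q8h steady-state peak and trough against the numeric ODE integrator
  q8 <- build_regimen("short_q8h", 20, bw = 7.88, horizon = 168)
  got <- conc_at(ind, q8, c(160.5, 168))
  a <- list(st = seq(0, 167.9, 8), du = rep(0.5, 21), rt = rep(315.2, 21))
  want <- ode_conc(c(160.5, 168), a$st, a$rt, a$du, ind$cl, ind$v)
  expect_lt(max(abs(got - want)), 1e-4)
  expect_equal(got[1], 41.665, tolerance = 1e-3) # end-of-infusion peak
  expect_equal(got[2], 5.342, tolerance = 1e-3)  # trough
  expect_error(conc_at(ind, q8, -1), ">= 0")
})

test_that("kinetics obey superposition, rate homogeneity and V-independent Css", {
  set.seed(7)
  for (i in 1:20) {
    cl <- runif(1, 0.2, 3); v <- runif(1, 0.8, 12)
    ind <- individual_params(
      population_parameters(cl, v, bw_ref = 1), subject_covariates(1))
    ns <- sample(1:4, 1)
    st <- sort(runif(ns, 0, 24)); du <- runif(ns, 0.3, 5)
    rt <- runif(ns, 5, 200)
    ev <- lapply(seq_len(ns), function(k) dose_event(st[k], rt[k], du[k]))
    tt <- sort(runif(5, 0, 40))
    full <- conc_at(ind, regimen(ev), tt)
    # ODE oracle agreement
    expect_lt(max(abs(full - ode_conc(tt, st, rt, du, cl, v))), 1e-4)
    # superposition over events
    parts <- sapply(ev, function(e) conc_at(ind, regimen(list(e)), tt))
    expect_equal(full, rowSums(parts), tolerance = 1e-10)
    # homogeneity of degree 1 in dose rate
    ev2 <- lapply(ev, function(e) dose_event(e$start, 2 * e$rate, e$duration))
    expect_equal(conc_at(ind, regimen(ev2), tt), 2 * full, tolerance = 1e-10)
  }
  # for fixed CL the continuous steady state does not depend on V
  base <- population_parameters(1.09, 3.98, bw_ref = 7.88)
  css <- sapply(c(1, 4, 16), function(vv) {
    ind <- individual_params(population_parameters(1.09, vv, bw_ref = 7.88),
                             subject_covariates(7.88))
    conc_at(ind, build_regimen("continuous", 120, 7.88, 500), 500)
  })
  expect_lt(diff(range(css)), 1e-6)
})

test_that("profiles validate their grid and locate the infusion peak", {
  pop <- final_model()
  ind <- individual_params(pop, subject_covariates(7.88))
  q8 <- build_regimen("short_q8h", 20, bw = 7.88, horizon = 168)
  expect_error(conc_profile(ind, q8, c(2, 1)), "increasing")
  expect_error(conc_profile(ind, q8, numeric(0)), "at least one")
  # single grid point at time zero, before any drug has been given
  expect_equal(conc_profile(ind, q8, 0)$conc, 0)
  # continuous regimen is flat at steady state
  cont <- build_regimen("continuous", 120, bw = 7.88, horizon = 168)
  pr <- conc_profile(ind, cont, seq(144, 168, 1))
  expect_equal(length(pr$conc), 25)
  expect_true(all(abs(pr$conc - 39.4 / 1.09) / (39.4 / 1.09) < 0.01))
  # over one steady-state q8h interval the maximum sits at end of infusion
  grid <- seq(160, 168, 0.25)
  pi8 <- conc_profile(ind, q8, grid)
  expect_equal(grid[which.max(pi8$conc)], 160.5)
  oracle <- ode_conc(grid, seq(0, 167.9, 8), rep(315.2, 21), rep(0.5, 21),
                     ind$cl, ind$v)
  expect_lt(max(abs(pi8$conc - oracle)), 1e-4)
})

test_that("fraction of time above MIC follows the grid-point convention", {
  pop <- final_model()
  ind <- individual_params(pop, subject_covariates(7.88))
  q8 <- build_regimen("short_q8h", 20, bw = 7.88, horizon = 168)
  pr <- conc_profile(ind, q8, seq(144, 168, 1))
  expect_equal(ft_above_mic(pr, 0.01), 1.0)          # all points above
  expect_equal(ft_above_mic(pr, max(pr$conc) + 1), 0) # MIC above the peak
  # typical subject keeps the whole interval above MIC 4 (trough ~ 5.3)
  expect_equal(ft_above_mic(pr, 4), 1.0)
  # strictly-above convention on a bare numeric profile
  expect_equal(ft_above_mic(c(1, 2, 3, 4), 2), 0.5)
  expect_error(ft_above_mic(pr, 0), "positive")
  expect_error(ft_above_mic(numeric(0), 1), "non-empty")
})
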