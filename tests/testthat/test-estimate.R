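# The OFV is checked against two independent oracles: a pure-R weighted
# least-squares deviance in the degenerate no-IIV case, and Gauss-Hermite
# quadrature (fixed-grid and adaptive) of the marginal likelihood.

test_that("with zero IIV the OFV is the fixed-effect WLS deviance", {
  d <- toy_tdm()
  pop <- population_parameters(1.2, 4.5, 0.9, 0, 0, 0.05)
  got <- ofv(d, pop)
  # independent computation: -2 sum log N(y; f, sigma2 f^2) at eta = 0
  want <- 0
  for (id in unique(d$ID)) {
    s <- d[d$ID == id, ]
    dd <- s[s$EVID == 1, ]; o <- s[s$EVID == 0, ]
    for (m in seq_len(nrow(o))) {
      cl <- 1.2 * o$BW[m] / 7.88
      v <- 4.5 * (o$BW[m] / 7.88) * (1 + 0.9)^o$CRRT[m]
      f <- conc_R(o$TIME[m], dd$TIME, dd$RATE, dd$AMT / dd$RATE, cl, v)
      want <- want - 2 * dnorm(o$DV[m], f, sqrt(0.05) * f, log = TRUE)
    }
  }
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("Laplace OFV agrees with Gauss-Hermite quadrature", {
  pop <- population_parameters(1.0, 4, 0, 0.09, 0.2, 0.04)
  # sparse 3-subject toy set: brute-force 32^2 fixed-grid quadrature is
  # accurate there and the Laplace approximation should track it closely
  co <- generate_cohort(cohort_spec(n_subjects = 3, seed = 43))
  toy <- generate_tdm(co, design_spec(obs_lambda = 0.5), pop, seed = 53)
  expect_lt(abs(ofv(toy, pop) - gh_ofv(toy, pop)), 0.1)
  # richer small instances against the adaptive (mode-centred) oracle
  for (s in 1:3) {
    co <- generate_cohort(cohort_spec(n_subjects = 4, seed = 60 + s))
    dat <- generate_tdm(co, design_spec(obs_lambda = 4), pop, seed = 70 + s)
    expect_lt(abs(ofv(dat, pop) - agh_ofv(dat, pop)), 0.5)
  }
})

test_that("the OFV prefers the generating parameters on rich data", {
  pop <- population_parameters(1.0, 4, 0, 0.04, 0.04, 0.02)
  wrong <- population_parameters(2.0, 8, 0, 0.04, 0.04, 0.02)
  wins <- 0
  for (r in 1:40) {
    co <- generate_cohort(cohort_spec(n_subjects = 1, seed = 100 + r))
    dat <- generate_tdm(co, design_spec(obs_lambda = 8), pop, seed = 200 + r)
    if (ofv(dat, pop) < ofv(dat, wrong)) wins <- wins + 1
  }
  expect_gt(wins / 40, 0.5)
})

test_that("noise-free rich data recover the fixed effects to 3 significant digits", {
  gen <- population_parameters(1.09, 3.98, 1.04, 0, 0, 0)
  co <- generate_cohort(cohort_spec(n_subjects = 12, seed = 301))
  dat <- generate_tdm(co, design_spec(obs_lambda = 8), gen, seed = 302)
  # deterministic weighted-least-squares limit: variances held fixed
  f <- suppressWarnings(
    fit_model(dat, final_structure(),
              fix = list(omega2_cl = 0, omega2_v = 0, sigma2 = 1e-4),
              restarts = 0, compute_rse = FALSE))
  expect_lt(abs(coef(f)["clp"] / 1.09 - 1), 5e-4)
  expect_lt(abs(coef(f)["vp"] / 3.98 - 1), 5e-4)
  expect_lt(abs(coef(f)["theta_CRRT_v"] / 1.04 - 1), 5e-3)
})

test_that("a single-subject dataset flags IIV variances as unidentifiable", {
  pop <- final_model()
  co <- generate_cohort(cohort_spec(n_subjects = 1, seed = 88))
  dat <- generate_tdm(co, design_spec(obs_lambda = 3), pop, seed = 89)
  expect_warning(f <- fit_model(dat, base_structure(), restarts = 0,
                                compute_rse = FALSE),
                 "not identifiable")
  expect_false(f$iiv_identifiable)
  expect_equal(unname(coef(f)["sigma2"] >= 0), TRUE)
})

test_that("nested models never increase the optimised OFV", {
  pop <- final_model()
  co <- generate_cohort(cohort_spec(seed = 401))
  dat <- generate_tdm(co, design_spec(), pop, seed = 402)
  set.seed(403) # restart jitter
  fb <- suppressWarnings(fit_model(dat, base_structure(), restarts = 1,
                                   compute_rse = FALSE))
  ff <- suppressWarnings(fit_model(dat, final_structure(), restarts = 1,
                                   compute_rse = FALSE))
  # the final structure nests the base model (theta = 0, BW exponent absorbed
  # by refit); its optimum cannot be worse by more than numerical tolerance
  expect_gt(fb$ofv - ff$ofv, -0.5)
})

test_that("estimates are invariant to relabeling and time-origin shifts", {
  pop <- final_model()
  co <- generate_cohort(cohort_spec(n_subjects = 20, seed = 501))
  dat <- generate_tdm(co, design_spec(), pop, seed = 502)
  f1 <- suppressWarnings(fit_model(dat, final_structure(), restarts = 0,
                                   compute_rse = FALSE))
  # relabel subjects in reverse order
  d2 <- as.data.frame(dat)
  d2$ID <- max(d2$ID) + 1 - d2$ID
  d2 <- d2[order(d2$ID, d2$TIME, -d2$EVID), ]
  f2 <- suppressWarnings(fit_model(as_tdm(d2), final_structure(),
                                   restarts = 0, compute_rse = FALSE))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-5)
  # shift every subject's clock by +24 h
  d3 <- as.data.frame(dat)
  d3$TIME <- d3$TIME + 24
  f3 <- suppressWarnings(fit_model(as_tdm(d3), final_structure(),
                                   restarts = 0, compute_rse = FALSE))
  expect_equal(coef(f3), coef(f1), tolerance = 1e-5)
  expect_equal(f3$ofv, f1$ofv, tolerance = 1e-6)
})

test_that("relative standard errors are produced on the natural scale", {
  pop <- final_model()
  co <- generate_cohort(cohort_spec(seed = 601))
  dat <- generate_tdm(co, design_spec(), pop, seed = 602)
  f <- suppressWarnings(fit_model(dat, final_structure(), restarts = 0))
  expect_false(is.null(f$rse))
  expect_true(all(f$rse >= 0))
  expect_named(f$rse, c("clp", "vp", "theta_CRRT_v", "omega2_cl",
                        "omega2_v", "sigma2"))
  # clearance is the best-determined parameter in this design
  expect_lt(f$rse["clp"], 25)
  p <- as_population_parameters(f)
  expect_s3_class(p, "pop_params")
  expect_equal(p$clp, unname(coef(f)["clp"]))
})
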