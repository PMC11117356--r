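test_that("standard study regimens are built with the correct events", {
  # continuous: one event at the daily rate for the whole horizon
  r <- build_regimen("continuous", 120, bw = 7.88, horizon = 168)
  expect_length(r$events, 1)
  expect_equal(r$events[[1]]$rate, 120 * 7.88 / 24) # 39.4 mg/h
  expect_equal(r$events[[1]]$duration, 168)
  # q8h short infusions over 24 h: three 157.6 mg doses over 0.5 h
  r2 <- build_regimen("short_q8h", 20, bw = 7.88, horizon = 24)
  expect_length(r2$events, 3)
  expect_equal(vapply(r2$events, `[[`, 0, "start"), c(0, 8, 16))
  for (e in r2$events) {
    expect_equal(e$rate * e$duration, 157.6)
    expect_equal(e$duration, 0.5)
  }
  # a single interval fits an 8 h horizon
  expect_length(build_regimen("short_q8h", 30, 5, horizon = 8)$events, 1)
  expect_equal(build_regimen("prolonged_q8h", 40, 10)$events[[1]]$duration, 3)
  expect_error(build_regimen("hourly", 20, 7.88))
  expect_error(build_regimen("short_q8h", -5, 7.88), "dose_per_kg")
})

test_that("sampled populations match the log-normal IIV model", {
  pop <- final_model()
  # degenerate variances collapse to the typical subject
  p0 <- population_parameters(1.09, 3.98, 1.04, 0, 0, 0.17)
  s0 <- sample_population(p0, simulation_config(n_subjects = 50, seed = 3))
  expect_true(all(s0$cl == 1.09) && all(s0$v == 3.98))
  # large sample: median CL = typical CL, log-variance = omega2_cl
  cfg <- simulation_config(n_subjects = 1e5, seed = 11)
  s <- sample_population(pop, cfg)
  expect_lt(abs(median(s$cl) / 1.09 - 1), 0.01)
  expect_lt(abs(var(log(s$cl)) / 0.0887 - 1), 0.05)
  expect_equal(s$ke, s$cl / s$v)
  # CRRT configuration doubles the median volume
  s1 <- sample_population(pop, simulation_config(n_subjects = 1e4, crrt_on = 1,
                                                 seed = 11))
  expect_lt(abs(median(s1$v) / (3.98 * 2.04) - 1), 0.05)
  # reproducibility
  expect_identical(s0, sample_population(p0, simulation_config(50, seed = 3)))
})

test_that("PTA is monotone, reproducible, and matches the lognormal oracle", {
  pop <- final_model()
  cfg <- simulation_config(n_subjects = 4000, seed = 5)
  regs <- list(build_regimen("short_q8h", 20, cfg$bw),
               build_regimen("short_q8h", 40, cfg$bw),
               build_regimen("continuous", 120, cfg$bw))
  res <- pta(pop, regs, cfg = cfg)
  # non-increasing in MIC for every regimen x target
  for (lb in unique(res$regimen)) for (tg in c(0.4, 1)) {
    p <- res$pta[res$regimen == lb & abs(res$target - tg) < 1e-9]
    expect_true(all(diff(p) <= 0))
  }
  # non-decreasing in dose for the same schedule shape and seed
  p20 <- res$pta[res$regimen == regs[[1]]$label]
  p40 <- res$pta[res$regimen == regs[[2]]$label]
  expect_true(all(p40 - p20 >= 0))
  # huge MIC: nobody attains
  far <- pta(pop, regs[[3]], mic_grid = c(0.5, 5000), cfg = cfg)
  expect_equal(far$pta[far$mic == 5000], c(0, 0))
  # bit-identical repetition at a fixed seed
  expect_identical(res, pta(pop, regs, cfg = cfg))
  expect_error(pta(pop, list(), cfg = cfg), "non-empty")
  expect_error(pta(pop, regs, mic_grid = c(2, 1), cfg = cfg), "ascending")
})

test_that("continuous-infusion PTA without residual error equals the closed form", {
  # with Css = R/CL and log-normal CL, attainment of any fT target is
  # P(CL < R/MIC) = Phi((log(R/MIC) - log(cl_typ)) / omega)
  pop <- final_model()
  n <- 10000
  cfg <- simulation_config(n_subjects = n, include_ruv = FALSE, seed = 9)
  reg <- build_regimen("continuous", 60, cfg$bw)
  res <- pta(pop, reg, mic_grid = c(4, 8, 16), targets = 1.0, cfg = cfg)
  R <- 60 * 7.88 / 24
  for (mic in c(4, 8, 16)) {
    p_hat <- res$pta[res$mic == mic] / 100
    p_true <- pnorm((log(R / mic) - log(1.09)) / sqrt(0.0887))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-9)
  }
})

test_that("doubling Vd cannot reduce intermittent-regimen fT at the 40% target", {
  # flatter profiles at fixed CL: CRRT-on fT >= CRRT-off fT subject by
  # subject when residual error is off (common random numbers)
  pop <- final_model()
  reg <- build_regimen("short_q8h", 20, 7.88)
  for (seed in 1:3) {
    p <- sapply(c(0, 1), function(crrt) {
      cfg <- simulation_config(n_subjects = 1500, crrt_on = crrt,
                               include_ruv = FALSE, seed = seed)
      pta(pop, reg, mic_grid = c(2, 8), targets = 0.4, cfg = cfg)$pta
    })
    expect_true(all(p[, 2] - p[, 1] >= 0))
  }
})

test_that("the wide PTA table is complete, rounded and errors on missing cells", {
  pop <- final_model()
  res <- rbind(
    pta(pop, list(build_regimen("short_q8h", 20, 7.88),
                  build_regimen("continuous", 60, 7.88)),
        cfg = simulation_config(n_subjects = 200, seed = 2)),
    pta(pop, list(build_regimen("short_q8h", 20, 7.88),
                  build_regimen("continuous", 60, 7.88)),
        cfg = simulation_config(n_subjects = 200, crrt_on = 1, seed = 2)))
  tab <- pta_table(res)
  expect_named(tab, c("40% fT>MIC", "100% fT>MIC"))
  expect_equal(dim(tab[[1]]), c(6, 4))
  expect_true(all(tab[[1]] == round(tab[[1]])))
  expect_error(pta_table(res[res$mic != 2 | res$crrt != 1, ]), "missing")
  f <- tempfile(fileext = ".csv")
  pta_table(res, file = f)
  expect_true(file.exists(f))
  expect_equal(sum(grepl("Probability of target attainment",
                         readLines(f))), 2)
  unlink(f)
})
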