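# Model validation: nonparametric bootstrap, normalized prediction
# distribution errors (NPDE) and residual-based goodness of fit.

# rebuild a dataset from a vector of (possibly repeated) subject ids,
# renumbering subjects 1..n
.resample_data <- function(data, ids) {
  pieces <- lapply(seq_along(ids), function(k) {
    s <- data[data$ID == ids[k], , drop = FALSE]
    s$ID <- k
    s
  })
  do.call(rbind, pieces)
}

#' Nonparametric bootstrap of a population PK model
#'
#' Resamples subjects with replacement to the original subject count,
#' refits the model on every replicate (warm-started from the original
#' estimates) and summarises the converged replicates with the median and a
#' 95\% percentile interval per parameter.
#'
#' @param data a `tdm_dataset`.
#' @param structure a [model_structure()].
#' @param n number of replicates (the published analysis used 1000).
#' @param seed integer seed.
#' @param fit0 optional original fit (computed if omitted).
#' @param fix passed to [fit_model()].
#' @return An object of class `bootstrap_result`: `summary` data.frame
#'   (parameter, median, lower, upper), `estimates` matrix, `converged`
#'   logical vector, `n_replicates`, and the original estimates `original`.
#' @export
bootstrap_model <- function(data, structure = final_structure(), n = 1000,
                            seed = 1L, fit0 = NULL, fix = .default_fix()) {
  data <- as_tdm(as.data.frame(data))
  if (is.null(fit0))
    fit0 <- fit_model(data, structure, fix = fix, compute_rse = FALSE)
  if (!isTRUE(fit0$converged)) stop("original fit did not converge")
  ids <- unique(data$ID)
  orig <- coef(fit0)
  est <- matrix(NA_real_, n, length(orig),
                dimnames = list(NULL, names(orig)))
  conv <- logical(n)
  .with_seed(seed, {
    for (b in seq_len(n)) {
      bd <- .resample_data(data, sample(ids, length(ids), replace = TRUE))
      fb <- tryCatch(
        suppressWarnings(
          fit_model(bd, structure, init = fit0$params, fix = fix,
                    restarts = 0, compute_rse = FALSE)),
        error = function(e) NULL)
      if (!is.null(fb) && isTRUE(fb$converged)) {
        est[b, ] <- coef(fb)
        conv[b] <- TRUE
      }
    }
  })
  ok <- est[conv, , drop = FALSE]
  if (!nrow(ok)) stop("no bootstrap replicate converged")
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(ok, 2, stats::median),
    lower = apply(ok, 2, stats::quantile, 0.025),
    upper = apply(ok, 2, stats::quantile, 0.975),
    row.names = NULL)
  out <- list(summary = summ, estimates = est, converged = conv,
              n_replicates = n, convergence_rate = mean(conv),
              original = orig)
  class(out) <- "bootstrap_result"
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.1f%% converged\n",
              x$n_replicates, 100 * x$convergence_rate))
  s <- x$summary
  s$original <- x$original[s$parameter]
  print(s, digits = 4)
  invisible(x)
}

# simulate K replicate observation vectors under the model on the original
# design; returns n_obs x K matrix.  The residual multiplier is truncated
# positive exactly as in the data-generating observation model.
.simulate_obs <- function(comp, clt, vt, pop_like, K) {
  eta_cl <- matrix(stats::rnorm(comp$n_sub * K, 0,
                                sqrt(pop_like$omega2_cl)), comp$n_sub)
  eta_v <- matrix(stats::rnorm(comp$n_sub * K, 0,
                               sqrt(pop_like$omega2_v)), comp$n_sub)
  f <- pred_bulk_cpp(comp$obs_t, comp$obs_off, comp$d_st, comp$d_rt,
                     comp$d_du, comp$dose_off, clt, vt, eta_cl, eta_v)
  m <- 1 + stats::rnorm(length(f), 0, sqrt(pop_like$sigma2))
  bad <- which(m <= 0.02)
  while (length(bad)) {
    m[bad] <- 1 + stats::rnorm(length(bad), 0, sqrt(pop_like$sigma2))
    bad <- bad[m[bad] <= 0.02]
  }
  f * matrix(m, nrow(f))
}

#' Normalized prediction distribution errors
#'
#' Simulates the original design `n_sim` times under the model, decorrelates
#' observed and simulated vectors per subject with the Cholesky root of the
#' simulation covariance, rank-transforms each observation within its
#' simulated distribution and maps the ranks through the standard-normal
#' quantile function. Under a correct model the NPDEs are standard normal;
#' a t-test for mean 0 and a normal-approximation test for variance 1 are
#' reported. Simulation draws are made per subject in sorted-ID order, so
#' the result does not depend on the row order of the dataset.
#'
#' @param data a `tdm_dataset`.
#' @param pop a [population_parameters()] object (e.g. the original fit).
#' @param structure a [model_structure()].
#' @param n_sim number of simulated replicates (>= 50; the published
#'   analysis used 500).
#' @param seed integer seed.
#' @return An object of class `npde_result`: per-observation table
#'   (`ID`, `TIME`, `DV`, `npde`), `mean`, `se_mean`, `var`, `se_var`,
#'   `p_mean`, `p_var`, `degenerate` flag.
#' @export
npde <- function(data, pop, structure = final_structure(), n_sim = 500,
                 seed = 1L) {
  if (n_sim < 50)
    stop("n_sim must be >= 50 (rank resolution too coarse below that)")
  data <- as_tdm(as.data.frame(data))
  comp <- .compile_tdm(data)
  params <- .pop_to_params(pop, structure)
  m <- .cov_multipliers(structure, comp$X, params$thetas)
  clt <- params$clp * m$cl
  vt <- params$vp * m$v
  npde_v <- numeric(comp$n_obs)
  .with_seed(seed, {
    # subjects are processed in sorted-ID order with per-subject draws, so
    # the NPDEs do not depend on the row order of the input file
    for (i in order(comp$ids)) {
      idx <- (comp$obs_off[i] + 1L):comp$obs_off[i + 1L]
      kdx <- if (comp$dose_off[i] < comp$dose_off[i + 1L])
        (comp$dose_off[i] + 1L):comp$dose_off[i + 1L] else integer(0)
      sub <- list(n_sub = 1L, obs_t = comp$obs_t[idx],
                  obs_off = c(0L, length(idx)),
                  d_st = comp$d_st[kdx], d_rt = comp$d_rt[kdx],
                  d_du = comp$d_du[kdx], dose_off = c(0L, length(kdx)))
      Yi <- .simulate_obs(sub, clt[idx], vt[idx], params, n_sim)
      y <- comp$dv[idx]
      mu <- rowMeans(Yi)
      S <- stats::cov(t(Yi))
      L <- tryCatch(chol(S), error = function(e)
        chol(S + diag(1e-8 * max(diag(S)), nrow(S))))
      ystar <- forwardsolve(t(L), y - mu)
      sstar <- forwardsolve(t(L), Yi - mu)
      pde <- rowMeans(sstar < ystar)
      pde[pde == 0] <- 1 / (2 * n_sim)
      pde[pde == 1] <- 1 - 1 / (2 * n_sim)
      npde_v[idx] <- stats::qnorm(pde)
    }
  })
  n <- length(npde_v)
  mean_npde <- mean(npde_v)
  var_npde <- stats::var(npde_v)
  degenerate <- n < 3
  if (!degenerate) {
    se_mean <- stats::sd(npde_v) / sqrt(n)
    p_mean <- stats::t.test(npde_v)$p.value
    se_var <- var_npde * sqrt(2 / (n - 1))
    p_var <- 2 * stats::pnorm(-abs(var_npde - 1) / se_var)
  } else {
    se_mean <- p_mean <- se_var <- p_var <- NA_real_
    if (is.na(var_npde)) var_npde <- NA_real_
  }
  obs <- data[data$EVID == 0 & data$MDV == 0,
              c("ID", "TIME", "DV"), drop = FALSE]
  obs$npde <- npde_v
  out <- list(table = obs, mean = mean_npde, se_mean = se_mean,
              var = var_npde, se_var = se_var,
              p_mean = p_mean, p_var = p_var,
              n_sim = n_sim, degenerate = degenerate)
  class(out) <- "npde_result"
  out
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d simulations)\n",
              nrow(x$table), x$n_sim))
  if (x$degenerate) {
    cat("  too few observations: normality tests degenerate\n")
  } else {
    cat(sprintf("  mean %.3f (SE %.3f), p[mean=0] = %.3g\n",
                x$mean, x$se_mean, x$p_mean))
    cat(sprintf("  variance %.3f (SE %.3f), p[var=1] = %.3g\n",
                x$var, x$se_var, x$p_var))
  }
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Returns per-observation population predictions (random effects at zero),
#' individual predictions (at the empirical-Bayes estimates) and conditional
#' weighted residuals (CWRES) from a first-order-conditional linearisation:
#' the residual `y - (f(eta_hat) - J eta_hat)` decorrelated by
#' `J Omega J' + diag(sigma2 f(eta_hat)^2)`.
#'
#' @param data a `tdm_dataset`.
#' @param fit a converged `pk_fit` (its empirical-Bayes etas are used).
#' @return A data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`,
#'   plus an attribute `fallback` listing subjects where the model covariance
#'   was singular and plain standardised residuals were used.
#' @export
gof <- function(data, fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  data <- as_tdm(as.data.frame(data))
  comp <- .compile_tdm(data)
  p <- fit$params
  m <- .cov_multipliers(fit$structure, comp$X, p$thetas)
  clt <- p$clp * m$cl
  vt <- p$vp * m$v
  Omega <- diag(c(p$omega2_cl, p$omega2_v))
  pred <- ipred <- cwres <- numeric(comp$n_obs)
  fallback <- character(0)
  for (i in seq_len(comp$n_sub)) {
    idx <- (comp$obs_off[i] + 1L):comp$obs_off[i + 1L]
    kdx <- if (comp$dose_off[i] < comp$dose_off[i + 1L])
      (comp$dose_off[i] + 1L):comp$dose_off[i + 1L] else integer(0)
    eta <- fit$etas[i, ]
    pj0 <- pred_jac_cpp(comp$obs_t[idx], comp$d_st[kdx], comp$d_rt[kdx],
                        comp$d_du[kdx], clt[idx], vt[idx], 0, 0)
    pji <- pred_jac_cpp(comp$obs_t[idx], comp$d_st[kdx], comp$d_rt[kdx],
                        comp$d_du[kdx], clt[idx], vt[idx], eta[1], eta[2])
    pred[idx] <- pj0$f
    ipred[idx] <- pji$f
    y <- comp$dv[idx]
    J <- pji$J
    Ey <- pji$f - as.numeric(J %*% eta)
    V <- J %*% Omega %*% t(J) + diag(p$sigma2 * pmax(pji$f, 1e-6)^2,
                                     length(idx))
    cw <- tryCatch(forwardsolve(t(chol(V)), y - Ey), error = function(e) NULL)
    if (is.null(cw)) {
      fallback <- c(fallback, as.character(comp$ids[i]))
      cw <- (y - Ey) / sqrt(pmax(diag(V), 1e-12))
    }
    cwres[idx] <- cw
  }
  obs <- data[data$EVID == 0 & data$MDV == 0,
              c("ID", "TIME", "DV"), drop = FALSE]
  obs$PRED <- pred
  obs$IPRED <- ipred
  obs$CWRES <- cwres
  attr(obs, "fallback") <- fallback
  obs
}
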