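# Nonlinear mixed-effects estimation for the one-compartment infusion model.
# The marginal likelihood is approximated per subject by a Laplace
# approximation with an exact inner Newton optimisation over the two
# log-normal random effects (compiled kernel in src/laplace.cpp); the outer
# problem is solved by nlminb on a log/shifted-log transformed scale.

# ---- parameter encoding -----------------------------------------------------

.default_fix <- function() list()

.par_layout <- function(structure, fix) {
  est_idx <- .est_terms(structure)
  vc <- c("omega2_cl", "omega2_v", "sigma2")
  vc_est <- vc[!vc %in% names(fix)]
  list(est_idx = est_idx, vc_est = vc_est,
       n = 2L + length(est_idx) + length(vc_est))
}

.encode <- function(params, structure, fix) {
  lay <- .par_layout(structure, fix)
  th <- vapply(lay$est_idx, function(k) {
    tm <- structure$terms[[k]]
    if (tm$form == "cat") log1p(params$thetas[k]) else params$thetas[k]
  }, numeric(1))
  c(log(params$clp), log(params$vp), th,
    log(pmax(unlist(params[lay$vc_est]), 1e-8)))
}

.decode <- function(par, structure, fix) {
  lay <- .par_layout(structure, fix)
  nt <- length(lay$est_idx)
  thetas <- rep(NA_real_, length(structure$terms))
  if (nt) {
    raw <- par[2L + seq_len(nt)]
    for (j in seq_len(nt)) {
      tm <- structure$terms[[lay$est_idx[j]]]
      thetas[lay$est_idx[j]] <- if (tm$form == "cat") expm1(raw[j]) else raw[j]
    }
  }
  vc <- list(omega2_cl = 0, omega2_v = 0, sigma2 = 1e-8)
  for (nm in names(fix)) vc[[nm]] <- fix[[nm]]
  if (length(lay$vc_est)) {
    tail_par <- par[(2L + nt + 1L):length(par)]
    for (j in seq_along(lay$vc_est)) vc[[lay$vc_est[j]]] <- exp(tail_par[j])
  }
  list(clp = exp(par[1]), vp = exp(par[2]), thetas = thetas,
       omega2_cl = vc$omega2_cl, omega2_v = vc$omega2_v, sigma2 = vc$sigma2)
}

.pop_to_params <- function(pop, structure) {
  thetas <- rep(NA_real_, length(structure$terms))
  for (k in seq_along(structure$terms)) {
    tm <- structure$terms[[k]]
    if (tm$form == "prop") next
    if (tm$param == "v" && tm$cov == "CRRT" && tm$form == "cat")
      thetas[k] <- pop$theta_crrt
    else thetas[k] <- tm$value
  }
  list(clp = pop$clp, vp = pop$vp, thetas = thetas,
       omega2_cl = pop$omega2_cl, omega2_v = pop$omega2_v,
       sigma2 = pop$sigma2_prop)
}

# ---- objective --------------------------------------------------------------

.make_objective <- function(comp, structure, fix) {
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, comp$n_sub, 2)
  obj <- function(par) {
    p <- .decode(par, structure, fix)
    m <- .cov_multipliers(structure, comp$X, p$thetas)
    clt <- p$clp * m$cl
    vt <- p$vp * m$v
    if (any(!is.finite(clt)) || any(!is.finite(vt)) ||
        any(clt <= 0) || any(vt <= 0)) return(1e10)
    res <- ofv_laplace_cpp(comp$obs_t, comp$dv, comp$obs_off,
                           comp$d_st, comp$d_rt, comp$d_du, comp$dose_off,
                           clt, vt, p$omega2_cl, p$omega2_v, p$sigma2,
                           env$eta)
    if (!is.finite(res$ofv)) return(1e10)
    env$eta <- res$eta
    res$ofv
  }
  list(obj = obj, env = env)
}

#' Approximate -2 log-likelihood (objective function value)
#'
#' Evaluates the Laplace-approximated marginal -2 log-likelihood of a TDM
#' dataset under given population parameters: per subject the joint density
#' of data and random effects is maximised over `(eta_cl, eta_v)` by an exact
#' inner Newton search and corrected with the log-determinant of the numeric
#' Hessian at the mode. The residual-error variance is proportional,
#' `sigma2_prop * pred^2`, with predictions floored at 1e-6 mg/L.
#'
#' @param data a `tdm_dataset` (see [as_tdm()]).
#' @param pop a [population_parameters()] object.
#' @param structure a [model_structure()]; default the final covariate model.
#' @return The OFV (numeric scalar).
#' @export
ofv <- function(data, pop, structure = final_structure()) {
  stopifnot(inherits(pop, "pop_params"))
  comp <- .compile_tdm(as_tdm(as.data.frame(data)))
  params <- .pop_to_params(pop, structure)
  m <- .cov_multipliers(structure, comp$X, params$thetas)
  res <- ofv_laplace_cpp(comp$obs_t, comp$dv, comp$obs_off,
                         comp$d_st, comp$d_rt, comp$d_du, comp$dose_off,
                         params$clp * m$cl, params$vp * m$v,
                         params$omega2_cl, params$omega2_v, params$sigma2,
                         matrix(0, comp$n_sub, 2))
  res$ofv
}

# ---- fitting ----------------------------------------------------------------

.init_params <- function(comp, structure, fix) {
  medbw <- stats::median(comp$X[, "BW"])
  thetas <- rep(NA_real_, length(structure$terms))
  for (k in .est_terms(structure)) thetas[k] <- structure$terms[[k]]$value
  p <- list(clp = 0.1 * medbw, vp = 0.5 * medbw, thetas = thetas,
            omega2_cl = 0.1, omega2_v = 0.3, sigma2 = 0.05)
  for (nm in names(fix)) p[[sub("sigma2_prop", "sigma2", nm)]] <- fix[[nm]]
  p
}

#' Fit a population PK model by Laplace estimation
#'
#' Minimises the Laplace objective ([ofv()]) over the fixed effects, the
#' covariate coefficients of `structure`, the two IIV variances and the
#' proportional residual variance. Positivity is enforced by log transforms
#' (the categorical fractional shift via `log(1 + theta)`). By default the
#' optimisation is restarted from jittered versions of literature-magnitude
#' starting values (CL 0.1 L/h/kg, V 0.5 L/kg at the median body weight) and
#' the best objective wins.
#'
#' @param data a `tdm_dataset`.
#' @param structure a [model_structure()].
#' @param init optional initial values: a [population_parameters()] object or
#'   a named list with elements among `clp`, `vp`, `thetas`, `omega2_cl`,
#'   `omega2_v`, `sigma2`.
#' @param fix named list of variance components to fix, e.g.
#'   `list(omega2_v = 0)`.
#' @param restarts number of additional jittered starts (default 3).
#' @param compute_rse compute relative standard errors from the inverse
#'   numeric Hessian of the objective (default `TRUE`).
#' @param control passed to [stats::nlminb()].
#' @return An object of class `pk_fit`: estimates (`params`), `ofv`, `rse`
#'   (percent, delta method on the natural scale), empirical-Bayes `etas`,
#'   `converged`, `n_obs`, `n_sub`, the structure and the data.
#' @examples
#' pop <- final_model()
#' dat <- generate_tdm(generate_cohort(cohort_spec(seed = 1)),
#'                     design_spec(), pop, seed = 2)
#' f <- fit_model(dat, final_structure(), restarts = 0, compute_rse = FALSE)
#' coef(f)
#' @export
fit_model <- function(data, structure = final_structure(), init = NULL,
                      fix = .default_fix(), restarts = 3,
                      compute_rse = TRUE, control = list()) {
  data <- as_tdm(as.data.frame(data))
  comp <- .compile_tdm(data)
  iiv_identifiable <- TRUE
  if (comp$n_sub < 2) {
    est_vc <- setdiff(c("omega2_cl", "omega2_v"), names(fix))
    if (length(est_vc)) {
      warning("single-subject dataset: IIV variances are not identifiable; ",
              "fixing ", paste(est_vc, collapse = ", "), " to 0")
      for (nm in est_vc) fix[[nm]] <- 0
      iiv_identifiable <- FALSE
    }
  }
  p0 <- .init_params(comp, structure, fix)
  if (inherits(init, "pop_params")) init <- .pop_to_params(init, structure)
  if (!is.null(init)) for (nm in names(init)) p0[[nm]] <- init[[nm]]
  mk <- .make_objective(comp, structure, fix)
  lay <- .par_layout(structure, fix)
  ctl <- utils::modifyList(list(iter.max = 300, eval.max = 800,
                                rel.tol = 1e-8), control)
  starts <- list(.encode(p0, structure, fix))
  if (restarts > 0) {
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- starts[[1L]] + stats::rnorm(lay$n, 0, 0.3)
  }
  # cold evaluation (inner modes re-solved from zero) for fair comparison
  # across starts, uncontaminated by the warm-start path
  cold <- function(par) {
    mk2 <- .make_objective(comp, structure, fix)
    mk2$obj(par)
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(stats::nlminb(s, mk$obj, control = ctl,
                                  lower = -30, upper = 30),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    opt$cold <- cold(opt$par)
    if (is.null(best) || opt$cold < best$cold) best <- opt
  }
  if (is.null(best)) {
    warning("all optimisation starts failed")
    out <- list(converged = FALSE, ofv = NA_real_,
                diagnostics = "all starts failed")
    class(out) <- "pk_fit"
    return(out)
  }
  params <- .decode(best$par, structure, fix)
  mk <- .make_objective(comp, structure, fix) # fresh inner state
  ofv_final <- mk$obj(best$par)
  etas <- mk$env$eta
  rownames(etas) <- comp$ids
  # nlminb's "false convergence" usually just means the line search stalled
  # at the optimum at this tolerance; treat relative/false convergence as
  # converged, anything else (iteration limit, singular convergence, ...) not
  ok_msg <- grepl("relative convergence|false convergence|X-convergence",
                  best$message %||% "")
  converged <- is.finite(ofv_final) && (best$convergence == 0 || ok_msg)
  if (!converged)
    warning("optimiser did not report convergence: ", best$message)
  rse <- se <- NULL
  if (compute_rse) {
    H <- tryCatch(stats::optimHess(best$par, mk$obj), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve(H), error = function(e) NULL) # ofv = -2 logLik
      if (!is.null(V) && all(diag(V) > 0)) {
        se_t <- sqrt(diag(V))
        nat <- .natural_vector(params, structure, fix)
        # log-scale params: RSE(natural) = 100 * se(log); cat term via delta
        rse <- 100 * se_t * .delta_scale(best$par, structure, fix) /
          abs(nat)
        names(rse) <- names(nat)
      }
    }
    if (is.null(rse)) warning("standard errors unavailable (singular Hessian)")
  }
  out <- list(params = params, structure = structure, fix = fix,
              ofv = ofv_final, etas = etas, rse = rse,
              converged = converged, iiv_identifiable = iiv_identifiable,
              n_obs = comp$n_obs, n_sub = comp$n_sub,
              par = best$par, data = data)
  class(out) <- "pk_fit"
  out
}

# natural-scale parameter vector aligned with the encoded vector
.natural_vector <- function(params, structure, fix) {
  lay <- .par_layout(structure, fix)
  th <- vapply(lay$est_idx, function(k) params$thetas[k], numeric(1))
  nm_th <- vapply(lay$est_idx, function(k) {
    tm <- structure$terms[[k]]
    sprintf("theta_%s_%s", tm$cov, tm$param)
  }, character(1))
  vc <- if (length(lay$vc_est))
    stats::setNames(unlist(params[lay$vc_est]), lay$vc_est)
  else numeric(0)
  c(clp = params$clp, vp = params$vp, stats::setNames(th, nm_th), vc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# d(natural)/d(transformed) for the delta method
.delta_scale <- function(par, structure, fix) {
  lay <- .par_layout(structure, fix)
  p <- .decode(par, structure, fix)
  th_sc <- vapply(lay$est_idx, function(k) {
    tm <- structure$terms[[k]]
    if (tm$form == "cat") 1 + p$thetas[k] else 1
  }, numeric(1))
  c(p$clp, p$vp, th_sc, unlist(p[lay$vc_est]))
}

#' @export
print.pk_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.na(x$ofv)) {
    cat("pk_fit: estimation failed\n"); return(invisible(x))
  }
  cat(sprintf("Population PK fit ('%s' structure), %d subjects / %d observations\n",
              x$structure$label, x$n_sub, x$n_obs))
  cat(sprintf("  OFV: %.3f   converged: %s\n", x$ofv, x$converged))
  est <- .natural_vector(x$params, x$structure, x$fix)
  for (i in seq_along(est)) {
    r <- if (!is.null(x$rse)) sprintf(" (RSE %.0f%%)", x$rse[i]) else ""
    cat(sprintf("  %-14s %.4g%s\n", names(est)[i], est[i], r))
  }
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  .natural_vector(object$params, object$structure, object$fix)
}

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par), class = "logLik")
}

#' Convert a fitted final-structure model to population parameters
#'
#' @param fit a `pk_fit` from [fit_model()] with the [final_structure()]
#'   (or base structure; missing terms default to 0).
#' @return A [population_parameters()] object.
#' @export
as_population_parameters <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  th <- 0; bw_ref <- 7.88
  for (k in seq_along(fit$structure$terms)) {
    tm <- fit$structure$terms[[k]]
    if (tm$form == "prop" && tm$cov == "BW") bw_ref <- tm$ref
    if (tm$param == "v" && tm$cov == "CRRT" && tm$form == "cat")
      th <- fit$params$thetas[k]
  }
  population_parameters(unname(fit$params$clp), unname(fit$params$vp),
                        unname(th), unname(fit$params$omega2_cl),
                        unname(fit$params$omega2_v),
                        unname(fit$params$sigma2), bw_ref)
}
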