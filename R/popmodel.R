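#' Population PK parameters of the final meropenem model
#'
#' Container for the fixed effects, variance components and reference body
#' weight of the one-compartment meropenem model:
#' \deqn{CL = CL_p (BW/BW_{ref}) e^{\eta_{CL}}, \quad
#'       V  = V_p (BW/BW_{ref}) (1+\theta_{CRRT})^{CRRT} e^{\eta_V}}
#' with log-normal inter-individual variability (variances `omega2_cl`,
#' `omega2_v`) and a proportional residual error with variance `sigma2_prop`.
#'
#' @param clp population clearance (L/h) at the reference body weight.
#' @param vp population volume of distribution (L) at the reference body
#'   weight, off CRRT.
#' @param theta_crrt fractional increase in V when CRRT is running
#'   (dimensionless, > -1); the CRRT multiplier is `(1 + theta_crrt)`.
#' @param omega2_cl,omega2_v log-scale variances of the subject-level random
#'   effects on CL and V.
#' @param sigma2_prop variance of the proportional residual error.
#' @param bw_ref reference body weight (kg) the fixed effects are anchored to.
#' @return An object of class `pop_params`.
#' @seealso [final_model()] for the packaged published estimates.
#' @examples
#' p <- population_parameters(1.09, 3.98, 1.04, 0.0887, 0.916, 0.17)
#' p
#' @export
population_parameters <- function(clp, vp, theta_crrt = 0,
                                  omega2_cl = 0, omega2_v = 0,
                                  sigma2_prop = 0, bw_ref = 7.88) {
  stopifnot(is.numeric(clp), is.numeric(vp), is.numeric(theta_crrt),
            length(clp) == 1L, length(vp) == 1L, length(theta_crrt) == 1L)
  if (!is.finite(clp) || clp <= 0) stop("clp must be a positive number")
  if (!is.finite(vp) || vp <= 0) stop("vp must be a positive number")
  if (!is.finite(theta_crrt) || theta_crrt <= -1)
    stop("theta_crrt must be > -1")
  for (nm in c("omega2_cl", "omega2_v", "sigma2_prop")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(nm, " must be a non-negative number")
  }
  if (!is.finite(bw_ref) || bw_ref <= 0) stop("bw_ref must be positive")
  structure(list(clp = clp, vp = vp, theta_crrt = theta_crrt,
                 omega2_cl = omega2_cl, omega2_v = omega2_v,
                 sigma2_prop = sigma2_prop, bw_ref = bw_ref),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (one-compartment, BW-scaled)\n")
  cat(sprintf("  CL = %.4g L/h x (BW/%.4g)\n", x$clp, x$bw_ref))
  cat(sprintf("  V  = %.4g L   x (BW/%.4g) x (1 + %.4g)^CRRT\n",
              x$vp, x$bw_ref, x$theta_crrt))
  cat(sprintf("  IIV variances: CL %.4g, V %.4g (log scale)\n",
              x$omega2_cl, x$omega2_v))
  cat(sprintf("  Proportional residual variance: %.4g\n", x$sigma2_prop))
  invisible(x)
}

#' Subject-level covariates
#'
#' @param bw body weight in kg.
#' @param crrt_on 0/1 flag: is CRRT running.
#' @param extras optional named list of additional covariates (postnatal age,
#'   creatinine clearance, severity scores, ...) used by covariate search and
#'   the synthetic-data generator only.
#' @return An object of class `subject_covariates`.
#' @export
subject_covariates <- function(bw, crrt_on = 0, extras = list()) {
  if (!is.numeric(bw) || length(bw) != 1L || !is.finite(bw) || bw <= 0)
    stop("bw must be a positive number")
  if (!crrt_on %in% c(0, 1)) stop("crrt_on must be 0 or 1")
  if (length(extras) && !all(vapply(extras, function(v)
        all(is.finite(unlist(v))), logical(1))))
    stop("extras values must be finite")
  structure(list(bw = bw, crrt_on = as.numeric(crrt_on), extras = extras),
            class = "subject_covariates")
}

#' Realise individual PK parameters from the covariate model
#'
#' Applies the body-weight scaling, the CRRT volume shift and the log-normal
#' random effects:
#' `cl = clp * (bw/bw_ref) * exp(eta_cl)`,
#' `v = vp * (bw/bw_ref) * (1 + theta_crrt)^crrt_on * exp(eta_v)`.
#'
#' @param pop a [population_parameters()] object.
#' @param cov a [subject_covariates()] object.
#' @param eta_cl,eta_v subject-level random effects (log scale).
#' @return An object of class `ind_params` with elements `cl` (L/h), `v` (L)
#'   and the derived elimination rate constant `ke = cl/v` (1/h).
#' @examples
#' pop <- final_model()
#' individual_params(pop, subject_covariates(bw = 7.88, crrt_on = 0))
#' @export
individual_params <- function(pop, cov, eta_cl = 0, eta_v = 0) {
  stopifnot(inherits(pop, "pop_params"), inherits(cov, "subject_covariates"))
  if (!is.finite(eta_cl) || !is.finite(eta_v))
    stop("eta_cl and eta_v must be finite")
  cl <- pop$clp * (cov$bw / pop$bw_ref) * exp(eta_cl)
  v  <- pop$vp * (cov$bw / pop$bw_ref) *
    (1 + pop$theta_crrt)^cov$crrt_on * exp(eta_v)
  structure(list(cl = cl, v = v, ke = cl / v), class = "ind_params")
}

#' @export
print.ind_params <- function(x, ...) {
  cat(sprintf("Individual PK parameters: CL = %.4g L/h, V = %.4g L, ke = %.4g 1/h\n",
              x$cl, x$v, x$ke))
  invisible(x)
}

#' Published final-model estimates
#'
#' Loads the packaged estimates of the final covariate model (fixed effects,
#' IIV variances, proportional residual variance, reference body weight) from
#' a structured text fixture, together with their relative standard errors
#' and bootstrap intervals as attributes.
#'
#' @param path path to a YAML model file; defaults to the packaged fixture.
#' @return A [population_parameters()] object with attributes `rse` and
#'   `bootstrap_ci`.
#' @examples
#' final_model()
#' @export
final_model <- function(path = system.file("extdata", "final_model.yaml",
                                           package = "neoperem")) {
  if (!nzchar(path) || !file.exists(path)) stop("model file not found: ", path)
  y <- yaml::read_yaml(path)
  p <- population_parameters(clp = y$clp, vp = y$vp,
                             theta_crrt = y$theta_crrt,
                             omega2_cl = y$omega2_cl, omega2_v = y$omega2_v,
                             sigma2_prop = y$sigma2_prop, bw_ref = y$bw_ref)
  attr(p, "rse") <- unlist(y$rse_percent)
  attr(p, "bootstrap_ci") <- y$bootstrap_ci
  p
}
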