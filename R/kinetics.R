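#' Infusion dose event
#'
#' @param start start of the infusion, hours since first dose.
#' @param rate infusion rate, mg/h.
#' @param duration infusion duration, h. The administered amount is
#'   `rate * duration` mg.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(start, rate, duration) {
  if (!is.finite(start) || start < 0) stop("start must be >= 0")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(rate * duration)) stop("dose amount must be finite")
  structure(list(start = start, rate = rate, duration = duration),
            class = "dose_event")
}

#' Dosing regimen
#'
#' An ordered collection of infusion events. Events must be sorted by start
#' time; an empty regimen (no drug) is allowed.
#'
#' @param events list of [dose_event()] objects.
#' @param label text label for tables.
#' @return An object of class `regimen`.
#' @seealso [build_regimen()] for the standard study regimens.
#' @export
regimen <- function(events = list(), label = "") {
  stopifnot(is.list(events))
  for (e in events) if (!inherits(e, "dose_event"))
    stop("all events must be dose_event objects")
  starts <- vapply(events, `[[`, numeric(1), "start")
  if (is.unsorted(starts)) stop("events must be sorted by start time")
  structure(list(events = events, label = label), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen '%s': %d infusion event(s)\n", x$label,
              length(x$events)))
  if (length(x$events)) {
    e1 <- x$events[[1]]
    cat(sprintf("  first: start %.2f h, %.4g mg/h for %.2f h (%.4g mg)\n",
                e1$start, e1$rate, e1$duration, e1$rate * e1$duration))
  }
  invisible(x)
}

.regimen_arrays <- function(reg) {
  list(st = vapply(reg$events, `[[`, numeric(1), "start"),
       rt = vapply(reg$events, `[[`, numeric(1), "rate"),
       du = vapply(reg$events, `[[`, numeric(1), "duration"))
}

#' Concentration at given times
#'
#' Closed-form one-compartment solution with zero-order input, superposed
#' over all infusion events of the regimen: while an event is running
#' (elapsed time `tau <= duration`) it contributes
#' `(rate/cl) (1 - exp(-ke tau))`; afterwards the accumulated amount washes
#' out as `(rate/cl) (1 - exp(-ke duration)) exp(-ke (tau - duration))`.
#'
#' @param ind an `ind_params` object from [individual_params()].
#' @param reg a [regimen()].
#' @param t time(s) in hours since first dose; must be >= 0.
#' @return Numeric vector of concentrations (mg/L), same length as `t`.
#' @examples
#' pop <- final_model()
#' ind <- individual_params(pop, subject_covariates(7.88))
#' reg <- build_regimen("continuous", 120, bw = 7.88, horizon = 168)
#' conc_at(ind, reg, c(1, 24, 168))
#' @export
conc_at <- function(ind, reg, t) {
  stopifnot(inherits(ind, "ind_params"), inherits(reg, "regimen"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  if (!length(reg$events)) return(rep(0, length(t)))
  a <- .regimen_arrays(reg)
  conc_cpp(as.numeric(t), a$st, a$rt, a$du, ind$cl, ind$v)
}

#' Concentration-time profile on a grid
#'
#' @param ind an `ind_params` object.
#' @param reg a [regimen()].
#' @param grid strictly increasing time grid (h).
#' @return An object of class `conc_profile`: list with `time` and `conc`.
#' @export
conc_profile <- function(ind, reg, grid) {
  if (!is.numeric(grid) || length(grid) < 1L)
    stop("grid must contain at least one time point")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  structure(list(time = as.numeric(grid), conc = conc_at(ind, reg, grid)),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d points, %.2f-%.2f h, max %.4g mg/L\n",
              length(x$time), min(x$time), max(x$time), max(x$conc)))
  invisible(x)
}

#' Fraction of time above MIC
#'
#' Computes fT>MIC on the discrete grid of the profile: the fraction of grid
#' points with concentration strictly above the MIC. On an evenly spaced
#' grid this is the grid approximation of the fraction of the window spent
#' above the MIC.
#'
#' @param profile a [conc_profile()] (or anything with `$conc`), or a bare
#'   numeric vector of concentrations.
#' @param mic minimum inhibitory concentration, mg/L (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
ft_above_mic <- function(profile, mic) {
  if (!is.numeric(mic) || length(mic) != 1L || !is.finite(mic) || mic <= 0)
    stop("mic must be a positive number")
  conc <- if (is.numeric(profile)) profile else profile$conc
  if (!length(conc)) stop("profile must be non-empty")
  mean(conc > mic)
}

#' Build a standard study regimen
#'
#' Constructs the dosing schedules evaluated in the dosing simulations:
#' q8h short (0.5 h) infusions, q8h prolonged (3 h) infusions, or a
#' continuous infusion. Doses are specified per kg and converted to mg with
#' the subject's body weight; for the continuous kind `dose_per_kg` is the
#' daily dose (mg/kg/day), for the q8h kinds the per-dose amount (mg/kg).
#'
#' @param kind one of `"short_q8h"`, `"prolonged_q8h"`, `"continuous"`.
#' @param dose_per_kg dose in mg/kg (q8h) or mg/kg/day (continuous).
#' @param bw body weight, kg.
#' @param horizon treatment horizon, h.
#' @param label optional label; a descriptive default is built from the
#'   arguments.
#' @return A [regimen()].
#' @examples
#' build_regimen("continuous", 120, bw = 7.88, horizon = 168)
#' @export
build_regimen <- function(kind = c("short_q8h", "prolonged_q8h", "continuous"),
                          dose_per_kg, bw, horizon = 168, label = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(dose_per_kg) || dose_per_kg <= 0)
    stop("dose_per_kg must be > 0")
  if (!is.finite(bw) || bw <= 0) stop("bw must be > 0")
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (kind == "continuous") {
    rate <- dose_per_kg * bw / 24
    events <- list(dose_event(0, rate, horizon))
    if (is.null(label)) label <- sprintf("%g mg/kg/day cont.", dose_per_kg)
  } else {
    dur <- if (kind == "short_q8h") 0.5 else 3
    amt <- dose_per_kg * bw
    starts <- seq(0, horizon - 1e-9, by = 8)
    events <- lapply(starts, function(s) dose_event(s, amt / dur, dur))
    if (is.null(label))
      label <- sprintf("%g mg/kg %s q8h", dose_per_kg,
                       if (kind == "short_q8h") "0.5 h" else "3 h")
  }
  regimen(events, label)
}
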