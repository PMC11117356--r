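#' Monte Carlo simulation settings
#'
#' @param n_subjects number of simulated subjects per probability-of-target-
#'   attainment (PTA) cell.
#' @param bw simulated body weight, kg.
#' @param crrt_on 0/1: simulate the population on CRRT.
#' @param horizon simulated treatment duration, h (default 7 days).
#' @param eval_window two-element window (h) over which fT>MIC is evaluated;
#'   the default is the final 24 h, i.e. steady state.
#' @param grid_dt spacing of the evaluation grid, h.
#' @param include_ruv apply the proportional residual error to every simulated
#'   grid concentration before computing fT>MIC (default `TRUE`).
#' @param seed integer seed; all draws of a [pta()] call derive from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 10000, bw = 7.88, crrt_on = 0,
                              horizon = 168, eval_window = c(144, 168),
                              grid_dt = 1, include_ruv = TRUE, seed = 1L) {
  stopifnot(n_subjects >= 1, length(eval_window) == 2L)
  if (!crrt_on %in% c(0, 1)) stop("crrt_on must be 0 or 1")
  if (eval_window[1] < 0 || eval_window[2] > horizon ||
      eval_window[1] >= eval_window[2])
    stop("eval_window must be increasing and within [0, horizon]")
  if (grid_dt <= 0) stop("grid_dt must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), bw = bw,
                 crrt_on = as.numeric(crrt_on), horizon = horizon,
                 eval_window = eval_window, grid_dt = grid_dt,
                 include_ruv = isTRUE(include_ruv), seed = as.integer(seed)),
            class = "sim_config")
}

# run code with a local RNG state derived from `seed`
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

.draw_etas <- function(pop, cfg) {
  n <- cfg$n_subjects
  list(eta_cl = rnorm(n, 0, sqrt(pop$omega2_cl)),
       eta_v  = rnorm(n, 0, sqrt(pop$omega2_v)))
}

#' Sample a simulated population of individual PK parameters
#'
#' Draws `n_subjects` pairs of independent log-normal random effects and
#' realises CL and V for the configured body weight and CRRT status.
#' Reproducible for a fixed `cfg$seed`.
#'
#' @param pop a [population_parameters()] object.
#' @param cfg a [simulation_config()].
#' @return A data.frame with columns `cl`, `v`, `ke`, `eta_cl`, `eta_v`.
#' @export
sample_population <- function(pop, cfg) {
  stopifnot(inherits(pop, "pop_params"), inherits(cfg, "sim_config"))
  cov <- subject_covariates(cfg$bw, cfg$crrt_on)
  .with_seed(cfg$seed, {
    et <- .draw_etas(pop, cfg)
    cl <- pop$clp * (cfg$bw / pop$bw_ref) * exp(et$eta_cl)
    v  <- pop$vp * (cfg$bw / pop$bw_ref) *
      (1 + pop$theta_crrt)^cfg$crrt_on * exp(et$eta_v)
    data.frame(cl = cl, v = v, ke = cl / v,
               eta_cl = et$eta_cl, eta_v = et$eta_v)
  })
}

# population concentration matrix (n_subjects x n_grid) for one regimen
.conc_matrix <- function(reg, cl, v, grid) {
  n <- length(cl)
  ke <- cl / v
  C <- matrix(0, n, length(grid))
  for (e in reg$events) {
    tau <- grid - e$start
    t1 <- pmin(pmax(tau, 0), e$duration)
    t2 <- pmax(tau - e$duration, 0)
    C <- C + (e$rate / cl) * (1 - exp(-outer(ke, t1))) * exp(-outer(ke, t2))
  }
  C
}

#' Probability of target attainment by Monte Carlo simulation
#'
#' For each regimen, simulates steady-state concentration-time profiles for
#' `cfg$n_subjects` subjects on an evenly spaced grid over the evaluation
#' window, optionally perturbs every grid concentration with the proportional
#' residual error, computes the fraction of grid points strictly above each
#' MIC, and reports the percentage of subjects whose fraction reaches each
#' target.
#'
#' All regimens share one set of random-effect and residual draws (common
#' random numbers), so PTA is exactly non-increasing in MIC and comparable
#' across regimens at a fixed seed.
#'
#' @param pop a [population_parameters()] object.
#' @param regimens a [regimen()] or a list of regimens.
#' @param mic_grid positive, strictly ascending MIC values (mg/L).
#' @param targets fT>MIC targets as fractions (default 40\% and 100\%).
#' @param cfg a [simulation_config()].
#' @return A data.frame of class `pta_result` with columns `regimen`, `crrt`,
#'   `mic`, `target`, `pta` (percent), `n`, `seed`.
#' @examples
#' pop <- final_model()
#' cfg <- simulation_config(n_subjects = 500, seed = 7)
#' reg <- build_regimen("continuous", 120, bw = cfg$bw)
#' pta(pop, reg, mic_grid = c(2, 8), cfg = cfg)
#' @export
pta <- function(pop, regimens, mic_grid = c(0.5, 1, 2, 4, 8, 16),
                targets = c(0.40, 1.00), cfg = simulation_config()) {
  stopifnot(inherits(pop, "pop_params"), inherits(cfg, "sim_config"))
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  if (!length(regimens)) stop("regimen set must be non-empty")
  for (r in regimens) if (!inherits(r, "regimen"))
    stop("regimens must be regimen objects")
  if (any(mic_grid <= 0) || is.unsorted(mic_grid, strictly = TRUE))
    stop("mic_grid must be positive and strictly ascending")
  if (any(targets <= 0 | targets > 1)) stop("targets must be in (0, 1]")
  grid <- seq(cfg$eval_window[1], cfg$eval_window[2], by = cfg$grid_dt)
  out <- .with_seed(cfg$seed, {
    et <- .draw_etas(pop, cfg)
    cl <- pop$clp * (cfg$bw / pop$bw_ref) * exp(et$eta_cl)
    v  <- pop$vp * (cfg$bw / pop$bw_ref) *
      (1 + pop$theta_crrt)^cfg$crrt_on * exp(et$eta_v)
    eps <- if (cfg$include_ruv)
      matrix(rnorm(cfg$n_subjects * length(grid), 0, sqrt(pop$sigma2_prop)),
             cfg$n_subjects)
    else NULL
    rows <- list()
    for (r in regimens) {
      C <- .conc_matrix(r, cl, v, grid)
      if (!is.null(eps)) C <- C * (1 + eps)
      for (target in targets) for (mic in mic_grid) {
        ft <- rowMeans(C > mic)
        rows[[length(rows) + 1L]] <- data.frame(
          regimen = r$label, crrt = cfg$crrt_on, mic = mic,
          target = target, pta = 100 * mean(ft >= target - 1e-9),
          n = cfg$n_subjects, seed = cfg$seed)
      }
    }
    do.call(rbind, rows)
  })
  class(out) <- c("pta_result", "data.frame")
  out
}

#' Lay a PTA result out as a published-style wide table
#'
#' Rows are MICs, columns regimen-by-CRRT combinations, one block per target,
#' with PTA rounded to whole percent. All factorial cells must be present.
#'
#' @param results a `pta_result` data.frame (rows for both CRRT settings can
#'   be concatenated with `rbind`).
#' @param file optional path; when given, the blocks are written as CSV.
#' @param digits digits for rounding (default 0, as printed).
#' @return A named list of matrices, one per target, invisibly when `file`
#'   is given.
#' @export
pta_table <- function(results, file = NULL, digits = 0) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  mics <- sort(unique(results$mic))
  regs <- unique(results$regimen)
  crrts <- sort(unique(results$crrt))
  targets <- sort(unique(results$target))
  blocks <- list()
  for (tg in targets) {
    m <- matrix(NA_real_, length(mics), length(regs) * length(crrts))
    colnames(m) <- as.vector(t(outer(regs, crrts, function(r, cr)
      sprintf("%s | CRRT=%g", r, cr))))
    rownames(m) <- as.character(mics)
    sub <- results[abs(results$target - tg) < 1e-9, ]
    for (k in seq_len(nrow(sub))) {
      i <- match(sub$mic[k], mics)
      j <- match(sprintf("%s | CRRT=%g", sub$regimen[k], sub$crrt[k]),
                 colnames(m))
      m[i, j] <- round(sub$pta[k], digits)
    }
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing PTA cell: MIC %s, column '%s', target %g",
                   rownames(m)[idx[1]], colnames(m)[idx[2]], tg))
    }
    blocks[[sprintf("%g%% fT>MIC", 100 * tg)]] <- m
  }
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    for (nm in names(blocks)) {
      writeLines(sprintf("Probability of target attainment for %s", nm), con)
      writeLines(paste(c("MIC", colnames(blocks[[nm]])), collapse = ","), con)
      b <- blocks[[nm]]
      for (i in seq_len(nrow(b)))
        writeLines(paste(c(rownames(b)[i], b[i, ]), collapse = ","), con)
    }
    return(invisible(blocks))
  }
  blocks
}
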