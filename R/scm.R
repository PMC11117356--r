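#' Stepwise covariate modeling configuration
#'
#' @param candidates named character vector mapping covariate column names to
#'   their type, `"continuous"` or `"categorical"`. Continuous candidates are
#'   tried in linear and power forms; categorical ones as a fractional shift.
#' @param params parameters the candidates may enter (default CL and V).
#' @param threshold objective-function drop required for inclusion
#'   (default 3.84, the 5\% point of chi-square with 1 df).
#' @return An object of class `scm_config`.
#' @export
scm_config <- function(candidates = c(BW = "continuous", PNA = "continuous",
                                      CRRT = "categorical"),
                       params = c("cl", "v"), threshold = 3.84) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric")
  if (threshold <= 0) stop("threshold must be > 0")
  if (!all(candidates %in% c("continuous", "categorical")))
    stop("candidate types must be 'continuous' or 'categorical'")
  structure(list(candidates = candidates, params = params,
                 threshold = threshold), class = "scm_config")
}

#' Forward stepwise covariate selection
#'
#' Starting from `base`, every remaining covariate-parameter-form combination
#' is added in turn and refitted; the combination with the largest drop in
#' OFV is included if the drop exceeds `config$threshold`, and the search
#' repeats until no candidate qualifies. Once a covariate is included on a
#' parameter (in its best form), its other forms are retired for that
#' parameter. Constant covariates are skipped with a warning. Refits are
#' warm-started from the current model's estimates.
#'
#' @param data a `tdm_dataset`.
#' @param base the starting [model_structure()].
#' @param config an [scm_config()].
#' @param restarts jittered restarts per candidate fit (default 0; the warm
#'   start from the current model is usually sufficient for one added term).
#' @return A list of class `scm_result`: final `structure`, final `fit`, and
#'   a `log` data.frame with one row per tested candidate
#'   (step, covariate, parameter, form, ofv, delta_ofv, selected).
#' @export
scm <- function(data, base = base_structure(), config = scm_config(),
                restarts = 0) {
  data <- as_tdm(as.data.frame(data))
  cols <- toupper(names(data))
  cand <- config$candidates
  names(cand) <- toupper(names(cand))
  drop_c <- character(0)
  for (nm in names(cand)) {
    if (!nm %in% cols) {
      warning("candidate ", nm, " not in dataset; skipped")
      drop_c <- c(drop_c, nm)
    } else {
      x <- data[[match(nm, cols)]][data$EVID == 0]
      if (stats::sd(x) == 0 || !all(is.finite(x))) {
        warning("candidate ", nm, " is constant or non-finite; skipped")
        drop_c <- c(drop_c, nm)
      }
    }
  }
  cand <- cand[setdiff(names(cand), drop_c)]
  # candidate pool: one row per covariate x parameter x form
  pool <- do.call(rbind, lapply(names(cand), function(nm) {
    forms <- if (cand[[nm]] == "categorical") "cat" else c("lin", "pow")
    expand.grid(cov = nm, param = config$params, form = forms,
                stringsAsFactors = FALSE)
  }))
  if (is.null(pool))
    pool <- data.frame(cov = character(), param = character(),
                       form = character())
  # drop combinations already in the base structure
  in_base <- vapply(seq_len(nrow(pool)), function(i)
    any(vapply(base$terms, function(tm)
      tm$cov == pool$cov[i] && tm$param == pool$param[i], logical(1))),
    logical(1))
  pool <- pool[!in_base, , drop = FALSE]
  current <- base
  cur_fit <- fit_model(data, current, restarts = max(restarts, 1),
                       compute_rse = FALSE)
  log_rows <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (!nrow(pool) || is.infinite(config$threshold)) break
    best <- NULL
    for (i in seq_len(nrow(pool))) {
      ref <- stats::median(data[[match(pool$cov[i], cols)]][data$EVID == 0])
      tm <- covariate_term(pool$param[i], pool$cov[i], pool$form[i],
                           ref = ref, value = 0.1)
      cand_str <- model_structure(c(current$terms, list(tm)),
                                  label = sprintf("%s+%s~%s", current$label,
                                                  pool$param[i], pool$cov[i]))
      # candidate fits start from fresh literature values rather than the
      # current model's estimates: warm starts are regularly trapped when a
      # covariate effect is already absorbed into an inflated IIV variance
      f <- suppressWarnings(
        fit_model(data, cand_str, restarts = restarts, compute_rse = FALSE,
                  control = list(rel.tol = 1e-7, eval.max = 350)))
      d_ofv <- cur_fit$ofv - f$ofv
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, cov = pool$cov[i], param = pool$param[i],
        form = pool$form[i], ofv = f$ofv, delta_ofv = d_ofv,
        converged = isTRUE(f$converged), selected = FALSE)
      if (is.finite(d_ofv) && isTRUE(f$converged) &&
          (is.null(best) || d_ofv > best$d_ofv))
        best <- list(i = i, d_ofv = d_ofv, fit = f, structure = cand_str)
    }
    if (is.null(best) || best$d_ofv <= config$threshold) break
    sel_row <- length(log_rows) - nrow(pool) + best$i
    log_rows[[sel_row]]$selected <- TRUE
    current <- best$structure
    cur_fit <- best$fit
    pool <- pool[!(pool$cov == pool$cov[best$i] &
                     pool$param == pool$param[best$i]), , drop = FALSE]
  }
  out <- list(structure = current, fit = cur_fit,
              log = do.call(rbind, log_rows))
  class(out) <- "scm_result"
  out
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate modeling result\n")
  print(x$structure)
  if (!is.null(x$log)) {
    sel <- x$log[x$log$selected, , drop = FALSE]
    cat(sprintf("  steps taken: %d, candidates tested: %d\n",
                nrow(sel), nrow(x$log)))
  }
  invisible(x)
}
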