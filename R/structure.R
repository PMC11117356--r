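#' Covariate term of a model structure
#'
#' Functional forms, with `x` the covariate and `r` its reference value:
#' \describe{
#'   \item{`prop`}{fixed proportional scaling `x/r` (no estimated
#'     coefficient), the body-weight normalisation of the final model;}
#'   \item{`lin`}{linear, `1 + theta (x/r - 1)`;}
#'   \item{`pow`}{power, `(x/r)^theta`;}
#'   \item{`cat`}{fractional shift for a 0/1 covariate, `(1 + theta)^x`.}
#' }
#'
#' @param param `"cl"` or `"v"`: which parameter the term multiplies.
#' @param cov covariate column name (matched case-insensitively against the
#'   dataset columns).
#' @param form one of `"prop"`, `"lin"`, `"pow"`, `"cat"`.
#' @param ref reference value (ignored for `cat`).
#' @param value coefficient value; fixed for `form = "prop"` (unused),
#'   estimated otherwise (this is the initial/current value).
#' @return An object of class `cov_term`.
#' @export
covariate_term <- function(param = c("cl", "v"), cov,
                           form = c("prop", "lin", "pow", "cat"),
                           ref = NA_real_, value = 0.1) {
  param <- match.arg(param)
  form <- match.arg(form)
  if (form != "cat" && form != "prop" && !is.finite(ref))
    stop("continuous forms need a finite reference value")
  structure(list(param = param, cov = toupper(cov), form = form,
                 ref = ref, value = value),
            class = "cov_term")
}

#' Model structure: which covariate terms enter CL and V
#'
#' @param terms list of [covariate_term()] objects.
#' @param label text label.
#' @return An object of class `model_structure`.
#' @export
model_structure <- function(terms = list(), label = "custom") {
  for (tm in terms) if (!inherits(tm, "cov_term"))
    stop("terms must be covariate_term objects")
  structure(list(terms = terms, label = label), class = "model_structure")
}

#' Structural base model (no covariates)
#' @return A [model_structure()] with no covariate terms.
#' @export
base_structure <- function() model_structure(list(), "base")

#' Final covariate structure
#'
#' Body weight enters proportionally (reference `bw_ref`) on both CL and V;
#' CRRT shifts V by an estimated fraction.
#'
#' @param bw_ref reference body weight, kg.
#' @return A [model_structure()].
#' @export
final_structure <- function(bw_ref = 7.88) {
  model_structure(list(
    covariate_term("cl", "BW", "prop", ref = bw_ref),
    covariate_term("v", "BW", "prop", ref = bw_ref),
    covariate_term("v", "CRRT", "cat", value = 1.04)
  ), "final")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("Model structure '%s': %d covariate term(s)\n", x$label,
              length(x$terms)))
  for (tm in x$terms)
    cat(sprintf("  %s ~ %s (%s%s)\n", toupper(tm$param), tm$cov, tm$form,
                if (tm$form == "prop") "" else sprintf(", theta=%.3g", tm$value)))
  invisible(x)
}

# indices of estimated coefficients among the terms
.est_terms <- function(structure) {
  which(vapply(structure$terms, function(tm) tm$form != "prop", logical(1)))
}

# multiplier vectors for CL and V over all observation rows.
# X: covariate matrix from .compile_tdm (one row per observation);
# thetas: coefficient values aligned with structure$terms (prop entries ignored)
.cov_multipliers <- function(structure, X, thetas) {
  n <- nrow(X)
  m <- list(cl = rep(1, n), v = rep(1, n))
  for (k in seq_along(structure$terms)) {
    tm <- structure$terms[[k]]
    x <- X[, tm$cov]
    f <- switch(tm$form,
      prop = x / tm$ref,
      lin  = 1 + thetas[k] * (x / tm$ref - 1),
      pow  = (x / tm$ref)^thetas[k],
      cat  = (1 + thetas[k])^x)
    m[[tm$param]] <- m[[tm$param]] * f
  }
  m
}
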