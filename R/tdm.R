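#' Validate and classify a NONMEM-style TDM dataset
#'
#' The dataset dialect follows NONMEM conventions: one row per event, columns
#' `ID`, `TIME` (h), `AMT` (mg, dose rows), `RATE` (mg/h, dose rows), `DV`
#' (observed concentration mg/L, observation rows), `EVID` (1 = dose,
#' 0 = observation), `MDV` (1 = DV missing), plus covariate columns `BW` and
#' `CRRT` (time-varying allowed) and any extras (e.g. `PNA`, `CRCL`).
#'
#' Invariants checked: non-negative, within-subject non-decreasing times;
#' every subject has at least one dose and at least two observations;
#' observed concentrations are positive; BW positive; CRRT in \{0, 1\}.
#'
#' @param df a data.frame in the dialect above.
#' @return `df` with class `tdm_dataset` prepended.
#' @export
as_tdm <- function(df) {
  need <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV", "BW", "CRRT")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$TIME)) || any(df$TIME < 0))
    stop("TIME must be finite and >= 0")
  if (!all(df$EVID %in% c(0, 1))) stop("EVID must be 0 or 1")
  if (!all(df$CRRT %in% c(0, 1))) stop("CRRT must be 0 or 1")
  if (any(!is.finite(df$BW)) || any(df$BW <= 0)) stop("BW must be positive")
  for (id in unique(df$ID)) {
    s <- df[df$ID == id, ]
    if (is.unsorted(s$TIME)) stop("times not non-decreasing for subject ", id)
    if (sum(s$EVID == 1) < 1) stop("subject ", id, " has no dose event")
    obs <- s[s$EVID == 0 & s$MDV == 0, ]
    if (nrow(obs) < 2) stop("subject ", id, " has fewer than 2 observations")
    if (any(!is.finite(obs$DV)) || any(obs$DV <= 0))
      stop("non-positive observation for subject ", id)
    d <- s[s$EVID == 1, ]
    if (any(!is.finite(d$AMT)) || any(d$AMT <= 0) ||
        any(!is.finite(d$RATE)) || any(d$RATE <= 0))
      stop("dose rows need positive AMT and RATE (subject ", id, ")")
  }
  class(df) <- unique(c("tdm_dataset", class(df)))
  df
}

#' Read a TDM dataset from CSV
#' @param path CSV file in the dialect described in [as_tdm()].
#' @return A validated `tdm_dataset`.
#' @export
read_tdm <- function(path) {
  as_tdm(utils::read.csv(path))
}

#' Write a TDM dataset to CSV
#' @param data a `tdm_dataset` (validated on the way out).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tdm <- function(data, path) {
  data <- as_tdm(as.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.tdm_dataset <- function(x, ...) {
  nobs <- sum(x$EVID == 0 & x$MDV == 0)
  cat(sprintf("TDM dataset: %d subjects, %d observations, %d dose events\n",
              length(unique(x$ID)), nobs, sum(x$EVID == 1)))
  NextMethod()
}

# Compile a tdm_dataset into the flat arrays the likelihood kernel consumes.
# Subjects are ordered by first appearance; observations/doses keep file order.
.compile_tdm <- function(data, extras = TRUE) {
  data <- as.data.frame(data)
  ids <- unique(data$ID)
  obs_t <- numeric(0); dv <- numeric(0)
  d_st <- numeric(0); d_rt <- numeric(0); d_du <- numeric(0)
  obs_off <- integer(length(ids) + 1L)
  dose_off <- integer(length(ids) + 1L)
  xcols <- setdiff(names(data),
                   c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV"))
  X <- NULL
  for (i in seq_along(ids)) {
    s <- data[data$ID == ids[i], ]
    o <- s[s$EVID == 0 & s$MDV == 0, ]
    d <- s[s$EVID == 1, ]
    obs_t <- c(obs_t, o$TIME); dv <- c(dv, o$DV)
    d_st <- c(d_st, d$TIME); d_rt <- c(d_rt, d$RATE)
    d_du <- c(d_du, d$AMT / d$RATE)
    obs_off[i + 1L] <- length(obs_t)
    dose_off[i + 1L] <- length(d_st)
    X <- rbind(X, as.matrix(o[, xcols, drop = FALSE]))
  }
  colnames(X) <- xcols
  list(ids = ids, n_sub = length(ids), n_obs = length(obs_t),
       obs_t = obs_t, dv = dv, obs_off = obs_off,
       d_st = d_st, d_rt = d_rt, d_du = d_du, dose_off = dose_off,
       X = X)
}
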