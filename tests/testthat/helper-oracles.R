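# Independent oracles used by the tests.  These deliberately avoid the
# package's closed-form kinetics and Laplace code paths.

# numeric ODE solution of dC/dt = rate(t)/V - ke*C, integrated piecewise
# between event boundaries with deSolve (tight tolerances)
ode_conc <- function(times, starts, rates, durs, cl, v) {
  ke <- cl / v
  bounds <- sort(unique(c(0, starts, starts + durs, times)))
  rate_at <- function(t) {
    sum(rates[t >= starts & t < starts + durs])
  }
  out <- numeric(length(times))
  C <- 0
  t_prev <- 0
  for (b in bounds[bounds > 0]) {
    if (b - t_prev > 1e-12) {
      r <- rate_at((t_prev + b) / 2) # constant within the segment
      sol <- deSolve::ode(
        y = c(C = C), times = c(t_prev, b),
        func = function(t, y, p) list(r / v - ke * y[1]),
        rtol = 1e-12, atol = 1e-12, method = "lsoda")
      C <- sol[nrow(sol), 2]
    }
    if (any(idx <- abs(times - b) < 1e-12)) out[idx] <- C
    t_prev <- b
  }
  out[abs(times) < 1e-12] <- 0
  out
}

# independent R evaluation of the structural model at one time
conc_R <- function(t, st, rt, du, cl, v) {
  ke <- cl / v
  s <- 0
  for (e in seq_along(st)) {
    tau <- t - st[e]
    if (tau <= 0) next
    t1 <- min(tau, du[e]); t2 <- max(tau - du[e], 0)
    s <- s + (rt[e] / cl) * (1 - exp(-ke * t1)) * exp(-ke * t2)
  }
  s
}

# -2 log marginal likelihood by fixed-grid 2-D Gauss-Hermite quadrature
gh_ofv <- function(dat, pop, nq = 32) {
  gh <- pracma::gaussHermite(nq)
  tot <- 0
  for (id in unique(dat$ID)) {
    s <- dat[dat$ID == id, ]
    d <- s[s$EVID == 1, ]; o <- s[s$EVID == 0 & s$MDV == 0, ]
    Li <- 0
    for (j in seq_len(nq)) for (k in seq_len(nq)) {
      e1 <- sqrt(2 * pop$omega2_cl) * gh$x[j]
      e2 <- sqrt(2 * pop$omega2_v) * gh$x[k]
      ll <- 0
      for (m in seq_len(nrow(o))) {
        cl <- pop$clp * (o$BW[m] / pop$bw_ref) * exp(e1)
        v <- pop$vp * (o$BW[m] / pop$bw_ref) *
          (1 + pop$theta_crrt)^o$CRRT[m] * exp(e2)
        f <- max(conc_R(o$TIME[m], d$TIME, d$RATE, d$AMT / d$RATE, cl, v),
                 1e-6)
        ll <- ll + stats::dnorm(o$DV[m], f, sqrt(pop$sigma2_prop) * f,
                                log = TRUE)
      }
      Li <- Li + gh$w[j] * gh$w[k] * exp(ll) / pi
    }
    tot <- tot - 2 * log(Li)
  }
  tot
}

# adaptive variant: mode-centred, Hessian-scaled quadrature per subject
agh_ofv <- function(dat, pop, nq = 20) {
  gh <- pracma::gaussHermite(nq)
  tot <- 0
  for (id in unique(dat$ID)) {
    s <- dat[dat$ID == id, ]
    d <- s[s$EVID == 1, ]; o <- s[s$EVID == 0 & s$MDV == 0, ]
    h <- function(e) {
      ll <- 0
      for (m in seq_len(nrow(o))) {
        cl <- pop$clp * (o$BW[m] / pop$bw_ref) * exp(e[1])
        v <- pop$vp * (o$BW[m] / pop$bw_ref) *
          (1 + pop$theta_crrt)^o$CRRT[m] * exp(e[2])
        f <- max(conc_R(o$TIME[m], d$TIME, d$RATE, d$AMT / d$RATE, cl, v),
                 1e-6)
        ll <- ll + stats::dnorm(o$DV[m], f, sqrt(pop$sigma2_prop) * f,
                                log = TRUE)
      }
      -ll - stats::dnorm(e[1], 0, sqrt(pop$omega2_cl), log = TRUE) -
        stats::dnorm(e[2], 0, sqrt(pop$omega2_v), log = TRUE)
    }
    op <- stats::optim(c(0, 0), h, method = "BFGS", hessian = TRUE)
    for (st in list(c(0.5, 0.5), c(-0.5, -0.5), c(1, -1), c(-1, 1),
                    c(1.5, 1.5), c(-1.5, -1.5))) {
      o2 <- stats::optim(st, h, method = "BFGS", hessian = TRUE)
      if (o2$value < op$value) op <- o2
    }
    Sg <- solve(op$hessian)
    L <- t(chol(Sg))
    acc <- 0
    for (j in seq_len(nq)) for (k in seq_len(nq)) {
      z <- sqrt(2) * c(gh$x[j], gh$x[k])
      e <- op$par + as.numeric(L %*% z)
      acc <- acc + gh$w[j] * gh$w[k] * exp(-(h(e) - op$value) + sum(z^2) / 2)
    }
    tot <- tot - 2 * log(2 * sqrt(det(Sg)) * exp(-op$value) * acc)
  }
  tot
}

# tiny deterministic TDM set built in code (2 subjects, q8h short infusions)
toy_tdm <- function() {
  mk <- function(id, bw, crrt, dv_times, dvs) {
    rbind(
      data.frame(ID = id, TIME = c(0, 8, 16), AMT = 20 * bw,
                 RATE = 20 * bw / 0.5, DV = NA_real_, EVID = 1, MDV = 1,
                 BW = bw, CRRT = crrt),
      data.frame(ID = id, TIME = dv_times, AMT = NA_real_, RATE = NA_real_,
                 DV = dvs, EVID = 0, MDV = 0, BW = bw, CRRT = crrt))
  }
  d <- rbind(mk(1, 7.88, 0, c(1, 7.5, 17), c(30, 6, 25)),
             mk(2, 4.0, 1, c(2, 10), c(18, 8)))
  d <- d[order(d$ID, d$TIME, -d$EVID), ]
  as_tdm(d)
}
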