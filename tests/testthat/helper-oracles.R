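# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form code paths.

# Stiff-ODE integration of the three-compartment chain, piecewise across
# the delivery-window boundaries so lsoda never steps over a
# discontinuity.
ode_compartments <- function(p, c, sb) {
  k1 <- 1 / c$T1b + 1 / p$t_a
  k2 <- 1 / c$T1b + 1 / p$tex
  k3 <- 1 / c$T1t
  A <- 2 * c$alpha * (p$cbf / 6e6) * exp(-p$att_a / c$T1b) / c$lambda_bp
  T_read <- sb$duration + sb$pld
  deriv <- function(t, y, parms) {
    u <- if (parms) A else 0
    list(c(u - k1 * y[1],
           y[1] / p$t_a - k2 * y[2],
           y[2] / p$tex - k3 * y[3]))
  }
  seg <- sort(unique(pmin(pmax(
    c(0, p$att_a, p$att_a + sb$duration, T_read), 0), T_read)))
  y <- c(0, 0, 0)
  for (i in seq_len(length(seg) - 1)) {
    if (seg[i + 1] <= seg[i]) next
    mid <- (seg[i] + seg[i + 1]) / 2
    on <- mid > p$att_a && mid < p$att_a + sb$duration
    out <- deSolve::lsoda(y, c(seg[i], seg[i + 1]), deriv, parms = on,
                          rtol = 1e-12, atol = 1e-18)
    y <- out[nrow(out), 2:4]
  }
  unname(y)
}

# Normal-equations OLS: (X'X)^{-1} X'y.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# Benjamini-Hochberg step-up applied by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Closed-form Welch t statistic and two-sided p.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Simulate the decoded difference signals a noiseless acquisition would
# yield, directly from the forward model (bypasses encode/decode).
forward_decoded <- function(p, protocols, c) {
  dm8 <- unlist(lapply(Filter(function(pr) pr$had_order == 8, protocols),
                       function(pr) {
    dm <- multi_te_signal(p, c, pr$subboluses, pr$tes)
    rev(dm[, 1])
  }))
  pr4 <- Filter(function(pr) pr$had_order == 4, protocols)[[1]]
  dm4 <- multi_te_signal(p, c, pr4$subboluses, pr4$tes)
  list(dm8 = dm8, dm4 = dm4[rev(seq_len(nrow(dm4))), , drop = FALSE])
}

standard_protocols <- function() {
  list(protocol_had8("A"), protocol_had8("B"), protocol_had4())
}
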