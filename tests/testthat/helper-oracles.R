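# Independent oracles used across the suite.  These deliberately avoid the
# package's own construction paths.

# Natural cubic spline space via truncated powers with the natural
# constraints imposed by a direct linear solve.  Knot set = boundary +
# interior knots; the space is {1, x, (x - t_j)^3_+} subject to
# sum(c_j) = 0 and sum(c_j t_j) = 0 (zero 2nd/3rd derivative beyond the
# last knot).  Returns a basis matrix whose column space is the NCS space
# including the intercept.
tp_natural_basis <- function(x, interior, boundary) {
  knots <- sort(c(boundary, interior))
  TP <- vapply(knots, function(t) pmax(x - t, 0)^3, numeric(length(x)))
  C <- rbind(rep(1, length(knots)), knots)
  nullsp <- qr.Q(qr(t(C)), complete = TRUE)[, -(1:2), drop = FALSE]
  cbind(1, x, TP %*% nullsp)
}

# Max residual of projecting the columns of A onto the column space of B.
proj_resid <- function(A, B) {
  fit <- qr.fitted(qr(B), A)
  max(abs(A - fit))
}

# Brute-force cross-basis entry: sum over lags of var-basis x lag-basis,
# computed one scalar at a time from the raw series.
bf_crossbasis_entry <- function(x, t, j, k, max_lag, var_knots, L) {
  s <- 0
  for (l in 0:max_lag) {
    if (t - l < 1) return(NA_real_)
    s <- s + as.numeric(ncs_basis(x[t - l], var_knots)[1, j]) *
      as.numeric(L[l + 1, k])
  }
  s
}

# NB2 log-likelihood summed term by term from the pmf.
nb2_loglik <- function(y, mu, theta) sum(dnbinom(y, mu = mu, size = theta,
                                                 log = TRUE))

# The spline-family true surface used in selection-recovery experiments:
# drawn exactly from the 4-df-temperature x 3-df-lag cross-basis family,
# with the 4-df component strong enough to be identifiable at the
# simulated sample size.
recovery_surface <- function() {
  vk <- knot_spec(c(23, 26.3, 28.9), c(14.4, 33.9))
  xs <- seq(14.4, 33.9, length.out = 200)
  B <- ncs_basis(xs, vk)
  g0 <- 0.4 * ((xs - 26.3) / 7)^2 + 0.45 * sin(2 * pi * (xs - 14.4) / 10)
  co <- qr.solve(cbind(1, B), g0)
  L <- cbind(1, ncs_basis(0:28, place_lag_knots(28, 2)))
  p0 <- exp(-(0:28) / 5)
  w <- qr.solve(L, p0 / sum(p0))
  w <- w / sum(drop(L %*% w))
  crossbasis_surface(vk, outer(co[-1], as.vector(w)), max_lag = 28)
}
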