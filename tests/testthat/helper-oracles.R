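# Independent brute-force oracles, deliberately naive (explicit loops,
# normal equations) so they share no code path with the implementation.

naive_vol_avg_velocity <- function(state) {
  r <- state$r; u <- state$u; v <- state$v
  nx <- nrow(r); ny <- ncol(r)
  num <- 0; den <- 0
  for (i in 1:nx) for (j in 1:ny) {
    uc <- (u[i, j] + u[i + 1, j]) / 2
    vc <- (v[i, j] + v[i, j + 1]) / 2
    num <- num + r[i, j] * sqrt(uc^2 + vc^2)
    den <- den + r[i, j]
  }
  num / den
}

naive_wall_wss <- function(state) {
  r <- state$r; u <- state$u; v <- state$v
  nx <- nrow(r); ny <- ncol(r)
  dx <- state$dx; dy <- state$dy
  mu <- r * state$phases$liquid$dynamic_viscosity +
    (1 - r) * state$phases$gas$dynamic_viscosity
  taus <- c(); lens <- c()
  for (i in 1:nx) {                       # bottom
    if (r[i, 1] > 0.5) {
      uc <- (u[i, 1] + u[i + 1, 1]) / 2
      taus <- c(taus, mu[i, 1] * abs(uc) / (dy / 2)); lens <- c(lens, dx)
    }
  }
  for (j in 1:ny) {                       # left, right
    if (r[1, j] > 0.5) {
      vc <- (v[1, j] + v[1, j + 1]) / 2
      taus <- c(taus, mu[1, j] * abs(vc) / (dx / 2)); lens <- c(lens, dy)
    }
    if (r[nx, j] > 0.5) {
      vc <- (v[nx, j] + v[nx, j + 1]) / 2
      taus <- c(taus, mu[nx, j] * abs(vc) / (dx / 2)); lens <- c(lens, dy)
    }
  }
  if (!length(taus)) return(list(avg = 0, max = 0))
  list(avg = sum(taus * lens) / sum(lens), max = max(taus))
}

# normal-equations least squares: columns of X solved via solve(t(X) X)
oracle_lm <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

oracle_origin_fit <- function(x, y) {
  slope <- sum(x * y) / sum(x^2)
  res <- y - slope * x
  n <- length(x)
  mse <- sum(res^2) / (n - 1)
  list(slope = slope,
       R2 = 1 - sum(res^2) / sum(y^2),
       F = slope^2 * sum(x^2) / mse)
}

oracle_quadratic_fit <- function(x, y) {
  X <- cbind(1, x, x^2)
  oracle_lm(X, y)
}

oracle_intercept_F <- function(x, ya, yb) {
  # nested-model RSS comparison computed from scratch
  xx <- c(x, x); yy <- c(ya, yb); d <- rep(c(0, 1), each = length(x))
  full <- oracle_lm(cbind(1, xx, d), yy)
  red <- oracle_lm(cbind(1, xx), yy)
  rss_f <- sum((yy - cbind(1, xx, d) %*% full)^2)
  rss_r <- sum((yy - cbind(1, xx) %*% red)^2)
  dfd <- length(yy) - 3
  (rss_r - rss_f) / (rss_f / dfd)
}

# Higbie K_L as the time-average of the instantaneous penetration flux
# coefficient sqrt(D / (pi t)) over one renewal period, by quadrature.
oracle_higbie_quadrature <- function(D, t_C) {
  stats::integrate(function(t) sqrt(D / (pi * t)), 0, t_C,
                   rel.tol = 1e-12)$value / t_C
}

# Unit-conversion oracle for K_bag: OTR in cm^3(STP)/m^2/day ->
# mol/(m^2 s) -> m/s, written out step by step.
oracle_kbag <- function(otr, c_sat = 1.38) {
  cm3_per_day <- otr                       # cm^3 STP per m^2 per day
  m3_per_day <- cm3_per_day * 1e-6
  mol_per_day <- m3_per_day / 22.414e-3    # ideal gas molar volume at STP
  mol_per_s <- mol_per_day / (24 * 3600)
  mol_per_s / c_sat
}
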