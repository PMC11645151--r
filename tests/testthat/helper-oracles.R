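# Independent numerical oracles used across the suite. These deliberately
# avoid the package's closed-form convolution path.

# RK4 integration of dCt/dt = K1 Ca(t) - k2 Ct(t) on a fine grid, followed
# by Riemann frame averaging of C_PET = (1 - vb) Ct + vb Ca
rk4_frame_averages <- function(K1, k2, vb, ca_fun, schedule, dt = 0.001) {
  tmax <- max(schedule$end)
  # grid includes the exact frame boundaries (variable-step RK4)
  tt <- sort(unique(c(seq(0, tmax, by = dt), schedule$start, schedule$end)))
  ct <- numeric(length(tt))
  f <- function(t, c) K1 * ca_fun(t) - k2 * c
  for (i in seq_len(length(tt) - 1L)) {
    h <- tt[i + 1L] - tt[i]
    t0 <- tt[i]; c0 <- ct[i]
    k1v <- f(t0, c0)
    k2v <- f(t0 + h / 2, c0 + h / 2 * k1v)
    k3v <- f(t0 + h / 2, c0 + h / 2 * k2v)
    k4v <- f(t0 + h, c0 + h * k3v)
    ct[i + 1L] <- c0 + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  cpet <- (1 - vb) * ct + vb * ca_fun(tt)
  vapply(seq_along(schedule$start), function(j) {
    sel <- tt >= schedule$start[j] - 1e-12 & tt <= schedule$end[j] + 1e-12
    x <- tt[sel]; y <- cpet[sel]
    trap <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
    trap / (schedule$end[j] - schedule$start[j])
  }, numeric(1))
}

# evaluate an expression under a local RNG seed (test-side twin of the
# package-internal seeding helper)
with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# a dense 1-second frame schedule for comparing the linearized and
# nonlinear fits where discretization error is negligible
dense_schedule <- function(duration = 30, dt = 1 / 60) {
  ends <- seq(dt, duration, by = dt)
  frame_schedule(ends - dt, ends)
}

# exhaustive two-sided exact Mann-Whitney p-value by enumerating all
# assignments of the pooled sample to the two groups
mw_exact_p_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force KS distance by scanning ECDF differences on a fine grid
ks_D_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  grid <- c(grid, grid - 1e-9)
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
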