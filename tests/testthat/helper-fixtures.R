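# Shared fixtures: a fast substrate configuration for tests that do not
# depend on the calibrated operating point (coarser dt, fewer samples), and
# small helper constructors.

fast_cfg <- function(...) {
  substrate_config(dt = 0.02, ...)
}

mid_genes <- c(511L, 511L)

# A deliberately asymmetric heterogeneous genome for 9-gene tests.
hetero_genes <- c(300L, 450L, 600L, 750L, 900L, 200L, 400L, 600L, 800L)

# Independent attenuation-fit oracle: separable least squares.  For each
# lambda on a coarse-to-fine grid the model is linear in (a, c); solve that
# exactly, then polish all three parameters with Nelder-Mead.  Shares no code
# with fit_attenuation().
oracle_fit <- function(y) {
  x <- seq_along(y) - 1
  sse_for <- function(lambda) {
    X <- cbind(exp(-x / lambda), 1)
    beta <- qr.solve(X, y)
    c(sum((y - X %*% beta)^2), beta)
  }
  grid <- seq(0.05, 10, by = 0.001)
  sse <- vapply(grid, function(l) sse_for(l)[1], numeric(1))
  l0 <- grid[which.min(sse)]
  b0 <- sse_for(l0)[2:3]
  polish <- stats::optim(c(b0[1], l0, b0[2]), function(p)
    sum((y - p[1] * exp(-x / p[2]) - p[3])^2),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
  list(a = polish$par[1], lambda = polish$par[2], c = polish$par[3])
}
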