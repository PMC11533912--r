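# Independent oracles used across the suite.

# Numerical ODE integration of the Pb-212 chain (Po-212 folded into Bi-212,
# matching the instantaneous-daughter treatment). Returns activities at `times`
# for a pure Pb-212 source of activity a0.
ode_chain_activities <- function(chain, a0, times) {
  lam <- setNames(log(2) / chain$nuclides$half_life_h, chain$nuclides$nuclide)
  rhs <- function(t, y, p) {
    dPb <- -lam[["Pb-212"]] * y[1]
    dBi <- lam[["Pb-212"]] * y[1] - lam[["Bi-212"]] * y[2]
    dTl <- 0.3594 * lam[["Bi-212"]] * y[2] - lam[["Tl-208"]] * y[3]
    list(c(dPb, dBi, dTl))
  }
  y0 <- c(a0 / lam[["Pb-212"]], 0, 0)
  sol <- deSolve::lsoda(y0, c(0, times), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-14)
  sol <- sol[-1, , drop = FALSE]
  data.frame(time = sol[, 1],
             `Pb-212` = lam[["Pb-212"]] * sol[, 2],
             `Bi-212` = lam[["Bi-212"]] * sol[, 3],
             `Tl-208` = lam[["Tl-208"]] * sol[, 4],
             check.names = FALSE)
}

# Empirical (no-censoring) survival fraction: #(event times > t) / n
empirical_survival <- function(times, t) {
  vapply(t, function(tt) mean(times > tt), numeric(1))
}

# Sum-of-squares grid + Nelder-Mead refit of the one-site model, independent
# of the package's fitting path.
oracle_one_site <- function(conc, b) {
  sse <- function(p) sum((b - p[2] * conc / (p[1] + conc))^2)
  grid <- expand.grid(kd = exp(seq(log(0.1), log(100), length.out = 60)),
                      bmax = max(b) * seq(0.5, 2, length.out = 40))
  vals <- apply(grid, 1, sse)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, sse, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  c(kd = opt$par[1], bmax = opt$par[2])
}

# The bundled chain, loaded once per test file.
test_chain <- function() decay_chain()
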