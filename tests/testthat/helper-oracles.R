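# shared fixtures and independent oracles used across the suite

theta_1a <- model_params(-1.250, 0.004, 1.460, -0.007)
theta_1b <- model_params(1.513, -0.013, 6.103, -0.034)

# printed robust / dual-objective designs used as evaluation inputs
published_designs <- list(
  rd_arrest = design(c(0, 250, 300, 1000), c(0.341, 0.032, 0.375, 0.252)),
  rd_aboral = design(c(0, 163, 207, 450), c(0.450, 0.154, 0.166, 0.230)),
  rdc25_aboral = design(c(0, 158, 163, 212, 226, 450),
                        c(0.246, 0.154, 0.116, 0.091, 0.287, 0.106))
)

# central finite-difference gradient oracle
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h * max(1, abs(x[i])))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

# quadrature of a density over (0, 1)
integrate01 <- function(f) stats::integrate(f, 0, 1, rel.tol = 1e-10)$value

# Monte-Carlo estimate of the expected negative Hessian of the Beta
# log density with respect to the regression parameters, at one dose
mc_point_information <- function(theta, x, n = 5e5, h = 1e-3, seed = 99) {
  set.seed(seed)
  sp <- shape_params(theta, x)
  y <- rbeta(n, sp$a, sp$b)
  ll <- function(th) mean(dbeta(y, exp(th[1] + th[2] * x),
                                exp(th[3] + th[4] * x), log = TRUE))
  H <- matrix(0, 4, 4)
  for (i in 1:4) for (j in i:4) {
    ei <- replace(numeric(4), i, h); ej <- replace(numeric(4), j, h)
    H[i, j] <- H[j, i] <-
      -(ll(theta + ei + ej) - ll(theta + ei - ej) -
          ll(theta - ei + ej) + ll(theta - ei - ej)) / (4 * h^2)
  }
  H
}

# slow, obviously-correct design information: explicit Jacobian push-forward
naive_design_information <- function(d, theta) {
  M <- matrix(0, 4, 4)
  for (i in seq_len(nrow(d))) {
    sp <- shape_params(theta, d$dose[i])
    a <- sp$a; b <- sp$b
    t12 <- trigamma(a + b)
    I2 <- matrix(c(trigamma(a) - t12, -t12, -t12, trigamma(b) - t12), 2, 2)
    J <- rbind(c(a, a * d$dose[i], 0, 0), c(0, 0, b, b * d$dose[i]))
    M <- M + d$weight[i] * t(J) %*% I2 %*% J
  }
  M
}

# exhaustive locally D-optimal search: every 4-point support on the grid,
# inner weight optimization on the leaders of an equal-weight screen
brute_force_d_optimal <- function(theta, grid, interval, top = 50) {
  combos <- utils::combn(length(grid), 4, simplify = FALSE)
  screen <- vapply(combos, function(ix) {
    d_criterion(design(grid[ix], rep(0.25, 4), interval), theta)
  }, numeric(1))
  spec <- criterion_spec("D", parameter_prior(list(theta)), interval = interval)
  best <- NULL
  for (ix in combos[order(screen, decreasing = TRUE)[seq_len(top)]]) {
    d <- optimize_weights(grid[ix], spec)
    v <- criterion_value(d, spec)
    if (is.null(best) || v > best$value) best <- list(design = d, value = v)
  }
  best
}
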