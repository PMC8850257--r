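test_that("optimized weights are simplex-feasible with equalized sensitivity", {
  spec <- criterion_spec("D", nominal_priors("arrest"), interval = c(0, 1000))
  d <- optimize_weights(c(0, 290, 1000), spec)
  expect_equal(sum(d$weight), 1, tolerance = 1e-12)
  expect_true(all(d$weight > 0))
  s <- sensitivity(d$dose, d, spec)
  expect_lt(max(abs(s)), 1e-4)   # KKT: zero sensitivity at supported points
})

test_that("two-point weights match a golden-section brute force", {
  spec <- criterion_spec("D", parameter_prior(list(theta_1a)), interval = c(0, 1000))
  d <- optimize_weights(c(0, 1000), spec)
  f <- function(w) criterion_value(design(c(0, 1000), c(w, 1 - w), c(0, 1000)), spec)
  w_star <- optimize(f, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(d$weight[1], w_star, tolerance = 1e-5)
})

test_that("symmetric problems give symmetric designs", {
  # b(L - x) = a(x) on [0, 1000] for this parameter set, so the D criterion
  # is invariant under dose reflection
  th <- model_params(0, 0.001, 1, -0.001)
  spec <- criterion_spec("D", parameter_prior(list(th)), interval = c(0, 1000))
  res <- find_optimal_design(spec, grid_step = 5)
  expect_true(res$converged)
  d <- res$design
  expect_equal(d$dose, 1000 - rev(d$dose), tolerance = 1e-9)
  expect_equal(d$weight, rev(d$weight), tolerance = 1e-4)
})

test_that("the exchange result matches exhaustive search on a coarse grid", {
  grid <- seq(0, 1000, 125)             # 9 points: full enumeration feasible
  spec <- criterion_spec("D", parameter_prior(list(theta_1a)), interval = c(0, 1000))
  res <- find_optimal_design(spec, grid_step = 125, collapse = FALSE)
  brute <- brute_force_d_optimal(theta_1a, grid, c(0, 1000), top = 126)
  keep <- brute$design$weight > 1e-6
  expect_equal(res$design$dose, brute$design$dose[keep])
  expect_equal(res$design$weight, brute$design$weight[keep] /
                 sum(brute$design$weight[keep]), tolerance = 1e-5)
  expect_equal(res$criterion_value, brute$value, tolerance = 1e-9)
})

test_that("every converged search carries an equivalence-theorem certificate", {
  pr <- nominal_priors("arrest")
  specs <- list(
    criterion_spec("D", pr, interval = c(0, 1000)),
    criterion_spec("cLCp", pr, p = 0.1, interval = c(0, 1000)),
    criterion_spec("compound", pr, p = 0.5, W = 0.5, interval = c(0, 1000)))
  for (spec in specs) {
    res <- find_optimal_design(spec, grid_step = 20)
    expect_true(res$converged)
    expect_lte(res$max_sensitivity, res$tol)
    s_sup <- sensitivity(res$design$dose, res$design, spec)
    expect_lt(max(abs(s_sup)), 5 * res$tol)
    # monotone improvement across exchange iterations
    expect_true(all(diff(res$trace$criterion) > -1e-9))
  }
})

test_that("the search is deterministic", {
  spec <- criterion_spec("compound", nominal_priors("aboral"), p = 0.25, W = 0.5,
                         interval = c(0, 450))
  r1 <- find_optimal_design(spec, grid_step = 10)
  r2 <- find_optimal_design(spec, grid_step = 10)
  expect_identical(r1$design$dose, r2$design$dose)
  expect_identical(r1$design$weight, r2$design$weight)
  expect_identical(r1$criterion_value, r2$criterion_value)
})

test_that("support collapsing merges only near-duplicates", {
  d <- design(c(100, 100.4, 500), c(0.3, 0.2, 0.5), c(0, 1000))
  cd <- collapse_support(d, dose_tol = 1)
  expect_equal(cd$dose, c(100.16, 500))
  expect_equal(cd$weight, c(0.5, 0.5))
  # no near-duplicates: identity
  expect_equal(collapse_support(cd, dose_tol = 1), cd)
  # genuinely separated optima (5 uM apart) must not merge
  sep <- collapse_support(published_designs$rdc25_aboral, dose_tol = 1)
  expect_equal(nrow(sep), 6)
  # a floor-weight point is dropped and weights renormalized
  d2 <- design(c(0, 300, 600), c(0.5, 5e-5, 0.49995), c(0, 1000))
  expect_equal(collapse_support(d2)$dose, c(0, 600))
})

test_that("rounding to exact designs is feasible and proportional", {
  d <- design(c(0, 250, 300, 1000), c(0.341, 0.032, 0.375, 0.252))
  al <- round_to_exact(d, 1000)
  expect_equal(al$n, c(341L, 32L, 375L, 252L))
  # tie toward the lower dose
  expect_equal(round_to_exact(design(c(100, 200), c(0.5, 0.5)), 3)$n, c(2L, 1L))
  set.seed(9)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    w <- runif(k); w <- w / sum(w)
    dd <- design(sort(sample(0:1000, k)), w, c(0, 1000))
    n_tot <- sample(k:60, 1)
    al <- round_to_exact(dd, n_tot)
    expect_equal(sum(al$n), n_tot)
    expect_true(all(al$n >= 1))
  }
  expect_error(round_to_exact(d, 3), "smaller than")
})
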