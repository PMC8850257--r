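test_that("robust criteria reduce to local ones under a degenerate prior", {
  single <- parameter_prior(list(theta_1a))
  u4 <- uniform_design(4, c(0, 1000))
  expect_equal(robust_d(u4, single), d_criterion(u4, theta_1a))
  expect_equal(robust_c(u4, single, 0.2), log(c_criterion(u4, theta_1a, 0.2)))
  # and the robust value is the probability-weighted average
  pr <- nominal_priors("arrest")
  manual <- sum(pr$prob * vapply(seq_len(6), function(i) {
    d_criterion(u4, unlist(pr[i, c("alpha1", "alpha2", "beta1", "beta2")]))
  }, numeric(1)))
  expect_equal(robust_d(u4, pr), manual, tolerance = 1e-12)
})

test_that("singular designs hit the sentinels instead of crashing", {
  one <- design(500, 1, c(0, 1000))
  expect_identical(d_criterion(one, theta_1a), -Inf)
  expect_identical(robust_d(one, nominal_priors("arrest")), -Inf)
  # rank-2 information cannot estimate the 4-dim LCp gradient
  expect_identical(c_criterion(one, theta_1a, 0.5), Inf)
  expect_identical(robust_c(one, nominal_priors("arrest"), 0.5), Inf)
})

test_that("c criterion is the delta-method quadratic form", {
  u4 <- uniform_design(4, c(0, 1000))
  cc <- lcp_gradient(theta_1a, 0.25)
  direct <- drop(crossprod(cc, solve(design_information(u4, theta_1a), cc)))
  expect_equal(c_criterion(u4, theta_1a, 0.25), direct, tolerance = 1e-10)
})

test_that("no design beats the optimized weights on a fixed support", {
  support <- c(0, 250, 1000)
  spec <- criterion_spec("cLCp", parameter_prior(list(theta_1a)), p = 0.5,
                         interval = c(0, 1000))
  opt <- optimize_weights(support, spec)
  v_opt <- criterion_value(opt, spec)
  # simplex lattice brute force (step 0.01)
  best <- -Inf
  for (w1 in seq(0.01, 0.98, 0.01)) {
    for (w2 in seq(0.01, 0.99 - w1, 0.01)) {
      v <- criterion_value(design(support, c(w1, w2, 1 - w1 - w2), c(0, 1000)), spec)
      if (v > best) best <- v
    }
  }
  expect_gte(v_opt, best)
  expect_equal(v_opt, best, tolerance = 1e-3)
})

test_that("the compound criterion interpolates its two endpoint criteria", {
  pr <- nominal_priors("arrest")
  u4 <- uniform_design(4, c(0, 1000))
  u8 <- uniform_design(8, c(0, 1000))
  expect_equal(compound_criterion(u4, pr, 0.5, 1), robust_d(u4, pr) / 4)
  expect_equal(compound_criterion(u4, pr, 0.5, 0), -robust_c(u4, pr, 0.5))
  # intermediate W is the exact convex combination
  expect_equal(compound_criterion(u8, pr, 0.2, 0.3),
               0.3 * robust_d(u8, pr) / 4 - 0.7 * robust_c(u8, pr, 0.2),
               tolerance = 1e-12)
})

test_that("efficiencies are 1 against self and scale like sample size", {
  pr <- nominal_priors("arrest")
  u4 <- uniform_design(4, c(0, 1000))
  u11 <- uniform_design(11, c(0, 1000))
  expect_equal(d_efficiency(u4, u4, pr), 1)
  expect_equal(c_efficiency(u11, u11, pr, 0.1), 1)
  # a design with D-efficiency e matches the reference when its information
  # is multiplied by 1/e (i.e., it needs 1/e times more observations)
  e <- d_efficiency(u4, u11, pr)
  boosted <- robust_d(u4, pr) + 4 * log(1 / e)   # log det(kM) = 4 log k + log det M
  expect_equal(exp((boosted - robust_d(u11, pr)) / 4), 1, tolerance = 1e-12)
})

test_that("sensitivity obeys the weighted-support trace identity", {
  pr <- nominal_priors("arrest")
  set.seed(8)
  for (i in 1:5) {
    doses <- sort(sample(0:1000, 5))
    w <- runif(5); w <- w / sum(w)
    d <- design(doses, w, c(0, 1000))
    for (spec in list(
      criterion_spec("D", pr, interval = c(0, 1000)),
      criterion_spec("cLCp", pr, p = 0.2, interval = c(0, 1000)),
      criterion_spec("compound", pr, p = 0.2, W = 0.5, interval = c(0, 1000)))) {
      s <- sensitivity(doses, d, spec)
      expect_equal(sum(w * s), 0, tolerance = 1e-8)
    }
  }
})

test_that("suboptimal designs show positive sensitivity somewhere", {
  pr <- nominal_priors("arrest")
  spec <- criterion_spec("D", pr, interval = c(0, 1000))
  u4 <- uniform_design(4, c(0, 1000))
  s <- sensitivity(seq(0, 1000, 5), u4, spec)
  expect_gt(max(s), 0.1)
})
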