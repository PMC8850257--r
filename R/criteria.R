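#' Fisher information of one observation at one dose
#'
#' For a Beta-distributed rate with shape parameters `a`, `b`, the
#' information in shape space is
#' `[[psi'(a)-psi'(a+b), -psi'(a+b)], [-psi'(a+b), psi'(b)-psi'(a+b)]]`
#' (psi' the trigamma function). Pushing it to the four regression
#' parameters through the Jacobian of `(a(x), b(x))` gives a symmetric
#' positive-semidefinite 4x4 matrix of rank (at most) 2.
#'
#' @inheritParams shape_params
#' @param dose A single dose in micromolar.
#' @return A 4x4 symmetric matrix.
#' @export
point_information <- function(theta, dose) {
  stopifnot(length(dose) == 1)
  matrix(pinfo_cols(as_theta(theta), dose), 4, 4,
         dimnames = list(names(as_theta(theta)), names(as_theta(theta))))
}

# vectorized point information: one row per dose, 16 columns = vec(m(x))
pinfo_cols <- function(theta, xs) {
  sp <- shape_params(theta, xs)
  a <- sp$a; b <- sp$b
  t12 <- trigamma(a + b)
  i11 <- trigamma(a) - t12
  i22 <- trigamma(b) - t12
  i12 <- -t12
  cbind(a^2 * i11,      a^2 * xs * i11,   a * b * i12,      a * b * xs * i12,
        a^2 * xs * i11, a^2 * xs^2 * i11, a * b * xs * i12, a * b * xs^2 * i12,
        a * b * i12,    a * b * xs * i12, b^2 * i22,        b^2 * xs * i22,
        a * b * xs * i12, a * b * xs^2 * i12, b^2 * xs * i22, b^2 * xs^2 * i22)
}

#' Information matrix of a design
#'
#' The weighted sum of per-dose information matrices,
#' \eqn{M(\xi,\theta) = \sum_i w_i m(x_i,\theta)}. Nonsingularity requires
#' at least two distinct support doses (each dose contributes rank 2).
#'
#' @param x A [design()].
#' @param theta Model parameters.
#' @return A 4x4 symmetric matrix.
#' @export
design_information <- function(x, theta) {
  theta <- as_theta(theta)
  g <- pinfo_cols(theta, x$dose)
  matrix(colSums(g * x$weight), 4, 4, dimnames = list(names(theta), names(theta)))
}

# Moore-Penrose inverse via eigendecomposition (symmetric input)
sym_pinv <- function(m, tol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# inverse with pseudo-inverse fallback; attribute "singular" flags it
safe_inverse <- function(m) {
  inv <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv))) {
    inv <- sym_pinv(m)
    attr(inv, "singular") <- TRUE
  }
  inv
}

#' D-optimality criterion
#'
#' `d_criterion()` is the log determinant of the design's information
#' matrix at one parameter vector; `robust_d()` averages it over a prior,
#' weighting each set by its probability. Singular designs return `-Inf`
#' so optimizers reject them without crashing.
#'
#' @param x A [design()].
#' @param theta Model parameters.
#' @return A scalar criterion value (larger is better).
#' @export
d_criterion <- function(x, theta) {
  M <- design_information(x, theta)
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) -Inf else as.numeric(ld$modulus)
}

#' @rdname d_criterion
#' @param prior A [parameter_prior()].
#' @export
robust_d <- function(x, prior) {
  pr <- prior[prior$prob > 0, ]
  sum(pr$prob * vapply(prior_thetas(pr), function(th) d_criterion(x, th), numeric(1)))
}

#' c-optimality criterion for estimating LCp
#'
#' `c_criterion()` is the asymptotic (per-observation) variance
#' \eqn{c^\top M(\xi,\theta)^- c} of the plug-in LCp estimate, with `c`
#' the delta-method gradient of [lcp()]. When the information matrix is
#' singular a pseudo-inverse is used provided `c` lies in its range
#' (estimability residual below `1e-8`); otherwise `+Inf` is returned.
#' `robust_c()` averages the log variance over a prior (smaller is
#' better).
#'
#' @inheritParams d_criterion
#' @param p Target response proportion in (0, 1).
#' @return `c_criterion()`: the asymptotic variance (scale of dose
#'   squared); `robust_c()`: the prior-averaged log variance.
#' @export
c_criterion <- function(x, theta, p) {
  theta <- as_theta(theta)
  M <- design_information(x, theta)
  cc <- lcp_gradient(theta, p)
  Mi <- safe_inverse(M)
  if (isTRUE(attr(Mi, "singular"))) {
    resid <- M %*% (Mi %*% cc) - cc
    if (sqrt(sum(resid^2)) > 1e-8 * sqrt(sum(cc^2))) return(Inf)
  }
  drop(crossprod(cc, Mi %*% cc))
}

#' @rdname c_criterion
#' @export
robust_c <- function(x, prior, p) {
  pr <- prior[prior$prob > 0, ]
  v <- vapply(prior_thetas(pr), function(th) c_criterion(x, th, p), numeric(1))
  if (any(!is.finite(v))) return(Inf)
  sum(pr$prob * log(v))
}

#' Dual-objective (compound) criterion
#'
#' Convex combination, on the log-efficiency scale, of parameter
#' estimation and LCp estimation, averaged over the prior:
#' \deqn{\sum_i \lambda_i [ W \tfrac14 \log|M(\xi,\theta_i)| -
#'   (1-W) \log(c_i^\top M(\xi,\theta_i)^- c_i) ].}
#' `W = 1` ranks designs exactly as `robust_d()/4`; `W = 0` exactly as
#' `-robust_c()`.
#'
#' @inheritParams c_criterion
#' @param prior A [parameter_prior()].
#' @param W Importance weight of the parameter-estimation objective,
#'   in `[0, 1]`.
#' @return A scalar criterion value (larger is better).
#' @export
compound_criterion <- function(x, prior, p, W) {
  stopifnot(W >= 0, W <= 1)
  pr <- prior[prior$prob > 0, ]
  val <- 0
  for (i in seq_len(nrow(pr))) {
    th <- model_params(pr$alpha1[i], pr$alpha2[i], pr$beta1[i], pr$beta2[i])
    dpart <- if (W > 0) d_criterion(x, th) else 0
    cpart <- if (W < 1) c_criterion(x, th, p) else 1
    if (!is.finite(dpart) || !is.finite(cpart)) return(-Inf)
    val <- val + pr$prob[i] * (W * dpart / 4 - (1 - W) * log(cpart))
  }
  val
}

#' Specify a design criterion
#'
#' Bundles the criterion kind, the prior over nominal parameter sets, the
#' target proportion `p` (for LCp-related criteria), the importance weight
#' `W` (compound only) and the dose interval.
#'
#' @param kind `"D"`, `"cLCp"` or `"compound"`.
#' @param prior A [parameter_prior()].
#' @param p Target proportion; required unless `kind = "D"`.
#' @param W Importance weight in `[0, 1]`; required for `"compound"`.
#' @param interval Dose interval `c(lo, hi)`.
#' @return A `criterion_spec` object.
#' @examples
#' criterion_spec("D", nominal_priors("arrest"), interval = c(0, 1000))
#' @export
criterion_spec <- function(kind = c("D", "cLCp", "compound"), prior,
                           p = NULL, W = NULL, interval) {
  kind <- match.arg(kind)
  if (!inherits(prior, "parameter_prior")) prior <- parameter_prior(prior)
  if (kind != "D") {
    if (is.null(p) || p <= 0 || p >= 1) abort("`p` in (0,1) required for LCp criteria")
  } else {
    p <- NULL
  }
  if (kind == "compound") {
    if (is.null(W) || W < 0 || W > 1) abort("`W` in [0,1] required for the compound criterion")
  } else {
    W <- NULL
  }
  if (length(interval) != 2 || interval[1] >= interval[2]) {
    abort("`interval` must be c(lo, hi) with lo < hi")
  }
  structure(list(kind = kind, prior = prior, p = p, W = W,
                 interval = as.numeric(interval)),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat("Criterion:", x$kind,
      if (!is.null(x$p)) sprintf("(p = %g)", x$p),
      if (!is.null(x$W)) sprintf("(W = %g)", x$W),
      sprintf("on [%g, %g] uM with %d prior set(s)\n",
              x$interval[1], x$interval[2], sum(x$prior$prob > 0)))
  invisible(x)
}

#' Evaluate a criterion specification on a design
#'
#' @param x A [design()].
#' @param spec A [criterion_spec()].
#' @return Scalar criterion value, on the maximization scale for every
#'   kind (`cLCp` returns `-robust_c`).
#' @export
criterion_value <- function(x, spec) {
  switch(spec$kind,
    D = robust_d(x, spec$prior),
    cLCp = { v <- robust_c(x, spec$prior, spec$p); if (is.finite(v)) -v else -Inf },
    compound = compound_criterion(x, spec$prior, spec$p, spec$W))
}

# per-set quantities reused by sensitivity and the optimizer:
# list of (theta, Minv, u = Minv c, cv = c' Minv c) for positive-prob sets
spec_state <- function(x, spec) {
  pr <- spec$prior[spec$prior$prob > 0, ]
  lapply(seq_len(nrow(pr)), function(i) {
    th <- model_params(pr$alpha1[i], pr$alpha2[i], pr$beta1[i], pr$beta2[i])
    M <- design_information(x, th)
    Mi <- safe_inverse(M)
    st <- list(theta = th, prob = pr$prob[i], Minv = Mi)
    if (spec$kind != "D") {
      cc <- lcp_gradient(th, spec$p)
      st$u <- drop(Mi %*% cc)
      st$cv <- drop(crossprod(cc, st$u))
    }
    st
  })
}

#' Equivalence-theorem sensitivity function
#'
#' The directional derivative of the criterion at the design toward a
#' one-point design at `dose`, normalized so that a design is optimal if
#' and only if the sensitivity is `<= 0` over the whole interval, with
#' equality at its support points. For the D criterion it is
#' `sum_i lambda_i tr(M_i^{-1} m(x, theta_i)) - 4`; for c(LCp),
#' `sum_i lambda_i [c_i' M_i^{-1} m(x) M_i^{-1} c_i / (c_i' M_i^{-1} c_i) - 1]`;
#' the compound criterion takes the `W`-convex combination of the two
#' normalized forms. This is the convergence certificate used by
#' [find_optimal_design()].
#'
#' @param dose Dose(s) at which to evaluate the sensitivity.
#' @param x A [design()].
#' @param spec A [criterion_spec()].
#' @return Numeric vector, one value per dose.
#' @export
sensitivity <- function(dose, x, spec) {
  state <- spec_state(x, spec)
  s <- numeric(length(dose))
  W <- spec$W
  for (st in state) {
    g <- pinfo_cols(st$theta, dose)
    trv <- drop(g %*% as.vector(st$Minv))
    if (spec$kind == "D") {
      s <- s + st$prob * (trv - 4)
    } else {
      qv <- drop(g %*% as.vector(tcrossprod(st$u))) / st$cv
      s <- s + switch(spec$kind,
        cLCp = st$prob * (qv - 1),
        compound = st$prob * (W * (trv / 4 - 1) + (1 - W) * (qv - 1)))
    }
  }
  s
}

#' Design efficiencies
#'
#' `d_efficiency()` is `exp{(robust_d(x) - robust_d(reference)) / 4}`: with
#' a single-set prior this is the printed determinant-ratio-to-the-1/4th
#' reading, and a design with D-efficiency 0.80 needs `1/0.80 = 1.25`
#' times more observations to match the reference. `c_efficiency()` is the
#' variance ratio `exp{robust_c(reference) - robust_c(x)}`. Under a
#' multi-set prior both are geometric means of the per-set efficiencies.
#' Values lie in (0, 1] when the reference is the certified optimal design
#' for the same criterion; singular designs score 0.
#'
#' @param x,reference Designs; `reference` is typically the optimal design
#'   for the criterion.
#' @param prior A [parameter_prior()].
#' @return A proportion.
#' @export
d_efficiency <- function(x, reference, prior) {
  v <- robust_d(x, prior)
  if (!is.finite(v)) return(0)
  exp((v - robust_d(reference, prior)) / 4)
}

#' @rdname d_efficiency
#' @param p Target proportion for the LCp being estimated.
#' @export
c_efficiency <- function(x, reference, prior, p) {
  v <- robust_c(x, prior, p)
  if (!is.finite(v)) return(0)
  exp(robust_c(reference, prior, p) - v)
}
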