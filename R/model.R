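#' Parameter vector for the dose-parametrized Beta regression model
#'
#' The model places a Beta distribution on each flask-level response rate
#' \eqn{y \in (0,1)} at dose \eqn{x}, with shape parameters log-linear in
#' dose: \eqn{a(x) = \exp(\alpha_1 + \alpha_2 x)} and
#' \eqn{b(x) = \exp(\beta_1 + \beta_2 x)}. The mean response
#' \eqn{a/(a+b)} is then a sigmoidal (logistic) function of dose and the
#' response variance changes with dose, matching the inhomogeneous spread
#' seen in concentration-response data.
#'
#' @param alpha1,beta1 Dimensionless intercepts of the log shape parameters.
#' @param alpha2,beta2 Slopes of the log shape parameters, per micromolar.
#' @return A named numeric vector of length 4 with names
#'   `alpha1`, `alpha2`, `beta1`, `beta2`.
#' @examples
#' theta <- model_params(-1.25, 0.004, 1.46, -0.007)
#' mean_response(theta, c(0, 250, 1000))
#' @export
model_params <- function(alpha1, alpha2, beta1, beta2) {
  theta <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
  if (!all(is.finite(theta))) {
    abort("all four model parameters must be finite")
  }
  theta
}

# coerce a length-4 numeric (possibly unnamed) to the canonical order
as_theta <- function(theta) {
  if (is.data.frame(theta)) theta <- unlist(theta[1, c("alpha1", "alpha2", "beta1", "beta2")])
  if (!is.numeric(theta) || length(theta) != 4 || !all(is.finite(theta))) {
    abort("`theta` must be 4 finite numbers (alpha1, alpha2, beta1, beta2)")
  }
  nm <- c("alpha1", "alpha2", "beta1", "beta2")
  if (!is.null(names(theta)) && all(nm %in% names(theta))) theta <- theta[nm]
  setNames(as.numeric(theta), nm)
}

#' Beta shape parameters at given doses
#'
#' @param theta Model parameters, see [model_params()].
#' @param dose Dose(s) in micromolar.
#' @return A tibble with columns `dose`, `a`, `b`.
#' @examples
#' shape_params(model_params(-1.25, 0.004, 1.46, -0.007), 0)
#' @export
shape_params <- function(theta, dose) {
  theta <- as_theta(theta)
  stopifnot(is.numeric(dose), all(is.finite(dose)))
  a <- exp(theta[1] + theta[2] * dose)
  b <- exp(theta[3] + theta[4] * dose)
  bad <- !is.finite(a) | !is.finite(b) | a <= 0 | b <= 0
  if (any(bad)) {
    abort(paste0("shape parameters overflow at dose ", dose[which(bad)[1]]))
  }
  tibble(dose = dose, a = unname(a), b = unname(b))
}

#' Mean response rate at given doses
#'
#' Equals \eqn{1 / (1 + \exp\{(\beta_1-\alpha_1) + (\beta_2-\alpha_2) x\})},
#' the mean \eqn{a/(a+b)} of the Beta distribution at dose \eqn{x}. The
#' curve is strictly monotone in dose whenever \eqn{\beta_2 \neq \alpha_2}.
#'
#' @inheritParams shape_params
#' @return Numeric vector of proportions, strictly inside (0, 1).
#' @export
mean_response <- function(theta, dose) {
  theta <- as_theta(theta)
  stopifnot(is.numeric(dose), all(is.finite(dose)))
  # logistic form: numerically safe for any dose
  unname(plogis(-((theta[3] - theta[1]) + (theta[4] - theta[2]) * dose)))
}

#' Log density of the Beta distribution
#'
#' Thin wrapper around [stats::dbeta()] kept as the single place where the
#' observation density enters the likelihood.
#'
#' @param y Rates strictly inside (0, 1).
#' @param a,b Positive Beta shape parameters.
#' @return Log density values.
#' @export
beta_log_density <- function(y, a, b) {
  if (any(y <= 0 | y >= 1)) {
    abort("rates must lie strictly inside (0, 1); clamp boundary rates first")
  }
  stopifnot(all(a > 0), all(b > 0))
  dbeta(y, a, b, log = TRUE)
}

#' Lethal concentration LCp
#'
#' The dose at which the mean response equals `p`, obtained by inverting the
#' logistic mean-response curve:
#' \eqn{x^* = [\log((1-p)/p) - (\beta_1-\alpha_1)] / (\beta_2-\alpha_2)}.
#' The value may fall outside any experimental dose range; no clipping is
#' applied.
#'
#' @inheritParams shape_params
#' @param p Target response proportion(s) strictly inside (0, 1).
#' @return Dose(s) in micromolar.
#' @examples
#' lcp(model_params(-1.25, 0.004, 1.46, -0.007), 0.5)
#' @export
lcp <- function(theta, p) {
  theta <- as_theta(theta)
  stopifnot(is.numeric(p), all(p > 0), all(p < 1))
  d1 <- theta[3] - theta[1]
  d2 <- theta[4] - theta[2]
  if (d2 == 0) abort("flat response curve: LC_p undefined (beta2 equals alpha2)")
  unname((log((1 - p) / p) - d1) / d2)
}

#' Delta-method gradient of LCp with respect to the model parameters
#'
#' @inheritParams lcp
#' @param p A single target proportion in (0, 1).
#' @return Named numeric vector of length 4: the gradient of [lcp()] with
#'   respect to (alpha1, alpha2, beta1, beta2). Feeds the asymptotic
#'   variance \eqn{c^\top M^{-1} c} used by the c-optimality criterion.
#' @export
lcp_gradient <- function(theta, p) {
  theta <- as_theta(theta)
  stopifnot(length(p) == 1, p > 0, p < 1)
  d2 <- theta[4] - theta[2]
  if (d2 == 0) abort("flat response curve: LC_p undefined (beta2 equals alpha2)")
  xs <- lcp(theta, p)
  c(alpha1 = 1 / d2, alpha2 = xs / d2, beta1 = -1 / d2, beta2 = -xs / d2)
}

#' Derive endpoint response rates from grouped counts
#'
#' Adds the two endpoint rates to a grouped dose-response table: the
#' arrest rate (arrested or dead embryos over all examined) and the aboral
#' radialization rate among presumed survivors (radialized over examined
#' minus arrested). The aboral rate is `NA` for records where every embryo
#' arrested.
#'
#' @param data A data frame with columns `dose_uM`, `n_examined`,
#'   `n_eda_d`, `n_radial` (and optionally `n_normal`).
#' @return The input as a tibble with `arrest_rate` and `aboral_rate`
#'   columns appended.
#' @export
endpoint_rates <- function(data) {
  data <- as_tibble(data)
  need <- c("dose_uM", "n_examined", "n_eda_d", "n_radial")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(data$n_examined == 0)) abort("records with zero embryos examined")
  if (any(data$n_eda_d > data$n_examined)) abort("more arrested embryos than examined")
  if (any(data$n_eda_d < 0 | data$n_radial < 0)) abort("negative counts")
  surv <- data$n_examined - data$n_eda_d
  dplyr::mutate(data,
    arrest_rate = .data$n_eda_d / .data$n_examined,
    aboral_rate = ifelse(surv > 0, .data$n_radial / surv, NA_real_)
  )
}

# pick the rate column for an endpoint, deriving it from counts if absent;
# returns list(rate, n_examined or NULL)
endpoint_rate_column <- function(data, endpoint) {
  endpoint <- match.arg(endpoint, c("arrest", "aboral"))
  col <- paste0(endpoint, "_rate")
  if (!col %in% names(data)) data <- endpoint_rates(data)
  list(rate = data[[col]],
       n_examined = if ("n_examined" %in% names(data)) data$n_examined else NULL)
}

# per-record boundary tolerance; default 1/(2 n_examined), 0.005 fallback
boundary_eps <- function(rate, n_examined = NULL, clamp_epsilon = NULL) {
  eps <- clamp_epsilon %||%
    (if (is.null(n_examined)) rep(0.005, length(rate)) else 1 / (2 * n_examined))
  if (any(eps <= 0 | eps >= 0.5)) abort("clamp epsilon must lie in (0, 0.5)")
  rep_len(eps, length(rate))
}

# continuity clamp for boundary rates
clamp_rates <- function(rate, n_examined = NULL, clamp_epsilon = NULL) {
  eps <- boundary_eps(rate, n_examined, clamp_epsilon)
  pmin(pmax(rate, eps), 1 - eps)
}

# per-record log-likelihood contributions under either boundary treatment:
# "clamp"  - boundary rates moved to eps / 1-eps, Beta density throughout;
# "censor" - rates within eps of a boundary contribute the Beta tail
#            probability P(Y <= eps) or P(Y >= 1 - eps) instead of a density
loglik_records <- function(y, a, b, eps, boundary = c("clamp", "censor")) {
  boundary <- match.arg(boundary)
  if (boundary == "clamp") {
    return(dbeta(pmin(pmax(y, eps), 1 - eps), a, b, log = TRUE))
  }
  out <- numeric(length(y))
  lo <- y <= eps
  hi <- y >= 1 - eps
  mid <- !lo & !hi
  if (any(mid)) out[mid] <- dbeta(y[mid], a[mid], b[mid], log = TRUE)
  if (any(lo)) out[lo] <- beta_tail_log(eps[lo], a[lo], b[lo], lower = TRUE)
  if (any(hi)) out[hi] <- beta_tail_log(1 - eps[hi], a[hi], b[hi], lower = FALSE)
  out
}

# log Beta tail probability with a normal-approximation fallback for the
# extreme shape values pbeta's series cannot handle (it warns and returns
# NaN there); at such shapes a + b is huge and the normal tail is accurate
beta_tail_log <- function(q, a, b, lower) {
  v <- suppressWarnings(pbeta(q, a, b, lower.tail = lower, log.p = TRUE))
  bad <- is.nan(v)
  if (any(bad)) {
    m <- a[bad] / (a[bad] + b[bad])
    s <- sqrt(a[bad] * b[bad] / ((a[bad] + b[bad])^2 * (a[bad] + b[bad] + 1)))
    v[bad] <- stats::pnorm(q[bad], m, pmax(s, 1e-300),
                           lower.tail = lower, log.p = TRUE)
  }
  v
}

#' Log-likelihood of grouped rate data under the Beta regression model
#'
#' Sums the Beta log density of each flask-level rate at its dose-specific
#' shape parameters. Rates exactly 0 or 1 have zero Beta density, so they
#' are clamped into `[eps, 1 - eps]`; by default `eps` is `1/(2 n_examined)`
#' per record (0.005 when counts are unavailable). Aboral records where all
#' embryos arrested carry no rate and are skipped with a warning.
#'
#' @param data Grouped dose-response records: one row per flask with
#'   `dose_uM` and either an endpoint rate column (`arrest_rate` /
#'   `aboral_rate`) or the counts needed to derive it.
#' @param theta Model parameters.
#' @param endpoint `"arrest"` or `"aboral"`.
#' @param clamp_epsilon Optional fixed clamp value in (0, 0.5) overriding
#'   the per-record default.
#' @param boundary How boundary rates enter the likelihood: `"clamp"`
#'   (default here) replaces them by `eps` / `1 - eps` and uses the
#'   density; `"censor"` gives them the Beta tail probability mass
#'   `P(Y <= eps)` or `P(Y >= 1 - eps)` instead.
#' @return The log-likelihood (a scalar).
#' @export
beta_loglik <- function(data, theta, endpoint = c("arrest", "aboral"),
                        clamp_epsilon = NULL, boundary = c("clamp", "censor")) {
  endpoint <- match.arg(endpoint)
  boundary <- match.arg(boundary)
  if (nrow(data) == 0) abort("no data records")
  rc <- endpoint_rate_column(data, endpoint)
  keep <- !is.na(rc$rate)
  if (!all(keep)) {
    warn(sprintf("%d record(s) with undefined %s rate skipped", sum(!keep), endpoint))
  }
  if (!any(keep)) abort("no records with a defined rate")
  eps <- boundary_eps(rc$rate[keep], rc$n_examined[keep], clamp_epsilon)
  sp <- shape_params(theta, data$dose_uM[keep])
  sum(loglik_records(rc$rate[keep], sp$a, sp$b, eps, boundary))
}

#' Fit the Beta regression model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [beta_loglik()] from a starting
#' value plus a few jittered restarts; the best converged run wins. The
#' covariance of the estimates is the inverse of the numerical negative
#' Hessian at the optimum (omitted with a warning if singular). The default
#' start is obtained by regressing the empirical logit of the clamped rates
#' on dose, which pins down the two mean-curve contrasts, and splitting
#' them symmetrically between the alpha and beta intercepts/slopes.
#'
#' @inheritParams beta_loglik
#' @param init Optional starting parameter vector.
#' @param restarts Number of additional jittered starts (default 5).
#' @param seed Seed for the jitter (default 1).
#' @param boundary Boundary-rate treatment; the fitter defaults to
#'   `"censor"` because maximizing the clamped density is inconsistent
#'   when boundary rates are common (the clamp creates an artificial
#'   spike at `1 - eps` that a low-precision Beta can chase); the
#'   censored likelihood has no such artifact.
#' @return An object of class `beta_fit`: a list with `estimates`,
#'   `loglik`, `aic` (`2*4 - 2*loglik`), `vcov`, `converged`,
#'   `clamp_epsilon`, `endpoint`, `n`. Supports [tidy()], [glance()] and
#'   `print()`.
#' @export
fit_beta_mle <- function(data, endpoint = c("arrest", "aboral"), init = NULL,
                         clamp_epsilon = NULL, restarts = 5, seed = 1,
                         boundary = c("censor", "clamp")) {
  endpoint <- match.arg(endpoint)
  boundary <- match.arg(boundary)
  rc <- endpoint_rate_column(data, endpoint)
  keep <- !is.na(rc$rate)
  dose <- data$dose_uM[keep]
  if (length(unique(dose)) < 2) abort("need at least 2 distinct dose levels with defined rates")
  y <- rc$rate[keep]
  eps <- boundary_eps(y, rc$n_examined[keep], clamp_epsilon)

  if (is.null(init)) {
    # logit regression identifies (beta1-alpha1, beta2-alpha2); split evenly
    co <- coef(lm(qlogis(pmin(pmax(y, eps), 1 - eps)) ~ dose))
    init <- c(co[1] / 2, co[2] / 2, -co[1] / 2, -co[2] / 2)
  }
  init <- as_theta(init)

  negll <- function(th) {
    a <- exp(th[1] + th[2] * dose); b <- exp(th[3] + th[4] * dose)
    if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) return(1e10)
    v <- -sum(suppressWarnings(loglik_records(y, a, b, eps, boundary)))
    if (!is.finite(v)) 1e10 else v
  }

  starts <- list(init)
  if (restarts > 0) {
    set.seed(seed)
    for (i in seq_len(restarts)) starts[[i + 1]] <- init + rnorm(4, sd = 0.5)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negll, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed")

  converged <- best$convergence == 0
  if (!converged) warn("MLE search did not converge; estimates are the best found")
  hess <- tryCatch(optim(best$par, negll, method = "BFGS", hessian = TRUE,
                         control = list(maxit = 1))$hessian, error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
      warn("singular or indefinite Hessian: covariance omitted")
      vcov <- NULL
    } else {
      vcov <- (vcov + t(vcov)) / 2
      dimnames(vcov) <- list(names(init), names(init))
    }
  }
  ll <- -best$value
  eps_used <- clamp_epsilon %||% NA_real_
  structure(list(
    estimates = setNames(best$par, names(init)),
    loglik = ll, aic = 2 * 4 - 2 * ll, vcov = vcov, converged = converged,
    clamp_epsilon = eps_used, boundary = boundary, endpoint = endpoint,
    n = length(y)
  ), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta dose-response fit (", x$endpoint, " endpoint, n = ", x$n, ")\n", sep = "")
  print(round(x$estimates, 5))
  cat("logLik:", format(x$loglik, digits = 7), " AIC:", format(x$aic, digits = 7),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @rdname fit_beta_mle
#' @param x A `beta_fit` object.
#' @param ... Unused.
#' @method tidy beta_fit
#' @export
tidy.beta_fit <- function(x, ...) {
  se <- if (is.null(x$vcov)) rep(NA_real_, 4) else sqrt(diag(x$vcov))
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(se))
}

#' @rdname fit_beta_mle
#' @method glance beta_fit
#' @export
glance.beta_fit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, nobs = x$n, converged = x$converged)
}

#' Read / write grouped dose-response data
#'
#' CSV dialect: header `dose_uM,n_examined,n_normal,n_eda_d,n_radial`, one
#' row per flask, dot decimal separator.
#'
#' @param path File path.
#' @return `read_dose_data()` returns a tibble with the derived endpoint
#'   rates appended.
#' @export
read_dose_data <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  endpoint_rates(as_tibble(read.csv(path)))
}

#' @rdname read_dose_data
#' @param data A grouped dose-response data frame.
#' @export
write_dose_data <- function(data, path) {
  cols <- intersect(c("dose_uM", "n_examined", "n_normal", "n_eda_d", "n_radial"),
                    names(data))
  write.csv(as.data.frame(data[cols]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
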