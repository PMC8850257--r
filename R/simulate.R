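#' Simulate grouped dose-response data from the Beta regression model
#'
#' Draws one response rate per flask from `Beta(a(x), b(x))` at each dose,
#' reproducing the sigmoidal mean and dose-dependent (inhomogeneous)
#' variance `a b / ((a+b)^2 (a+b+1))` of the model. Counts are synthesized
#' consistently with the drawn rate (`round(rate * n_examined)`); set
#' `binomial_counts = TRUE` to thin the latent rate binomially instead.
#' With `zero_noise = TRUE` the rates are set exactly to the mean-response
#' curve, a degenerate mode useful for identifiability checks.
#'
#' @param theta Model parameters.
#' @param doses Dose levels (micromolar), or a [design()] whose doses are
#'   used.
#' @param flasks_per_dose Number of flasks per dose, a single count or one
#'   per dose.
#' @param endpoint Which endpoint the rate represents: `"arrest"` (rate
#'   among all examined embryos) or `"aboral"` (rate among survivors; the
#'   simulated records then carry no arrested embryos).
#' @param n_examined Embryos phenotyped per flask (default 100).
#' @param seed Seed making the draw reproducible (default 1).
#' @param binomial_counts Thin the latent rate with a binomial draw.
#' @param zero_noise Replace the Beta draw by the model mean.
#' @return A tibble, one row per flask: `dose_uM`, `flask`, `n_examined`,
#'   `n_normal`, `n_eda_d`, `n_radial` and the endpoint rate column
#'   carrying the exact simulated rate.
#' @examples
#' simulate_rates(model_params(-1.25, 0.004, 1.46, -0.007),
#'                doses = c(0, 250, 500, 1000), flasks_per_dose = 3)
#' @export
simulate_rates <- function(theta, doses, flasks_per_dose, endpoint = c("arrest", "aboral"),
                           n_examined = 100, seed = 1,
                           binomial_counts = FALSE, zero_noise = FALSE) {
  endpoint <- match.arg(endpoint)
  if (inherits(doses, "dose_design") || is.data.frame(doses)) doses <- doses$dose
  stopifnot(all(flasks_per_dose >= 1))
  flasks <- rep_len(flasks_per_dose, length(doses))
  dose <- rep(doses, flasks)
  set.seed(seed)
  sp <- shape_params(theta, dose)
  rate <- if (zero_noise) mean_response(theta, dose) else rbeta(length(dose), sp$a, sp$b)
  n_aff <- if (binomial_counts) rbinom(length(dose), n_examined, rate)
           else as.integer(round(rate * n_examined))
  out <- tibble(
    dose_uM = dose,
    flask = unlist(lapply(flasks, seq_len)),
    n_examined = as.integer(n_examined),
    n_normal = as.integer(n_examined - n_aff),
    n_eda_d = if (endpoint == "arrest") n_aff else 0L,
    n_radial = if (endpoint == "aboral") n_aff else 0L
  )
  out[[paste0(endpoint, "_rate")]] <- rate
  out
}

#' @importFrom stats rbinom
NULL

#' Parameter-recovery experiment for a design
#'
#' Repeated simulate-and-fit cycles quantifying how well a design supports
#' inference: per-parameter bias and RMSE of the MLEs, empirical variance
#' of the plug-in LCp estimate, and its delta-method prediction
#' \eqn{c^\top M(\xi,\theta)^{-1} c / n} under the generating parameters.
#' The design is first rounded to `n_total` flasks with
#' [round_to_exact()].
#'
#' @param theta Generating ("true") model parameters.
#' @param x A [design()].
#' @param n_total Total number of flasks per replicate.
#' @param replicates Number of simulate-and-fit replicates.
#' @param p LCp level tracked (default 0.5).
#' @param endpoint Endpoint simulated (default `"arrest"`).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param restarts Jittered restarts per fit (default 0: the data-driven
#'   start is reliable at these sample sizes).
#' @return A list: `params` (tibble with bias, RMSE and empirical coverage
#'   of the nominal 95% Wald interval per parameter), `lcp` (tibble with
#'   the empirical variance of the LCp estimate and its delta-method
#'   prediction), `n_failed` (replicates discarded for non-convergence),
#'   and `estimates` (per-replicate tidy estimates).
#' @export
mle_recovery_experiment <- function(theta, x, n_total, replicates,
                                    p = 0.5, endpoint = "arrest",
                                    seed = 1, restarts = 0) {
  theta <- as_theta(theta)
  alloc <- round_to_exact(x, n_total)
  ests <- matrix(NA_real_, replicates, 4)
  ses <- matrix(NA_real_, replicates, 4)
  lcps <- rep(NA_real_, replicates)
  ok <- logical(replicates)
  for (r in seq_len(replicates)) {
    dat <- simulate_rates(theta, alloc$dose, alloc$n, endpoint = endpoint,
                          seed = seed + r)
    fit <- tryCatch(
      fit_beta_mle(dat, endpoint = endpoint, restarts = restarts, seed = seed + r),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    ok[r] <- TRUE
    ests[r, ] <- fit$estimates
    if (!is.null(fit$vcov)) ses[r, ] <- sqrt(diag(fit$vcov))
    lcps[r] <- tryCatch(lcp(fit$estimates, p), error = function(e) NA_real_)
  }
  if (!any(ok)) abort("no replicate converged")
  e <- ests[ok, , drop = FALSE]
  s <- ses[ok, , drop = FALSE]
  covered <- abs(sweep(e, 2, theta)) <= 1.96 * s
  params <- tibble(
    term = names(theta),
    truth = unname(theta),
    bias = colMeans(e) - theta,
    rmse = sqrt(colMeans(sweep(e, 2, theta)^2)),
    coverage = colMeans(covered)
  )
  M <- design_information(x, theta)
  cc <- lcp_gradient(theta, p)
  pred_var <- drop(crossprod(cc, solve(M, cc))) / n_total
  lcp_ok <- lcps[ok]
  lcp_tbl <- tibble(
    p = p, truth = lcp(theta, p),
    mean_estimate = mean(lcp_ok, na.rm = TRUE),
    empirical_variance = var(lcp_ok, na.rm = TRUE),
    delta_method_variance = pred_var
  )
  list(params = params, lcp = lcp_tbl, n_failed = sum(!ok),
       estimates = as_tibble(`colnames<-`(e, names(theta))))
}
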