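#' A finite prior over nominal parameter sets
#'
#' Robust ("pseudo-Bayesian") design criteria average a criterion over a
#' small collection of plausible parameter vectors with given
#' probabilities. The prior is a tibble with one row per parameter set.
#'
#' @param sets A list of parameter vectors (each as in [model_params()]),
#'   or a data frame / matrix with columns alpha1, alpha2, beta1, beta2.
#' @param probs Probabilities, one per set; default equal. Sets with zero
#'   probability are allowed and simply carried along.
#' @param labels Optional set labels.
#' @return A `parameter_prior` tibble with columns `set`, `alpha1`,
#'   `alpha2`, `beta1`, `beta2`, `prob`.
#' @examples
#' parameter_prior(list(model_params(-1.25, 0.004, 1.46, -0.007)))
#' @export
parameter_prior <- function(sets, probs = NULL, labels = NULL) {
  if (is.data.frame(sets) || is.matrix(sets)) {
    m <- as.matrix(as.data.frame(sets)[, c("alpha1", "alpha2", "beta1", "beta2")])
  } else {
    m <- do.call(rbind, lapply(sets, as_theta))
  }
  k <- nrow(m)
  probs <- probs %||% rep(1 / k, k)
  if (length(probs) != k || any(probs < 0)) abort("invalid prior probabilities")
  if (abs(sum(probs) - 1) > 1e-9) abort("prior probabilities must sum to 1")
  if (!any(probs > 0)) abort("at least one prior probability must be positive")
  out <- tibble(set = labels %||% paste0("theta_", seq_len(k)),
                alpha1 = m[, 1], alpha2 = m[, 2],
                beta1 = m[, 3], beta2 = m[, 4],
                prob = as.numeric(probs))
  class(out) <- c("parameter_prior", class(out))
  out
}

# prior rows as a list of theta vectors (dropping zero-probability sets
# when `positive_only`)
prior_thetas <- function(prior, positive_only = FALSE) {
  pr <- as.data.frame(prior)
  if (positive_only) pr <- pr[pr$prob > 0, , drop = FALSE]
  lapply(seq_len(nrow(pr)), function(i)
    model_params(pr$alpha1[i], pr$alpha2[i], pr$beta1[i], pr$beta2[i]))
}

#' Nominal parameter sets from the sea urchin trimethoprim study
#'
#' The six published nominal parameter vectors per endpoint (the MLE set
#' from an earlier experiment plus five plausible departures), with equal
#' probabilities 1/6. These are the study conditions under which the
#' robust and dual-objective designs in this package are constructed.
#'
#' @param endpoint `"arrest"` (developmental arrest/death, dose range
#'   0-1000 uM) or `"aboral"` (aboral radialization among survivors, dose
#'   range 0-450 uM).
#' @return A [parameter_prior()] with six rows.
#' @examples
#' nominal_priors("arrest")
#' @export
nominal_priors <- function(endpoint = c("arrest", "aboral")) {
  endpoint <- match.arg(endpoint)
  sets <- switch(endpoint,
    arrest = list(
      c(-1.250, 0.004, 1.460, -0.007),
      c(-1.500, 0.007, 1.700, -0.010),
      c(-1.750, 0.010, 2.000, -0.013),
      c(-1.500, 0.004, 1.460, -0.007),
      c(-1.000, 0.004, 2.460, -0.007),
      c(-1.000, 0.006, 3.460, -0.010)),
    aboral = list(
      c(1.513, -0.013, 6.103, -0.034),
      c(0.900, -0.021, 6.103, -0.052),
      c(0.900, -0.021, 8.930, -0.053),
      c(0.900, -0.021, 9.700, -0.060),
      c(1.100, -0.015, 9.700, -0.072),
      c(1.500, -0.015, 11.500, -0.065)))
  sets <- lapply(sets, function(v) model_params(v[1], v[2], v[3], v[4]))
  parameter_prior(sets, labels = paste0("theta_", 1:6, substr(endpoint, 1, 1)))
}

#' Read / write a prior as JSON
#'
#' JSON layout: `{"sets": [[a1,a2,b1,b2], ...], "probs": [...]}`. Between
#' one and six sets are accepted; omitted probabilities default to equal.
#'
#' @param path File path.
#' @return `read_prior()` returns a [parameter_prior()].
#' @export
read_prior <- function(path) {
  if (!file.exists(path)) abort(paste("prior file not found:", path))
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(j$sets)) abort("prior JSON must contain a 'sets' field")
  sets <- if (is.matrix(j$sets)) lapply(seq_len(nrow(j$sets)), function(i) j$sets[i, ])
          else j$sets
  sets <- lapply(sets, function(v) {
    if (length(v) != 4) abort("each prior set must have 4 numbers")
    model_params(v[1], v[2], v[3], v[4])
  })
  parameter_prior(sets, probs = j$probs)
}

#' @rdname read_prior
#' @param prior A `parameter_prior`.
#' @export
write_prior <- function(prior, path) {
  m <- as.matrix(as.data.frame(prior)[, c("alpha1", "alpha2", "beta1", "beta2")])
  jsonlite::write_json(
    list(sets = unname(lapply(seq_len(nrow(m)), function(i) m[i, ])),
         probs = prior$prob),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
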