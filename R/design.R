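#' Approximate designs on a dose interval
#'
#' An approximate design is a probability measure on the dose interval:
#' finitely many support doses with positive weights summing to one. It is
#' stored as a tibble with columns `dose` and `weight` plus an `interval`
#' attribute, so all the usual dplyr verbs apply.
#'
#' @param dose Strictly increasing support doses (micromolar).
#' @param weight Positive weights summing to 1.
#' @param interval Dose interval `c(lo, hi)`; defaults to the dose range.
#' @return A `dose_design` tibble.
#' @examples
#' design(c(0, 250, 300, 1000), c(0.341, 0.032, 0.375, 0.252))
#' @export
design <- function(dose, weight, interval = range(dose)) {
  stopifnot(length(dose) == length(weight), length(dose) >= 1)
  if (is.unsorted(dose, strictly = TRUE)) abort("support doses must be strictly increasing")
  if (any(weight <= 0)) abort("all design weights must be positive")
  if (abs(sum(weight) - 1) > 1e-12) abort("design weights must sum to 1")
  if (length(interval) != 2 || interval[1] >= interval[2]) {
    abort("`interval` must be c(lo, hi) with lo < hi")
  }
  if (any(dose < interval[1] - 1e-9) || any(dose > interval[2] + 1e-9)) {
    abort("support doses must lie within the dose interval")
  }
  out <- tibble(dose = as.numeric(dose), weight = as.numeric(weight))
  attr(out, "interval") <- as.numeric(interval)
  class(out) <- c("dose_design", class(out))
  out
}

#' @rdname design
#' @param x A data frame with `dose` and `weight` columns.
#' @export
as_dose_design <- function(x, interval = NULL) {
  if (inherits(x, "dose_design") && is.null(interval)) return(x)
  design(x$dose, x$weight / sum(x$weight), interval %||% range(x$dose))
}

#' @rdname design
#' @export
design_interval <- function(x) attr(x, "interval") %||% range(x$dose)

#' @export
print.dose_design <- function(x, ...) {
  iv <- design_interval(x)
  cat(sprintf("Approximate design on [%g, %g] uM, %d support point(s)\n",
              iv[1], iv[2], nrow(x)))
  NextMethod()
}

#' Uniform design with k equally spaced doses
#'
#' `k` equally spaced doses spanning the interval (both endpoints included)
#' with weight `1/k` each.
#'
#' @param k Number of doses (at least 2).
#' @param interval Dose interval `c(lo, hi)`.
#' @return A `dose_design`.
#' @examples
#' uniform_design(11, c(0, 1000))
#' @export
uniform_design <- function(k, interval) {
  if (k < 2) abort("a uniform design needs at least 2 doses")
  design(seq(interval[1], interval[2], length.out = k), rep(1 / k, k), interval)
}

#' Merge near-duplicate support points and drop negligible weights
#'
#' Adjacent doses closer than `dose_tol` are merged at their weight-weighted
#' mean; weights below `weight_floor` are removed and the rest renormalized.
#' Genuinely separated support points (further apart than `dose_tol`) are
#' never merged.
#'
#' @param x A `dose_design`.
#' @param dose_tol Merge tolerance in micromolar (default 1).
#' @param weight_floor Weights below this are dropped (default 1e-4).
#' @return A `dose_design`.
#' @export
collapse_support <- function(x, dose_tol = 1, weight_floor = 1e-4) {
  x <- as_dose_design(x, design_interval(x))
  d <- x$dose; w <- x$weight
  keep <- w >= weight_floor
  if (sum(keep) < 1) abort("all weights below the floor")
  d <- d[keep]; w <- w[keep] / sum(w[keep])
  # group adjacent points within dose_tol
  grp <- cumsum(c(TRUE, diff(d) > dose_tol))
  nd <- tapply(d * w, grp, sum) / tapply(w, grp, sum)
  nw <- tapply(w, grp, sum)
  if (length(nd) < 2) abort("design collapsed to fewer than 2 support points")
  design(as.numeric(nd), as.numeric(nw), design_interval(x))
}

#' Round an approximate design to an exact allocation
#'
#' Apportions `n_total` experimental units to the support doses. Every
#' support dose receives at least one unit; the base allocation is the
#' floor of `weight * n_total` and remaining units are assigned either by
#' largest remainder (default) or, when a criterion specification is
#' supplied, greedily to maximize the criterion of the rounded design.
#' Ties break toward the lower dose.
#'
#' @param x A `dose_design`.
#' @param n_total Total number of experimental units.
#' @param spec Optional [criterion_spec()]; when given, remainders are
#'   placed to maximize the criterion.
#' @return A tibble with columns `dose`, `weight`, `n`.
#' @examples
#' d <- design(c(0, 250, 300, 1000), c(0.341, 0.032, 0.375, 0.252))
#' round_to_exact(d, 1000)
#' @export
round_to_exact <- function(x, n_total, spec = NULL) {
  x <- as_dose_design(x, design_interval(x))
  k <- nrow(x)
  if (n_total < k) abort("n_total smaller than the number of support points")
  n <- pmax(1L, floor(x$weight * n_total))
  while (sum(n) > n_total) {            # rare: the >=1 guarantee overshot
    i <- which(n > 1L)
    j <- i[which.max(n[i] - x$weight * n_total)]
    n[j] <- n[j] - 1L
  }
  while (sum(n) < n_total) {
    if (is.null(spec)) {
      rem <- x$weight * n_total - n
      j <- which(rem == max(rem))[1]    # ties: lowest dose (doses are sorted)
    } else {
      cand <- vapply(seq_len(k), function(i) {
        ni <- n; ni[i] <- ni[i] + 1L
        criterion_value(design(x$dose, ni / sum(ni), design_interval(x)), spec)
      }, numeric(1))
      j <- which(cand == max(cand))[1]
    }
    n[j] <- n[j] + 1L
  }
  tibble(dose = x$dose, weight = x$weight, n = as.integer(n))
}

#' Read / write a design CSV
#'
#' Dialect: header `dose_uM,weight`; values round-trip to 12 significant
#' digits.
#'
#' @param path File path.
#' @param interval Optional interval for the design read back.
#' @return `read_design()` returns a `dose_design`.
#' @export
read_design <- function(path, interval = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- read.csv(path)
  if (!all(c("dose_uM", "weight") %in% names(df))) {
    abort("design CSV needs columns dose_uM, weight")
  }
  design(df$dose_uM, df$weight / sum(df$weight), interval %||% range(df$dose_uM))
}

#' @rdname read_design
#' @param x A `dose_design`.
#' @export
write_design <- function(x, path) {
  df <- data.frame(dose_uM = signif(x$dose, 12), weight = signif(x$weight, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
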