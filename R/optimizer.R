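# ---- internal machinery shared by the exchange algorithm and the public
# ---- weight optimizer ------------------------------------------------------

# per-set constants of a criterion spec
spec_sets <- function(spec) {
  pr <- spec$prior[spec$prior$prob > 0, ]
  thetas <- prior_thetas(pr)
  list(thetas = thetas,
       probs = pr$prob,
       cs = if (spec$kind != "D") lapply(thetas, lcp_gradient, p = spec$p) else NULL,
       kind = spec$kind, W = spec$W)
}

# information matrices per set from per-set support-info rows (k_sup x 16)
core_M <- function(Gsup, w) {
  lapply(Gsup, function(g) matrix(colSums(g * w), 4, 4))
}

# criterion value (maximization scale) from per-set matrices
core_crit <- function(ss, Ms) {
  val <- 0
  for (k in seq_along(ss$thetas)) {
    ld <- determinant(Ms[[k]], logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    ld <- as.numeric(ld$modulus)
    if (ss$kind == "D") { val <- val + ss$probs[k] * ld; next }
    cv <- tryCatch(drop(crossprod(ss$cs[[k]], solve(Ms[[k]], ss$cs[[k]]))),
                   error = function(e) Inf)
    if (!is.finite(cv) || cv <= 0) return(-Inf)
    val <- val + switch(ss$kind,
      cLCp = -ss$probs[k] * log(cv),
      compound = ss$probs[k] * (ss$W * ld / 4 - (1 - ss$W) * log(cv)))
  }
  val
}

# normalized directional quantity phi at the rows of Grows (list per set);
# satisfies sum_i w_i phi(x_i) = 1 over the support of any nonsingular design
core_phi <- function(ss, Grows, Ms) {
  ph <- numeric(nrow(Grows[[1]]))
  for (k in seq_along(ss$thetas)) {
    Mi <- solve(Ms[[k]])
    trv <- drop(Grows[[k]] %*% as.vector(Mi))
    if (ss$kind == "D") { ph <- ph + ss$probs[k] * trv / 4; next }
    u <- drop(Mi %*% ss$cs[[k]])
    qv <- drop(Grows[[k]] %*% as.vector(tcrossprod(u))) / drop(crossprod(ss$cs[[k]], u))
    ph <- ph + switch(ss$kind,
      cLCp = ss$probs[k] * qv,
      compound = ss$probs[k] * (ss$W * trv / 4 + (1 - ss$W) * qv))
  }
  ph
}

# weight optimization over a fixed support: damped multiplicative updates to
# a relative criterion change below `reltol`, then vertex-exchange passes
# that equalize phi across the support (simplex KKT polish)
core_optw <- function(ss, Gsup, w, reltol = 1e-9, kkt_tol = 1e-11,
                      max_outer = 400) {
  crit_w <- function(w) core_crit(ss, core_M(Gsup, w))
  cur <- crit_w(w)
  for (outer in seq_len(max_outer)) {
    # multiplicative passes
    for (it in 1:100) {
      ph <- core_phi(ss, Gsup, core_M(Gsup, w))
      gamma <- 1
      repeat {
        wn <- w * ph^gamma
        wn <- wn / sum(wn)
        new <- crit_w(wn)
        if (new >= cur - 1e-14 || gamma < 1e-3) break
        gamma <- gamma / 2
      }
      done <- abs(new - cur) <= reltol * (abs(cur) + 1e-12)
      w <- wn; cur <- new
      if (done) break
    }
    # vertex exchange: move mass from the lowest-phi to the highest-phi point
    ph <- core_phi(ss, Gsup, core_M(Gsup, w))
    jb <- which.max(ph); jw <- which.min(ph)
    if (ph[jb] - ph[jw] < kkt_tol) break
    f <- function(al) { w2 <- w; w2[jb] <- w2[jb] + al; w2[jw] <- w2[jw] - al; crit_w(w2) }
    al <- optimize(f, c(0, w[jw]), maximum = TRUE)$maximum
    cand <- f(al)
    if (cand > cur) {
      w[jb] <- w[jb] + al; w[jw] <- w[jw] - al
      w[w < 0] <- 0; w <- w / sum(w)
      cur <- crit_w(w)
    } else break
  }
  list(w = w, value = cur)
}

#' Optimize design weights over a fixed support
#'
#' Maximizes the criterion over the probability simplex for the given
#' support doses. All three criteria are concave in the weights; the
#' solver uses damped multiplicative updates followed by a vertex-exchange
#' polish of the simplex KKT conditions (the sensitivity is equal, within
#' tolerance, across support points with positive weight).
#'
#' @param support Distinct support doses (at least 2).
#' @param spec A [criterion_spec()].
#' @param w_init Optional starting weights (default equal).
#' @param reltol Relative criterion-change tolerance (default 1e-9).
#' @return A [design()] on the support with optimized weights. Support
#'   points driven to (numerically) zero weight are kept with weight
#'   `1e-12`-truncated; use [collapse_support()] to drop them.
#' @export
optimize_weights <- function(support, spec, w_init = NULL, reltol = 1e-9) {
  support <- sort(unique(as.numeric(support)))
  if (length(support) < 2) abort("need at least 2 distinct support doses")
  ss <- spec_sets(spec)
  Gsup <- lapply(ss$thetas, pinfo_cols, xs = support)
  w <- w_init %||% rep(1 / length(support), length(support))
  w <- w / sum(w)
  res <- core_optw(ss, Gsup, w, reltol = reltol)
  w <- pmax(res$w, 1e-12)
  design(support, w / sum(w), spec$interval)
}

#' Find an optimal approximate design by a grid exchange algorithm
#'
#' Constructs the optimal approximate design for any [criterion_spec()] on
#' an equally spaced dose grid. The iteration starts from four equally
#' spaced grid points with equal weights and alternates (i) full weight
#' optimization over the current support, (ii) deletion of support points
#' with weight below `weight_floor`, and (iii) addition of the grid point
#' with maximal [sensitivity()] (ties break toward the lowest dose). It
#' stops when the maximum sensitivity over the whole grid is at most
#' `tol` - the general-equivalence-theorem certificate of optimality - or
#' when `max_iter` exchanges have been performed. Support points that end
#' up closer than `dose_tol` are merged at their weight-weighted mean and
#' the certificate is re-evaluated on the merged design.
#'
#' @param spec A [criterion_spec()].
#' @param grid_step Grid resolution in micromolar (default 1).
#' @param tol Sensitivity tolerance for convergence (default 1e-3).
#' @param max_iter Maximum number of exchange iterations (default 500).
#' @param weight_floor Support weights below this are dropped (default 1e-4).
#' @param dose_tol Merge tolerance for the final support (default 1 uM).
#' @param collapse Merge near-duplicate support points at the end
#'   (default TRUE).
#' @return A `design_opt` object: list with `design` (a [design()]),
#'   `criterion_value`, `max_sensitivity`, `iterations`, `converged`,
#'   `grid = c(lo, hi, step)`, `spec` and a per-iteration `trace` tibble.
#'   Supports [tidy()], [glance()], `print()` and [autoplot()].
#' @examples
#' \donttest{
#' spec <- criterion_spec("D", nominal_priors("arrest"), interval = c(0, 1000))
#' res <- find_optimal_design(spec, grid_step = 10)
#' res$design
#' }
#' @export
find_optimal_design <- function(spec, grid_step = 1, tol = 1e-3, max_iter = 500,
                                weight_floor = 1e-4, dose_tol = 1,
                                collapse = TRUE) {
  grid <- seq(spec$interval[1], spec$interval[2], by = grid_step)
  if (abs(grid[length(grid)] - spec$interval[2]) > 1e-9) {
    grid <- c(grid, spec$interval[2])
  }
  n <- length(grid)
  if (n < 8) abort("grid must have at least 8 points; decrease `grid_step`")
  ss <- spec_sets(spec)
  G <- lapply(ss$thetas, pinfo_cols, xs = grid)   # n x 16 per set

  idx <- unique(round(seq(1, n, length.out = 4)))
  w <- rep(1 / length(idx), length(idx))
  if (!is.finite(core_crit(ss, core_M(lapply(G, function(g) g[idx, , drop = FALSE]), w)))) {
    abort("singular starting design: the criterion is degenerate on this grid")
  }

  trace <- vector("list", max_iter)
  max_sens <- Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    Gsup <- lapply(G, function(g) g[idx, , drop = FALSE])
    res <- core_optw(ss, Gsup, w)
    w <- res$w
    keep <- w > weight_floor
    if (sum(keep) >= 2) {
      idx <- idx[keep]
      w <- w[keep] / sum(w[keep])
    }
    Gsup <- lapply(G, function(g) g[idx, , drop = FALSE])
    Ms <- core_M(Gsup, w)
    s <- core_phi(ss, G, Ms) - 1
    if (ss$kind == "D") s <- 4 * s   # match the tr(M^-1 m) - 4 convention
    max_sens <- max(s)
    trace[[iter]] <- tibble(iteration = iter, criterion = core_crit(ss, Ms),
                            max_sensitivity = max_sens, support = length(idx))
    if (max_sens <= tol) { converged <- TRUE; break }
    j <- which.max(s)                  # first maximum = lowest dose
    if (j %in% idx) break              # cannot improve by exchange on this grid
    # line search for the mass of the entering point, then merge
    Gj <- lapply(G, function(g) g[c(idx, j), , drop = FALSE])
    f <- function(al) core_crit(ss, core_M(Gj, c((1 - al) * w, al)))
    al <- optimize(f, c(0, 1), maximum = TRUE)$maximum
    idx <- c(idx, j); w <- c((1 - al) * w, al)
    o <- order(idx); idx <- idx[o]; w <- w[o]
  }

  d <- design(grid[idx], w / sum(w), spec$interval)
  if (collapse) {
    d2 <- tryCatch(collapse_support(d, dose_tol, weight_floor), error = function(e) d)
    if (!identical(d2$dose, d$dose)) {
      # re-polish the merged weights and re-certify off-grid
      d2 <- optimize_weights(d2$dose, spec, w_init = d2$weight)
      d2 <- tryCatch(collapse_support(d2, dose_tol, weight_floor), error = function(e) d2)
    }
    d <- d2
  }
  s_final <- sensitivity(grid, d, spec)
  max_sens <- max(s_final)
  converged <- max_sens <= tol

  structure(list(
    design = d,
    criterion_value = criterion_value(d, spec),
    max_sensitivity = max_sens,
    iterations = iter,
    converged = converged,
    grid = c(lo = spec$interval[1], hi = spec$interval[2], step = grid_step),
    tol = tol,
    spec = spec,
    trace = dplyr::bind_rows(trace[seq_len(iter)])
  ), class = "design_opt")
}

#' @export
print.design_opt <- function(x, ...) {
  cat("Optimal design search (", x$spec$kind, " criterion)\n", sep = "")
  print(x$design)
  cat(sprintf("criterion %.6f | max sensitivity %.3g | %d iteration(s) | converged: %s\n",
              x$criterion_value, x$max_sensitivity, x$iterations, x$converged))
  invisible(x)
}

#' @rdname find_optimal_design
#' @param x A `design_opt` object.
#' @param ... Unused.
#' @method tidy design_opt
#' @export
tidy.design_opt <- function(x, ...) {
  tibble(dose = x$design$dose, weight = x$design$weight)
}

#' @rdname find_optimal_design
#' @method glance design_opt
#' @export
glance.design_opt <- function(x, ...) {
  tibble(criterion = x$spec$kind,
         criterion_value = x$criterion_value,
         max_sensitivity = x$max_sensitivity,
         support_points = nrow(x$design),
         iterations = x$iterations,
         converged = x$converged)
}

#' @rdname find_optimal_design
#' @param object A `design_opt` object.
#' @param n_grid Number of doses at which to draw the sensitivity curve.
#' @method autoplot design_opt
#' @export
autoplot.design_opt <- function(object, n_grid = 401, ...) {
  xs <- seq(object$spec$interval[1], object$spec$interval[2], length.out = n_grid)
  df <- tibble(dose = xs, sensitivity = sensitivity(xs, object$design, object$spec))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$sensitivity)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble(dose = object$design$dose,
                                      sensitivity = sensitivity(object$design$dose,
                                                                object$design, object$spec)),
                        colour = "red") +
    ggplot2::labs(x = "dose (uM)", y = "sensitivity",
                  title = "Equivalence-theorem sensitivity",
                  subtitle = "optimal designs touch 0 exactly at their support points") +
    ggplot2::theme_minimal()
}
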