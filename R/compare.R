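#' The ad-hoc empirical designs of the sea urchin study
#'
#' The implemented laboratory design had 11 distinct trimethoprim
#' concentration levels on \[0, 1000\] uM (the arrest endpoint); the design
#' for the aboral endpoint is its restriction to \[0, 450\] uM with the
#' weights renormalized, because past 450 uM every embryo arrests and the
#' aboral rate is unobservable. The packaged fixture is a curated
#' emulation of the published dose pattern with equal weights per level
#' (the per-level replicate counts are not reliably recoverable from the
#' publication); supply your own design CSV to override.
#'
#' @param path Optional path to a design CSV (`dose_uM,weight`) replacing
#'   the packaged fixture for the full-range design.
#' @param cutoff Upper dose limit of the restricted design (default 450).
#' @return A list with elements `xi_o1` (full range) and `xi_o2`
#'   (restricted, renormalized), both [design()]s.
#' @export
adhoc_designs <- function(path = NULL, cutoff = 450) {
  path <- path %||% system.file("extdata", "xi_o1.csv", package = "betadose")
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    abort("ad-hoc design fixture not found; pass `path` or reinstall the package (inst/extdata/xi_o1.csv)")
  }
  xi_o1 <- read_design(path)
  keep <- xi_o1$dose <= cutoff
  if (sum(keep) < 2) abort("fewer than 2 doses at or below the cutoff")
  xi_o2 <- design(xi_o1$dose[keep], xi_o1$weight[keep] / sum(xi_o1$weight[keep]),
                  c(design_interval(xi_o1)[1], cutoff))
  list(xi_o1 = xi_o1, xi_o2 = xi_o2)
}

# parse criterion labels like "D", "cLC10", "cLC25"
parse_criterion_label <- function(lbl) {
  if (identical(lbl, "D")) return(list(kind = "D", p = NULL))
  m <- regmatches(lbl, regexec("^cLC([0-9]+)$", lbl))[[1]]
  if (length(m) < 2) abort(paste("unknown criterion label:", lbl))
  list(kind = "cLCp", p = as.numeric(m[2]) / 100)
}

#' Efficiency audit of designs across nominal parameter sets
#'
#' Computes, for every combination of candidate design, prior parameter
#' set and criterion, the efficiency of the design relative to a reference
#' optimal design. Two reference policies are offered: `"per-set"` (the
#' stricter, self-consistent choice) rebuilds the locally optimal design
#' for each parameter set; `"mle"` uses the locally optimal design at the
#' first prior set throughout, so efficiencies at other sets may exceed 1.
#'
#' @param designs A named list of [design()]s.
#' @param prior A [parameter_prior()]; one table row is produced per set.
#' @param criteria Character vector of criterion labels: `"D"` and/or
#'   `"cLC10"`-style LCp labels.
#' @param reference_policy `"per-set"` or `"mle"`.
#' @param interval Dose interval for the reference optimal designs;
#'   defaults to the interval of the first design.
#' @param grid_step,tol Passed to [find_optimal_design()] for the
#'   references.
#' @return An `efficiency_table` tibble with columns `design`,
#'   `param_set`, `criterion`, `efficiency`. Reference designs are kept in
#'   the `references` attribute. Singular cells score 0 with a warning.
#' @export
efficiency_table <- function(designs, prior,
                             criteria = "D",
                             reference_policy = c("per-set", "mle"),
                             interval = NULL, grid_step = 1, tol = 1e-3) {
  reference_policy <- match.arg(reference_policy)
  if (is.null(names(designs)) || any(!nzchar(names(designs)))) {
    abort("`designs` must be a named list")
  }
  interval <- interval %||% design_interval(designs[[1]])
  pr <- prior[prior$prob > 0, ]
  nset <- nrow(pr)
  refs <- list()
  rows <- list()
  for (lbl in criteria) {
    cr <- parse_criterion_label(lbl)
    ref_for_set <- function(i) {
      key <- paste(lbl, if (reference_policy == "per-set") i else 1)
      if (is.null(refs[[key]])) {
        single <- parameter_prior(prior_thetas(pr)[if (reference_policy == "per-set") i else 1])
        sp <- criterion_spec(cr$kind, single, p = cr$p, interval = interval)
        refs[[key]] <<- find_optimal_design(sp, grid_step = grid_step, tol = tol)$design
      }
      refs[[key]]
    }
    for (i in seq_len(nset)) {
      single <- parameter_prior(prior_thetas(pr)[i], labels = pr$set[i])
      ref <- ref_for_set(i)
      for (nm in names(designs)) {
        eff <- if (cr$kind == "D") d_efficiency(designs[[nm]], ref, single)
               else c_efficiency(designs[[nm]], ref, single, cr$p)
        if (!is.finite(eff) || eff <= 0) {
          warn(sprintf("singular cell: design %s, set %s, criterion %s", nm, pr$set[i], lbl))
          eff <- 0
        }
        rows[[length(rows) + 1]] <- tibble(design = nm, param_set = pr$set[i],
                                           criterion = lbl, efficiency = eff)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_policy") <- reference_policy
  attr(out, "references") <- refs
  attr(out, "p") <- NULL
  class(out) <- c("efficiency_table", class(out))
  out
}

#' @rdname efficiency_table
#' @param object An `efficiency_table`.
#' @param ... Unused.
#' @method autoplot efficiency_table
#' @export
autoplot.efficiency_table <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$param_set, y = .data$efficiency,
                 colour = .data$design, group = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::labs(x = "nominal parameter set", y = "efficiency") +
    ggplot2::theme_minimal()
}
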