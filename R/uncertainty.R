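# Error propagation and the statistical comparisons used on the
# upscaled emissions.

#' A value with absolute uncertainty
#'
#' The unit of all budget arithmetic: a quantity and its absolute
#' uncertainty in the same units.
#'
#' @param value Quantity.
#' @param delta Absolute uncertainty (>= 0), same units.
#' @return List of class `"uncertain"`.
#' @export
#' @examples
#' uncertain(0.104, 0.013)
uncertain <- function(value, delta) {
  check_number(value, "value")
  check_number(delta, "delta", lower = 0)
  structure(list(value = value, delta = delta), class = "uncertain")
}

#' @export
format.uncertain <- function(x, digits = 3, ...) {
  sprintf("%s (+/- %s)", signif(x$value, digits), signif(x$delta, digits))
}

#' @export
print.uncertain <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Propagate relative uncertainties through a product
#'
#' Standard multiplicative error propagation:
#' `deltaR = |R| * sqrt(sum((delta_x/x)^2))`. With the package's uniform
#' 15% convention on rates, areas and season lengths, every three-factor
#' product carries a relative uncertainty of `sqrt(3) * 15% ~ 26%`.
#'
#' @param value The product R.
#' @param relative Vector of relative uncertainties (proportions in
#'   `[0, 1)`), one per factor; may be empty.
#' @return `"uncertain"` object.
#' @export
#' @examples
#' propagate_product(0.039, c(0.15, 0.15, 0.15)) # delta ~0.010
propagate_product <- function(value, relative = rep(0.15, 3)) {
  check_number(value, "value")
  if (length(relative) > 0 &&
      (any(!is.finite(relative)) || any(relative < 0) ||
       any(relative >= 1))) {
    stop("relative uncertainties must lie in [0, 1)", call. = FALSE)
  }
  uncertain(value, abs(value) * sqrt(sum(relative^2)))
}

#' Combine absolute uncertainties in quadrature
#'
#' `delta = sqrt(sum(delta_i^2))`; always at least the largest component
#' and at most their plain sum.
#'
#' @param deltas Non-negative absolute uncertainties.
#' @return Combined absolute uncertainty.
#' @export
#' @examples
#' combine_quadrature(c(0.006, 0.002, 0.010)) # ~0.012
combine_quadrature <- function(deltas) {
  if (length(deltas) == 0L) return(0)
  if (any(!is.finite(deltas)) || any(deltas < 0)) {
    stop("uncertainties must be non-negative", call. = FALSE)
  }
  sqrt(sum(deltas^2))
}

#' Monte Carlo batch uncertainty of the transect rate
#'
#' Repeatedly subsamples the transect pools (pCO2, temperature, pH) in
#' batches, evaluates the gas-exchange rate for each batch, and reports
#' the spread of batch means and medians. With a right-skewed pCO2
#' distribution the batch mean exceeds the batch median.
#'
#' @param samples Transect `data.frame` (columns `pco2_uatm`, `temp_c`,
#'   `ph`).
#' @param params [exchange_params()].
#' @param n_batches Number of batches (default 10).
#' @param batch_size Values per batch (default 1000).
#' @param replace Sample with replacement? Default `TRUE`; when `FALSE`,
#'   `batch_size` must not exceed the pool.
#' @param seed Seed.
#' @return List with `batch_mean`, `batch_median` (vectors), and summary
#'   elements `mean_of_means`, `sd_of_means`, `mean_median_ratio`.
#' @export
mc_rate_uncertainty <- function(samples, params = exchange_params(),
                                n_batches = 10L, batch_size = 1000L,
                                replace = TRUE, seed = NULL) {
  n <- nrow(samples)
  if (n == 0L) stop("empty sample pool", call. = FALSE)
  if (!replace && batch_size > n) {
    stop("batch_size exceeds the pool for sampling without replacement",
         call. = FALSE)
  }
  with_seed(seed, {
    bm <- numeric(n_batches)
    bmed <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      idx <- sample.int(n, batch_size, replace = replace)
      r <- co2_emission_rate(samples$pco2_uatm[idx], samples$temp_c[idx],
                             samples$ph[idx], params)
      bm[b] <- mean(r)
      bmed[b] <- stats::median(r)
    }
    list(batch_mean = bm, batch_median = bmed,
         mean_of_means = mean(bm), sd_of_means = stats::sd(bm),
         mean_median_ratio = mean(bm) / mean(bmed))
  })
}

#' Kruskal-Wallis comparison with subsampling
#'
#' Rank-based comparison of per-zone values. Groups larger than
#' `subsample` are first reduced by random subsampling without
#' replacement (recorded seed), then the tie-corrected Kruskal-Wallis
#' statistic is computed with a chi-squared reference on
#' `groups - 1` degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (e.g. permafrost zone), same length.
#' @param subsample Maximum group size before ranking (default 500).
#' @param seed Seed for the subsampling.
#' @return List with `H`, `df`, `p_value`, `n_used` (per-group counts
#'   after subsampling).
#' @export
#' @examples
#' kruskal_zones(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_zones <- function(values, groups, subsample = 500L, seed = NULL) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  with_seed(seed, {
    keep <- unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      if (length(idx) > subsample) sample(idx, subsample) else idx
    }))
    v <- values[keep]
    gk <- droplevels(g[keep])
    if (any(table(gk) < 2L)) {
      stop("each group needs at least 2 values after subsampling",
           call. = FALSE)
    }
    if (length(unique(v)) == 1L) {
      stop("all pooled values identical: H is undefined", call. = FALSE)
    }
    kt <- stats::kruskal.test(v, gk)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value,
         n_used = as.integer(table(gk)))
  })
}
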