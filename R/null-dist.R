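# The common container for simulation-based inference: an observed statistic
# plus its simulant values under a null model. Fold enrichment, Z scores and
# empirical p values are all computed from this one object.

#' Construct a null distribution
#'
#' @param observed Observed value of the statistic (length-1 numeric).
#' @param simulants Numeric vector of the statistic under the null, one value
#'   per simulation iteration (at least one).
#' @return A `null_dist` object.
#' @export
#' @examples
#' nd <- null_distribution(0.10, c(0.12, 0.13, 0.11, 0.14))
#' fold_enrichment(nd)
#' empirical_p(nd, "lower")
null_distribution <- function(observed, simulants) {
  if (!is.numeric(observed) || length(observed) != 1L || is.na(observed)) {
    abort("`observed` must be a single numeric value")
  }
  simulants <- as.numeric(simulants)
  if (length(simulants) < 1L || anyNA(simulants)) {
    abort("`simulants` must be a nonempty numeric vector without NAs")
  }
  structure(
    list(
      observed = observed,
      simulants = simulants,
      n_iterations = length(simulants)
    ),
    class = "null_dist"
  )
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf(
    "<null_dist> observed = %.6g, null mean = %.6g (n = %d iterations)\n",
    x$observed, mean(x$simulants), x$n_iterations
  ))
  invisible(x)
}

#' Fold enrichment of an observed statistic over its null expectation
#'
#' `FE = (O - E) / E` where `E` is the mean of the simulants. `FE < 0`
#' indicates depletion, `FE > 0` enrichment, `FE ~ 0` agreement with the
#' null.
#'
#' @param dist A [null_distribution()] object.
#' @return Numeric scalar.
#' @export
fold_enrichment <- function(dist) {
  stopifnot(inherits(dist, "null_dist"))
  e <- mean(dist$simulants)
  if (e == 0) {
    abort("fold enrichment undefined: null expectation is zero")
  }
  (dist$observed - e) / e
}

#' Z score of an observed statistic against its null distribution
#'
#' `(O - mean) / sd` using the sample standard deviation (n - 1 denominator)
#' of the simulants. Positive Z means the observation lies above the null.
#'
#' @inheritParams fold_enrichment
#' @return Numeric scalar.
#' @export
z_score <- function(dist) {
  stopifnot(inherits(dist, "null_dist"))
  if (dist$n_iterations < 2L) {
    abort("Z score requires at least 2 simulants")
  }
  s <- sd(dist$simulants)
  if (s == 0) {
    abort("Z score undefined: simulants have zero standard deviation")
  }
  (dist$observed - mean(dist$simulants)) / s
}

#' Empirical p value from a null distribution
#'
#' `p = (m + 1) / (n + 1)` where, for the lower tail, `m` counts simulants
#' less than or equal to the observed value, and for the upper tail,
#' simulants greater than or equal to it. Ties count towards `m` in both
#' tails, so the p value is never below `1 / (n + 1)`.
#'
#' @inheritParams fold_enrichment
#' @param tail `"lower"` (is the observation unusually small?) or `"upper"`.
#' @return Named list with `p` and `m`.
#' @export
empirical_p <- function(dist, tail = c("lower", "upper")) {
  stopifnot(inherits(dist, "null_dist"))
  tail <- match.arg(tail)
  m <- if (tail == "lower") {
    sum(dist$simulants <= dist$observed)
  } else {
    sum(dist$simulants >= dist$observed)
  }
  list(p = (m + 1) / (dist$n_iterations + 1), m = as.integer(m))
}

#' @describeIn null_distribution One-row tibble with observed value, null
#'   mean and sd, fold enrichment, Z (NA when undefined), both empirical p
#'   values and their tie-inclusive counts.
#' @param x A `null_dist` object.
#' @param ... Unused.
#' @export
tidy.null_dist <- function(x, ...) {
  e <- mean(x$simulants)
  s <- if (x$n_iterations >= 2L) sd(x$simulants) else NA_real_
  lo <- empirical_p(x, "lower")
  up <- empirical_p(x, "upper")
  tibble(
    observed = x$observed,
    null_mean = e,
    null_sd = s,
    fe = if (e == 0) NA_real_ else (x$observed - e) / e,
    z = if (is.na(s) || s == 0) NA_real_ else (x$observed - e) / s,
    p_lower = lo$p,
    m_lower = lo$m,
    p_upper = up$p,
    m_upper = up$m,
    n_iterations = x$n_iterations
  )
}

#' @describeIn null_distribution Alias of `tidy()` for a one-row model
#'   summary.
#' @export
glance.null_dist <- function(x, ...) tidy.null_dist(x, ...)

#' Histogram of simulants with the observed value marked
#'
#' @param object A `null_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_dist <- function(object, ...) {
  df <- tibble(simulant = object$simulants)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$simulant)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$observed,
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "statistic under null", y = "iterations",
      title = sprintf(
        "observed = %.4g, FE = %.3f",
        object$observed,
        (object$observed - mean(object$simulants)) / mean(object$simulants)
      )
    ) +
    ggplot2::theme_minimal()
}
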