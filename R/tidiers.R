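#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an effective-population-size estimate
#'
#' @param x An [estimate_ne()] result.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble::tibble(term = "ne", estimate = x$ne_mle,
                 conf.low = x$ci_lower, conf.high = x$ci_upper)
}

#' @rdname tidy.ne_estimate
#' @export
glance.ne_estimate <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n_individuals, n_bins = x$n_bins)
}

#' Tidy a lineage-cemetery association test
#'
#' @param x A [test_lineage_association()] result.
#' @param ... Unused.
#' @export
tidy.association_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 nobs = x$n, n.perm = x$n_perm)
}

#' Tidy an intra- versus inter-cemetery comparison
#'
#' @param x A [compare_intra_inter()] result.
#' @param ... Unused.
#' @return A tibble with the two group means, the Welch t row and the
#'   permutation row.
#' @export
tidy.intra_inter_test <- function(x, ...) {
  tibble::tibble(
    term = c("mean_intra", "mean_inter", "welch_t", "permutation"),
    estimate = c(x$mean_intra, x$mean_inter, x$t_statistic, x$mean_diff),
    p.value = c(NA, NA, x$t_p_value, x$perm_p_value)
  )
}

#' Tidy a Mantel burial-distance test
#'
#' @param x A [mantel_burial()] result.
#' @param ... Unused.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_value, nobs = x$n,
                 n.perm = x$n_perm)
}

#' Summarise a mismatch-cutoff classification
#'
#' @param x A [read_classify()] result.
#' @param ... Unused.
#' @return One-row tibble with the baseline, the absolute cutoffs and class
#'   counts.
#' @export
glance.read_result <- function(x, ...) {
  co <- attr(x, "cutoffs")
  counts <- table(factor(x$class, levels = read_classes))
  tibble::tibble(
    baseline = attr(x, "baseline"),
    cutoff_identical = co$absolute_cutoff[1],
    cutoff_first = co$absolute_cutoff[2],
    cutoff_second = co$absolute_cutoff[3],
    n_identical = as.integer(counts["IDENTICAL"]),
    n_first = as.integer(counts["FIRST"]),
    n_second = as.integer(counts["SECOND"]),
    n_unrelated = as.integer(counts["UNRELATED"]),
    n_pairs = nrow(x)
  )
}
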