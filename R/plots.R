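#' Plot the normalised P0 distribution with class cutoffs
#'
#' @param object A [read_classify()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.read_result <- function(object, ...) {
  co <- attr(object, "cutoffs")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normalized_p0)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = co$normalized_cutoff,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "normalised P0", y = "pairs",
                  title = "Pairwise mismatch, normalised by cohort baseline") +
    ggplot2::theme_minimal()
}

#' Plot ROH length-bin counts against expected curves
#'
#' Mean per-individual ROH counts per length bin (with ±1 standard error),
#' overlaid with the closed-form expectation for a set of effective
#' population sizes — the standard diagnostic for reading Ne off the ROH
#' length spectrum.
#'
#' @param object A [bin_roh()] result.
#' @param ne Effective sizes for the expectation overlay.
#' @param map The [genetic_map()] the segments live on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roh_bins <- function(object, ne = c(100, 300, 1000, 3000),
                              map = default_genetic_map(), ...) {
  per <- object$per_individual |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$count),
                     se = stats::sd(.data$count) / sqrt(dplyr::n()),
                     .groups = "drop")
  finite_edges <- object$edges[is.finite(object$edges)]
  exp_df <- purrr::map_dfr(ne, function(v) {
    e <- expected_roh_counts(v, map, edges = object$edges)
    e$ne <- v
    e
  }) |>
    dplyr::mutate(bin = paste0("[", .data$bin_start_cM, ",", .data$bin_end_cM, ")"))
  ggplot2::ggplot(per, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean), fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_point(
      data = exp_df,
      ggplot2::aes(y = .data$expected_count, colour = factor(.data$ne),
                   group = factor(.data$ne))
    ) +
    ggplot2::geom_line(
      data = exp_df,
      ggplot2::aes(y = .data$expected_count, colour = factor(.data$ne),
                   group = factor(.data$ne))
    ) +
    ggplot2::labs(x = "ROH length bin (cM)", y = "segments per individual",
                  colour = "expected, Ne") +
    ggplot2::theme_minimal()
}

#' Plot the Ne profile log-likelihood
#'
#' @param object An [estimate_ne()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ne_estimate <- function(object, ...) {
  prof <- attr(object, "profile")
  if (is.null(prof)) stop("estimate carries no profile", call. = FALSE)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$ne, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$ne_mle, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(object$loglik - 20, object$loglik + 1)) +
    ggplot2::labs(x = "effective population size (log scale)",
                  y = "Poisson log-likelihood") +
    ggplot2::theme_minimal()
}

#' Plot within- versus between-cemetery IBD sharing
#'
#' @param object A [compare_intra_inter()] result.
#' @param ... Unused.
#' @return A ggplot (boxplots of cumulative IBD by pair group).
#' @export
autoplot.intra_inter_test <- function(object, ...) {
  df <- attr(object, "groups")
  if (is.null(df)) stop("comparison carries no per-pair values", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$cum_ibd_cM)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = NULL, y = "cumulative IBD (cM)",
                  subtitle = sprintf("permutation p = %.4g", object$perm_p_value)) +
    ggplot2::theme_minimal()
}
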