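#' Simulate homozygosity tract lengths under a renewal coalescent
#'
#' Simulates, for `n_individuals` independent diploid genomes, the tracts
#' into which recombination partitions each chromosome when the two
#' haplotypes of an individual coalesce: a tract is a maximal chromosome
#' region delimited by two recombination events whose interior coalesces to
#' a single common ancestor at TMRCA `t`. The TMRCA at the chromosome start
#' is exponential with mean `2 Ne` generations; the distance to the next
#' recombination event is exponential with rate `2 t` per Morgan; at each
#' breakpoint the TMRCA of the next tract is redrawn from the
#' recombination-rate-biased law Gamma(shape 2, rate `1/(2 Ne)`), the unique
#' redraw under which the TMRCA marginal at every genomic position stays
#' exponential with mean `2 Ne` — and under which the closed-form tract
#' density of [expected_roh_counts()] is exact.
#'
#' Tract lengths partition each chromosome exactly; tracts touching a
#' chromosome end are truncated and flagged `interior = FALSE`. Interior
#' tracts are the simulated analogue of detectable runs of homozygosity.
#'
#' @param ne Diploid effective population size (>= 2).
#' @param map A [genetic_map()].
#' @param n_individuals Number of independent diploid genomes.
#' @param seed Integer seed.
#' @param min_length_cM Tracts shorter than this are not recorded (memory
#'   guard: small `ne` produces hundreds of thousands of tiny tracts per
#'   genome; set >= 2 cM when only the ROH length bins matter).
#' @return A tibble of class `tract_list`: `individual`, `chrom`,
#'   `start_cM`, `end_cM`, `length_cM`, `tmrca`, `interior`; attributes
#'   `ne`, `n_individuals`, `map`.
#' @export
simulate_roh_tracts <- function(ne, map = default_genetic_map(),
                                n_individuals = 1000, seed = 1L,
                                min_length_cM = 0) {
  if (!is.finite(ne) || ne < 2) stop("`ne` must be >= 2", call. = FALSE)
  if (n_individuals < 1) stop("`n_individuals` must be >= 1", call. = FALSE)
  map <- assert_genetic_map(map)
  lambda <- 1 / (2 * ne)
  df <- with_seed(seed, {
    sim_tracts_cpp(map$length_cM / 100, lambda, as.integer(n_individuals),
                   min_length_cM / 100)
  })
  out <- tibble::tibble(
    individual = df$individual,
    chrom = map$chrom[df$chrom_idx],
    start_cM = df$start_M * 100,
    end_cM = df$end_M * 100,
    length_cM = (df$end_M - df$start_M) * 100,
    tmrca = df$tmrca,
    interior = df$interior == 1L
  )
  attr(out, "ne") <- ne
  attr(out, "n_individuals") <- n_individuals
  attr(out, "map") <- map
  class(out) <- c("tract_list", class(out))
  out
}

#' Closed-form expected homozygosity tract counts per diploid genome
#'
#' Under the renewal coalescent of [simulate_roh_tracts()], interior tracts
#' of length `l` (Morgans) occur with density `n(l) = 8 lambda /
#' (2 l + lambda)^3` per Morgan of map, `lambda = 1/(2 Ne)` — the mixture
#' `integral( 4 t^2 exp(-2 t l) lambda exp(-lambda t) dt )` of exponential
#' tract lengths over the exponential TMRCA marginal. On a finite chromosome
#' of genetic length `L` only starts in `[0, L - l]` yield an untruncated
#' tract, so the expected count in a length bin `[l1, l2)` is
#' `integral_{l1}^{min(l2, L)} n(l) (L - l) dl`, evaluated in closed form
#' and summed over chromosomes.
#'
#' @param ne Diploid effective population size (>= 2).
#' @param map A [genetic_map()].
#' @param edges Bin edges in cM; edges `c(4, 8, 12, 20, Inf)` give the four
#'   conventional ROH length bins.
#' @return Tibble with `bin_start_cM`, `bin_end_cM`, `expected_count` (per
#'   diploid genome).
#' @export
expected_roh_counts <- function(ne, map = default_genetic_map(),
                                edges = c(4, 8, 12, 20, Inf)) {
  if (!is.finite(ne) || ne < 2) stop("`ne` must be >= 2", call. = FALSE)
  map <- assert_genetic_map(map)
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("`edges` must be strictly increasing with at least two values",
         call. = FALSE)
  }
  lambda <- 1 / (2 * ne)
  # antiderivative of 8*lambda*(L - l)/(2l+lambda)^3 dl, with u = 2l + lambda
  F_at <- function(l, L) {
    u <- 2 * l + lambda
    2 * lambda / u - lambda * (2 * L + lambda) / u^2
  }
  l1 <- edges[-length(edges)] / 100
  l2 <- edges[-1] / 100
  expected <- vapply(seq_along(l1), function(b) {
    sum(vapply(map$length_cM / 100, function(L) {
      lo <- l1[b]
      hi <- min(l2[b], L)
      if (lo >= L) return(0)
      F_at(hi, L) - F_at(lo, L)
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(
    bin_start_cM = edges[-length(edges)],
    bin_end_cM = edges[-1],
    expected_count = expected
  )
}

#' Bin ROH segments and apply the inbreeding exclusion filter
#'
#' Counts and sums each individual's ROH segments within length bins, and
#' flags individuals whose long-ROH burden marks extensive inbreeding: an
#' individual is excluded from Ne fitting when the summed length of its ROH
#' segments longer than 20 cM exceeds `exclude_threshold_cM` (default 40),
#' and flagged as closely consanguineous when that sum exceeds 100 cM.
#'
#' @param segments Tibble with `id`, `chrom`, `start_cM`, `end_cM` (sorted,
#'   non-overlapping within individual and chromosome).
#' @param edges Bin edges in cM (default `c(4, 8, 12, 20, Inf)`).
#' @param exclude_threshold_cM Inbreeding exclusion threshold on the summed
#'   length of ROH > 20 cM; some analyses prefer 50.
#' @return An object of class `roh_bins`: list with `per_individual`
#'   (tibble: `id`, `bin`, `count`, `sum_cM`), `individuals` (tibble: `id`,
#'   `sum_gt20_cM`, `max_cM`, `excluded`, `consanguineous`), `edges`,
#'   `exclude_threshold_cM`.
#' @export
bin_roh <- function(segments, edges = c(4, 8, 12, 20, Inf),
                    exclude_threshold_cM = 40) {
  if (exclude_threshold_cM <= 0) stop("exclusion threshold must be > 0", call. = FALSE)
  seg <- dplyr::mutate(tibble::as_tibble(segments),
                       len = .data$end_cM - .data$start_cM)
  if (any(seg$len < 0)) stop("negative-length ROH segment", call. = FALSE)
  bad <- seg |>
    dplyr::arrange(.data$id, .data$chrom, .data$start_cM) |>
    dplyr::group_by(.data$id, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1,
                  .data$start_cM < dplyr::lag(.data$end_cM)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    stop("overlapping ROH segments within an individual", call. = FALSE)
  }
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  seg$bin <- cut(seg$len, breaks = edges, right = FALSE, labels = labs)
  per_ind <- seg |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$id, .data$bin) |>
    dplyr::summarise(count = dplyr::n(), sum_cM = sum(.data$len), .groups = "drop") |>
    tidyr::complete(id = unique(segments$id), bin = factor(labs, levels = labs),
                    fill = list(count = 0L, sum_cM = 0))
  individuals <- seg |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      sum_gt20_cM = sum(.data$len[.data$len > 20]),
      max_cM = max(.data$len, 0),
      .groups = "drop"
    ) |>
    tidyr::complete(id = unique(segments$id),
                    fill = list(sum_gt20_cM = 0, max_cM = 0)) |>
    dplyr::mutate(
      excluded = .data$sum_gt20_cM > exclude_threshold_cM,
      consanguineous = .data$sum_gt20_cM > 100
    )
  structure(
    list(per_individual = per_ind, individuals = individuals,
         edges = edges, exclude_threshold_cM = exclude_threshold_cM),
    class = "roh_bins"
  )
}

#' @export
print.roh_bins <- function(x, ...) {
  cat(sprintf("<roh_bins> %d individuals (%d excluded, %d consanguineous), edges %s cM\n",
              nrow(x$individuals), sum(x$individuals$excluded),
              sum(x$individuals$consanguineous),
              paste(x$edges, collapse = "/")))
  invisible(x)
}

#' Maximum-likelihood effective population size from binned ROH counts
#'
#' Treats the total observed ROH counts per length bin (summed over retained
#' individuals) as independent Poisson observations with mean
#' `n_individuals * expected_roh_counts(Ne)` and maximises the Poisson
#' log-likelihood over a log-spaced Ne grid followed by golden-section
#' refinement. The 95% confidence interval is the profile-likelihood set
#' `{Ne : logL(Ne) >= logL_max - 1.92}`.
#'
#' @param binned A [bin_roh()] result (excluded individuals are dropped), or
#'   a tibble with `bin_start_cM`, `bin_end_cM`, `count` of totals.
#' @param map The [genetic_map()] the segments live on.
#' @param n_individuals Number of retained diploid genomes behind the counts
#'   (taken from `binned` when it is a `roh_bins`).
#' @param fit_edges Bin edges used for fitting; the default
#'   `c(4, 8, 12, 20)` fits the 4-8, 8-12 and 12-20 cM bins, the range where
#'   counts are informative about Ne rather than about recent consanguinity.
#' @param ne_range Search range for Ne.
#' @return A tibble of class `ne_estimate`: `ne_mle`, `ci_lower`,
#'   `ci_upper`, `loglik`, `n_individuals`, `n_bins`; the profile is in
#'   attribute `"profile"`.
#' @export
estimate_ne <- function(binned, map = default_genetic_map(),
                        n_individuals = NULL, fit_edges = c(4, 8, 12, 20),
                        ne_range = c(50, 20000)) {
  map <- assert_genetic_map(map)
  if (inherits(binned, "roh_bins")) {
    keep <- binned$individuals$id[!binned$individuals$excluded]
    if (length(keep) == 0L) stop("no individuals retained after exclusion", call. = FALSE)
    segs <- binned$per_individual  # re-binning to fit_edges needs raw sums; use counts
    # rebuild counts on fit_edges from the stored per-individual bins when
    # possible, otherwise require matching edges
    if (!all(fit_edges %in% binned$edges)) {
      stop("fit_edges must be a subset of the edges used in bin_roh()", call. = FALSE)
    }
    labs_all <- paste0("[", binned$edges[-length(binned$edges)], ",",
                       binned$edges[-1], ")")
    labs_fit <- paste0("[", fit_edges[-length(fit_edges)], ",", fit_edges[-1], ")")
    counts <- segs |>
      dplyr::filter(.data$id %in% keep, .data$bin %in% labs_fit) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    counts <- counts$count[match(labs_fit, as.character(counts$bin))]
    counts[is.na(counts)] <- 0L
    n_individuals <- length(keep)
    obs <- tibble::tibble(
      bin_start_cM = fit_edges[-length(fit_edges)],
      bin_end_cM = fit_edges[-1],
      count = counts
    )
  } else {
    obs <- tibble::as_tibble(binned)
    if (is.null(n_individuals)) {
      stop("`n_individuals` is required when passing raw counts", call. = FALSE)
    }
  }
  edges <- c(obs$bin_start_cM, obs$bin_end_cM[nrow(obs)])
  loglik <- function(ne) {
    mu <- n_individuals *
      expected_roh_counts(ne, map, edges = edges)$expected_count
    sum(obs$count * log(mu) - mu)
  }
  grid <- exp(seq(log(ne_range[1]), log(ne_range[2]), length.out = 150))
  ll <- vapply(grid, loglik, numeric(1))
  if (all(obs$count == 0)) {
    # logL = -sum(mu) increases to 0 as Ne grows: MLE and CI upper unbounded
    thr0 <- -1.92
    ci_lower <- if (loglik(ne_range[1]) >= thr0) {
      ne_range[1]
    } else {
      # the likelihood interval may start beyond the search range
      ub <- ne_range[2]
      while (loglik(ub) < thr0 && ub < 1e12) ub <- ub * 10
      exp(stats::uniroot(function(x) loglik(exp(x)) - thr0,
                         c(log(ne_range[1]), log(ub)))$root)
    }
    out <- tibble::tibble(ne_mle = Inf, ci_lower = ci_lower, ci_upper = Inf,
                          loglik = NA_real_, n_individuals = n_individuals,
                          n_bins = nrow(obs))
    class(out) <- c("ne_estimate", class(out))
    return(out)
  }
  i_best <- which.max(ll)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(length(grid), i_best + 1L)]
  opt <- stats::optimize(function(x) loglik(exp(x)), c(log(lo), log(hi)),
                         maximum = TRUE, tol = 1e-8)
  ne_mle <- exp(opt$maximum)
  ll_max <- opt$objective
  thr <- ll_max - 1.92
  ci_lower <- if (loglik(ne_range[1]) >= thr) {
    ne_range[1]
  } else {
    exp(stats::uniroot(function(x) loglik(exp(x)) - thr,
                       c(log(ne_range[1]), log(ne_mle)))$root)
  }
  ci_upper <- if (loglik(ne_range[2]) >= thr) {
    Inf
  } else {
    exp(stats::uniroot(function(x) loglik(exp(x)) - thr,
                       c(log(ne_mle), log(ne_range[2])))$root)
  }
  out <- tibble::tibble(
    ne_mle = ne_mle, ci_lower = ci_lower, ci_upper = ci_upper,
    loglik = ll_max, n_individuals = n_individuals, n_bins = nrow(obs)
  )
  attr(out, "profile") <- tibble::tibble(ne = grid, loglik = ll)
  class(out) <- c("ne_estimate", class(out))
  out
}

#' Tabulate observed interior tract counts per bin per genome
#'
#' @param tracts A [simulate_roh_tracts()] result or an ROH segment tibble
#'   with `individual`/`id` and `length_cM`.
#' @param edges Bin edges in cM.
#' @return Tibble `bin_start_cM`, `bin_end_cM`, `count`, `mean_per_genome`,
#'   `se_per_genome` (across genomes).
#' @export
tract_bin_counts <- function(tracts, edges = c(4, 8, 12, 20)) {
  tr <- tibble::as_tibble(tracts)
  if ("interior" %in% names(tr)) tr <- dplyr::filter(tr, .data$interior)
  idcol <- if ("individual" %in% names(tr)) "individual" else "id"
  n_ind <- attr(tracts, "n_individuals")
  if (is.null(n_ind)) n_ind <- dplyr::n_distinct(tr[[idcol]])
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  tr$bin <- cut(tr$length_cM, breaks = edges, right = FALSE, labels = labs)
  tr <- dplyr::filter(tr, !is.na(.data$bin))
  all_ind <- if (idcol == "individual") seq_len(n_ind) else unique(tr[[idcol]])
  per_genome <- tr |>
    dplyr::group_by(.data$bin, ind = .data[[idcol]]) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(bin = factor(labs, levels = labs),
                    ind = all_ind, fill = list(n = 0L))
  per_genome |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      count = sum(.data$n),
      mean_per_genome = mean(.data$n),
      se_per_genome = stats::sd(.data$n) / sqrt(n_ind),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_start_cM = edges[-length(edges)],
      bin_end_cM = edges[-1],
      .before = 1
    ) |>
    dplyr::select(-"bin")
}
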