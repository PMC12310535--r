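#' Build a non-overlapping physical window grid over a site table
#'
#' Windows are defined on physical coordinates (default 1 Mb) within each
#' chromosome; every site belongs to exactly one window.
#'
#' @param sites Site tibble with `chrom` and `bp`.
#' @param window_bp Window span in base pairs.
#' @return An object of class `window_grid`: list with `site_window` (integer
#'   window index per site) and `windows` (tibble: `window`, `chrom`,
#'   `start_bp`).
#' @export
window_grid <- function(sites, window_bp = 1e6) {
  if (window_bp <= 0) stop("`window_bp` must be > 0", call. = FALSE)
  key <- paste(sites$chrom, floor(sites$bp / window_bp))
  uk <- unique(key)
  idx <- match(key, uk)
  windows <- tibble::tibble(
    window = seq_along(uk),
    chrom = sites$chrom[match(uk, key)],
    start_bp = floor(sites$bp[match(uk, key)] / window_bp) * window_bp
  )
  structure(list(site_window = idx, windows = windows, window_bp = window_bp),
            class = "window_grid")
}

all_pairs <- function(ids) {
  idx <- utils::combn(length(ids), 2L)
  tibble::tibble(id1 = ids[idx[1L, ]], id2 = ids[idx[2L, ]])
}

#' Windowed pairwise mismatch proportion (P0)
#'
#' For every pair of individuals, computes the proportion of non-matching
#' pseudo-haploid calls (P0) within non-overlapping physical windows, using
#' only sites where both individuals have a call. Windows with fewer than
#' `min_overlap` jointly called sites are dropped, and the pair-level mean P0
#' is the unweighted mean across retained windows.
#'
#' @param mat A [pseudohaploid_matrix()].
#' @param grid A [window_grid()]; default 1 Mb windows over `mat$sites`.
#' @param pairs Tibble with `id1`, `id2` (default: all unordered pairs).
#' @param min_overlap Minimum jointly called sites for a window to count.
#' @return A tibble of class `p0_result` with one row per pair: `id1`, `id2`,
#'   `n_windows` (retained), `mean_p0`, `insufficient` (`TRUE` when no window
#'   was retained, in which case `mean_p0` is `NA` and the pair must be
#'   excluded downstream). Per-window P0 and overlap matrices are carried in
#'   the `"windows"` attribute for the likelihood classifier.
#' @export
compute_p0 <- function(mat, grid = NULL, pairs = NULL, min_overlap = 20) {
  stopifnot(inherits(mat, "pseudohaploid_matrix"))
  if (is.null(grid)) {
    if (is.null(mat$sites)) stop("matrix has no site table; supply `grid`", call. = FALSE)
    grid <- window_grid(mat$sites)
  }
  ids <- mat$ids
  if (is.null(pairs)) pairs <- all_pairs(ids)
  i1 <- match(pairs$id1, ids); i2 <- match(pairs$id2, ids)
  if (anyNA(i1) || anyNA(i2)) stop("pair references unknown individual", call. = FALSE)

  X <- mat$calls
  M <- !is.na(X)
  storage.mode(M) <- "double"
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"

  n_win <- nrow(grid$windows)
  n_pair <- nrow(pairs)
  mism <- matrix(0, n_win, n_pair)
  olap <- matrix(0, n_win, n_pair)
  rows_by_win <- split(seq_len(nrow(X)), grid$site_window)
  flat <- cbind(i1, i2)
  for (w in seq_len(n_win)) {
    rows <- rows_by_win[[as.character(w)]]
    if (is.null(rows)) next
    Xw <- X[rows, , drop = FALSE]
    Mw <- M[rows, , drop = FALSE]
    A <- crossprod(Xw)             # both-alt counts on jointly called sites
    B <- crossprod(Mw)             # jointly called counts
    D <- crossprod(Xw, Mw)         # i alt & j called
    mism[w, ] <- (D + t(D) - 2 * A)[flat]
    olap[w, ] <- B[flat]
  }
  p0 <- mism / olap
  p0[olap < min_overlap] <- NA_real_

  n_windows <- colSums(!is.na(p0))
  mean_p0 <- suppressWarnings(colMeans(p0, na.rm = TRUE))
  mean_p0[n_windows == 0] <- NA_real_
  out <- tibble::tibble(
    id1 = pairs$id1, id2 = pairs$id2,
    n_windows = as.integer(n_windows),
    mean_p0 = mean_p0,
    insufficient = n_windows == 0
  )
  attr(out, "windows") <- list(p0 = p0, overlap = olap, grid = grid)
  attr(out, "min_overlap") <- min_overlap
  class(out) <- c("p0_result", class(out))
  out
}

read_classes <- c("IDENTICAL", "FIRST", "SECOND", "UNRELATED")

#' Normalised P0 cutoffs of the mismatch-based degree classifier
#'
#' The classifier places class boundaries midway between the expected
#' normalised P0 of adjacent relationship tiers (1 for unrelated, 0.875 for
#' second degree, 0.75 for first degree, 0.5 for identical), giving the
#' normalised cutoffs 0.90625, 0.8125 and 0.625. Absolute cutoffs are the
#' normalised cutoffs times the baseline.
#'
#' @param baseline Cohort baseline P0 (the unrelated level).
#' @return Tibble with `class`, `normalized_cutoff`, `absolute_cutoff`.
#' @examples
#' read_cutoffs(0.214)
#' @export
read_cutoffs <- function(baseline = 1) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop("`baseline` must be a positive number", call. = FALSE)
  }
  tibble::tibble(
    class = read_classes[1:3],
    normalized_cutoff = c(0.625, 0.8125, 0.90625),
    absolute_cutoff = baseline * c(0.625, 0.8125, 0.90625)
  )
}

#' Classify pairwise relatedness from mean P0 (mismatch-cutoff method)
#'
#' Normalises each pair's mean P0 by the cohort baseline — by default the
#' median of mean P0 across all pairs, taken to represent unrelated
#' individuals — and applies strict less-than cutoffs: `IDENTICAL` below
#' 0.625, `FIRST` below 0.8125, `SECOND` below 0.90625, otherwise
#' `UNRELATED`. Note the median baseline is biased downward in heavily
#' related cohorts; `baseline` can be supplied externally.
#'
#' @param p0_tbl A [compute_p0()] result (or any tibble with `id1`, `id2`,
#'   `mean_p0`).
#' @param baseline Optional externally supplied baseline P0 (> 0).
#' @return A tibble of class `read_result`: the input pair rows plus
#'   `normalized_p0` and `class`, with the baseline and the cutoff table in
#'   attributes `"baseline"` and `"cutoffs"`.
#' @export
read_classify <- function(p0_tbl, baseline = NULL) {
  p0 <- p0_tbl$mean_p0
  if (is.null(baseline)) baseline <- stats::median(p0, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline P0 must be positive; supply `baseline` explicitly", call. = FALSE)
  }
  norm <- p0 / baseline
  cls <- dplyr::case_when(
    is.na(norm) ~ NA_character_,
    norm < 0.625 ~ "IDENTICAL",
    norm < 0.8125 ~ "FIRST",
    norm < 0.90625 ~ "SECOND",
    TRUE ~ "UNRELATED"
  )
  out <- dplyr::mutate(
    tibble::as_tibble(p0_tbl),
    normalized_p0 = norm,
    class = factor(cls, levels = read_classes)
  )
  attr(out, "baseline") <- baseline
  attr(out, "cutoffs") <- read_cutoffs(baseline)
  class(out) <- c("read_result", class(out))
  out
}

#' Relationship model library of (k0, k1, k2) IBD-state fractions
#'
#' Genome fractions spent in 0, 1 or 2 shared-haplotype states for the
#' canonical close-kin relationships.
#'
#' @return Tibble with `model`, `k0`, `k1`, `k2`.
#' @export
relationship_models <- function() {
  tibble::tribble(
    ~model, ~k0, ~k1, ~k2,
    "UNRELATED", 1, 0, 0,
    "PARENT_CHILD", 0, 1, 0,
    "SIBLINGS", 0.25, 0.5, 0.25,
    "SECOND_DEGREE", 0.5, 0.5, 0,
    "THIRD_DEGREE", 0.75, 0.25, 0,
    "IDENTICAL", 0, 0, 1
  )
}

#' Relationship-model likelihood classification from windowed P0
#'
#' A transparent windowed-mixture simplification of HMM-based IBD-state
#' classifiers: each window's P0 is modelled as a mixture over IBD states
#' 0/1/2 with weights `(k0, k1, k2)` and state means `(b, 0.75 b, 0.5 b)`
#' (`b` = unrelated baseline), the pseudo-haploid expectations. The
#' observation model is a normal approximation to the binomial window count
#' with variance inflated by `error_spread`. Model log-likelihoods are summed
#' over retained windows; the best model and its log-likelihood ratio against
#' `UNRELATED` are reported, with calls deemed reliable when the ratio
#' exceeds 1.0.
#'
#' For distinguishing sibling-type from parent-child relationships the window
#' span should be large enough that window means separate from window noise;
#' 10 Mb windows (`window_grid(sites, 1e7)`) are a good default at aDNA site
#' densities.
#'
#' @param p0_res A [compute_p0()] result carrying per-window matrices.
#' @param baseline Baseline P0 `b`; default median of pair mean P0.
#' @param models Model library, see [relationship_models()].
#' @param error_spread Multiplicative variance inflation (default 1.5).
#' @param min_windows Pairs with fewer retained windows are flagged
#'   unreliable.
#' @return A tibble of class `kin_result`: `id1`, `id2`, `n_windows`,
#'   `best_model`, `loglik_best`, `loglik_unrelated`, `log_lr`, `reliable`,
#'   plus one `ll_<model>` column per model.
#' @export
kin_classify <- function(p0_res, baseline = NULL, models = relationship_models(),
                         error_spread = 1.5, min_windows = 20) {
  win <- attr(p0_res, "windows")
  if (is.null(win)) stop("`p0_res` must come from compute_p0()", call. = FALSE)
  if (is.null(baseline)) baseline <- stats::median(p0_res$mean_p0, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline P0 must be positive", call. = FALSE)
  }
  stopifnot(all(abs(rowSums(models[, c("k0", "k1", "k2")]) - 1) < 1e-8))
  p0 <- win$p0
  n <- win$overlap
  mu <- baseline * c(1, 0.75, 0.5)
  # per-state log-densities, shared across models
  logd <- lapply(mu, function(m) {
    sd <- sqrt(pmax(m * (1 - m), 1e-12) * error_spread / n)
    d <- stats::dnorm(p0, m, sd, log = TRUE)
    d[is.na(p0)] <- NA_real_
    d
  })
  n_pair <- ncol(p0)
  ll <- matrix(NA_real_, n_pair, nrow(models),
               dimnames = list(NULL, models$model))
  for (m in seq_len(nrow(models))) {
    k <- as.numeric(models[m, c("k0", "k1", "k2")])
    active <- which(k > 0)
    if (length(active) == 1L) {
      lw <- logd[[active]] + log(k[active])
    } else {
      mx <- do.call(pmax, c(logd[active], list(na.rm = FALSE)))
      acc <- 0
      for (s in active) acc <- acc + k[s] * exp(logd[[s]] - mx)
      lw <- mx + log(acc)
    }
    ll[, m] <- colSums(lw, na.rm = TRUE)
  }
  n_windows <- colSums(!is.na(p0))
  ll[n_windows == 0, ] <- NA_real_
  best <- models$model[max.col(replace(ll, is.na(ll), -Inf))]
  best[n_windows == 0] <- NA_character_
  loglik_best <- unname(apply(ll, 1, function(z) {
    if (all(is.na(z))) NA_real_ else max(z)
  }))
  log_lr <- loglik_best - unname(ll[, "UNRELATED"])
  out <- tibble::tibble(
    id1 = p0_res$id1, id2 = p0_res$id2,
    n_windows = as.integer(n_windows),
    best_model = best,
    loglik_best = loglik_best,
    loglik_unrelated = unname(ll[, "UNRELATED"]),
    log_lr = log_lr,
    reliable = !is.na(log_lr) & log_lr > 1 & n_windows >= min_windows
  )
  lltbl <- tibble::as_tibble(ll)
  names(lltbl) <- paste0("ll_", tolower(models$model))
  out <- dplyr::bind_cols(out, lltbl)
  attr(out, "baseline") <- baseline
  attr(out, "error_spread") <- error_spread
  class(out) <- c("kin_result", class(out))
  out
}

#' Summarise IBD segment sharing per pair
#'
#' Filters segments to length `>= min_len_cM`, then reports cumulative
#' length, count, longest segment and whether the cumulative length exceeds
#' 100 cM (the conventional marker of close familial connection).
#'
#' @param segments Tibble with `id1`, `id2`, `chrom`, `start_cM`, `end_cM`
#'   (a `state` column, if present, is ignored: any shared state counts).
#' @param min_len_cM Minimum segment length retained (default 12).
#' @param pairs Optional pair tibble; pairs without segments get zero rows.
#' @return Tibble `id1`, `id2`, `cum_ibd_cM`, `n_segments`, `longest_cM`,
#'   `over_100cM`.
#' @export
ibd_summarize <- function(segments, min_len_cM = 12, pairs = NULL) {
  len <- segments$end_cM - segments$start_cM
  if (any(len < 0)) stop("negative-length segment in input", call. = FALSE)
  seg <- segments[len >= min_len_cM, , drop = FALSE]
  out <- seg |>
    dplyr::mutate(len = .data$end_cM - .data$start_cM) |>
    dplyr::group_by(.data$id1, .data$id2) |>
    dplyr::summarise(
      cum_ibd_cM = sum(.data$len),
      n_segments = dplyr::n(),
      longest_cM = max(.data$len, 0),  # lengths are >= min_len_cM >= 0
      .groups = "drop"
    )
  if (!is.null(pairs)) {
    out <- pairs |>
      dplyr::select("id1", "id2") |>
      dplyr::left_join(out, by = c("id1", "id2")) |>
      dplyr::mutate(
        cum_ibd_cM = dplyr::coalesce(.data$cum_ibd_cM, 0),
        n_segments = dplyr::coalesce(.data$n_segments, 0L),
        longest_cM = dplyr::coalesce(.data$longest_cM, 0)
      )
  }
  dplyr::mutate(out, over_100cM = .data$cum_ibd_cM > 100)
}
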