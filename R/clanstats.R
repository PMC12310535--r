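#' Label all unordered pairs as intra- or inter-cemetery
#'
#' @param roster Tibble with `id` and `cemetery` (>= 2 individuals).
#' @return A tibble `id1`, `id2`, `group` (`"intra-<cemetery>"` or
#'   `"inter"`), with the per-group counts in attribute `"counts"`: for
#'   cemetery sizes `nA`, `nB` the intra counts are `choose(nA, 2)` and
#'   `choose(nB, 2)` and the inter count is `nA * nB`.
#' @examples
#' r <- tibble::tibble(id = as.character(1:5),
#'                     cemetery = c("N", "N", "S", "S", "S"))
#' attr(pair_groups(r), "counts")
#' @export
pair_groups <- function(roster) {
  if (nrow(roster) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (anyNA(roster$cemetery)) stop("unknown cemetery label (NA)", call. = FALSE)
  pr <- all_pairs(roster$id)
  cem <- stats::setNames(roster$cemetery, roster$id)
  c1 <- cem[pr$id1]; c2 <- cem[pr$id2]
  pr$group <- ifelse(c1 == c2, paste0("intra-", c1), "inter")
  counts <- dplyr::count(pr, .data$group, name = "n_pairs")
  attr(pr, "counts") <- counts
  pr
}

perm_pvalue <- function(observed, perm_stats) {
  (1 + sum(perm_stats >= observed)) / (1 + length(perm_stats))
}

#' Permutation test of lineage-cemetery association
#'
#' The observed statistic is the number of individuals whose matriline equals
#' the modal matriline of their own cemetery; the null distribution is
#' obtained by permuting cemetery labels across individuals. The one-sided
#' p-value uses add-one smoothing: `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param roster Tibble with `id`, `cemetery` and a lineage column.
#' @param lineage Name of the lineage column (default `"matriline"`).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A tibble of class `association_test`: `statistic`, `n`,
#'   `n_perm`, `p_value`; permuted statistics in attribute `"perm"`.
#' @export
test_lineage_association <- function(roster, lineage = "matriline",
                                     n_perm = 9999, seed = 1L) {
  if (!lineage %in% names(roster)) {
    stop(sprintf("column '%s' not found in roster", lineage), call. = FALSE)
  }
  cem <- roster$cemetery
  lin <- roster[[lineage]]
  if (dplyr::n_distinct(cem) < 2) {
    stop("association test needs at least two cemeteries", call. = FALSE)
  }
  stat <- function(cem) {
    sum(unlist(lapply(split(lin, cem), function(g) max(table(g)))))
  }
  obs <- stat(cem)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(cem)), numeric(1))
  })
  out <- tibble::tibble(
    statistic = obs, n = length(cem),
    n_perm = as.integer(n_perm),
    p_value = perm_pvalue(obs, perm)
  )
  attr(out, "perm") <- perm
  class(out) <- c("association_test", class(out))
  out
}

#' Compare within- versus between-cemetery IBD sharing
#'
#' Pools the intra-cemetery pairs and compares their cumulative IBD against
#' inter-cemetery pairs with a two-sided Welch t-test, and with a label
#' permutation that shuffles individual cemetery labels and recomputes the
#' intra-minus-inter mean difference (which respects the dependence of pairs
#' sharing an individual, unlike the t-test, whose p-value is
#' anti-conservative for pair data and is reported for reference only — the
#' permutation p is the headline number).
#'
#' @param roster Tibble with `id`, `cemetery`.
#' @param ibd_summary Pair tibble with `id1`, `id2`, `cum_ibd_cM` (see
#'   [ibd_summarize()]); pairs absent from it count as 0 sharing.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return A tibble of class `intra_inter_test`: group means, `mean_diff`
#'   (intra - inter), `t_statistic`, `t_p_value` (two-sided Welch, `NA` if a
#'   group has < 2 pairs), `perm_p_value`, `n_perm`; the per-group values
#'   are kept in attribute `"groups"`.
#' @export
compare_intra_inter <- function(roster, ibd_summary, n_perm = 9999, seed = 1L) {
  pg <- pair_groups(roster)
  val <- pg |>
    dplyr::left_join(dplyr::select(ibd_summary, "id1", "id2", "cum_ibd_cM"),
                     by = c("id1", "id2")) |>
    dplyr::mutate(cum_ibd_cM = dplyr::coalesce(.data$cum_ibd_cM, 0))
  intra <- val$cum_ibd_cM[val$group != "inter"]
  inter <- val$cum_ibd_cM[val$group == "inter"]
  if (length(inter) == 0 || length(intra) == 0) {
    stop("both intra- and inter-cemetery pairs are required", call. = FALSE)
  }
  mean_diff <- mean(intra) - mean(inter)
  tt <- if (length(intra) >= 2 && length(inter) >= 2 &&
            (stats::var(intra) + stats::var(inter)) > 0) {
    stats::t.test(intra, inter, alternative = "two.sided", var.equal = FALSE)
  } else {
    NULL
  }
  cem <- stats::setNames(roster$cemetery, roster$id)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pc <- stats::setNames(sample(cem), names(cem))
      is_intra <- pc[val$id1] == pc[val$id2]
      mean(val$cum_ibd_cM[is_intra]) - mean(val$cum_ibd_cM[!is_intra])
    }, numeric(1))
  })
  out <- tibble::tibble(
    mean_intra = mean(intra), mean_inter = mean(inter),
    mean_diff = mean_diff,
    t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    t_p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    perm_p_value = perm_pvalue(abs(mean_diff), abs(perm)),
    n_intra = length(intra), n_inter = length(inter),
    n_perm = as.integer(n_perm)
  )
  attr(out, "groups") <- val
  class(out) <- c("intra_inter_test", class(out))
  out
}

#' Mantel test of burial distance versus genetic distance
#'
#' Within one cemetery, correlates the pairwise burial distance (Euclidean,
#' from the roster's `x`, `y` coordinates in metres) with a pairwise genetic
#' distance, and assesses significance by jointly permuting individual
#' identities (rows and columns). Genetic distance is `1 - cumulative IBD /
#' genome length` when an IBD summary is supplied, or the pedigree degree
#' rank (unrelated = `max degree + 1`) as a fallback.
#'
#' @param roster Tibble with `id`, `x`, `y` for one cemetery (>= 4 rows).
#' @param ibd_summary Optional pair tibble with `id1`, `id2`, `cum_ibd_cM`.
#' @param degrees Optional pair tibble with `id1`, `id2`, `degree` (used
#'   when `ibd_summary` is `NULL`).
#' @param genome_cM Total map length for the IBD normalisation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble of class `mantel_result`: `r`, `p_value`, `n`,
#'   `n_perm`, `degenerate` (`TRUE` when a distance matrix is constant, in
#'   which case `r` is `NA`).
#' @export
mantel_burial <- function(roster, ibd_summary = NULL, degrees = NULL,
                          genome_cM = total_map_cM(default_genetic_map()),
                          n_perm = 9999, seed = 1L) {
  if (nrow(roster) < 4 || anyNA(roster$x) || anyNA(roster$y)) {
    stop("need >= 4 individuals with burial coordinates", call. = FALSE)
  }
  ids <- roster$id
  spat <- as.matrix(stats::dist(cbind(roster$x, roster$y)))
  dimnames(spat) <- list(ids, ids)
  gen <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  fill_pairs <- function(tbl, value_col, transform) {
    keep <- tbl$id1 %in% ids & tbl$id2 %in% ids
    tbl <- tbl[keep, ]
    v <- transform(tbl[[value_col]])
    gen[cbind(tbl$id1, tbl$id2)] <<- v
    gen[cbind(tbl$id2, tbl$id1)] <<- v
  }
  if (!is.null(ibd_summary)) {
    gen[] <- 1  # unobserved pairs: no detected sharing
    fill_pairs(ibd_summary, "cum_ibd_cM", function(v) 1 - v / genome_cM)
  } else if (!is.null(degrees)) {
    maxd <- max(degrees$degree, na.rm = TRUE)
    gen[] <- maxd + 1
    fill_pairs(degrees, "degree",
               function(v) ifelse(is.na(v), maxd + 1, v))
  } else {
    stop("supply `ibd_summary` or `degrees`", call. = FALSE)
  }
  diag(gen) <- 0
  v_spat <- spat[lower.tri(spat)]
  v_gen <- gen[lower.tri(gen)]
  if (stats::sd(v_spat) == 0 || stats::sd(v_gen) == 0) {
    out <- tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(ids),
                          n_perm = as.integer(n_perm), degenerate = TRUE)
    class(out) <- c("mantel_result", class(out))
    return(out)
  }
  mt <- with_seed(seed, {
    suppressMessages(
      vegan::mantel(stats::as.dist(spat), stats::as.dist(gen),
                    method = "pearson", permutations = n_perm)
    )
  })
  out <- tibble::tibble(
    r = unname(mt$statistic), p_value = mt$signif, n = length(ids),
    n_perm = as.integer(n_perm), degenerate = FALSE
  )
  class(out) <- c("mantel_result", class(out))
  out
}

#' Community-level endogamy summary
#'
#' @param ibd_summary Pair tibble from [ibd_summarize()] covering all pairs.
#' @param roh_bins Optional [bin_roh()] result.
#' @param short_roh_threshold_cM Short-ROH bin upper edge (default 8): the
#'   summary reports the fraction of individuals whose summed ROH shorter
#'   than this exceeds 40 cM, a signature of sustained small-pool endogamy.
#' @return A one-row tibble: `frac_pairs_over_100cM`, `median_cum_ibd_cM`,
#'   `n_pairs`, and (when `roh_bins` is given) `frac_short_roh_over_40cM`,
#'   `n_consanguineous`.
#' @export
endogamy_report <- function(ibd_summary, roh_bins = NULL,
                            short_roh_threshold_cM = 8) {
  out <- tibble::tibble(
    frac_pairs_over_100cM = mean(ibd_summary$cum_ibd_cM > 100),
    median_cum_ibd_cM = stats::median(ibd_summary$cum_ibd_cM),
    n_pairs = nrow(ibd_summary)
  )
  if (!is.null(roh_bins)) {
    labs <- levels(roh_bins$per_individual$bin)
    short_labs <- labs[roh_bins$edges[-1] <= short_roh_threshold_cM]
    short <- roh_bins$per_individual |>
      dplyr::filter(.data$bin %in% short_labs) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(short_cM = sum(.data$sum_cM), .groups = "drop")
    out$frac_short_roh_over_40cM <- mean(short$short_cM > 40)
    out$n_consanguineous <- sum(roh_bins$individuals$consanguineous)
  }
  out
}

#' Decision rule for the burial organisation of a community
#'
#' Calls a sampled cemetery roster "matrilineal-consistent" when (a) the
#' matriline-cemetery association is significant (permutation p below
#' `alpha`) and (b) maternal-lineage diversity within cemeteries is lower
#' than paternal-lineage diversity (mean per-cemetery Simpson index of mt
#' lineages below that of Y lineages); otherwise "unstructured".
#'
#' @param roster Tibble with `cemetery`, `mt_lineage`, `y_lineage`, `sex`.
#' @param association An [test_lineage_association()] result for the roster.
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: `call`, `association_p`, `mean_mt_sdi`,
#'   `mean_y_sdi`.
#' @export
classify_burial_organization <- function(roster, association, alpha = 0.01) {
  sdi_by_cem <- function(col, rows) {
    vapply(split(rows[[col]], rows$cemetery), function(g) {
      g <- g[!is.na(g)]
      if (length(g) < 1) return(NA_real_)
      simpson_index(as.integer(table(g)), "plain")$value
    }, numeric(1))
  }
  mt_sdi <- mean(sdi_by_cem("mt_lineage", roster), na.rm = TRUE)
  males <- roster[roster$sex == "M", ]
  y_sdi <- mean(sdi_by_cem("y_lineage", males), na.rm = TRUE)
  call <- if (association$p_value < alpha && isTRUE(mt_sdi < y_sdi)) {
    "matrilineal-consistent"
  } else {
    "unstructured"
  }
  tibble::tibble(call = call, association_p = association$p_value,
                 mean_mt_sdi = mt_sdi, mean_y_sdi = y_sdi)
}
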