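#' Assemble a validated pipeline run configuration
#'
#' @param sim Named list of [sim_config()] arguments.
#' @param sample_n Number of individuals excavated from the community.
#' @param kinship Named list: `window_bp` (P0 windows, default 1e6),
#'   `kin_window_bp` (likelihood-classifier windows, default 1e7),
#'   `min_overlap`, `ibd_min_cM`.
#' @param roh Named list: `edges`, `exclude_threshold_cM`, `fit_edges`.
#' @param clanstats Named list: `n_perm`, `alpha`.
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Output directory for per-stage tables and the JSON report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = list(), sample_n = 50,
                       kinship = list(), roh = list(), clanstats = list(),
                       seed = 1L, out_dir = tempfile("matrikin_run_")) {
  known <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop(sprintf("unknown %s option(s): %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    x
  }
  known(sim, names(formals(sim_config)), "sim")
  kinship <- utils::modifyList(
    list(window_bp = 1e6, kin_window_bp = 1e7, min_overlap = 20,
         ibd_min_cM = 12),
    known(kinship, c("window_bp", "kin_window_bp", "min_overlap", "ibd_min_cM"),
          "kinship"))
  roh <- utils::modifyList(
    list(edges = c(4, 8, 12, 20, Inf), exclude_threshold_cM = 40,
         fit_edges = c(4, 8, 12, 20)),
    known(roh, c("edges", "exclude_threshold_cM", "fit_edges"), "roh"))
  clanstats <- utils::modifyList(
    list(n_perm = 9999, alpha = 0.01),
    known(clanstats, c("n_perm", "alpha"), "clanstats"))
  structure(
    list(sim = sim, sample_n = sample_n, kinship = kinship, roh = roh,
         clanstats = clanstats, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `seed`, `out_dir`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(y), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

#' Run the full community analysis pipeline
#'
#' Executes simulate -> kinship -> uniparental -> ROH/Ne -> clan statistics
#' on one synthetic community, writes per-stage TSVs plus a single JSON
#' report carrying all estimates, p-values, seeds, the config hash and the
#' package version, and returns the report invisibly-printable object.
#'
#' @param config A [run_config()] (or a path to a YAML file).
#' @param map A [genetic_map()].
#' @return An object of class `pipeline_report` (a named list).
#' @export
run_pipeline <- function(config, map = default_genetic_map()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  map <- assert_genetic_map(map)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim_args <- utils::modifyList(config$sim, list(seed = config$seed))
  cfg <- do.call(sim_config, sim_args)

  comm <- stage("simulate", simulate_community(cfg, map))
  roster <- stage("simulate", sample_individuals(comm, config$sample_n))
  readr::write_tsv(dplyr::select(comm$roster, -dplyr::any_of("x")),
                   out("community_roster.tsv"))
  readr::write_tsv(roster, out("sampled_roster.tsv"))

  drop <- stage("simulate", gene_drop(comm, ids = roster$id))
  mat <- stage("simulate", pseudo_haploidize(
    drop, missing_rate = cfg$missing_rate, error_rate = cfg$error_rate,
    seed = cfg$seed + 303L))
  write_eigenstrat(mat, out("genotypes"), roster)

  # truth tables for the sampled roster
  pairs <- all_pairs(roster$id)
  truth_deg <- comm$truth$degrees |>
    dplyr::semi_join(pairs, by = c("id1", "id2"))
  readr::write_tsv(truth_deg, out("pairs_truth.tsv"))
  truth_ibd <- purrr::map2_dfr(pairs$id1, pairs$id2, function(a, b) {
    seg <- derive_true_ibd(drop, a, b)
    if (nrow(seg) == 0) return(NULL)
    dplyr::mutate(seg, id1 = a, id2 = b, .before = 1)
  })
  truth_roh <- purrr::map_dfr(roster$id, function(a) {
    seg <- derive_true_roh(drop, a)
    if (nrow(seg) == 0) return(NULL)
    dplyr::mutate(seg, id = a, .before = 1)
  })
  write_segments_tsv(truth_ibd, out("ibd_truth.tsv"))
  write_segments_tsv(truth_roh, out("roh_truth.tsv"))

  # kinship stage
  kin <- config$kinship
  p0 <- stage("kinship", compute_p0(
    mat, grid = window_grid(mat$sites, kin$window_bp),
    min_overlap = kin$min_overlap))
  rc <- stage("kinship", read_classify(p0))
  p0_kin <- stage("kinship", compute_p0(
    mat, grid = window_grid(mat$sites, kin$kin_window_bp),
    min_overlap = kin$min_overlap))
  kc <- stage("kinship", kin_classify(p0_kin))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(rc), "id1", "id2", "mean_p0",
                  "normalized_p0", "n_windows", "class"),
    out("pairs_p0.tsv"))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(kc), "id1", "id2", "best_model",
                  "log_lr", "reliable"),
    out("kin_models.tsv"))
  ibd_sum <- stage("kinship", ibd_summarize(
    truth_ibd, min_len_cM = kin$ibd_min_cM, pairs = pairs))
  readr::write_tsv(ibd_sum, out("ibd_summary.tsv"))

  # uniparental stage
  mtset <- stage("uniparental", transmit_uniparental(comm))
  write_mt_fasta(mtset, out("mtdna.fasta"), ids = roster$id)
  diffs <- mt_diff_matrix(
    structure(list(sets = mtset$sets[roster$id], ref_length = mtset$ref_length),
              class = "mt_set"))
  cl <- stage("uniparental", mt_cluster(diffs))
  roster_cl <- dplyr::left_join(roster, cl$partition, by = "id") |>
    dplyr::mutate(matriline_inferred = paste0("MT", .data$cluster))
  sdi <- roster_cl |>
    dplyr::group_by(.data$cemetery) |>
    dplyr::summarise(
      mt_sdi = simpson_index(as.integer(table(.data$matriline_inferred)),
                             "plain")$value,
      y_sdi = {
        ys <- .data$y_lineage[.data$sex == "M" & !is.na(.data$y_lineage)]
        if (length(ys) >= 2) {
          simpson_index(as.integer(table(ys)), "unbiased")$value
        } else {
          NA_real_
        }
      },
      n = dplyr::n(), .groups = "drop"
    )
  readr::write_tsv(sdi, out("uniparental_sdi.tsv"))

  # ROH / Ne stage
  roh_segments <- dplyr::select(truth_roh, "id", "chrom", "start_cM", "end_cM")
  binned <- stage("roh", bin_roh(
    roh_segments, edges = config$roh$edges,
    exclude_threshold_cM = config$roh$exclude_threshold_cM))
  ne <- stage("roh", estimate_ne(binned, map = map,
                                 fit_edges = config$roh$fit_edges))
  readr::write_tsv(binned$individuals, out("roh_individuals.tsv"))

  # clan statistics stage
  cs <- config$clanstats
  assoc <- stage("clanstats", test_lineage_association(
    roster_cl, lineage = "matriline_inferred", n_perm = cs$n_perm,
    seed = config$seed + 404L))
  intra <- stage("clanstats", compare_intra_inter(
    roster_cl, ibd_sum, n_perm = cs$n_perm, seed = config$seed + 405L))
  mantel <- lapply(split(roster_cl, roster_cl$cemetery), function(r) {
    if (nrow(r) < 4) return(NULL)
    mantel_burial(r, ibd_summary = ibd_sum, genome_cM = total_map_cM(map),
                  n_perm = cs$n_perm, seed = config$seed + 406L)
  })
  mantel <- mantel[!vapply(mantel, is.null, logical(1))]
  endog <- endogamy_report(ibd_sum, binned)
  org <- classify_burial_organization(roster_cl, assoc, alpha = cs$alpha)

  report <- list(
    package = "matrikin",
    version = as.character(utils::packageVersion("matrikin")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(unclass(config)), "out_dir")]),
    n_sampled = nrow(roster),
    cemeteries = as.list(table(roster$cemetery)),
    kinship = list(
      baseline_p0 = attr(rc, "baseline"),
      read_classes = as.list(table(rc$class)),
      n_reliable_kin = sum(kc$reliable)
    ),
    uniparental = list(
      n_matrilines = cl$n_clusters,
      min_inter_matriline_diff = cl$min_inter_diff,
      sdi = purrr::transpose(sdi)
    ),
    ne = list(ne_mle = ne$ne_mle, ci_lower = ne$ci_lower,
              ci_upper = ne$ci_upper,
              n_retained = ne$n_individuals),
    clanstats = list(
      association_p = assoc$p_value,
      intra_mean_ibd = intra$mean_intra,
      inter_mean_ibd = intra$mean_inter,
      t_statistic = intra$t_statistic,
      t_p_value = intra$t_p_value,
      perm_p_value = intra$perm_p_value,
      mantel = lapply(mantel, function(m) list(r = m$r, p = m$p_value)),
      endogamy = as.list(endog),
      burial_call = org$call
    )
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  seed %d, %d sampled individuals\n", x$seed, x$n_sampled))
  cat(sprintf("  READ baseline P0: %.4f\n", x$kinship$baseline_p0))
  cat(sprintf("  Ne MLE: %.0f [%.0f, %.0f]\n", x$ne$ne_mle, x$ne$ci_lower,
              x$ne$ci_upper))
  cat(sprintf("  matriline-cemetery association p: %.4g\n",
              x$clanstats$association_p))
  cat(sprintf("  burial organisation call: %s\n", x$clanstats$burial_call))
  invisible(x)
}
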