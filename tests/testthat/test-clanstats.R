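test_that("pair group counts reproduce the two-cemetery combinatorics", {
  roster <- tibble::tibble(
    id = sprintf("i%02d", 1:47),
    cemetery = rep(c("N", "S"), c(13, 34))
  )
  pg <- pair_groups(roster)
  counts <- attr(pg, "counts")
  get <- function(g) counts$n_pairs[counts$group == g]
  expect_equal(get("intra-N"), 78L)
  expect_equal(get("intra-S"), 561L)
  expect_equal(get("inter"), 442L)
  expect_equal(nrow(pg), 1081L)
})

test_that("pair group identities hold for random rosters", {
  matrikin:::with_seed(81, {
    for (i in 1:10) {
      na <- sample(0:12, 1); nb <- sample(2:12, 1)
      roster <- tibble::tibble(
        id = sprintf("x%02d", seq_len(na + nb)),
        cemetery = rep(c("A", "B"), c(na, nb))
      )
      pg <- pair_groups(roster)
      counts <- attr(pg, "counts")
      expect_equal(sum(pg$group == "inter"), na * nb)
      expect_equal(sum(pg$group == "intra-B"), choose(nb, 2))
      if (na >= 2) expect_equal(sum(pg$group == "intra-A"), choose(na, 2))
    }
  })
  expect_error(pair_groups(tibble::tibble(id = "a", cemetery = "A")),
               "at least 2")
})

test_that("perfect lineage segregation is highly significant, uniform labels are not", {
  roster <- tibble::tibble(
    id = sprintf("i%02d", 1:20),
    cemetery = rep(c("N", "S"), each = 10),
    matriline = rep(c("m1", "m2"), each = 10)
  )
  at <- test_lineage_association(roster, n_perm = 999, seed = 9)
  expect_equal(at$statistic, 20)
  expect_lte(at$p_value, 0.01)

  same <- dplyr::mutate(roster, matriline = "m1")
  at2 <- test_lineage_association(same, n_perm = 199, seed = 9)
  expect_equal(at2$p_value, 1)

  one_cem <- dplyr::mutate(roster, cemetery = "N")
  expect_error(test_lineage_association(one_cem), "two cemeteries")
})

test_that("permutation p-values are super-uniform under a random-burial null", {
  matrikin:::with_seed(83, {
    pvals <- replicate(200, {
      roster <- tibble::tibble(
        id = sprintf("i%02d", 1:30),
        cemetery = sample(rep(c("N", "S"), 15)),
        matriline = sample(rep(c("m1", "m2", "m3"), 10))
      )
      test_lineage_association(roster, n_perm = 199,
                               seed = sample.int(1e6, 1))$p_value
    })
    ks <- suppressWarnings(
      stats::ks.test(pvals, "punif", alternative = "greater"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("intra/inter comparison separates structured sharing and respects symmetry", {
  roster <- tibble::tibble(
    id = sprintf("i%02d", 1:12),
    cemetery = rep(c("N", "S"), each = 6)
  )
  pg <- pair_groups(roster)
  ibd <- pg |>
    dplyr::mutate(cum_ibd_cM = ifelse(group == "inter", 10, 100) +
                    rep_len(c(0, 1, 2), dplyr::n())) |>
    dplyr::select(id1, id2, cum_ibd_cM)
  cmp <- compare_intra_inter(roster, ibd, n_perm = 499, seed = 5)
  expect_gt(cmp$mean_diff, 80)
  expect_lt(cmp$perm_p_value, 0.01)
  expect_lt(cmp$t_p_value, 0.001)

  swapped <- dplyr::mutate(roster,
                           cemetery = ifelse(cemetery == "N", "S", "N"))
  cmp2 <- compare_intra_inter(swapped, ibd, n_perm = 499, seed = 5)
  expect_equal(abs(cmp2$t_statistic), abs(cmp$t_statistic))

  flat <- dplyr::mutate(ibd, cum_ibd_cM = 50)
  cmp3 <- compare_intra_inter(roster, flat, n_perm = 199, seed = 5)
  expect_equal(cmp3$mean_diff, 0)
  expect_equal(cmp3$perm_p_value, 1)
})

test_that("the Mantel test flags degenerate inputs and detects built-in structure", {
  roster <- tibble::tibble(
    id = sprintf("i%02d", 1:8),
    x = rep(1, 8), y = rep(2, 8)
  )
  pg <- matrikin:::all_pairs(roster$id)
  ibd <- dplyr::mutate(pg, cum_ibd_cM = 5)
  res <- mantel_burial(roster, ibd_summary = ibd, n_perm = 99, seed = 3)
  expect_true(res$degenerate)

  matrikin:::with_seed(84, {
    roster2 <- tibble::tibble(id = sprintf("i%02d", 1:10),
                              x = runif(10, 0, 50), y = runif(10, 0, 50))
    d <- as.matrix(stats::dist(cbind(roster2$x, roster2$y)))
    dimnames(d) <- list(roster2$id, roster2$id)
    pg2 <- matrikin:::all_pairs(roster2$id)
    # genetic distance constructed to equal spatial distance exactly
    gcm <- 330
    pg2$cum_ibd_cM <- gcm * (1 - d[cbind(pg2$id1, pg2$id2)] / max(d))
    res2 <- mantel_burial(roster2, ibd_summary = pg2, genome_cM = gcm,
                          n_perm = 999, seed = 4)
    expect_equal(res2$r, 1, tolerance = 1e-8)
    expect_lt(res2$p_value, 0.01)
  })
  expect_error(mantel_burial(roster[1:3, ], ibd_summary = ibd), ">= 4")
})

test_that("endogamy summaries follow the worked arithmetic", {
  ibd <- tibble::tibble(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                        cum_ibd_cM = c(50, 150, 200))
  rep1 <- endogamy_report(ibd)
  expect_equal(rep1$frac_pairs_over_100cM, 2 / 3)
  expect_equal(rep1$median_cum_ibd_cM, 150)

  none <- dplyr::mutate(ibd, cum_ibd_cM = 0)
  rep0 <- endogamy_report(none)
  expect_equal(rep0$frac_pairs_over_100cM, 0)
  expect_equal(rep0$median_cum_ibd_cM, 0)
})

test_that("stronger endogamy raises the fraction of heavily sharing pairs (paired seeds)", {
  frac_for <- function(e, seed) {
    cfg <- sim_config(founders_per_clan = 6, generations = 6, endogamy_prob = e,
                      n_sites = 100, seed = seed)
    comm <- simulate_community(cfg, tiny_map)
    ro <- sample_individuals(comm, 16)
    drop <- gene_drop(comm, ids = ro$id[1], n_sites = 10)
    pairs <- matrikin:::all_pairs(ro$id)
    seg <- purrr::map2_dfr(pairs$id1, pairs$id2, function(a, b) {
      s <- derive_true_ibd(drop, a, b)
      if (nrow(s) == 0) return(NULL)
      dplyr::mutate(s, id1 = a, id2 = b, .before = 1)
    })
    endogamy_report(ibd_summarize(seg, pairs = pairs))$frac_pairs_over_100cM
  }
  expect_gt(frac_for(0.95, 1), frac_for(0.3, 1))
})

test_that("the burial-organisation rule separates matriclan from shuffled rosters", {
  roster <- tibble::tibble(
    id = sprintf("i%02d", 1:24),
    sex = rep(c("F", "M"), 12),
    cemetery = rep(c("N", "S"), each = 12),
    matriline = rep(c("m1", "m2"), each = 12),
    mt_lineage = rep(c("mtA", "mtB"), each = 12),
    y_lineage = rep(paste0("Y", 1:6), 4)
  )
  assoc <- test_lineage_association(roster, n_perm = 999, seed = 6)
  org <- classify_burial_organization(roster, assoc)
  expect_equal(org$call, "matrilineal-consistent")
  expect_lt(org$mean_mt_sdi, org$mean_y_sdi)

  shuffled <- matrikin:::with_seed(85, {
    dplyr::mutate(roster,
                  matriline = sample(matriline),
                  mt_lineage = matriline)
  })
  assoc2 <- test_lineage_association(shuffled, n_perm = 999, seed = 6)
  org2 <- classify_burial_organization(shuffled, assoc2)
  expect_equal(org2$call, "unstructured")
})
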