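test_that("haplogroup table validation rejects malformed trees", {
  edges <- tibble::tibble(parent = c("R", "R"), child = c("A", "B"))
  mk <- tibble::tibble(haplogroup = "A", marker_id = "m1",
                       ancestral = "C", derived = "T")
  expect_s3_class(haplogroup_table(edges, mk), "haplogroup_table")
  expect_error(haplogroup_table(tibble::tibble(parent = c("R", "X"),
                                               child = c("A", "B")),
                                mk), "root")
  expect_error(haplogroup_table(edges, dplyr::bind_rows(mk, mk)),
               "exactly one branch")
  expect_error(haplogroup_table(edges,
                                dplyr::mutate(mk, haplogroup = "Z")),
               "unknown haplogroup")
})

test_that("theoretical genotypes are derived exactly along the root path", {
  tab <- toy_tree()
  theo <- theoretical_genotypes(tab)
  expect_true(all(theo["R", ] == tab$markers$ancestral))
  expect_equal(unname(theo["A1", c("m1", "m2", "m4")]), c("T", "A", "C"))
  expect_equal(unname(theo["A1", c("m3", "m5", "m6")]), c("A", "C", "G"))
})

test_that("theoretical genotypes equal brute-force path enumeration on random trees", {
  for (s in 1:5) {
    tab <- random_tree(n_nodes = sample(5:20, 1), seed = s)
    theo <- theoretical_genotypes(tab)
    # independent oracle: ancestor sets via repeated parent lookups
    for (h in tab$haplogroups) {
      anc <- h
      while (!is.na(tab$parent[[anc[length(anc)]]])) {
        anc <- c(anc, tab$parent[[anc[length(anc)]]])
      }
      expected <- ifelse(tab$markers$haplogroup %in% anc,
                         tab$markers$derived, tab$markers$ancestral)
      expect_equal(unname(theo[h, tab$markers$marker_id]), expected)
    }
  }
})

test_that("assignment scores exact matches at 1 and enforces the SNP-count QC", {
  tab <- toy_tree()
  theo <- theoretical_genotypes(tab)
  calls <- tibble::tibble(id = "s1", marker_id = colnames(theo),
                          allele = theo["A2", ])
  res <- assign_haplogroup(calls, tab, min_snps = 3)
  expect_equal(res$haplogroup, "A2")
  expect_equal(res$score, 1)
  expect_false(res$ambiguous)
  expect_true(res$qc_pass)

  res_qc <- assign_haplogroup(calls, tab, min_snps = 1000)
  expect_false(res_qc$qc_pass)  # 6 < 1000 called markers

  expect_error(assign_haplogroup(calls[0, ], tab), "no called markers")
})

test_that("masked assignments match an exhaustive scorer and recover the truth", {
  tab <- random_tree(20, n_markers_per_branch = 3, seed = 7)
  theo <- theoretical_genotypes(tab)
  truth_h <- tab$haplogroups[12]
  ok <- 0
  matrikin:::with_seed(70, {
    for (rep in 1:100) {
      keep <- sample(ncol(theo), ceiling(0.7 * ncol(theo)))
      calls <- tibble::tibble(id = "x", marker_id = colnames(theo)[keep],
                              allele = theo[truth_h, keep])
      res <- assign_haplogroup(calls, tab, min_snps = 1)
      # independent oracle: loop over haplogroups, count matches
      scores <- vapply(tab$haplogroups, function(h) {
        mean(theo[h, keep] == calls$allele)
      }, numeric(1))
      expect_setequal(res$best[[1]], names(scores)[scores == max(scores)])
      if (identical(res$best[[1]], truth_h)) ok <- ok + 1
      # the truth haplogroup always scores 1, so it is always a maximiser
      expect_true(truth_h %in% res$best[[1]])
    }
  })
  expect_gt(ok, 50)
})

test_that("alleles matching neither state count against every haplogroup", {
  tab <- toy_tree()
  calls <- tibble::tibble(id = "s", marker_id = c("m1", "m2"),
                          allele = c("G", "G"))  # m1: neither C nor T
  res <- assign_haplogroup(calls, tab, min_snps = 1)
  # m2 derived is A for branch A; G matches nothing at m1
  expect_lte(res$score, 0.5)
})

test_that("mtDNA difference counts and zero-difference clustering behave", {
  sets <- structure(list(sets = list(a = integer(0), b = integer(0),
                                     c = c(5L, 9L, 100L, 200L, 300L, 400L)),
                         ref_length = 16569L), class = "mt_set")
  d <- mt_diff_matrix(sets)
  expect_equal(d["a", "b"], 0L)
  expect_equal(d["a", "c"], 6L)
  expect_identical(d, t(d))
  cl <- mt_cluster(d)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$min_inter_diff, 6L)

  one <- mt_cluster(matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(one$n_clusters, 1L)
  expect_true(is.na(one$min_inter_diff))
})

test_that("zero-mutation transmission recovers the true matrilines in every community", {
  for (s in 1:30) {
    cfg <- sim_config(founders_per_clan = 3, generations = 3, mt_mut_prob = 0,
                      offspring_mean = 4, n_sites = 100, seed = 100 + s)
    comm <- simulate_community(cfg, tiny_map)
    mt <- transmit_uniparental(comm)
    cl <- mt_cluster(mt)
    joined <- dplyr::left_join(comm$roster, cl$partition, by = "id")
    # zero-difference clusters = founding mt lineages, exactly
    tab <- table(joined$mt_lineage, joined$cluster)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("engineered matrilines differ by at least their seed separation", {
  cfg <- sim_config(founders_per_clan = 3, generations = 3, mt_mut_prob = 0.05,
                    mt_clan_mutations = 3, n_sites = 100, seed = 55)
  comm <- simulate_community(cfg, tiny_map)
  mt <- transmit_uniparental(comm)
  d <- mt_diff_matrix(mt)
  r <- comm$roster
  inter <- outer(r$mt_lineage, r$mt_lineage, "!=")
  expect_gte(min(d[inter]), 3L)
})

test_that("Simpson diversity matches the worked examples and formulas", {
  expect_equal(simpson_index(14, "unbiased")$value, 0)
  expect_equal(simpson_index(c(1, 1, 1), "unbiased")$value, 1)
  expect_equal(round(simpson_index(c(44, 2), "plain")$value, 2), 0.08)
  expect_equal(simpson_index(c(3, 2, 2, 1, 1, 1), "unbiased")$value,
               1 - 10 / 90)
  expect_error(simpson_index(1, "unbiased"), "N >= 2")
  expect_error(simpson_index(c(-1, 2)), "non-negative")
})

test_that("Simpson estimator properties hold and plain form matches vegan", {
  matrikin:::with_seed(77, {
    for (i in 1:10) {
      k <- sample(2:6, 1)
      counts <- sample(1:20, k, replace = TRUE)
      plain <- simpson_index(counts, "plain")$value
      expect_lte(plain, 1 - 1 / k + 1e-12)
      expect_equal(plain, unname(vegan::diversity(counts, "simpson")))
      unb <- simpson_index(counts, "unbiased")$value
      expect_equal(unb == 1, all(counts == 1))
    }
  })
  # equality at uniform counts
  expect_equal(simpson_index(rep(7, 4), "plain")$value, 1 - 1 / 4)
})
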