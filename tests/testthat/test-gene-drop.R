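test_that("tile lengths of every haplotype sum exactly to the chromosome length", {
  cfg <- sim_config(founders_per_clan = 4, generations = 3, n_sites = 500, seed = 11)
  comm <- simulate_community(cfg, tiny_map)
  drop <- gene_drop(comm, ids = comm$roster$id[1:5], n_sites = 500)
  for (id in comm$roster$id) {
    til <- drop$tilings[[id]]
    for (ci in seq_len(nrow(tiny_map))) {
      for (h in 1:2) {
        m <- til[[ci]][[h]]
        expect_equal(sum(m[, "end"] - m[, "start"]), tiny_map$length_cM[ci],
                     tolerance = 1e-9)
        expect_true(all(m[, "end"] > m[, "start"]))  # no zero-length tiles
      }
    }
  }
})

test_that("crossover counts per meiosis are Poisson with mean one per Morgan", {
  founder <- list(
    matrix(c(0, 100, 1), 1, 3, dimnames = list(NULL, c("start", "end", "fid"))),
    matrix(c(0, 100, 2), 1, 3, dimnames = list(NULL, c("start", "end", "fid")))
  )
  n <- 3000
  k <- matrikin:::with_seed(99, {
    vapply(seq_len(n), function(i) nrow(matrikin:::meiosis(founder, 100)) - 1L,
           integer(1))
  })
  se <- sd(k) / sqrt(n)
  expect_lt(abs(mean(k) - 1), 3 * se)
})

test_that("a parent and child are IBD1 across the entire map", {
  drop <- make_drop(sib_roster(), seed = 13)
  seg <- derive_true_ibd(drop, "F0", "C1")
  expect_true(all(seg$state == 1L))
  expect_equal(sum(seg$end_cM - seg$start_cM), sum(tiny_map$length_cM),
               tolerance = 1e-9)
})

test_that("self pairs are IBD2 everywhere and founder pairs share nothing", {
  drop <- make_drop(sib_roster(), seed = 14)
  self <- derive_true_ibd(drop, "C1", "C1")
  expect_true(all(self$state == 2L))
  expect_equal(sum(self$end_cM - self$start_cM), sum(tiny_map$length_cM),
               tolerance = 1e-9)
  expect_equal(nrow(derive_true_ibd(drop, "F0", "M0")), 0)
  expect_error(derive_true_ibd(drop, "F0", "nobody"), "unknown")
})

test_that("IBD and ROH segments agree with a dense 0.01 cM grid scan", {
  cfg <- sim_config(founders_per_clan = 3, generations = 3, endogamy_prob = 1,
                    n_sites = 100, seed = 15)
  comm <- simulate_community(cfg, tiny_map)
  drop <- gene_drop(comm, ids = comm$roster$id[1:2], n_sites = 100)
  ids <- comm$roster$id
  pick <- matrikin:::with_seed(16, {
    t(replicate(20, sample(ids, 2)))
  })
  for (r in seq_len(nrow(pick))) {
    seg <- derive_true_ibd(drop, pick[r, 1], pick[r, 2])
    expect_identical(segments_to_states(seg, tiny_map),
                     scan_states_pair(drop, pick[r, 1], pick[r, 2]))
  }
  scan_ids <- matrikin:::with_seed(21, sample(ids, 20))
  for (id in scan_ids) {
    roh <- derive_true_roh(drop, id)
    scan <- scan_states_pair(drop, id, id)  # self-pair IBD2 regions
    # ROH = positions where the two haplotypes of `id` share a founder id
    roh_states <- segments_to_states(roh, tiny_map)
    direct <- unlist(lapply(seq_len(nrow(tiny_map)), function(ci) {
      pos <- seq(0.005, tiny_map$length_cM[ci], by = 0.01)
      h1 <- drop$tilings[[id]][[ci]][[1]]
      h2 <- drop$tilings[[id]][[ci]][[2]]
      as.integer(matrikin:::fid_at(h1, pos) == matrikin:::fid_at(h2, pos))
    }))
    expect_identical(roh_states, direct)
  }
})

test_that("full sibs average half the genome IBD1 and a quarter IBD2", {
  n <- 1000
  ks <- matrikin:::with_seed(17, {
    t(replicate(n, {
      drop <- structure(
        list(tilings = matrikin:::drop_tilings(sib_roster(), tiny_map),
             map = tiny_map),
        class = "gene_drop")
      realized_k(drop, "C1", "C2")
    }))
  })
  se1 <- sd(ks[, "k1"]) / sqrt(n)
  se2 <- sd(ks[, "k2"]) / sqrt(n)
  expect_lt(abs(mean(ks[, "k1"]) - 0.5), 3 * se1)
  expect_lt(abs(mean(ks[, "k2"]) - 0.25), 3 * se2)
})

test_that("half-sib style relationships average (0.5, 0.5, 0)", {
  half_roster <- dplyr::bind_rows(
    founder_row("F0", "F"), founder_row("Ma", "M"), founder_row("Mb", "M"),
    child_row("H1", "F", "F0", "Ma"), child_row("H2", "M", "F0", "Mb")
  )
  n <- 500
  ks <- matrikin:::with_seed(18, {
    t(replicate(n, {
      drop <- structure(
        list(tilings = matrikin:::drop_tilings(half_roster, tiny_map),
             map = tiny_map),
        class = "gene_drop")
      realized_k(drop, "H1", "H2")
    }))
  })
  expect_lt(abs(mean(ks[, "k1"]) - 0.5), 3 * sd(ks[, "k1"]) / sqrt(n))
  expect_equal(mean(ks[, "k2"]), 0)
})

test_that("a parent-offspring union produces ROH covering a quarter of the map", {
  selfed <- dplyr::bind_rows(
    founder_row("F0", "F"), founder_row("M0", "M"),
    child_row("A", "F", "F0", "M0"),
    child_row("Z", "F", "A", "M0", gen = 2L)  # father x daughter
  )
  # full-length map: on a short toy map whole-genome absence of ROH is not rare
  full_map <- default_genetic_map()
  n <- 200
  fr <- matrikin:::with_seed(19, {
    vapply(seq_len(n), function(i) {
      drop <- structure(
        list(tilings = matrikin:::drop_tilings(selfed, full_map),
             map = full_map),
        class = "gene_drop")
      seg <- derive_true_roh(drop, "Z")
      sum(seg$end_cM - seg$start_cM) / sum(full_map$length_cM)
    }, numeric(1))
  })
  expect_gte(mean(fr > 0), 0.99)  # inbreeding F = 0.25: ROH essentially always
  expect_lt(abs(mean(fr) - 0.25), 3 * sd(fr) / sqrt(n))
})

test_that("pseudo-haploidisation follows the sampling model exactly", {
  g <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  m <- pseudo_haploidize(g, missing_rate = 0, error_rate = 0, seed = 1)
  expect_identical(m$calls, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  het <- matrix(1L, 10000, 1)
  mh <- pseudo_haploidize(het, missing_rate = 0, error_rate = 0, seed = 2)
  p <- mean(mh$calls)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))

  # error flips are deterministic at rate 1
  mflip <- pseudo_haploidize(matrix(0L, 5, 5), missing_rate = 0,
                             error_rate = 1, seed = 3)
  expect_true(all(mflip$calls == 1L))

  mm <- pseudo_haploidize(matrix(2L, 100, 100), missing_rate = 0.3,
                          error_rate = 0, seed = 4)
  miss <- mean(is.na(mm$calls))
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))

  expect_error(pseudo_haploidize(g, missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(pseudo_haploidize(matrix(3L, 2, 2)), "\\{0, 1, 2\\}")
})

test_that("raising endogamy does not decrease truth ROH burden (paired seeds)", {
  roh_mean <- function(e, seed) {
    cfg <- sim_config(founders_per_clan = 8, generations = 8, endogamy_prob = e,
                      n_sites = 100, seed = seed)
    comm <- simulate_community(cfg, tiny_map)
    ids <- comm$roster$id[comm$roster$generation >= 6 & !comm$roster$external]
    ids <- head(ids, 40)
    drop <- gene_drop(comm, ids = ids[1], n_sites = 10)
    mean(vapply(ids, function(a) {
      seg <- derive_true_roh(drop, a)
      len <- seg$end_cM - seg$start_cM
      sum(len[len >= 4])
    }, numeric(1)))
  }
  for (s in 1:3) {
    expect_gte(roh_mean(0.95, s), roh_mean(0.3, s))
  }
})
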