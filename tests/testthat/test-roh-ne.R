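test_that("simulated tracts partition each chromosome exactly", {
  tr <- simulate_roh_tracts(50, tiny_map, n_individuals = 5, seed = 61)
  sums <- tr |>
    dplyr::group_by(individual, chrom) |>
    dplyr::summarise(tot = sum(length_cM), .groups = "drop") |>
    dplyr::left_join(tiny_map, by = "chrom")
  expect_equal(sums$tot, sums$length_cM, tolerance = 1e-9)
  expect_true(all(tr$tmrca > 0))
})

test_that("TMRCA laws of the tract process are preserved", {
  ne <- 200
  tr <- simulate_roh_tracts(ne, tiny_map, n_individuals = 400, seed = 62)
  # chromosome-start tracts draw from the position marginal Exp(1/(2 Ne))
  first <- tr[tr$start_cM == 0, ]
  se <- stats::sd(first$tmrca) / sqrt(nrow(first))
  expect_lt(abs(mean(first$tmrca) - 2 * ne), 3 * se)
  # length-weighted mean TMRCA is the position marginal mean 2 Ne
  w <- tr$length_cM / sum(tr$length_cM)
  lw <- sum(w * tr$tmrca)
  expect_lt(abs(lw - 2 * ne) / (2 * ne), 0.15)
})

test_that("conditional on TMRCA, interior tract lengths average 1/(2t) Morgans", {
  tr <- simulate_roh_tracts(50, genetic_map("1", 5000, 5e9),
                            n_individuals = 1, seed = 63)
  it <- tr[tr$interior & tr$tmrca >= 45 & tr$tmrca <= 55, ]
  expect_gt(nrow(it), 200)
  expected <- mean(100 / (2 * it$tmrca))  # cM
  se <- stats::sd(it$length_cM) / sqrt(nrow(it))
  expect_lt(abs(mean(it$length_cM) - expected), 3 * se)
})

test_that("closed-form expected counts agree with numeric quadrature of the TMRCA mixture", {
  ne <- 350
  lambda <- 1 / (2 * ne)
  n_l <- function(l) 8 * lambda / (2 * l + lambda)^3
  # density oracle: integrate the exponential-length / exponential-TMRCA mixture
  for (l in seq(0.01, 0.4, length.out = 20)) {
    mix <- stats::integrate(function(t) 4 * t^2 * exp(-2 * t * l) *
                              lambda * exp(-lambda * t),
                            0, Inf, rel.tol = 1e-10)$value
    expect_equal(n_l(l), mix, tolerance = 1e-6)
  }
  # bin expectation oracle: quadrature of n(l) * (L - l)
  map1 <- genetic_map("1", 150, 1.5e8)
  got <- expected_roh_counts(ne, map1, edges = c(4, 8, 12, 20))
  L <- 1.5
  for (b in 1:3) {
    lo <- got$bin_start_cM[b] / 100
    hi <- got$bin_end_cM[b] / 100
    num <- stats::integrate(function(l) n_l(l) * pmax(L - l, 0), lo, hi,
                            rel.tol = 1e-10)$value
    expect_equal(got$expected_count[b], num, tolerance = 1e-8)
  }
})

test_that("expected counts vanish as Ne grows and scale like 1/Ne for long tracts", {
  huge <- expected_roh_counts(1e7, edges = c(4, 8, 12, 20))
  expect_true(all(huge$expected_count < 1e-2))
  # large-l limit: halving Ne doubles long-ROH counts
  a <- expected_roh_counts(250, edges = c(20, 30))$expected_count
  b <- expected_roh_counts(500, edges = c(20, 30))$expected_count
  expect_equal(a / b, 2, tolerance = 0.05)
  expect_error(expected_roh_counts(500, edges = c(8, 4)), "increasing")
  expect_error(expected_roh_counts(1), ">= 2")
})

test_that("ROH binning and the inbreeding exclusion rule follow the thresholds", {
  seg <- function(id, lens) {
    tibble::tibble(id = id, chrom = "1",
                   start_cM = cumsum(c(0, lens[-length(lens)])) + seq_along(lens),
                   end_cM = start_cM + lens)
  }
  b <- bin_roh(dplyr::bind_rows(seg("u", c(5, 9, 25)),
                                seg("v", c(30, 15)),
                                seg("w", c(30, 25))))
  pu <- b$per_individual[b$per_individual$id == "u", ]
  expect_equal(pu$count, c(1L, 1L, 0L, 1L))
  iv <- b$individuals
  expect_false(iv$excluded[iv$id == "u"])   # 25 cM of long ROH <= 40
  expect_false(iv$excluded[iv$id == "v"])   # 30 <= 40: retained
  expect_true(iv$excluded[iv$id == "w"])    # 30 + 25 = 55 > 40: excluded
  expect_false(any(iv$consanguineous))

  cons <- bin_roh(seg("z", c(60, 70)))
  expect_true(cons$individuals$consanguineous)

  overlapping <- tibble::tibble(id = "o", chrom = "1",
                                start_cM = c(0, 5), end_cM = c(10, 12))
  expect_error(bin_roh(overlapping), "overlapping")
  neg <- tibble::tibble(id = "n", chrom = "1", start_cM = 5, end_cM = 1)
  expect_error(bin_roh(neg), "negative")
})

test_that("Ne likelihood is maximised at the generating value for exact counts", {
  map <- default_genetic_map()
  ne0 <- 300
  mu <- expected_roh_counts(ne0, map, edges = c(4, 8, 12, 20))
  obs <- tibble::tibble(bin_start_cM = mu$bin_start_cM,
                        bin_end_cM = mu$bin_end_cM,
                        count = mu$expected_count * 500)
  est <- estimate_ne(obs, map, n_individuals = 500)
  expect_equal(est$ne_mle, ne0, tolerance = 0.005)
  expect_true(est$ci_lower <= ne0 && ne0 <= est$ci_upper)
})

test_that("more observed ROH pushes the Ne estimate down", {
  map <- default_genetic_map()
  mu <- expected_roh_counts(400, map, edges = c(4, 8, 12, 20))
  base <- tibble::tibble(bin_start_cM = mu$bin_start_cM,
                         bin_end_cM = mu$bin_end_cM,
                         count = round(mu$expected_count * 200))
  est1 <- estimate_ne(base, map, n_individuals = 200)
  est4 <- estimate_ne(dplyr::mutate(base, count = count * 4), map,
                      n_individuals = 200)
  expect_lt(est4$ne_mle, est1$ne_mle)
})

test_that("all-zero counts leave the upper confidence bound unbounded", {
  obs <- tibble::tibble(bin_start_cM = c(4, 8, 12), bin_end_cM = c(8, 12, 20),
                        count = c(0, 0, 0))
  est <- estimate_ne(obs, default_genetic_map(), n_individuals = 50)
  expect_equal(est$ci_upper, Inf)
  expect_equal(est$ne_mle, Inf)
  expect_true(is.finite(est$ci_lower))
})

test_that("a closed pedigree of census ~50 yields an Ne estimate of the same order", {
  cfg <- sim_config(n_clans = 2, founders_per_clan = 12, generations = 25,
                    endogamy_prob = 1, offspring_mean = 2.6, n_sites = 100,
                    seed = 31)
  comm <- simulate_community(cfg)
  r <- comm$roster
  census <- median(table(r$generation[r$generation >= 15]))
  ids <- head(r$id[r$generation >= 23 & !r$external], 40)
  drop <- gene_drop(comm, ids = ids[1], n_sites = 10)
  roh <- purrr::map_dfr(ids, function(a) {
    seg <- derive_true_roh(drop, a)
    if (nrow(seg) == 0) return(NULL)
    dplyr::mutate(seg, id = a, .before = 1)
  })
  est <- estimate_ne(bin_roh(roh, exclude_threshold_cM = 1e9))
  # census size is not effective size; agreement within a factor of two
  expect_gt(est$ne_mle, census / 2)
  expect_lt(est$ne_mle, census * 2)
})

test_that("higher endogamy lowers the estimated Ne (paired seeds)", {
  est_for <- function(e, seed) {
    cfg <- sim_config(founders_per_clan = 8, generations = 10,
                      endogamy_prob = e, n_sites = 100, seed = seed)
    comm <- simulate_community(cfg, tiny_map)
    ids <- head(comm$roster$id[comm$roster$generation >= 8 &
                                 !comm$roster$external], 40)
    drop <- gene_drop(comm, ids = ids[1], n_sites = 10)
    roh <- purrr::map_dfr(ids, function(a) {
      seg <- derive_true_roh(drop, a)
      if (nrow(seg) == 0) return(NULL)
      dplyr::mutate(seg, id = a, .before = 1)
    })
    if (nrow(roh) == 0) return(Inf)
    estimate_ne(bin_roh(roh, exclude_threshold_cM = 1e9), map = tiny_map)$ne_mle
  }
  for (s in 1:2) {
    expect_lte(est_for(0.95, s), est_for(0.4, s))
  }
})
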