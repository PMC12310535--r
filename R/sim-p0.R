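#' Simulate pseudo-haploid mismatch for a relationship's k-vector
#'
#' Draws pairs of diploid individuals whose per-site IBD state is sampled
#' from `(k0, k1, k2)`, pseudo-haploidises both, and reports each pair's
#' mismatch proportion P0 normalised by the analytic unrelated expectation
#' for the same site frequencies (`mean(2 p (1 - p))`). Under pseudo-haploid
#' sampling the expected normalised P0 is `1 - k1/4 - k2/2`: 1 for
#' unrelated, 0.875 for second-degree, 0.75 for first-degree, 0.5 for
#' identical genomes — the midpoints between adjacent tiers being exactly
#' the mismatch classifier's cutoffs (0.90625, 0.8125, 0.625).
#'
#' Site-level IBD states are drawn independently, which preserves the
#' expectation (the quantity under test) while ignoring the segmental
#' correlation of real IBD.
#'
#' @param k Numeric `(k0, k1, k2)`, summing to 1.
#' @param n_sites Sites per pair.
#' @param n_pairs Number of replicate pairs.
#' @param missing_rate,error_rate Degradation applied to both individuals.
#' @param seed Integer seed.
#' @param freq_shape1,freq_shape2,freq_min,freq_max Founder allele frequency
#'   spectrum (truncated Beta).
#' @return Tibble with one row per pair: `p0`, `baseline`, `normalized_p0`,
#'   `n_called`.
#' @export
simulate_p0_pairs <- function(k, n_sites = 50000, n_pairs = 1,
                              missing_rate = 0, error_rate = 0, seed = 1L,
                              freq_shape1 = 0.5, freq_shape2 = 0.5,
                              freq_min = 0.05, freq_max = 0.95) {
  stopifnot(length(k) == 3, abs(sum(k) - 1) < 1e-8, all(k >= 0))
  with_seed(seed, {
    lo <- stats::pbeta(freq_min, freq_shape1, freq_shape2)
    hi <- stats::pbeta(freq_max, freq_shape1, freq_shape2)
    out <- lapply(seq_len(n_pairs), function(r) {
      p <- stats::qbeta(stats::runif(n_sites, lo, hi), freq_shape1, freq_shape2)
      a <- matrix(stats::rbinom(4L * n_sites, 1L, rep(p, each = 4L)),
                  nrow = 4L) # founder alleles a1..a4 per site
      s <- sample.int(3L, n_sites, replace = TRUE, prob = k) - 1L
      # A carries (a1, a2); B shares s of A's haplotypes
      b1 <- ifelse(s >= 1L, a[1L, ], a[3L, ])
      b2 <- ifelse(s == 2L, a[2L, ], a[4L, ])
      pick <- function(x, y) ifelse(stats::rbinom(n_sites, 1L, 0.5) == 1L, x, y)
      degrade <- function(v) {
        if (error_rate > 0) {
          fl <- stats::rbinom(n_sites, 1L, error_rate) == 1L
          v[fl] <- 1L - v[fl]
        }
        if (missing_rate > 0) {
          v[stats::rbinom(n_sites, 1L, missing_rate) == 1L] <- NA_integer_
        }
        v
      }
      ca <- degrade(pick(a[1L, ], a[2L, ]))
      cb <- degrade(pick(b1, b2))
      called <- !is.na(ca) & !is.na(cb)
      pe <- p * (1 - error_rate) + (1 - p) * error_rate
      tibble::tibble(
        p0 = mean(ca[called] != cb[called]),
        baseline = mean(2 * pe * (1 - pe)),
        n_called = sum(called)
      )
    })
    dplyr::bind_rows(out) |>
      dplyr::mutate(normalized_p0 = .data$p0 / .data$baseline)
  })
}
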