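#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the pedigree simulator. Defaults describe a small,
#' strongly endogamous two-clan farming community: two matrilineal clans
#' persisting for ten generations, around one hundred community members per
#' generation, a 90% chance that a mate is found inside the community (the
#' remainder are external men who bring fresh haplotypes and Y lineages), and
#' aDNA-like genotype degradation (pseudo-haploid calls on ~100k sites with
#' 30% missingness and a small per-call error rate).
#'
#' @param n_clans Number of founding matrilineal clans (cemeteries under the
#'   `"matriclan"` burial rule).
#' @param founders_per_clan Founding females (and founding males) per clan;
#'   also the per-generation cap on reproducing females per clan, which keeps
#'   the census roughly stationary.
#' @param generations Number of offspring generations simulated (>= 1).
#' @param endogamy_prob Probability `e` that a mother's mate is drawn from
#'   within the community rather than being an external founder.
#' @param burial_rule One of `"matriclan"`, `"patriclan"`, `"random"`.
#' @param offspring_mean Mean of the Poisson number of children per couple.
#' @param mt_mut_prob Per-transmission probability that a child's mtDNA gains
#'   one new private mutation.
#' @param n_sites Number of SNP sites simulated by [gene_drop()].
#' @param missing_rate Per-site, per-individual missingness of the
#'   pseudo-haploid calls.
#' @param error_rate Per-call allele flip probability.
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output.
#' @param avoid_close_kin If `TRUE` (default), full-sib and parent-offspring
#'   unions are excluded from the internal mating pool.
#' @param founder_freq_shape1,founder_freq_shape2 Beta parameters of the
#'   founder alternative-allele frequency spectrum.
#' @param founder_freq_min,founder_freq_max Truncation bounds of that
#'   spectrum; truncation keeps the mismatch statistics informative.
#' @param mt_clan_mutations Private mtDNA mutations seeding each founding
#'   lineage, so distinct matrilines are separated by at least twice this
#'   many differences.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clans = 2,
                       founders_per_clan = 20,
                       generations = 10,
                       endogamy_prob = 0.9,
                       burial_rule = c("matriclan", "patriclan", "random"),
                       offspring_mean = 2.5,
                       mt_mut_prob = 0.01,
                       n_sites = 100000,
                       missing_rate = 0.3,
                       error_rate = 0.005,
                       seed = 1L,
                       avoid_close_kin = TRUE,
                       founder_freq_shape1 = 0.5,
                       founder_freq_shape2 = 0.5,
                       founder_freq_min = 0.05,
                       founder_freq_max = 0.95,
                       mt_clan_mutations = 5L) {
  burial_rule <- match.arg(burial_rule)
  probs <- c(endogamy_prob = endogamy_prob, mt_mut_prob = mt_mut_prob,
             missing_rate = missing_rate, error_rate = error_rate)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1][1]
    stop(sprintf("`%s` must be a probability in [0, 1]", bad), call. = FALSE)
  }
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  if (n_clans < 1) stop("`n_clans` must be >= 1", call. = FALSE)
  if (founders_per_clan < 1) stop("`founders_per_clan` must be >= 1", call. = FALSE)
  if (offspring_mean <= 0) stop("`offspring_mean` must be > 0", call. = FALSE)
  if (founder_freq_min <= 0 || founder_freq_max >= 1 ||
      founder_freq_min >= founder_freq_max) {
    stop("founder frequency truncation bounds must satisfy 0 < min < max < 1",
         call. = FALSE)
  }
  structure(
    list(
      n_clans = as.integer(n_clans),
      founders_per_clan = as.integer(founders_per_clan),
      generations = as.integer(generations),
      endogamy_prob = endogamy_prob,
      burial_rule = burial_rule,
      offspring_mean = offspring_mean,
      mt_mut_prob = mt_mut_prob,
      n_sites = as.integer(n_sites),
      missing_rate = missing_rate,
      error_rate = error_rate,
      seed = as.integer(seed),
      avoid_close_kin = isTRUE(avoid_close_kin),
      founder_freq_shape1 = founder_freq_shape1,
      founder_freq_shape2 = founder_freq_shape2,
      founder_freq_min = founder_freq_min,
      founder_freq_max = founder_freq_max,
      mt_clan_mutations = as.integer(mt_clan_mutations)
    ),
    class = "sim_config"
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
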