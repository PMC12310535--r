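#' Simulate a multi-generation community pedigree with clan structure
#'
#' Builds a pedigree of `generations` offspring generations descending from
#' `n_clans` founding matrilines. Matriline membership follows the maternal
#' line exactly; each clan's founding females share one matriline label and
#' one founding mtDNA lineage, so under the `"matriclan"` burial rule the
#' community buries its dead in exactly `n_clans` cemeteries, one per clan.
#' With probability `1 - endogamy_prob` a mother's mate is an external
#' founder, a man from a neighbouring community carrying fresh founder
#' haplotypes and a fresh Y lineage. Truth tables (pairwise pedigree degree
#' from kinship-coefficient bands) are computed from the full pedigree.
#'
#' Pedigree degrees use the deterministic band rule: a pair with kinship
#' coefficient phi is degree `d` when
#' `phi` lies in `(1.5 * 2^-(d+2), 1.5 * 2^-(d+1)]`; self/identical pairs are
#' degree 0 and pairs beyond degree 6 are unrelated (`degree = NA`).
#'
#' @param config A [sim_config()].
#' @param map A [genetic_map()]; stored with the community and used by
#'   downstream stages.
#'
#' @return An object of class `community`: a list with elements `roster`
#'   (tibble: `id`, `sex`, `mother_id`, `father_id`, `generation`,
#'   `matriline`, `patriline`, `mt_lineage`, `y_lineage`, `cemetery`,
#'   `external`), `kinship` (dense kinship-coefficient matrix), `truth`
#'   (list with `degrees`, a pair-level tibble), `config` and `map`.
#' @examples
#' cfg <- sim_config(founders_per_clan = 4, generations = 3, n_sites = 200)
#' comm <- simulate_community(cfg, toy_genetic_map())
#' head(comm$roster)
#' @export
simulate_community <- function(config, map = default_genetic_map()) {
  stopifnot(inherits(config, "sim_config"))
  map <- assert_genetic_map(map)
  with_seed(config$seed, simulate_community_impl(config, map))
}

simulate_community_impl <- function(config, map) {
  n_clans <- config$n_clans
  fpc <- config$founders_per_clan
  clans <- paste0("clan", seq_len(n_clans))

  # growing vectors; founders first, then generation by generation
  id <- character(0); sex <- character(0)
  mother <- character(0); father <- character(0)
  generation <- integer(0); matriline <- character(0); patriline <- character(0)
  mt_lineage <- character(0); y_lineage <- character(0)
  external <- logical(0)
  y_counter <- 0L
  mt_counter <- 0L
  ext_counter <- 0L

  add_ind <- function(i, s, m, f, g, mat, pat, mt, y, ext) {
    id <<- c(id, i); sex <<- c(sex, s)
    mother <<- c(mother, m); father <<- c(father, f)
    generation <<- c(generation, g)
    matriline <<- c(matriline, mat); patriline <<- c(patriline, pat)
    mt_lineage <<- c(mt_lineage, mt); y_lineage <<- c(y_lineage, y)
    external <<- c(external, ext)
  }

  for (cl in seq_len(n_clans)) {
    mt_counter <- mt_counter + 1L
    mt_cl <- sprintf("mt%03d", mt_counter)
    for (k in seq_len(fpc)) {
      fid <- sprintf("%s_F0_%02d", clans[cl], k)
      add_ind(fid, "F", NA, NA, 0L, clans[cl], fid, mt_cl, NA, FALSE)
      y_counter <- y_counter + 1L
      mid <- sprintf("%s_M0_%02d", clans[cl], k)
      add_ind(mid, "M", NA, NA, 0L, clans[cl], mid, mt_cl,
              sprintf("Y%03d", y_counter), FALSE)
    }
  }

  for (g in seq_len(config$generations)) {
    prev <- which(generation == g - 1L & !external)
    child_n <- 0L
    for (cl in clans) {
      mothers_pool <- prev[sex[prev] == "F" & matriline[prev] == cl]
      if (length(mothers_pool) == 0L) next
      n_mothers <- min(fpc, length(mothers_pool))
      mothers_g <- sample_ids(mothers_pool, n_mothers)
      males_pool <- prev[sex[prev] == "M"]
      for (mo in mothers_g) {
        internal_mate <- stats::runif(1) < config$endogamy_prob
        fa <- NA_integer_
        if (internal_mate) {
          eligible <- males_pool
          if (config$avoid_close_kin) {
            same_mother <- !is.na(mother[eligible]) & !is.na(mother[mo]) &
              mother[eligible] == mother[mo]
            same_father <- !is.na(father[eligible]) & !is.na(father[mo]) &
              father[eligible] == father[mo]
            eligible <- eligible[!(same_mother & same_father)]
          }
          if (length(eligible) == 0L) {
            if (config$endogamy_prob >= 1) {
              stop(sprintf(
                "impossible mating pool: no eligible internal mate for %s in generation %d with endogamy_prob = 1",
                id[mo], g), call. = FALSE)
            }
            internal_mate <- FALSE
          } else {
            fa <- sample_ids(eligible, 1L)
          }
        }
        if (!internal_mate) {
          ext_counter <- ext_counter + 1L
          y_counter <- y_counter + 1L
          mt_counter <- mt_counter + 1L
          eid <- sprintf("EXT_%03d", ext_counter)
          add_ind(eid, "M", NA, NA, g - 1L, eid, eid,
                  sprintf("mt%03d", mt_counter),
                  sprintf("Y%03d", y_counter), TRUE)
          fa <- length(id)
        }
        n_child <- stats::rpois(1, config$offspring_mean)
        if (n_child == 0L) next
        for (ch in seq_len(n_child)) {
          child_n <- child_n + 1L
          s <- if (stats::runif(1) < 0.5) "F" else "M"
          cid <- sprintf("G%d_%04d", g, child_n)
          add_ind(cid, s, id[mo], id[fa], g,
                  matriline[mo], patriline[fa], mt_lineage[mo],
                  if (s == "M") y_lineage[fa] else NA, FALSE)
        }
      }
    }
    if (child_n == 0L) {
      stop(sprintf("community died out: no children produced in generation %d", g),
           call. = FALSE)
    }
  }

  roster <- tibble::tibble(
    id = id, sex = sex, mother_id = mother, father_id = father,
    generation = generation, matriline = matriline, patriline = patriline,
    mt_lineage = mt_lineage, y_lineage = y_lineage, external = external
  )
  roster$cemetery <- assign_cemetery(roster, config$burial_rule, clans)

  phi <- kinship_matrix(roster)
  truth <- list(degrees = degree_table(phi))

  structure(
    list(roster = roster, kinship = phi, truth = truth,
         config = config, map = map),
    class = "community"
  )
}

# sample() without the scalar-x surprise
sample_ids <- function(x, n) x[sample.int(length(x), n)]

assign_cemetery <- function(roster, rule, clans) {
  switch(rule,
    matriclan = ifelse(roster$external, NA_character_, roster$matriline),
    patriclan = ifelse(roster$external, NA_character_, roster$patriline),
    random = ifelse(roster$external, NA_character_,
                    sample(clans, nrow(roster), replace = TRUE))
  )
}

#' Kinship coefficient matrix of a pedigree roster
#'
#' Standard recursive kinship computation: founders are mutually unrelated and
#' non-inbred; for an individual `i` with parents `(m, f)`,
#' `phi(i, j) = (phi(m, j) + phi(f, j)) / 2` for prior `j`, and
#' `phi(i, i) = (1 + phi(m, f)) / 2`.
#'
#' @param roster A community roster tibble (needs `id`, `mother_id`,
#'   `father_id`, ordered so parents precede children).
#' @return A symmetric numeric matrix with dimnames equal to `id`.
#' @export
kinship_matrix <- function(roster) {
  n <- nrow(roster)
  mi <- match(roster$mother_id, roster$id)
  fi <- match(roster$father_id, roster$id)
  phi <- matrix(0, n, n, dimnames = list(roster$id, roster$id))
  for (i in seq_len(n)) {
    if (is.na(mi[i]) || is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      if (mi[i] >= i || fi[i] >= i) {
        stop("roster must be ordered with parents before children", call. = FALSE)
      }
      if (i > 1) {
        j <- seq_len(i - 1L)
        v <- 0.5 * (phi[mi[i], j] + phi[fi[i], j])
        phi[i, j] <- v
        phi[j, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[mi[i], fi[i]])
    }
  }
  phi
}

#' Map kinship coefficients to pedigree degrees
#'
#' Degree `d` when `phi` is in `(1.5 * 2^-(d+2), 1.5 * 2^-(d+1)]`; degree 0
#' covers self/identical, and anything beyond degree 6 is unrelated (`NA`).
#'
#' @param phi Numeric vector of kinship coefficients.
#' @param max_degree Degrees beyond this are reported as `NA` (unrelated).
#' @return Integer vector of degrees (`NA` = unrelated).
#' @export
kinship_degree <- function(phi, max_degree = 6L) {
  d <- ifelse(phi > 0, floor(log2(1.5 / phi)) - 1, NA_real_)
  d[!is.na(d) & d < 0] <- 0
  d[!is.na(d) & d > max_degree] <- NA_real_
  as.integer(d)
}

degree_table <- function(phi) {
  n <- nrow(phi)
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  tibble::tibble(
    id1 = rownames(phi)[idx[, 1]],
    id2 = colnames(phi)[idx[, 2]],
    kinship = phi[idx],
    degree = kinship_degree(phi[idx])
  )
}

#' @export
print.community <- function(x, ...) {
  r <- x$roster
  cat(sprintf(
    "<community> %d individuals (%d external), %d generations, %d matrilines\n",
    nrow(r), sum(r$external), max(r$generation),
    dplyr::n_distinct(r$matriline[!r$external])
  ))
  cat(sprintf("  burial rule: %s; cemeteries: %s\n", x$config$burial_rule,
              paste(sort(unique(stats::na.omit(r$cemetery))), collapse = ", ")))
  invisible(x)
}

#' Sample a burial roster from a community
#'
#' Emulates cemetery excavation: draws `n` buried (non-external) individuals,
#' by default from the later generations, and assigns within-cemetery burial
#' coordinates (uniform on a 20 m x 20 m plot per cemetery, cemeteries 50 m
#' apart along x).
#'
#' @param community A [simulate_community()] result.
#' @param n Number of individuals to sample.
#' @param generations Generations to sample from; default the last three.
#' @param seed Integer seed.
#' @return A roster tibble with burial coordinates `x`, `y` (metres).
#' @export
sample_individuals <- function(community, n = 50, generations = NULL,
                               seed = community$config$seed + 1L) {
  r <- community$roster
  if (is.null(generations)) {
    gmax <- max(r$generation)
    generations <- seq(max(1L, gmax - 2L), gmax)
  }
  pool <- dplyr::filter(r, !.data$external, .data$generation %in% generations,
                        !is.na(.data$cemetery))
  if (nrow(pool) < n) {
    stop(sprintf("only %d buried individuals available, cannot sample %d",
                 nrow(pool), n), call. = FALSE)
  }
  with_seed(seed, {
    out <- pool[sample.int(nrow(pool), n), ]
    cem <- sort(unique(out$cemetery))
    offset <- stats::setNames(50 * (seq_along(cem) - 1), cem)
    out$x <- stats::runif(n, 0, 20) + offset[out$cemetery]
    out$y <- stats::runif(n, 0, 20)
    dplyr::arrange(out, .data$id)
  })
}
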