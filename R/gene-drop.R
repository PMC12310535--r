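#' Drop founder haplotypes through a simulated pedigree
#'
#' Performs standard gene dropping: every founder (including external mates)
#' carries two whole-chromosome haplotypes with unique founder-haplotype ids;
#' each meiosis draws a Poisson number of crossovers (mean = chromosome map
#' length in Morgans, no interference), with breakpoints uniform on the cM
#' axis, so each transmitted haplotype is a mosaic of the parent's two
#' haplotypes. Site positions, founder allele frequencies (truncated
#' Beta spectrum) and per-founder-haplotype alleles are drawn once, and
#' diploid genotypes are assembled for the requested individuals.
#'
#' @param community A [simulate_community()] result.
#' @param ids Individuals to genotype (default: the whole roster). Tilings
#'   are always built for the whole pedigree.
#' @param n_sites Number of SNP sites (default from the community's config).
#' @param seed Integer seed.
#'
#' @return An object of class `gene_drop`: list with `tilings` (per
#'   individual, per chromosome, two tile matrices `start`/`end`/`fid` in cM),
#'   `sites` (tibble: `snp_id`, `chrom`, `bp`, `cM`, `ref`, `alt`,
#'   `founder_alt_freq`), `geno` (sites x individuals integer matrix of
#'   diploid dosages 0/1/2), `ids`, and `map`.
#' @export
gene_drop <- function(community, ids = NULL,
                      n_sites = community$config$n_sites,
                      seed = community$config$seed + 101L) {
  stopifnot(inherits(community, "community"))
  roster <- community$roster
  if (is.null(ids)) ids <- roster$id
  if (!all(ids %in% roster$id)) {
    stop("unknown individual id in `ids`", call. = FALSE)
  }
  map <- community$map
  cfg <- community$config
  with_seed(seed, {
    tilings <- drop_tilings(roster, map)
    sites <- draw_sites(map, n_sites, cfg)
    founders <- roster$id[is.na(roster$mother_id)]
    n_hap <- 2L * length(founders)
    falleles <- matrix(
      stats::rbinom(n_hap * nrow(sites), 1L,
                    rep(sites$founder_alt_freq, each = n_hap)),
      nrow = n_hap
    )
    geno <- genotype_from_tilings(tilings, sites, falleles, ids, map)
    structure(
      list(tilings = tilings, sites = sites, geno = geno, ids = ids,
           map = map, founder_alleles = falleles),
      class = "gene_drop"
    )
  })
}

# Tile the whole pedigree; founders get two whole-chromosome tiles with fresh
# founder-haplotype ids.
drop_tilings <- function(roster, map) {
  n <- nrow(roster)
  mi <- match(roster$mother_id, roster$id)
  fi <- match(roster$father_id, roster$id)
  tilings <- vector("list", n)
  names(tilings) <- roster$id
  hap_counter <- 0L
  for (i in seq_len(n)) {
    if (is.na(mi[i])) {
      per_chrom <- lapply(map$length_cM, function(L) {
        h1 <- matrix(c(0, L, hap_counter + 1L), 1, 3,
                     dimnames = list(NULL, c("start", "end", "fid")))
        h2 <- matrix(c(0, L, hap_counter + 2L), 1, 3,
                     dimnames = list(NULL, c("start", "end", "fid")))
        list(h1, h2)
      })
      hap_counter <- hap_counter + 2L
    } else {
      tm <- tilings[[mi[i]]]
      tf <- tilings[[fi[i]]]
      per_chrom <- lapply(seq_len(nrow(map)), function(ci) {
        L <- map$length_cM[ci]
        list(meiosis(tm[[ci]], L), meiosis(tf[[ci]], L))
      })
    }
    names(per_chrom) <- map$chrom
    tilings[[i]] <- per_chrom
  }
  tilings
}

# One meiosis on one chromosome: recombine the parent's two tile lists.
meiosis <- function(parent_haps, L) {
  k <- stats::rpois(1, L / 100)
  breaks <- if (k > 0) sort(stats::runif(k, 0, L)) else numeric(0)
  bounds <- c(0, breaks, L)
  phase <- (sample.int(2L, 1L) + seq_len(length(bounds) - 1L)) %% 2L + 1L
  pieces <- vector("list", length(bounds) - 1L)
  for (s in seq_along(pieces)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    if (b <= a) next
    m <- parent_haps[[phase[s]]]
    keep <- m[, 2L] > a & m[, 1L] < b
    mm <- m[keep, , drop = FALSE]
    mm[, 1L] <- pmax(mm[, 1L], a)
    mm[, 2L] <- pmin(mm[, 2L], b)
    pieces[[s]] <- mm
  }
  out <- do.call(rbind, pieces)
  colnames(out) <- c("start", "end", "fid")
  out
}

draw_sites <- function(map, n_sites, cfg) {
  n_c <- diff(round(cumsum(c(0, map$length_bp)) / sum(map$length_bp) * n_sites))
  bases <- c("A", "C", "G", "T")
  per_chrom <- lapply(seq_len(nrow(map)), function(ci) {
    nc <- n_c[ci]
    if (nc == 0) return(NULL)
    bp <- sort(sample.int(map$length_bp[ci] - 1L, nc)) # distinct, ordered
    tibble::tibble(
      chrom = map$chrom[ci],
      bp = as.numeric(bp),
      cM = bp / map$length_bp[ci] * map$length_cM[ci]
    )
  })
  sites <- dplyr::bind_rows(per_chrom)
  n <- nrow(sites)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  # truncated Beta spectrum via inverse-CDF sampling
  lo <- stats::pbeta(cfg$founder_freq_min, cfg$founder_freq_shape1, cfg$founder_freq_shape2)
  hi <- stats::pbeta(cfg$founder_freq_max, cfg$founder_freq_shape1, cfg$founder_freq_shape2)
  freq <- stats::qbeta(stats::runif(n, lo, hi),
                       cfg$founder_freq_shape1, cfg$founder_freq_shape2)
  sites$snp_id <- sprintf("rs%06d", seq_len(n))
  sites$ref <- ref
  sites$alt <- alt
  sites$founder_alt_freq <- freq
  sites[, c("snp_id", "chrom", "bp", "cM", "ref", "alt", "founder_alt_freq")]
}

genotype_from_tilings <- function(tilings, sites, falleles, ids, map) {
  n_sites <- nrow(sites)
  geno <- matrix(NA_integer_, n_sites, length(ids),
                 dimnames = list(sites$snp_id, ids))
  chrom_rows <- split(seq_len(n_sites), factor(sites$chrom, levels = map$chrom))
  for (j in seq_along(ids)) {
    til <- tilings[[ids[j]]]
    g <- integer(n_sites)
    for (ci in seq_len(nrow(map))) {
      rows <- chrom_rows[[ci]]
      if (length(rows) == 0) next
      pos <- sites$cM[rows]
      for (h in 1:2) {
        m <- til[[ci]][[h]]
        fid <- m[findInterval(pos, m[, 1L]), 3L]
        g[rows] <- g[rows] + falleles[cbind(fid, rows)]
      }
    }
    geno[, j] <- g
  }
  geno
}

fid_at <- function(tile_matrix, pos) {
  tile_matrix[findInterval(pos, tile_matrix[, 1L]), 3L]
}

#' Truth IBD segments for one pair from founder-haplotype tilings
#'
#' Maximal intervals where the two individuals share founder haplotypes:
#' state `IBD1` where exactly one haplotype lineage is shared, `IBD2` where
#' the two haplotype pairs can be matched perfectly. Intervals are half-open
#' in cM.
#'
#' @param drop A [gene_drop()] result.
#' @param id1,id2 Individual ids.
#' @return A tibble `chrom`, `start_cM`, `end_cM`, `state`.
#' @export
derive_true_ibd <- function(drop, id1, id2) {
  stopifnot(inherits(drop, "gene_drop"))
  t1 <- drop$tilings[[id1]]; t2 <- drop$tilings[[id2]]
  if (is.null(t1) || is.null(t2)) stop("unknown individual id", call. = FALSE)
  map <- drop$map
  out <- lapply(seq_len(nrow(map)), function(ci) {
    haps <- list(t1[[ci]][[1]], t1[[ci]][[2]], t2[[ci]][[1]], t2[[ci]][[2]])
    bounds <- sort(unique(c(0, unlist(lapply(haps, function(m) m[, 1L])),
                            map$length_cM[ci])))
    starts <- bounds[-length(bounds)]
    f <- vapply(haps, fid_at, numeric(length(starts)), pos = starts)
    if (length(starts) == 1L) f <- matrix(f, nrow = 1L)
    n11 <- f[, 1] == f[, 3]; n12 <- f[, 1] == f[, 4]
    n21 <- f[, 2] == f[, 3]; n22 <- f[, 2] == f[, 4]
    ibd2 <- (n11 & n22) | (n12 & n21)
    any1 <- n11 | n12 | n21 | n22
    state <- ifelse(ibd2, 2L, ifelse(any1, 1L, 0L))
    segment_runs(bounds, state, map$chrom[ci])
  })
  dplyr::bind_rows(out)
}

#' Truth ROH segments for one individual from its tiling
#'
#' Maximal intervals where the individual's two haplotypes carry the same
#' founder-haplotype id.
#'
#' @param drop A [gene_drop()] result.
#' @param id Individual id.
#' @return A tibble `chrom`, `start_cM`, `end_cM`.
#' @export
derive_true_roh <- function(drop, id) {
  stopifnot(inherits(drop, "gene_drop"))
  til <- drop$tilings[[id]]
  if (is.null(til)) stop("unknown individual id", call. = FALSE)
  map <- drop$map
  out <- lapply(seq_len(nrow(map)), function(ci) {
    h1 <- til[[ci]][[1]]; h2 <- til[[ci]][[2]]
    bounds <- sort(unique(c(0, h1[, 1L], h2[, 1L], map$length_cM[ci])))
    starts <- bounds[-length(bounds)]
    state <- as.integer(fid_at(h1, starts) == fid_at(h2, starts))
    seg <- segment_runs(bounds, state, map$chrom[ci])
    seg[seg$state == 1L, c("chrom", "start_cM", "end_cM")]
  })
  dplyr::bind_rows(out)
}

# collapse per-elementary-interval states into maximal constant runs (state>0)
segment_runs <- function(bounds, state, chrom) {
  r <- rle(state)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values > 0L
  tibble::tibble(
    chrom = chrom,
    start_cM = bounds[starts_idx[keep]],
    end_cM = bounds[ends_idx[keep] + 1L],
    state = r$values[keep]
  )
}

#' Realized IBD-state genome fractions for one pair
#'
#' @param drop A [gene_drop()] result.
#' @param id1,id2 Individual ids.
#' @return Named numeric vector `c(k0, k1, k2)` of genome fractions.
#' @export
realized_k <- function(drop, id1, id2) {
  seg <- derive_true_ibd(drop, id1, id2)
  tot <- total_map_cM(drop$map)
  l1 <- sum(seg$end_cM[seg$state == 1L] - seg$start_cM[seg$state == 1L])
  l2 <- sum(seg$end_cM[seg$state == 2L] - seg$start_cM[seg$state == 2L])
  c(k0 = 1 - (l1 + l2) / tot, k1 = l1 / tot, k2 = l2 / tot)
}

#' Degrade diploid genotypes into pseudo-haploid calls
#'
#' Emulates the random-read sampling used for low-coverage ancient genomes:
#' per site and individual, with probability `missing_rate` the call is
#' missing; otherwise one of the two alleles is sampled uniformly and flipped
#' with probability `error_rate`.
#'
#' @param geno Integer matrix of diploid dosages in `{0, 1, 2}`
#'   (sites x individuals), or a [gene_drop()] result.
#' @param missing_rate,error_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param sites Optional site tibble (taken from `geno` when it is a
#'   `gene_drop`).
#' @return A `pseudohaploid_matrix`: list with `sites`, `calls` (integer
#'   matrix in `{0, 1, NA}`), `ids`.
#' @export
pseudo_haploidize <- function(geno, missing_rate = 0.3, error_rate = 0,
                              seed = 1L, sites = NULL) {
  if (inherits(geno, "gene_drop")) {
    sites <- geno$sites
    geno <- geno$geno
  }
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1) {
    stop("missing_rate and error_rate must be in [0, 1]", call. = FALSE)
  }
  if (!all(geno %in% 0:2)) {
    stop("diploid genotypes must be in {0, 1, 2}", call. = FALSE)
  }
  with_seed(seed, {
    n <- length(geno)
    call <- ifelse(geno == 1L, stats::rbinom(n, 1L, 0.5), geno %/% 2L)
    if (error_rate > 0) {
      flip <- stats::rbinom(n, 1L, error_rate) == 1L
      call[flip] <- 1L - call[flip]
    }
    if (missing_rate > 0) {
      call[stats::rbinom(n, 1L, missing_rate) == 1L] <- NA_integer_
    }
    call <- matrix(as.integer(call), nrow(geno), ncol(geno),
                   dimnames = dimnames(geno))
    pseudohaploid_matrix(sites, call)
  })
}

#' Construct a pseudo-haploid genotype matrix
#'
#' The genotype substrate the kinship stage consumes: one sampled allele per
#' site per individual, coded 0 (reference), 1 (alternative) or `NA`
#' (missing), with a site table carrying the genetic and physical map.
#'
#' @param sites Tibble with at least `chrom`, `bp`, `cM` (sorted by
#'   chromosome then position); may be `NULL` for positionless toy matrices.
#' @param calls Integer matrix (sites x individuals) with values in
#'   `{0, 1, NA}`; column names are individual ids.
#' @return An object of class `pseudohaploid_matrix`.
#' @export
pseudohaploid_matrix <- function(sites, calls) {
  if (!is.null(sites)) {
    if (nrow(sites) != nrow(calls)) {
      stop("site table and call matrix disagree on the number of sites",
           call. = FALSE)
    }
    ord <- order(match(sites$chrom, unique(sites$chrom)), sites$bp)
    if (is.unsorted(ord)) stop("sites must be sorted by (chrom, bp)", call. = FALSE)
  }
  vals <- unique(as.vector(calls))
  if (!all(vals %in% c(0L, 1L, NA_integer_))) {
    stop("pseudo-haploid calls must be 0, 1 or NA", call. = FALSE)
  }
  structure(list(sites = sites, calls = calls,
                 ids = colnames(calls)),
            class = "pseudohaploid_matrix")
}

#' @export
print.pseudohaploid_matrix <- function(x, ...) {
  cat(sprintf("<pseudohaploid_matrix> %d sites x %d individuals (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}
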