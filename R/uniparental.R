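#' Build a haplogroup tree with branch-defining markers
#'
#' A haplogroup tree is a rooted tree (parent pointer per haplogroup, single
#' root) in which every branch carries a set of defining SNP markers with
#' known ancestral and derived alleles. A haplogroup's theoretical genotype
#' is derived at exactly the markers on its root path.
#'
#' @param edges Tibble with columns `parent`, `child` (haplogroup names); the
#'   root is the one parent that never appears as a child.
#' @param markers Tibble with columns `haplogroup` (the branch leading into
#'   that haplogroup), `marker_id`, `ancestral`, `derived`. Each marker may
#'   sit on exactly one branch.
#' @return An object of class `haplogroup_table`: list with `haplogroups`,
#'   `parent` (named vector, `NA` at the root), `root`, `markers`.
#' @export
haplogroup_table <- function(edges, markers) {
  edges <- tibble::as_tibble(edges)
  markers <- tibble::as_tibble(markers)
  children <- as.character(edges$child)
  parents <- as.character(edges$parent)
  if (anyDuplicated(children) > 0) {
    stop("a haplogroup has more than one parent", call. = FALSE)
  }
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) {
    stop(sprintf("tree must have exactly one root (found %d)", length(roots)),
         call. = FALSE)
  }
  haplogroups <- c(roots, children)
  parent <- stats::setNames(c(NA_character_, parents), haplogroups)
  # reachability / acyclicity: walk each node to the root
  for (h in haplogroups) {
    seen <- character(0)
    cur <- h
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("haplogroup tree contains a cycle", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (!cur %in% haplogroups) {
        stop(sprintf("haplogroup '%s' is not reachable from the root", h),
             call. = FALSE)
      }
    }
  }
  if (anyDuplicated(markers$marker_id) > 0) {
    stop("each marker may be assigned to exactly one branch", call. = FALSE)
  }
  if (!all(markers$haplogroup %in% haplogroups)) {
    stop("marker assigned to unknown haplogroup", call. = FALSE)
  }
  structure(list(haplogroups = haplogroups, parent = parent, root = roots,
                 markers = markers),
            class = "haplogroup_table")
}

root_path <- function(table, h) {
  path <- character(0)
  cur <- h
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- table$parent[[cur]]
  }
  path
}

#' Theoretical allele vectors for every haplogroup
#'
#' Haplogroup `h` carries the derived allele at exactly the markers on the
#' branches of its root path and the ancestral allele at all other markers.
#'
#' @param table A [haplogroup_table()].
#' @return A character matrix (haplogroups x markers) of expected alleles.
#' @export
theoretical_genotypes <- function(table) {
  stopifnot(inherits(table, "haplogroup_table"))
  mk <- table$markers
  theo <- matrix(rep(mk$ancestral, each = length(table$haplogroups)),
                 nrow = length(table$haplogroups),
                 dimnames = list(table$haplogroups, mk$marker_id))
  for (h in table$haplogroups) {
    on_path <- mk$haplogroup %in% root_path(table, h)
    theo[h, on_path] <- mk$derived[on_path]
  }
  theo
}

#' Assign haplogroups by similarity score against the tree
#'
#' For each individual, the similarity score of haplogroup `h` is the number
#' of called markers whose allele equals `h`'s theoretical allele, divided by
#' the number of called markers (so differently covered samples are
#' comparable). Alleles matching neither the ancestral nor the derived state
#' count as mismatches against every haplogroup. The haplogroup(s) with the
#' highest score are assigned; ties are reported, never silently broken.
#' Samples with fewer than `min_snps` called markers fail QC.
#'
#' @param calls Tibble with `id`, `marker_id`, `allele` (one row per called
#'   marker; markers outside the table are ignored).
#' @param table A [haplogroup_table()].
#' @param min_snps Minimum called markers for `qc_pass` (default 1000, the
#'   conventional threshold for low-coverage Y calls; lower it for toy trees).
#' @return Tibble with one row per individual: `id`, `haplogroup` (ties
#'   joined with "/"), `best` (list column of all maximisers), `score`,
#'   `n_markers`, `qc_pass`, `ambiguous`.
#' @export
assign_haplogroup <- function(calls, table, min_snps = 1000) {
  stopifnot(inherits(table, "haplogroup_table"))
  theo <- theoretical_genotypes(table)
  calls <- dplyr::filter(calls, .data$marker_id %in% colnames(theo))
  ids <- unique(calls$id)
  if (length(ids) == 0L) {
    stop("no called markers overlap the haplogroup table", call. = FALSE)
  }
  rows <- lapply(ids, function(i) {
    ci <- calls[calls$id == i, ]
    if (nrow(ci) == 0L) {
      stop(sprintf("individual '%s' has zero called markers", i), call. = FALSE)
    }
    sub <- theo[, ci$marker_id, drop = FALSE]
    matches <- rowSums(sub == rep(ci$allele, each = nrow(sub)))
    score <- matches / nrow(ci)
    best <- names(score)[score == max(score)]
    tibble::tibble(
      id = i,
      haplogroup = paste(best, collapse = "/"),
      best = list(best),
      score = max(score),
      n_markers = nrow(ci),
      qc_pass = nrow(ci) >= min_snps,
      ambiguous = length(best) > 1L
    )
  })
  dplyr::bind_rows(rows)
}

#' mtDNA transmission with private mutations
#'
#' Models each individual's mitochondrial sequence as a set of mutated
#' positions on a circular 16,569-position reference. Every founding mtDNA
#' lineage is seeded with `mt_clan_mutations` private positions; each
#' mother-to-child transmission adds one new singleton position with
#' probability `mt_mut_prob`. All positions are distinct across the
#' simulation, so pairwise differences are exact symmetric-difference counts.
#'
#' @param community A [simulate_community()] result.
#' @param mt_mut_prob Per-transmission mutation probability (default from the
#'   community's config).
#' @param seed Integer seed.
#' @return An object of class `mt_set`: list with `sets` (named list of
#'   integer position vectors), `ref_length` (16569).
#' @export
transmit_uniparental <- function(community,
                                 mt_mut_prob = community$config$mt_mut_prob,
                                 seed = community$config$seed + 202L) {
  stopifnot(inherits(community, "community"))
  r <- community$roster
  ref_length <- 16569L
  with_seed(seed, {
    available <- sample.int(ref_length)  # pre-shuffled pool of unique positions
    used <- 0L
    take <- function(k) {
      pos <- available[used + seq_len(k)]
      used <<- used + k
      pos
    }
    lineage_seed <- list()
    sets <- vector("list", nrow(r))
    names(sets) <- r$id
    mi <- match(r$mother_id, r$id)
    for (i in seq_len(nrow(r))) {
      if (is.na(mi[i])) {
        lin <- r$mt_lineage[i]
        if (is.null(lineage_seed[[lin]])) {
          lineage_seed[[lin]] <- take(community$config$mt_clan_mutations)
        }
        sets[[i]] <- lineage_seed[[lin]]
      } else {
        s <- sets[[mi[i]]]
        if (stats::runif(1) < mt_mut_prob) s <- c(s, take(1L))
        sets[[i]] <- s
      }
    }
    structure(list(sets = sets, ref_length = ref_length), class = "mt_set")
  })
}

#' Pairwise mtDNA difference counts
#'
#' @param x An `mt_set` (mutated-position sets) or a named character vector
#'   of equal-length sequences.
#' @return A symmetric integer matrix of pairwise difference counts.
#' @export
mt_diff_matrix <- function(x) {
  if (inherits(x, "mt_set")) {
    sets <- x$sets
    n <- length(sets)
    d <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
    sizes <- lengths(sets)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        d[i, j] <- d[j, i] <- sizes[i] + sizes[j] - 2L * inter
      }
    }
    return(d)
  }
  seqs <- as.character(x)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must have equal length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(chars)
  d <- matrix(0L, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Cluster matrilines by zero-difference mtDNA identity
#'
#' Individuals with identical mtDNA sequences (difference count zero) are
#' placed in the same matriline cluster (connected components of the
#' zero-difference graph); the minimum between-cluster difference is
#' reported.
#'
#' @param diffs A difference matrix from [mt_diff_matrix()] (or an `mt_set`).
#' @return List of class `mt_cluster`: `partition` (tibble `id`, `cluster`),
#'   `n_clusters`, `min_inter_diff`.
#' @export
mt_cluster <- function(diffs) {
  if (inherits(diffs, "mt_set")) diffs <- mt_diff_matrix(diffs)
  g <- igraph::graph_from_adjacency_matrix(diffs == 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  cl <- comp$membership
  partition <- tibble::tibble(id = rownames(diffs), cluster = as.integer(cl))
  min_inter <- if (comp$no > 1L) {
    min(diffs[outer(cl, cl, "!=")])
  } else {
    NA_integer_
  }
  structure(list(partition = partition, n_clusters = comp$no,
                 min_inter_diff = min_inter),
            class = "mt_cluster")
}

#' Simpson's diversity index
#'
#' The probability that two sampled items belong to different categories.
#' The plain estimator is `1 - sum((n_i / N)^2)`; the unbiased
#' (sampling-without-replacement) estimator is
#' `1 - sum(n_i * (n_i - 1)) / (N * (N - 1))`.
#'
#' @param counts Non-negative integer category counts.
#' @param estimator `"plain"` or `"unbiased"`.
#' @return A tibble of class `diversity_result`: `estimator`, `value`, `n`,
#'   `k` (number of non-empty categories).
#' @examples
#' simpson_index(c(44, 2), "plain")       # ~0.08
#' simpson_index(c(1, 1, 1), "unbiased")  # exactly 1
#' @export
simpson_index <- function(counts, estimator = c("plain", "unbiased")) {
  estimator <- match.arg(estimator)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (estimator == "plain") {
    if (n < 1) stop("need at least one observation", call. = FALSE)
    value <- 1 - sum((counts / n)^2)
  } else {
    if (n < 2) stop("the unbiased estimator needs N >= 2", call. = FALSE)
    value <- 1 - sum(counts * (counts - 1)) / (n * (n - 1))
  }
  out <- tibble::tibble(estimator = estimator, value = value,
                        n = n, k = length(counts))
  class(out) <- c("diversity_result", class(out))
  out
}
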