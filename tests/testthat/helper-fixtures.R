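# shared builders for the test suite; everything is generated in code

tiny_map <- toy_genetic_map()

# a wrapped gene_drop-like object from a hand-built roster (tilings only)
make_drop <- function(roster, map = tiny_map, seed = 1L) {
  tilings <- matrikin:::with_seed(seed, matrikin:::drop_tilings(roster, map))
  structure(list(tilings = tilings, map = map), class = "gene_drop")
}

# hand-built pedigree rosters ---------------------------------------------

founder_row <- function(id, sex) {
  tibble::tibble(id = id, sex = sex, mother_id = NA_character_,
                 father_id = NA_character_, generation = 0L)
}

child_row <- function(id, sex, mother, father, gen = 1L) {
  tibble::tibble(id = id, sex = sex, mother_id = mother, father_id = father,
                 generation = gen)
}

# F0 x M0 -> C1, C2 (full sibs); M1 external line for half-sib constructions
sib_roster <- function() {
  dplyr::bind_rows(
    founder_row("F0", "F"), founder_row("M0", "M"),
    child_row("C1", "F", "F0", "M0"), child_row("C2", "M", "F0", "M0")
  )
}

# grid-scan oracle for shared-founder-haplotype states at fixed resolution
scan_states_pair <- function(drop, id1, id2, step = 0.01) {
  map <- drop$map
  unlist(lapply(seq_len(nrow(map)), function(ci) {
    pos <- seq(step / 2, map$length_cM[ci], by = step)
    f <- sapply(c(drop$tilings[[id1]][[ci]], drop$tilings[[id2]][[ci]]),
                function(m) matrikin:::fid_at(m, pos))
    n11 <- f[, 1] == f[, 3]; n12 <- f[, 1] == f[, 4]
    n21 <- f[, 2] == f[, 3]; n22 <- f[, 2] == f[, 4]
    ifelse((n11 & n22) | (n12 & n21), 2L,
           ifelse(n11 | n12 | n21 | n22, 1L, 0L))
  }))
}

# look up the segment-implied state at scan positions
segments_to_states <- function(segments, map, step = 0.01) {
  unlist(lapply(seq_len(nrow(map)), function(ci) {
    pos <- seq(step / 2, map$length_cM[ci], by = step)
    st <- integer(length(pos))
    seg <- segments[segments$chrom == map$chrom[ci], , drop = FALSE]
    if (nrow(seg) > 0) {
      for (k in seq_len(nrow(seg))) {
        inside <- pos >= seg$start_cM[k] & pos < seg$end_cM[k]
        st[inside] <- if ("state" %in% names(seg)) seg$state[k] else 1L
      }
    }
    st
  }))
}

# small haplogroup tree: root R with children A, B; A has leaves A1, A2
toy_tree <- function() {
  edges <- tibble::tribble(
    ~parent, ~child,
    "R", "A",
    "R", "B",
    "A", "A1",
    "A", "A2"
  )
  markers <- tibble::tribble(
    ~haplogroup, ~marker_id, ~ancestral, ~derived,
    "A", "m1", "C", "T",
    "A", "m2", "G", "A",
    "B", "m3", "A", "G",
    "A1", "m4", "T", "C",
    "A2", "m5", "C", "A",
    "A2", "m6", "G", "T"
  )
  haplogroup_table(edges, markers)
}

# random haplogroup tree with one marker chain per branch
random_tree <- function(n_nodes, n_markers_per_branch = 2, seed = 1) {
  matrikin:::with_seed(seed, {
    names <- paste0("H", seq_len(n_nodes))
    parent_idx <- vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), integer(1))
    edges <- tibble::tibble(parent = names[parent_idx], child = names[2:n_nodes])
    bases <- c("A", "C", "G", "T")
    markers <- purrr::map_dfr(2:n_nodes, function(i) {
      k <- n_markers_per_branch
      anc <- sample(bases, k, replace = TRUE)
      der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), character(1))
      tibble::tibble(haplogroup = names[i],
                     marker_id = paste0("mk", i, "_", seq_len(k)),
                     ancestral = anc, derived = der)
    })
    haplogroup_table(edges, markers)
  })
}

# hand-written 10-site matrix: two 1 Mb windows, mismatches 3/5 and 1/5
toy_p0_matrix <- function() {
  sites <- tibble::tibble(
    snp_id = sprintf("s%02d", 1:10),
    chrom = "1",
    bp = c(1e5 * 1:5, 1e6 + 1e5 * 1:5),
    cM = bp / 1e6,
    ref = "A", alt = "G"
  )
  a <- rep(0L, 10)
  b <- c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)
  calls <- cbind(A = a, B = b)
  rownames(calls) <- sites$snp_id
  pseudohaploid_matrix(sites, calls)
}
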