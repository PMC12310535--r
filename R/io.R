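#' Write a pseudo-haploid matrix in EIGENSTRAT dialect
#'
#' Pseudo-haploid calls are encoded `{0, 2, 9}` in the `.geno` file — never
#' 1 — to signal haploid sampling inside a diploid container: `0` = reference
#' call (counted twice), `2` = alternative call, `9` = missing. Consumers
#' that assume diploid dosages would mis-read these files. The `.snp` file
#' stores genetic positions in Morgans (the common dialect); in memory the
#' package works in cM, converting only at this boundary.
#'
#' @param mat A [pseudohaploid_matrix()] with a site table.
#' @param prefix Output path prefix; writes `<prefix>.geno`, `.snp`, `.ind`.
#' @param roster Optional tibble with `id`, `sex`, and a group column
#'   (`cemetery` or `group`) for the `.ind` file; defaults to unknown sex
#'   and group "Community".
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(mat, prefix, roster = NULL) {
  stopifnot(inherits(mat, "pseudohaploid_matrix"))
  if (is.null(mat$sites)) stop("matrix has no site table", call. = FALSE)
  calls <- mat$calls
  code <- matrix("9", nrow(calls), ncol(calls))
  code[!is.na(calls) & calls == 0L] <- "0"
  code[!is.na(calls) & calls == 1L] <- "2"
  geno_lines <- apply(code, 1, paste, collapse = "")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  s <- mat$sites
  snp_lines <- sprintf("%s\t%s\t%.8f\t%d\t%s\t%s",
                       s$snp_id, s$chrom, s$cM / 100, as.integer(s$bp),
                       s$ref, s$alt)
  writeLines(snp_lines, paste0(prefix, ".snp"))
  ids <- mat$ids
  if (is.null(roster)) {
    sex <- rep("U", length(ids))
    grp <- rep("Community", length(ids))
  } else {
    i <- match(ids, roster$id)
    if (anyNA(i)) stop("roster does not cover all matrix individuals", call. = FALSE)
    sex <- roster$sex[i]
    gcol <- intersect(c("group", "cemetery"), names(roster))[1]
    grp <- if (is.na(gcol)) rep("Community", length(ids)) else roster[[gcol]][i]
    grp[is.na(grp)] <- "Community"
  }
  writeLines(sprintf("%s\t%s\t%s", ids, sex, grp), paste0(prefix, ".ind"))
  invisible(prefix)
}

#' Read an EIGENSTRAT-dialect pseudo-haploid matrix
#'
#' Counterpart of [write_eigenstrat()]; rejects malformed input rather than
#' coercing it: geno line lengths must equal the roster size, the site count
#' must match the geno line count, genetic positions must be non-decreasing
#' within each chromosome, and only characters `{0, 2, 9}` are legal.
#'
#' @param prefix Path prefix of the `.geno`/`.snp`/`.ind` triplet.
#' @return A list with `mat` (a [pseudohaploid_matrix()]) and `roster`
#'   (tibble `id`, `sex`, `group`).
#' @export
read_eigenstrat <- function(prefix) {
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop(sprintf("missing file(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  geno_lines <- readLines(files[1])
  snp <- utils::read.table(files[2], header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(snp) <- c("snp_id", "chrom", "gpos_M", "bp", "ref", "alt")
  ind <- utils::read.table(files[3], header = FALSE, sep = "\t",
                           colClasses = "character")
  names(ind) <- c("id", "sex", "group")
  if (length(geno_lines) != nrow(snp)) {
    stop(sprintf("dimension mismatch: %d geno lines but %d snp rows",
                 length(geno_lines), nrow(snp)), call. = FALSE)
  }
  if (any(nchar(geno_lines) != nrow(ind))) {
    stop(sprintf("dimension mismatch: geno line length != %d individuals",
                 nrow(ind)), call. = FALSE)
  }
  for (ch in unique(snp$chrom)) {
    if (is.unsorted(snp$gpos_M[snp$chrom == ch])) {
      stop(sprintf("non-monotone genetic positions on chromosome %s", ch),
           call. = FALSE)
    }
  }
  chars <- do.call(rbind, strsplit(geno_lines, ""))
  bad <- setdiff(unique(as.vector(chars)), c("0", "2", "9"))
  if (length(bad) > 0) {
    stop(sprintf("illegal geno character(s): %s", paste(bad, collapse = " ")),
         call. = FALSE)
  }
  calls <- matrix(NA_integer_, nrow(chars), ncol(chars),
                  dimnames = list(snp$snp_id, ind$id))
  calls[chars == "0"] <- 0L
  calls[chars == "2"] <- 1L
  sites <- tibble::tibble(
    snp_id = snp$snp_id, chrom = snp$chrom, bp = as.numeric(snp$bp),
    cM = snp$gpos_M * 100, ref = snp$ref, alt = snp$alt
  )
  list(mat = pseudohaploid_matrix(sites, calls),
       roster = tibble::as_tibble(ind))
}

# deterministic synthetic mtDNA reference (fixed internal seed)
mt_reference <- function(length = 16569L) {
  with_seed(20260101L, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
}

#' Write mtDNA consensus sequences as FASTA
#'
#' Renders each individual's mutated-position set as a full-length sequence
#' on a fixed synthetic circular reference (16,569 positions): a mutated
#' position carries the next base in the A-C-G-T cycle, so distinct mutation
#' sets always differ at exactly their symmetric difference.
#'
#' @param mtset An `mt_set` from [transmit_uniparental()].
#' @param path Output FASTA path.
#' @param ids Individuals to write (default all).
#' @return `path`, invisibly.
#' @export
write_mt_fasta <- function(mtset, path, ids = NULL) {
  stopifnot(inherits(mtset, "mt_set"))
  if (is.null(ids)) ids <- names(mtset$sets)
  ref <- strsplit(mt_reference(mtset$ref_length), "")[[1]]
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  seqs <- vapply(ids, function(i) {
    s <- ref
    pos <- mtset$sets[[i]]
    if (length(pos) > 0) s[pos] <- cycle[s[pos]]
    paste(s, collapse = "")
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read mtDNA FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_mt_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a haplogroup tree from newick plus a marker table
#'
#' The newick file gives the topology (all nodes labelled); the marker TSV
#' has columns `haplogroup`, `marker_id`, `ancestral`, `derived`.
#'
#' @param tree_path Newick file with labelled internal nodes.
#' @param markers_path TSV of branch-defining markers.
#' @return A [haplogroup_table()].
#' @export
read_haplogroup_tree <- function(tree_path, markers_path) {
  tr <- ape::read.tree(tree_path)
  labels <- c(tr$tip.label, tr$node.label)
  if (any(labels == "" | is.na(labels))) {
    stop("all nodes of the haplogroup tree must be labelled", call. = FALSE)
  }
  edges <- tibble::tibble(
    parent = labels[tr$edge[, 1]],
    child = labels[tr$edge[, 2]]
  )
  markers <- readr::read_tsv(markers_path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  haplogroup_table(edges, markers)
}

#' Write or read genomic segment tables (IBD, ROH) as TSV
#'
#' @param segments Segment tibble (`id` or `id1`/`id2`, `chrom`,
#'   `start_cM`, `end_cM`, optional `state`).
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_segments_tsv <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}
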