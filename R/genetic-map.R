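#' Define a genetic map
#'
#' A genetic map lists the chromosomes the simulator and the interval
#' arithmetic operate on, with one constant centimorgan-per-basepair rate per
#' chromosome. All in-memory interval coordinates in matrikin are half-open
#' `[start, end)` in cM, 0-based; physical positions are derived by the
#' per-chromosome rate.
#'
#' @param chrom Character vector of unique chromosome identifiers.
#' @param length_cM Numeric vector of genetic lengths in centimorgans (> 0).
#' @param length_bp Numeric vector of physical lengths in base pairs (> 0).
#'
#' @return A tibble of class `genetic_map` with columns `chrom`, `length_cM`,
#'   `length_bp`.
#' @examples
#' genetic_map(c("1", "2"), c(120, 90), c(1.2e8, 0.9e8))
#' @export
genetic_map <- function(chrom, length_cM, length_bp) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom) > 0) {
    stop("chromosome identifiers must be unique", call. = FALSE)
  }
  if (length(chrom) != length(length_cM) || length(chrom) != length(length_bp)) {
    stop("chrom, length_cM and length_bp must have equal length", call. = FALSE)
  }
  if (any(!is.finite(length_cM)) || any(length_cM <= 0)) {
    stop("genetic lengths must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("physical lengths must be finite and > 0", call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = chrom,
    length_cM = as.numeric(length_cM),
    length_bp = as.numeric(length_bp)
  )
  class(out) <- c("genetic_map", class(out))
  out
}

#' Default 22-autosome genetic map
#'
#' Approximate human autosome genetic (cM) and physical (bp) lengths, totalling
#' about 35 Morgans, matching the scale of the 1240k capture panel the
#' pipeline emulates. Fully replaceable by any user-supplied [genetic_map()];
#' tests use [toy_genetic_map()] for speed.
#'
#' @return A `genetic_map` with chromosomes "1".."22".
#' @export
default_genetic_map <- function() {
  genetic_map(
    chrom = as.character(1:22),
    length_cM = c(
      286, 269, 223, 214, 204, 192, 187, 168, 166, 181, 158,
      175, 126, 119, 141, 134, 128, 117, 108, 108, 62, 74
    ),
    length_bp = 1e6 * c(
      249, 243, 198, 191, 181, 171, 159, 146, 141, 134, 135,
      133, 115, 107, 102, 90, 81, 78, 59, 63, 48, 51
    )
  )
}

#' Small three-chromosome map for examples and tests
#'
#' @param length_cM Genetic lengths for the three chromosomes.
#' @return A `genetic_map` with chromosomes "1".."3".
#' @export
toy_genetic_map <- function(length_cM = c(150, 100, 80)) {
  genetic_map(as.character(seq_along(length_cM)), length_cM, length_cM * 1e6)
}

total_map_cM <- function(map) sum(map$length_cM)

assert_genetic_map <- function(map) {
  if (!inherits(map, "genetic_map")) {
    if (is.data.frame(map) &&
        all(c("chrom", "length_cM", "length_bp") %in% names(map))) {
      return(genetic_map(map$chrom, map$length_cM, map$length_bp))
    }
    stop("`map` must be a genetic_map (see genetic_map())", call. = FALSE)
  }
  map
}

# cM -> bp under the chromosome's constant rate
cm_to_bp <- function(map, chrom, cM) {
  i <- match(as.character(chrom), map$chrom)
  if (anyNA(i)) stop("unknown chromosome in cm_to_bp()", call. = FALSE)
  round(cM / map$length_cM[i] * map$length_bp[i])
}

bp_to_cm <- function(map, chrom, bp) {
  i <- match(as.character(chrom), map$chrom)
  if (anyNA(i)) stop("unknown chromosome in bp_to_cm()", call. = FALSE)
  bp / map$length_bp[i] * map$length_cM[i]
}
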