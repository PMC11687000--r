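#' Construct a phased haplotype matrix
#'
#' A minimal container for phased biallelic haplotypes: a 0/1 matrix with
#' one row per haplotype and one column per site, with strictly increasing
#' site positions (1-based bp) as column names.
#'
#' @param alleles Numeric/integer matrix of 0/1 entries, haplotypes x sites.
#' @param positions Strictly increasing site positions (bp).
#' @param hap_ids Optional haplotype identifiers.
#' @return A `hap_matrix` object.
#' @export
hap_matrix <- function(alleles, positions, hap_ids = NULL) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L))) abort("haplotype entries must be 0/1.")
  if (nrow(alleles) < 2L) abort("need at least 2 haplotypes.")
  if (length(positions) != ncol(alleles)) {
    abort("`positions` must have one entry per site column.")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("site positions must be strictly increasing.")
  }
  storage.mode(alleles) <- "integer"
  colnames(alleles) <- as.character(positions)
  rownames(alleles) <- hap_ids %||% sprintf("hap_%d", seq_len(nrow(alleles)))
  structure(list(alleles = alleles, positions = as.numeric(positions)),
            class = "hap_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise linkage disequilibrium r-squared
#'
#' The standard composite measure for two biallelic sites on phased
#' haplotypes: with allele frequencies `p_A`, `p_B` and joint frequency
#' `p_AB`, `D = p_AB - p_A p_B` and
#' `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`. Symmetric in its arguments
#' and invariant to relabelling either site's alleles. A monomorphic site
#' makes r-squared undefined: the function returns `NA` with a warning
#' rather than 0.
#'
#' @param a,b 0/1 allele vectors over the same haplotypes.
#' @return r-squared in `[0, 1]`, or `NA` if either site is monomorphic.
#' @examples
#' r_squared(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'           c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))  # 0.642857...
#' @export
r_squared <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (!all(c(a, b) %in% c(0, 1))) abort("allele vectors must be 0/1.")
  p_a <- mean(a)
  p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warn("monomorphic site: r-squared undefined.")
    return(NA_real_)
  }
  d <- mean(a == 1 & b == 1) - p_a * p_b
  min(1, d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
}

#' r-squared profile of every site against an anchor site
#'
#' @param haps A [hap_matrix()].
#' @param anchor_pos Position (bp) of the anchor site (e.g. the GWAS lead
#'   SNP); must be present in the matrix.
#' @return A tibble with `pos` and `r2` (`NA` for monomorphic sites).
#' @export
r2_profile <- function(haps, anchor_pos) {
  j <- match(anchor_pos, haps$positions)
  if (is.na(j)) abort("anchor position not found among the sites.")
  anchor <- haps$alleles[, j]
  if (mean(anchor) %in% c(0, 1)) abort("anchor site is monomorphic.")
  r2 <- vapply(seq_along(haps$positions), function(k) {
    suppressWarnings(r_squared(haps$alleles[, k], anchor))
  }, numeric(1))
  tibble::tibble(pos = haps$positions, r2 = r2)
}

#' Derive LD blocks around an anchor site
#'
#' Finds maximal runs of consecutive sites whose r-squared with the anchor
#' meets the threshold, merges runs separated by at most `max_gap` bp, and
#' emits each as an interval spanning its outermost member sites (no
#' padding). Every member site satisfies `r2 >= r2_threshold`; monomorphic
#' sites never qualify.
#'
#' @inheritParams r2_profile
#' @param r2_threshold Minimum r-squared with the anchor (default 0.8,
#'   "high LD").
#' @param max_gap Merge qualifying runs separated by at most this many bp
#'   (default 10,000).
#' @param chrom Optional chromosome label attached to the blocks.
#' @param region Optional region name attached to the blocks.
#' @return A tibble of blocks: `chrom`, `start` (0-based), `end`
#'   (exclusive), `n_sites`, `min_r2`, `threshold`, `anchor_pos`,
#'   optional `region`. Zero rows when no site qualifies.
#' @export
ld_blocks <- function(haps, anchor_pos, r2_threshold = 0.8, max_gap = 10000,
                      chrom = NA_character_, region = NULL) {
  prof <- r2_profile(haps, anchor_pos)
  qual <- which(!is.na(prof$r2) & prof$r2 >= r2_threshold)
  anchor_idx <- match(anchor_pos, prof$pos)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_sites = integer(),
                          min_r2 = double(), threshold = double(),
                          anchor_pos = double())
  if (!is.null(region)) empty$region <- character()
  if (length(qual) == 0L) return(empty)
  # Runs of qualifying sites; a new block starts when the bp gap between
  # successive qualifying sites exceeds max_gap (intervening non-qualifying
  # sites inside a small gap do not break a block; they are not members).
  brk <- c(FALSE, diff(prof$pos[qual]) > max_gap)
  grp <- cumsum(brk)
  runs <- split(qual, grp)
  # The anchor is trivially in perfect LD with itself; a run containing only
  # the anchor site is no evidence of an LD block.
  runs <- runs[!vapply(runs, function(idx) identical(idx, anchor_idx),
                       logical(1))]
  if (length(runs) == 0L) return(empty)
  out <- purrr::map_dfr(runs, function(idx) {
    tibble::tibble(
      chrom = chrom,
      start = as.integer(min(prof$pos[idx]) - 1),
      end = as.integer(max(prof$pos[idx])),
      n_sites = length(idx),
      min_r2 = min(prof$r2[idx]),
      threshold = r2_threshold,
      anchor_pos = anchor_pos)
  })
  if (!is.null(region)) out$region <- region
  out
}
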