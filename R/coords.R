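#' Normalise chromosome labels
#'
#' Accepts both `"3"` and `"chr3"` styles and returns labels with the `"chr"`
#' prefix, so that interval operations never miss overlaps because two input
#' files used different naming conventions.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector with a `"chr"` prefix on every label.
#' @examples
#' norm_chrom(c("3", "chr3", "X"))
#' @export
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) return(character(0))
  ifelse(is.na(chrom) | chrom == "" | startsWith(chrom, "chr"),
         chrom, paste0("chr", chrom))
}

# All intervals in this package are 0-based half-open [start, end), the BED
# convention. VCF POS (1-based) maps to start = POS - 1; the 1-based display
# start is start + 1 and the display end equals `end`.

#' Convert between internal and display coordinates
#'
#' Internal intervals are 0-based half-open `[start, end)`; display
#' coordinates are the conventional 1-based inclusive pair. The two functions
#' are exact inverses.
#'
#' @param df A data frame with `start` and `end` columns (internal) or
#'   `start_display` and `end_display` columns.
#' @return A tibble with the alternative coordinate columns added.
#' @examples
#' to_display_coords(tibble::tibble(start = 0, end = 10))
#' @export
to_display_coords <- function(df) {
  dplyr::mutate(df, start_display = .data$start + 1L, end_display = .data$end)
}

#' @rdname to_display_coords
#' @export
to_internal_coords <- function(df) {
  dplyr::mutate(df, start = .data$start_display - 1L, end = .data$end_display)
}

# Overlapping row pairs between two interval tables, per chromosome.
# Returns tibble(x_idx, y_idx) of row indices with >= 1 bp overlap.
overlap_pairs <- function(x, y) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)),
            all(c("chrom", "start", "end") %in% names(y)))
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(tibble::tibble(x_idx = integer(), y_idx = integer()))
  }
  xs <- split(seq_len(nrow(x)), norm_chrom(x$chrom))
  ys <- split(seq_len(nrow(y)), norm_chrom(y$chrom))
  shared <- intersect(names(xs), names(ys))
  purrr::map_dfr(shared, function(ch) {
    xi <- xs[[ch]]
    yi <- ys[[ch]]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi]),
      IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi]))
    tibble::tibble(x_idx = xi[S4Vectors::queryHits(hits)],
                   y_idx = yi[S4Vectors::subjectHits(hits)])
  })
}

# Width of the pairwise intersection of [s1,e1) and [s2,e2); 0 when disjoint.
intersect_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# TRUE for rows of `x` overlapping any interval in `y` by >= 1 bp.
overlaps_any <- function(x, y) {
  hit <- rep(FALSE, nrow(x))
  hit[unique(overlap_pairs(x, y)$x_idx)] <- TRUE
  hit
}

#' Round half away from zero
#'
#' Report-style rounding in which 0.5 rounds up (R's `round()` rounds half to
#' even). Used when formatting tables to printed precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.225, 2.5), c(2, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
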