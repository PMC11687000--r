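annotation_classes <- c("enhancer_distal", "enhancer_proximal", "promoter",
                        "TFBS", "CTCF", "eQTL", "TSS", "miRNA_site",
                        "GWAS_hit", "other")

# Coerce free-text track labels onto the closed feature vocabulary.
normalise_feature_class <- function(x) {
  ifelse(x %in% annotation_classes, x, "other")
}

#' Functional-annotation features within a window around each locus
#'
#' Intersects loci with BED-like annotation tracks inside a symmetric window
#' (default +/- 2.5 kb, a plausible effect range for short structural
#' variants, repeats and transposable elements). Each hit carries a signed
#' distance: 0 when the feature overlaps the locus itself, otherwise the
#' display-coordinate difference to the nearest locus edge (positive
#' downstream of the locus in coordinate order, negative upstream). With
#' `anchor = "midpoint"` the distance is measured between midpoints instead.
#' Strand, if present in the tracks, is carried through but ignored for
#' overlap.
#'
#' @param loci Locus tibble (`locus_id`, `chrom`, `start`, `end`).
#' @param tracks Feature tibble: `chrom`, `start`, `end`, `feature_class`
#'   (free text; unknown labels map to `"other"`), optional `label`,
#'   `track`.
#' @param window Window half-width in bp (default 2500).
#' @param anchor `"edge"` (default) or `"midpoint"` distance convention.
#' @return A tibble of hits: locus columns, feature columns, `distance`
#'   (bp, `|distance| <= window`), `overlapping`.
#' @export
window_overlap <- function(loci, tracks, window = 2500,
                           anchor = c("edge", "midpoint")) {
  anchor <- match.arg(anchor)
  empty <- tibble::tibble(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), feature_class = character(), feature_start = integer(),
    feature_end = integer(), label = character(), distance = double(),
    overlapping = logical())
  if (nrow(loci) == 0L || is.null(tracks) || nrow(tracks) == 0L) return(empty)
  if (!"label" %in% names(tracks)) tracks$label <- NA_character_
  expanded <- dplyr::mutate(loci,
                            start = pmax(0L, .data$start - as.integer(window)),
                            end = .data$end + as.integer(window))
  pairs <- overlap_pairs(expanded, tracks)
  if (nrow(pairs) == 0L) return(empty)
  l <- loci[pairs$x_idx, ]
  f <- tracks[pairs$y_idx, ]
  ov <- intersect_width(l$start, l$end, f$start, f$end) > 0
  dist <- if (anchor == "edge") {
    dplyr::case_when(
      ov ~ 0,
      f$start >= l$end ~ as.numeric(f$start + 1L - l$end),   # downstream
      TRUE ~ as.numeric(f$end - (l$start + 1L)))             # upstream, < 0
  } else {
    dplyr::case_when(
      ov ~ 0,
      TRUE ~ round((f$start + f$end) / 2 - (l$start + l$end) / 2))
  }
  tibble::tibble(
    locus_id = l$locus_id, chrom = l$chrom, start = l$start, end = l$end,
    feature_class = normalise_feature_class(f$feature_class),
    feature_start = f$start, feature_end = f$end, label = f$label,
    distance = dist, overlapping = ov) |>
    dplyr::filter(abs(.data$distance) <= window)
}

#' Per-class annotation frequency across variant windows
#'
#' For a cohort of prioritised loci, the fraction whose window contains at
#' least one feature of each class (e.g. "distal enhancer-like elements in
#' 60% of variant windows").
#'
#' @param hits A [window_overlap()] result.
#' @param loci The full locus tibble the windows were computed for (so that
#'   loci with no hits still enter the denominator).
#' @return A tibble with `feature_class`, `n_loci_hit`, `frac` in `[0, 1]`,
#'   covering every class in the closed vocabulary.
#' @export
summarise_annotations <- function(hits, loci) {
  n_loci <- nrow(loci)
  counts <- hits |>
    dplyr::distinct(.data$locus_id, .data$feature_class) |>
    dplyr::count(.data$feature_class, name = "n_loci_hit")
  tibble::tibble(feature_class = annotation_classes) |>
    dplyr::left_join(counts, by = "feature_class") |>
    dplyr::mutate(n_loci_hit = dplyr::coalesce(.data$n_loci_hit, 0L),
                  frac = if (n_loci == 0L) 0 else .data$n_loci_hit / n_loci)
}
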