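#' Convert between error probability and Phred quality
#'
#' `phred_from_error()` maps a mean per-base error probability to the Phred
#' scale, `Q = -10 * log10(p)`; `error_from_phred()` is its exact inverse.
#' A Q9 read corresponds to roughly a 12.6% per-base error probability.
#'
#' @param p Error probabilities in (0, 1].
#' @param q Phred quality scores (>= 0).
#' @return Numeric vector of Phred scores or error probabilities.
#' @examples
#' phred_from_error(0.1)      # 10
#' error_from_phred(9)        # ~0.1259
#' @export
phred_from_error <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("error probabilities must lie in (0, 1].")
  }
  -10 * log10(p)
}

#' @rdname phred_from_error
#' @export
error_from_phred <- function(q) {
  if (any(!is.finite(q)) || any(q < 0)) abort("Phred scores must be >= 0.")
  10^(-q / 10)
}

#' Apply the sequencing read filter
#'
#' Removes reads below the quality/length thresholds applied automatically
#' during sequencing: reads shorter than `min_len` bp or with mean quality
#' below `min_q` are dropped; both boundaries are inclusive on the keep side
#' (a 500 bp, Q9.0 read is kept).
#'
#' @param reads Read-summary tibble with columns `read_len` (bp) and
#'   `mean_err` (mean per-base error probability).
#' @param min_q Minimum Phred quality (default 9).
#' @param min_len Minimum read length in bp (default 500).
#' @return A list with tibbles `kept` and `removed`;
#'   `nrow(kept) + nrow(removed) == nrow(reads)`.
#' @export
filter_reads <- function(reads, min_q = 9, min_len = 500) {
  q <- phred_from_error(reads$mean_err)
  keep <- q >= min_q & reads$read_len >= min_len
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Classify reads as on- or off-target
#'
#' A mapped read is on-target when its aligned interval overlaps any target
#' region by at least 1 bp (half-open intervals, so a read ending exactly at
#' a region start does not overlap). Unmapped reads (missing `chrom`) are
#' off-target and flagged.
#'
#' @param reads Read-summary tibble with `chrom`, `start`, `end`.
#' @param regions Target-region tibble.
#' @return `reads` with logical columns `on_target` and `unmapped` added.
#' @export
classify_on_target <- function(reads, regions) {
  unmapped <- is.na(reads$chrom) | reads$chrom == "*" | reads$chrom == ""
  on <- rep(FALSE, nrow(reads))
  mapped <- which(!unmapped)
  if (length(mapped) > 0L) {
    on[mapped] <- overlaps_any(reads[mapped, , drop = FALSE], regions)
  }
  dplyr::mutate(reads, on_target = on, unmapped = unmapped)
}

# Base-level split of each read's aligned bases into inside/outside regions.
aligned_base_split <- function(reads, regions) {
  aligned <- ifelse(is.na(reads$chrom) | reads$chrom == "*", 0L,
                    reads$end - reads$start)
  on_bases <- rep(0, nrow(reads))
  pairs <- overlap_pairs(reads, regions)
  if (nrow(pairs) > 0L) {
    w <- intersect_width(reads$start[pairs$x_idx], reads$end[pairs$x_idx],
                         regions$start[pairs$y_idx], regions$end[pairs$y_idx])
    agg <- tapply(w, pairs$x_idx, sum)
    on_bases[as.integer(names(agg))] <- as.numeric(agg)
  }
  tibble::tibble(aligned = as.numeric(aligned), on_bases = on_bases,
                 off_bases = as.numeric(aligned) - on_bases)
}

#' Per-sample on/off-target enrichment statistics
#'
#' For each sample and scope computes the Table-2-style statistics: mean read
#' length, mean read quality (mean of per-read error probabilities, converted
#' to Phred -- probability-space averaging, the platform convention), and
#' average fold coverage. On-target coverage is total aligned bases falling
#' inside target regions divided by total region length; off-target coverage
#' divides the remaining aligned bases by `genome_size` minus the total
#' region length. Coverage is base-level, so a read straddling a region
#' boundary contributes its inside bases to on-target coverage only.
#'
#' @param reads Read-summary tibble (`read_id`, `sample`, `chrom`, `start`,
#'   `end`, `read_len`, `mean_err`).
#' @param regions Target-region tibble.
#' @param genome_size Declared genome size in bp (off-target denominator).
#' @param qual_average `"probability"` (default) averages per-read error
#'   probabilities before converting to Phred; `"phred"` averages the
#'   per-read Phred scores arithmetically.
#' @return Tibble with one row per sample x scope: `sample`, `scope`,
#'   `n_reads`, `avg_len`, `avg_qual`, `avg_cov`. Scopes with zero reads get
#'   `n_reads = 0` and `NA` means.
#' @export
sample_stats <- function(reads, regions, genome_size,
                         qual_average = c("probability", "phred")) {
  qual_average <- match.arg(qual_average)
  target_len <- sum(regions$end - regions$start)
  if (genome_size <= target_len) {
    abort("`genome_size` must exceed the total target length.")
  }
  reads <- classify_on_target(reads, regions)
  split <- aligned_base_split(reads, regions)
  reads$on_bases <- split$on_bases
  reads$off_bases <- split$off_bases
  samples <- unique(reads$sample)
  grid <- tidyr::expand_grid(sample = samples,
                             scope = c("on_target", "off_target"))
  per <- reads |>
    dplyr::mutate(scope = ifelse(.data$on_target, "on_target", "off_target")) |>
    dplyr::group_by(.data$sample, .data$scope) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      avg_len = mean(.data$read_len),
      avg_qual = if (qual_average == "probability") {
        phred_from_error(mean(.data$mean_err))
      } else mean(phred_from_error(.data$mean_err)),
      .groups = "drop")
  cov <- reads |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(on_cov = sum(.data$on_bases) / target_len,
                     off_cov = sum(.data$off_bases) / (genome_size - target_len),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("on_cov", "off_cov"), names_to = "scope",
                        values_to = "avg_cov") |>
    dplyr::mutate(scope = ifelse(.data$scope == "on_cov", "on_target",
                                 "off_target"))
  grid |>
    dplyr::left_join(per, by = c("sample", "scope")) |>
    dplyr::left_join(cov, by = c("sample", "scope")) |>
    dplyr::mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L),
                  avg_cov = dplyr::coalesce(.data$avg_cov, 0)) |>
    dplyr::arrange(match(.data$sample, samples),
                   dplyr::desc(.data$scope))
}

#' Cohort mean and standard error of per-sample QC statistics
#'
#' Collapses per-sample enrichment statistics to a cohort summary row per
#' scope and metric: the mean and the standard error `SE = s / sqrt(n)`,
#' where `s` is the sample standard deviation (denominator `n - 1`) across
#' the `n` samples.
#'
#' @param stats Per-sample statistics tibble (see [sample_stats()] or
#'   [nanopore_run_qc()]) with columns `sample`, `scope` and one or more
#'   numeric metric columns.
#' @return Tibble with columns `scope`, `metric`, `n`, `mean`, `se`. With
#'   fewer than two samples `se` is `NA` (flagged, not zero).
#' @examples
#' cohort_summary(nanopore_run_qc())
#' @export
cohort_summary <- function(stats) {
  metrics <- setdiff(names(stats), c("sample", "scope", "n_reads"))
  metrics <- metrics[vapply(stats[metrics], is.numeric, logical(1))]
  out <- stats |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$scope, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = if (sum(!is.na(.data$value)) >= 2) {
        stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      } else NA_real_,
      .groups = "drop")
  if (any(out$n < 2)) {
    warn("standard error undefined for groups with fewer than 2 samples.")
  }
  out
}
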