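#' Run the full pipeline on a cohort bundle
#'
#' Orchestrates the whole analysis on an in-memory cohort (typically from
#' [generate_cohort()], or assembled from files with the package readers):
#' read filtering and enrichment QC, LD-block derivation from phased
#' haplotypes per region, the prioritisation cascade with audit, the
#' concordance matrix for the prioritised loci, and functional-annotation
#' window overlap. Deterministic: re-running on the same bundle reproduces
#' identical tables.
#'
#' @param bundle An `an_cohort` bundle (fields: `regions`, `calls`,
#'   `annotations`; optional `reads`, `haplotypes`, `tracks`,
#'   `bam_evidence`, `truth`).
#' @param config Configuration from [default_config()].
#' @return An object of class `nanosieve_run` with elements `qc`,
#'   `qc_cohort`, `ld_blocks`, `cascade`, `concordance`, `windows`,
#'   `annotation_summary`, `class_summary`, `score` (when truth is
#'   available), and `config`.
#' @export
run_pipeline <- function(bundle, config = default_config()) {
  regions <- bundle$regions
  genome_size <- bundle$params$genome_size %||% config$genome_size

  qc <- NULL; qc_cohort <- NULL; read_filter <- NULL
  if (!is.null(bundle$reads)) {
    fr <- filter_reads(bundle$reads, min_q = config$min_read_q,
                       min_len = config$min_read_len)
    read_filter <- tibble::tibble(n_in = nrow(bundle$reads),
                                  n_kept = nrow(fr$kept),
                                  n_removed = nrow(fr$removed))
    qc <- sample_stats(fr$kept, regions, genome_size = genome_size)
    qc_cohort <- cohort_summary(qc)
  }

  blocks <- NULL
  if (!is.null(bundle$haplotypes)) {
    blocks <- purrr::imap_dfr(bundle$haplotypes, function(hp, nm) {
      reg <- regions[regions$name == nm, ]
      ld_blocks(hp, anchor_pos = reg$lead_pos,
                r2_threshold = config$r2_threshold,
                max_gap = config$ld_max_gap,
                chrom = reg$chrom, region = nm)
    })
  }

  cascade <- run_cascade(bundle$calls, regions,
                         annotations = bundle$annotations,
                         ld_blocks = blocks,
                         bam_evidence = bundle$bam_evidence,
                         config = config)

  pri_ls <- subset_locus_set(cascade$locus_set,
                             cascade$prioritised$locus_id)
  concordance <- concordance_table(pri_ls, bundle$bam_evidence,
                                   samples = bundle$samples,
                                   len_tolerance = config$allele_len_tolerance)

  windows <- window_overlap(cascade$prioritised, bundle$tracks,
                            window = config$annotation_window,
                            anchor = config$distance_anchor)
  annotation_summary <- summarise_annotations(windows, cascade$prioritised)

  score <- if (!is.null(bundle$truth)) {
    score_prioritisation(cascade, bundle$truth)
  } else NULL

  structure(list(
    qc = qc, qc_cohort = qc_cohort, read_filter = read_filter,
    ld_blocks = blocks, cascade = cascade, concordance = concordance,
    windows = windows, annotation_summary = annotation_summary,
    class_summary = variant_class_summary(bundle$calls),
    score = score, samples = bundle$samples, regions = regions,
    config = config), class = "nanosieve_run")
}

#' Restrict a locus set to a subset of loci
#'
#' @param locus_set A [cluster_calls()] result.
#' @param locus_ids Locus ids to keep.
#' @return A `locus_set` containing only those loci and their member calls.
#' @export
subset_locus_set <- function(locus_set, locus_ids) {
  locus_set$loci <- locus_set$loci[locus_set$loci$locus_id %in% locus_ids, ]
  locus_set$calls <- locus_set$calls[locus_set$calls$locus_id %in% locus_ids, ]
  locus_set
}

#' @method glance nanosieve_run
#' @export
glance.nanosieve_run <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples),
    n_regions = nrow(x$regions),
    n_calls = x$class_summary$n_total,
    frac_nonsnv = x$class_summary$frac_nonsnv,
    n_prioritised = nrow(x$cascade$prioritised),
    mean_on_cov = if (is.null(x$qc_cohort)) NA_real_ else {
      x$qc_cohort$mean[x$qc_cohort$scope == "on_target" &
                         x$qc_cohort$metric == "avg_cov"]
    })
}

#' @export
print.nanosieve_run <- function(x, ...) {
  cat("<nanosieve_run>\n")
  print(glance(x), ...)
  invisible(x)
}

# Markdown pipe table from a data frame (for the plain-text report).
md_table <- function(df) {
  if (nrow(df) == 0L) return("(no rows)")
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 6) else
      as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

# Round QC columns to report precision: integer bp, 1 dp quality/coverage.
format_qc <- function(qc) {
  dplyr::mutate(qc,
                avg_len = round_half_up(.data$avg_len, 0),
                avg_qual = round_half_up(.data$avg_qual, 1),
                avg_cov = round_half_up(.data$avg_cov, 1))
}

#' Render a plain-text (Markdown) report of a pipeline run
#'
#' Produces a human-readable summary mirroring the study's table layouts:
#' target regions, per-sample enrichment QC with a cohort mean/SE row
#' (lengths as integer bp, quality and coverage to 1 decimal place, standard
#' errors to 2, half-up), the per-stage audit, the prioritised concordance
#' matrix, and annotation-window frequencies.
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of Markdown lines.
#' @export
render_report <- function(run) {
  lines <- c("# Targeted structural-variant prioritisation report", "")
  lines <- c(lines,
             sprintf("## Target regions (n = %d)", nrow(run$regions)), "",
             md_table(run$regions), "")
  if (!is.null(run$qc)) {
    lines <- c(lines,
               sprintf("## Enrichment QC (%d samples)", length(run$samples)),
               "",
               md_table(format_qc(run$qc)), "",
               "### Cohort mean and standard error", "",
               md_table(dplyr::mutate(run$qc_cohort,
                                      mean = round_half_up(.data$mean, 2),
                                      se = round_half_up(.data$se, 2))), "")
  }
  lines <- c(lines, "## Variant class summary", "",
             md_table(dplyr::mutate(run$class_summary,
                                    frac_nonsnv = round_half_up(
                                      .data$frac_nonsnv, 3))), "")
  lines <- c(lines, "## Prioritisation audit", "",
             md_table(run$cascade$audit), "")
  lines <- c(lines,
             sprintf("## Prioritised loci (n = %d)",
                     nrow(run$cascade$prioritised)), "",
             md_table(run$concordance), "")
  lines <- c(lines, "## Annotation classes within the variant windows", "",
             md_table(dplyr::mutate(run$annotation_summary,
                                    frac = round_half_up(.data$frac, 2))), "")
  lines
}
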