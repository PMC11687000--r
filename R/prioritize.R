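#' Default pipeline configuration
#'
#' One list governs every threshold in the pipeline, with the study design's
#' values as defaults: 100 kb flanks (200 kb regions), the Q >= 9 / >= 500 bp
#' read filter, caller quality >= 9 (caller-native scale), indels kept only
#' when strictly longer than 10 bp, HIGH predicted impact with no existing
#' rsID, LD blocks at r-squared >= 0.8, and a +/- 2.5 kb functional
#' annotation window.
#'
#' @param ... Named overrides of individual defaults.
#' @return A named list of configuration values.
#' @examples
#' default_config(qual_min = 12)
#' @export
default_config <- function(...) {
  cfg <- list(
    flank = 100000L,
    min_read_q = 9,
    min_read_len = 500L,
    qual_min = 9,
    indel_min_len = 10L,
    require_no_rsid = TRUE,
    impact_pad = 100L,
    annotation_window = 2500L,
    distance_anchor = "edge",
    r2_threshold = 0.8,
    ld_max_gap = 10000L,
    max_breakpoint_dist = 500L,
    min_reciprocal_overlap = 0.5,
    max_locus_span = 100000L,
    allele_len_tolerance = 0,
    genome_size = 4.8e6,
    stages = c("region", "quality", "class", "impact", "ld")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, dots)
}

stage_result <- function(kept, excluded, reason, stage, id) {
  attr(kept, "excluded") <- tibble::tibble(
    stage = stage, id = id, reason = reason)
  kept
}

#' Cascade stage 1: restrict calls to the target regions
#'
#' Retains calls whose interval overlaps a target region by at least 1 bp.
#'
#' @param calls Call tibble.
#' @param regions Target-region tibble.
#' @return Filtered calls; excluded rows recorded in the `excluded`
#'   attribute with reasons.
#' @export
filter_by_region <- function(calls, regions) {
  keep <- overlaps_any(calls, regions)
  stage_result(calls[keep, , drop = FALSE], calls[!keep, , drop = FALSE],
               reason = rep("outside_target_regions", sum(!keep)),
               stage = "region", id = calls$source[!keep])
}

#' Cascade stage 2: caller quality filter
#'
#' Retains calls with caller-native quality `>= qual_min` (inclusive, so a
#' call at exactly 9 survives the default) or from a no-quality source (STR
#' locus tables), which are kept and flagged `qual_exempt`.
#'
#' @param calls Call tibble.
#' @param qual_min Minimum caller-native quality (default 9).
#' @return Filtered calls with a `qual_exempt` column; exclusions in the
#'   `excluded` attribute.
#' @export
filter_by_quality <- function(calls, qual_min = 9) {
  exempt <- is.na(calls$qual)
  keep <- exempt | calls$qual >= qual_min
  kept <- dplyr::mutate(calls[keep, , drop = FALSE],
                        qual_exempt = exempt[keep])
  stage_result(kept, calls[!keep, , drop = FALSE],
               reason = rep("below_quality_threshold", sum(!keep)),
               stage = "quality", id = calls$source[!keep])
}

#' Cascade stage 3: variant class filter
#'
#' Removes SNV loci entirely and keeps insertions/deletions only when
#' strictly longer than `indel_min_len` bp (a 10 bp insertion is dropped
#' under the default); repeat (STR) and transposable-element (TE) loci are
#' kept regardless of length.
#'
#' @param loci Locus tibble with `var_class` and `sv_len` (variant length in
#'   bp) columns.
#' @param indel_min_len Strict lower bound on indel length (default 10).
#' @return Filtered loci; exclusions in the `excluded` attribute.
#' @export
filter_by_class <- function(loci, indel_min_len = 10) {
  sv_len <- if ("sv_len" %in% names(loci)) loci$sv_len else {
    loci$end - loci$start
  }
  reason <- dplyr::case_when(
    loci$var_class == "SNV" ~ "snv",
    loci$var_class %in% c("INS", "DEL") & !(sv_len > indel_min_len) ~
      "indel_too_short",
    TRUE ~ NA_character_)
  keep <- is.na(reason)
  stage_result(loci[keep, , drop = FALSE], loci[!keep, , drop = FALSE],
               reason = reason[!keep], stage = "class",
               id = loci$locus_id[!keep])
}

impact_order <- c(HIGH = 4L, MODERATE = 3L, LOW = 2L, MODIFIER = 1L)

#' Cascade stage 4: predicted impact and novelty filter
#'
#' Retains loci annotated with `"HIGH"` predicted impact and no existing
#' reported rsID (both the VCF ID field and the annotation table must lack
#' one). Loci are matched to annotation rows by interval overlap after
#' padding the locus by `pad` bp, which absorbs caller breakpoint jitter;
#' multiple overlapping rows reduce to the worst impact, and an rsID on any
#' row counts as known. Loci with no annotation row are quarantined with
#' reason `"needs_annotation"`, never silently dropped.
#'
#' @param loci Locus tibble.
#' @param annotations Impact table: `chrom`, `start`, `end`, `impact`
#'   (HIGH/MODERATE/LOW/MODIFIER), `rsid` (`NA` when novel).
#' @param require_no_rsid Require the absence of a known rsID (default TRUE).
#' @param pad Locus padding in bp for annotation matching (default 100).
#' @return Filtered loci with `impact` and `rsid` columns; exclusions
#'   (including the quarantine bin) in the `excluded` attribute.
#' @export
filter_by_impact <- function(loci, annotations, require_no_rsid = TRUE,
                             pad = 100) {
  padded <- dplyr::mutate(loci, start = pmax(0L, .data$start - as.integer(pad)),
                          end = .data$end + as.integer(pad))
  pairs <- overlap_pairs(padded, annotations)
  ann <- if (nrow(pairs) == 0L) {
    tibble::tibble(idx = integer(), impact = character(),
                   rsid = character())
  } else tibble::tibble(
    idx = pairs$x_idx,
    impact = annotations$impact[pairs$y_idx],
    rsid = annotations$rsid[pairs$y_idx]) |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(
      impact = .data$impact[which.max(impact_order[.data$impact])],
      rsid = if (all(is.na(.data$rsid))) NA_character_ else {
        .data$rsid[!is.na(.data$rsid)][1]
      },
      .groups = "drop")
  loci$impact <- NA_character_
  loci$rsid <- NA_character_
  loci$impact[ann$idx] <- ann$impact
  loci$rsid[ann$idx] <- ann$rsid
  annotated <- seq_len(nrow(loci)) %in% ann$idx
  reason <- dplyr::case_when(
    !annotated ~ "needs_annotation",
    loci$impact != "HIGH" ~ "impact_not_high",
    require_no_rsid & !is.na(loci$rsid) ~ "known_rsid",
    TRUE ~ NA_character_)
  keep <- is.na(reason)
  stage_result(loci[keep, , drop = FALSE], loci[!keep, , drop = FALSE],
               reason = reason[!keep], stage = "impact",
               id = loci$locus_id[!keep])
}

#' Cascade stage 5: linkage-disequilibrium block filter
#'
#' Retains loci overlapping a high-LD block around their region's lead SNP
#' by at least 1 bp. Regions with no declared blocks pass all their loci
#' through flagged `lenient_ld` (the lenient treatment applied to weaker,
#' non-coding GWAS signals where LD blocks could not be confidently drawn).
#'
#' @param loci Locus tibble.
#' @param ld_blocks Block tibble (`chrom`, `start`, `end`, optional
#'   `region`), e.g. from [ld_blocks()].
#' @param regions Target-region tibble (used to decide which regions carry
#'   blocks).
#' @return Filtered loci with a `lenient_ld` flag; exclusions in the
#'   `excluded` attribute.
#' @export
filter_by_ld <- function(loci, ld_blocks, regions) {
  if (is.null(ld_blocks)) ld_blocks <- tibble::tibble(
    chrom = character(), start = integer(), end = integer())
  region_idx <- rep(NA_integer_, nrow(loci))
  pairs <- overlap_pairs(loci, regions)
  region_idx[pairs$x_idx] <- pairs$y_idx
  region_name <- regions$name[region_idx]
  block_regions <- if ("region" %in% names(ld_blocks)) {
    unique(ld_blocks$region)
  } else {
    regions$name[unique(overlap_pairs(ld_blocks, regions)$y_idx)]
  }
  in_block <- overlaps_any(loci, ld_blocks)
  lenient <- !is.na(region_name) & !(region_name %in% block_regions)
  keep <- in_block | lenient
  kept <- dplyr::mutate(loci[keep, , drop = FALSE],
                        region = region_name[keep],
                        lenient_ld = lenient[keep])
  stage_result(kept, loci[!keep, , drop = FALSE],
               reason = rep("outside_ld_blocks", sum(!keep)),
               stage = "ld", id = loci$locus_id[!keep])
}

audit_row <- function(stage, unit, n_in, n_out) {
  tibble::tibble(stage = stage, unit = unit, n_in = n_in, n_out = n_out,
                 n_excluded = n_in - n_out)
}

#' Run the staged prioritisation cascade
#'
#' Applies the filter stages in their fixed order -- target region, caller
#' quality, (clustering into loci), non-SNV class, predicted impact without
#' rsID, LD-block overlap -- and returns the surviving loci together with a
#' complete audit: per-stage in/out counts and a per-record exclusion reason
#' for everything removed. Stages can be disabled (via `config$stages`) but
#' not reordered. The cascade is deterministic: identical inputs give
#' identical audits.
#'
#' @param calls Normalised call tibble (all callers, all samples).
#' @param regions Target-region tibble.
#' @param annotations Impact/rsID annotation table (see
#'   [filter_by_impact()]); required when the `"impact"` stage is enabled.
#' @param ld_blocks LD-block tibble (see [filter_by_ld()]).
#' @param bam_evidence Optional BAM-inspection table, attached to the result
#'   for presence/concordance reporting.
#' @param config Configuration list from [default_config()].
#' @return An object of class `sv_cascade`: list with `prioritised` (locus
#'   tibble), `locus_set`, `audit`, `exclusions`, `presence`, `config`.
#' @export
run_cascade <- function(calls, regions, annotations = NULL, ld_blocks = NULL,
                        bam_evidence = NULL, config = default_config()) {
  stages <- config$stages
  audit <- list()
  exclusions <- list()
  grab <- function(x) {
    ex <- attr(x, "excluded")
    if (!is.null(ex) && nrow(ex) > 0L) exclusions[[length(exclusions) + 1L]] <<- ex
    x
  }

  if ("region" %in% stages) {
    n_in <- nrow(calls)
    calls <- grab(filter_by_region(calls, regions))
    audit[[length(audit) + 1L]] <- audit_row("region", "call", n_in, nrow(calls))
  }
  if ("quality" %in% stages) {
    n_in <- nrow(calls)
    calls <- grab(filter_by_quality(calls, config$qual_min))
    audit[[length(audit) + 1L]] <- audit_row("quality", "call", n_in, nrow(calls))
  }

  ls <- cluster_calls(calls,
                      max_breakpoint_dist = config$max_breakpoint_dist,
                      min_reciprocal_overlap = config$min_reciprocal_overlap,
                      max_locus_span = config$max_locus_span)
  loci <- augment_loci(ls)
  audit[[length(audit) + 1L]] <- audit_row("cluster", "call->locus",
                                           nrow(calls), nrow(loci))

  if ("class" %in% stages) {
    n_in <- nrow(loci)
    loci <- grab(filter_by_class(loci, config$indel_min_len))
    audit[[length(audit) + 1L]] <- audit_row("class", "locus", n_in, nrow(loci))
  }
  if ("impact" %in% stages) {
    if (is.null(annotations)) {
      abort("the impact stage is enabled but no annotation table was given.")
    }
    n_in <- nrow(loci)
    loci <- grab(filter_by_impact(loci, annotations,
                                  require_no_rsid = config$require_no_rsid,
                                  pad = config$impact_pad))
    audit[[length(audit) + 1L]] <- audit_row("impact", "locus", n_in, nrow(loci))
  }
  if ("ld" %in% stages) {
    n_in <- nrow(loci)
    loci <- grab(filter_by_ld(loci, ld_blocks, regions))
    audit[[length(audit) + 1L]] <- audit_row("ld", "locus", n_in, nrow(loci))
  }

  presence <- if (nrow(loci) > 0L) {
    keep_ls <- ls
    keep_ls$loci <- dplyr::semi_join(ls$loci, loci, by = "locus_id")
    keep_ls$calls <- dplyr::semi_join(ls$calls, loci, by = "locus_id")
    presence_table(keep_ls, bam_evidence)
  } else tibble::tibble(locus_id = character(), sample = character(),
                        via_caller = logical(), via_bam = logical(),
                        present = logical())

  structure(list(
    prioritised = loci,
    locus_set = ls,
    audit = dplyr::bind_rows(audit),
    exclusions = dplyr::bind_rows(
      tibble::tibble(stage = character(), id = character(),
                     reason = character()),
      exclusions),
    presence = presence,
    bam_evidence = bam_evidence,
    config = config), class = "sv_cascade")
}

# Locus table enriched with the representative variant length per locus.
augment_loci <- function(locus_set) {
  lens <- locus_set$calls |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(sv_len = if (all(is.na(.data$alt_len))) NA_integer_ else {
      max(.data$alt_len, na.rm = TRUE)
    }, .groups = "drop")
  locus_set$loci |>
    dplyr::left_join(lens, by = "locus_id") |>
    dplyr::mutate(sv_len = dplyr::coalesce(.data$sv_len,
                                           .data$end - .data$start))
}

#' @method tidy sv_cascade
#' @export
tidy.sv_cascade <- function(x, ...) x$audit

#' @method glance sv_cascade
#' @export
glance.sv_cascade <- function(x, ...) {
  tibble::tibble(
    n_calls_in = x$audit$n_in[1],
    n_loci = nrow(x$locus_set$loci),
    n_prioritised = nrow(x$prioritised),
    n_excluded = nrow(x$exclusions),
    n_quarantined = sum(x$exclusions$reason == "needs_annotation"),
    stages = paste(x$audit$stage, collapse = ">"))
}

#' @export
print.sv_cascade <- function(x, ...) {
  cat("<sv_cascade>\n")
  print(x$audit, ...)
  cat(sprintf("%d prioritised locus/loci\n", nrow(x$prioritised)))
  invisible(x)
}

#' Score prioritised loci against a planted truth set
#'
#' Matches prioritised loci to truth variants by chromosome and interval
#' overlap (after symmetric padding, to absorb breakpoint jitter) and
#' reports precision and recall with respect to the truth rows flagged
#' `interesting`.
#'
#' @param cascade An [run_cascade()] result (or a locus tibble).
#' @param truth Truth-variant tibble with `chrom`, `start`, `end`,
#'   `interesting`.
#' @param pad Matching pad in bp (default 500).
#' @return One-row tibble: `n_prioritised`, `n_truth`, `tp`, `precision`,
#'   `recall`.
#' @export
score_prioritisation <- function(cascade, truth, pad = 500) {
  loci <- if (inherits(cascade, "sv_cascade")) cascade$prioritised else cascade
  interesting <- truth[truth$interesting, , drop = FALSE]
  padded <- dplyr::mutate(loci, start = pmax(0L, .data$start - as.integer(pad)),
                          end = .data$end + as.integer(pad))
  pairs <- overlap_pairs(padded, interesting)
  tibble::tibble(
    n_prioritised = nrow(loci),
    n_truth = nrow(interesting),
    tp = length(unique(pairs$x_idx)),
    precision = ifelse(nrow(loci) == 0, NA_real_,
                       length(unique(pairs$x_idx)) / nrow(loci)),
    recall = ifelse(nrow(interesting) == 0, NA_real_,
                    length(unique(pairs$y_idx)) / nrow(interesting)))
}
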