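#' Cluster calls across callers and samples into variant loci
#'
#' Single-linkage clustering of normalised calls within a chromosome under a
#' class-compatibility matrix, so that the same underlying variant reported
#' by different callers (with breakpoint jitter and different class labels)
#' lands in one locus:
#' \itemize{
#'   \item SNVs match only SNVs, at the exact position with identical
#'     alleles;
#'   \item insertions match insertions with breakpoint distance
#'     `<= max_breakpoint_dist`;
#'   \item deletions match deletions with breakpoint distance
#'     `<= max_breakpoint_dist` and reciprocal overlap
#'     `>= min_reciprocal_overlap`;
#'   \item STR calls match STR, INS and DEL calls by >= 1 bp interval
#'     overlap (length-change calls inside a repeat locus are repeat
#'     evidence);
#'   \item TE calls match TE and INS calls by >= 1 bp overlap.
#' }
#' Calls are sorted by (chrom, start, end, caller, sample) before linking,
#' so the partition is invariant to input order. Pathologically long loci
#' (span above `max_locus_span`) are split at their largest internal gap
#' with a warning.
#'
#' @param calls A call tibble (see [callset]).
#' @param max_breakpoint_dist Maximum breakpoint distance in bp (default 500).
#' @param min_reciprocal_overlap Minimum reciprocal overlap for DEL-DEL
#'   matches (default 0.5).
#' @param max_locus_span Span in bp above which a cluster is split (default
#'   100,000).
#' @return An object of class `locus_set`: a list with `loci` (one row per
#'   locus: `locus_id`, `chrom`, `start`, `end`, `var_class`, `n_calls`),
#'   `calls` (input calls with a `locus_id` column), and `params`.
#' @export
cluster_calls <- function(calls, max_breakpoint_dist = 500,
                          min_reciprocal_overlap = 0.5,
                          max_locus_span = 100000) {
  calls <- call_tibble_from(calls) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$caller,
                   .data$sample)
  n <- nrow(calls)
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  if (n > 1L) {
    expanded <- dplyr::mutate(calls,
      start = pmax(0L, .data$start - as.integer(max_breakpoint_dist)),
      end = .data$end + as.integer(max_breakpoint_dist))
    pairs <- overlap_pairs(expanded, expanded)
    pairs <- pairs[pairs$x_idx < pairs$y_idx, , drop = FALSE]
    if (nrow(pairs) > 0L) {
      ok <- calls_match(calls[pairs$x_idx, ], calls[pairs$y_idx, ],
                        max_breakpoint_dist, min_reciprocal_overlap)
      for (k in which(ok)) {
        a <- find(pairs$x_idx[k]); b <- find(pairs$y_idx[k])
        if (a != b) comp[max(a, b)] <- min(a, b)
      }
    }
  }
  if (n == 0L) {
    calls$locus_id <- character(0)
    return(structure(list(
      loci = tibble::tibble(locus_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            var_class = character(), n_calls = integer()),
      calls = calls,
      params = list(max_breakpoint_dist = max_breakpoint_dist,
                    min_reciprocal_overlap = min_reciprocal_overlap,
                    max_locus_span = max_locus_span)),
      class = "locus_set"))
  }
  cluster <- vapply(seq_len(n), find, integer(1))
  cluster <- split_mega_clusters(calls, cluster, max_locus_span)
  # Stable relabel in (chrom, start) order of each cluster's first member.
  first_idx <- vapply(split(seq_len(n), cluster), min, integer(1))
  ord <- order(calls$chrom[first_idx], calls$start[first_idx], first_idx)
  relabel <- setNames(seq_along(ord), names(first_idx)[ord])
  calls$locus_id <- sprintf("locus_%04d", relabel[as.character(cluster)])
  loci <- calls |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      var_class = locus_class(.data$var_class),
      n_calls = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$locus_id)
  structure(list(loci = loci, calls = calls,
                 params = list(max_breakpoint_dist = max_breakpoint_dist,
                               min_reciprocal_overlap = min_reciprocal_overlap,
                               max_locus_span = max_locus_span)),
            class = "locus_set")
}

# Vectorised pairwise match predicate over aligned rows of a and b.
calls_match <- function(a, b, max_bp_dist, min_ro) {
  same_chrom <- norm_chrom(a$chrom) == norm_chrom(b$chrom)
  ca <- a$var_class; cb <- b$var_class
  bp_dist <- abs(a$start - b$start)
  ov <- intersect_width(a$start, a$end, b$start, b$end)
  recip <- ov / pmax(1, a$end - a$start) >= min_ro &
    ov / pmax(1, b$end - b$start) >= min_ro
  # unordered class-pair membership
  pair_in <- function(s1, s2) {
    (ca %in% s1 & cb %in% s2) | (ca %in% s2 & cb %in% s1)
  }
  snv <- ca == "SNV" & cb == "SNV" & a$start == b$start &
    !is.na(a$alt_seq) & !is.na(b$alt_seq) & a$alt_seq == b$alt_seq
  ins <- ca == "INS" & cb == "INS" & bp_dist <= max_bp_dist
  del <- ca == "DEL" & cb == "DEL" & bp_dist <= max_bp_dist & recip
  str_pair <- pair_in("STR", c("STR", "INS", "DEL")) & ov >= 1
  te_pair <- pair_in("TE", c("TE", "INS")) & ov >= 1
  cpx <- ca == "COMPLEX" & cb == "COMPLEX" & ov >= 1
  same_chrom & (snv | ins | del | str_pair | te_pair | cpx)
}

# Split clusters whose span exceeds max_span at their largest internal gap.
split_mega_clusters <- function(calls, cluster, max_span) {
  repeat {
    spans <- tapply(seq_len(nrow(calls)), cluster, function(idx) {
      max(calls$end[idx]) - min(calls$start[idx])
    })
    big <- names(spans)[spans > max_span]
    if (length(big) == 0L) return(cluster)
    changed <- FALSE
    for (cl in big) {
      idx <- which(cluster == as.integer(cl))
      idx <- idx[order(calls$start[idx])]
      run_end <- cummax(calls$end[idx])
      gaps <- calls$start[idx][-1] - run_end[-length(idx)]
      if (length(gaps) == 0L || max(gaps) <= 0) next
      cut <- which.max(gaps)
      cluster[idx[(cut + 1L):length(idx)]] <- max(cluster) + 1L
      changed <- TRUE
      warn(sprintf("split over-long locus (span > %g bp) at its largest gap.",
                   max_span))
    }
    if (!changed) return(cluster)
  }
}

# Consensus class label for a locus from its member classes.
locus_class <- function(classes) {
  if (any(classes == "TE")) return("TE")
  if (any(classes == "STR")) return("STR")
  if (any(classes == "COMPLEX")) return("COMPLEX")
  if (any(classes == "DEL") && !any(classes == "INS")) return("DEL")
  if (any(classes == "INS") && !any(classes == "DEL")) return("INS")
  if (any(classes %in% c("INS", "DEL"))) {
    return(names(which.max(table(classes[classes %in% c("INS", "DEL")]))))
  }
  "SNV"
}

#' @method tidy locus_set
#' @export
tidy.locus_set <- function(x, ...) x$loci

#' @method glance locus_set
#' @export
glance.locus_set <- function(x, ...) {
  tibble::tibble(n_calls = nrow(x$calls), n_loci = nrow(x$loci),
                 n_samples = dplyr::n_distinct(x$calls$sample),
                 n_callers = dplyr::n_distinct(x$calls$caller))
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d loci from %d calls (%d samples, %d callers)\n",
              nrow(x$loci), nrow(x$calls),
              dplyr::n_distinct(x$calls$sample),
              dplyr::n_distinct(x$calls$caller)))
  print(x$loci, ...)
  invisible(x)
}

#' Per-sample variant presence under the union rule
#'
#' A variant locus is present in a sample if at least one caller reports a
#' non-reference genotype there, or if manual alignment (BAM) inspection
#' flagged a difference from the reference -- union semantics with no
#' majority vote, presence/absence rather than consensus genotype.
#' Unresolved genotypes do not count as caller support on their own.
#'
#' @param locus_set A [cluster_calls()] result.
#' @param bam_evidence Optional tibble of human BAM-inspection judgements:
#'   `sample`, `chrom`, `start`, `end`, `differs` (logical), linked to loci
#'   by >= 1 bp overlap.
#' @param samples Cohort sample ids (defaults to samples seen in calls and
#'   evidence).
#' @return A tibble with one row per locus x sample: `locus_id`, `sample`,
#'   `via_caller`, `via_bam`, `present`.
#' @export
presence_table <- function(locus_set, bam_evidence = NULL, samples = NULL) {
  calls <- locus_set$calls
  loci <- locus_set$loci
  if (is.null(samples)) {
    samples <- sort(unique(c(calls$sample,
                             if (!is.null(bam_evidence)) bam_evidence$sample)))
  }
  grid <- tidyr::expand_grid(locus_id = loci$locus_id, sample = samples)
  via_caller <- calls |>
    dplyr::filter(.data$genotype %in% c("het", "hom_alt")) |>
    dplyr::distinct(.data$locus_id, .data$sample) |>
    dplyr::mutate(via_caller = TRUE)
  out <- dplyr::left_join(grid, via_caller, by = c("locus_id", "sample")) |>
    dplyr::mutate(via_caller = dplyr::coalesce(.data$via_caller, FALSE))
  via_bam <- rep(FALSE, nrow(out))
  if (!is.null(bam_evidence) && nrow(bam_evidence) > 0L) {
    ev <- dplyr::filter(bam_evidence, .data$differs)
    pairs <- overlap_pairs(loci, ev)
    if (nrow(pairs) > 0L) {
      hit <- tibble::tibble(locus_id = loci$locus_id[pairs$x_idx],
                            sample = ev$sample[pairs$y_idx]) |>
        dplyr::distinct() |>
        dplyr::mutate(via_bam = TRUE)
      out <- dplyr::left_join(out, hit, by = c("locus_id", "sample")) |>
        dplyr::mutate(via_bam = dplyr::coalesce(.data$via_bam, FALSE))
    } else out$via_bam <- FALSE
  } else out$via_bam <- FALSE
  dplyr::mutate(out, present = .data$via_caller | .data$via_bam)
}

#' @rdname presence_table
#' @param locus_id,sample Single locus id and sample id to query.
#' @export
variant_present <- function(locus_set, locus_id, sample, bam_evidence = NULL) {
  tab <- presence_table(locus_set, bam_evidence)
  row <- tab[tab$locus_id == locus_id & tab$sample == sample, ]
  if (nrow(row) == 0L) return(FALSE)
  row$present[1]
}

# Group allele lengths into distinct alleles within +/- tol bp.
distinct_allele_count <- function(len, motif, class, tol = 0) {
  key <- paste(class, ifelse(is.na(motif), "", motif))
  sum(vapply(split(len, key), function(l) {
    l <- sort(unique(l))
    if (length(l) == 0L) return(0L)
    if (tol <= 0) return(length(l))
    groups <- 1L
    last <- l[1]
    for (v in l[-1]) {
      if (v - last > tol) {
        groups <- groups + 1L
        last <- v
      }
    }
    groups
  }, integer(1)))
}

#' Per-caller allele diversity at each locus
#'
#' For every locus and caller, counts the samples carrying at least one
#' non-reference allele and the number of distinct alternative alleles,
#' where distinctness is inequality of the (length, class, motif) tuple --
#' a 46 bp and a 47 bp insertion are distinct alleles; sequence-identical
#' alleles of equal length collapse to one.
#'
#' @param locus_set A [cluster_calls()] result.
#' @param len_tolerance Allele lengths within this many bp collapse to one
#'   allele (default 0 = exact).
#' @return A tibble with `locus_id`, `caller`, `n_samples_nonref`,
#'   `n_distinct_alt`.
#' @export
allele_diversity <- function(locus_set, len_tolerance = 0) {
  locus_set$calls |>
    dplyr::filter(.data$genotype %in% c("het", "hom_alt")) |>
    dplyr::group_by(.data$locus_id, .data$caller) |>
    dplyr::summarise(
      n_samples_nonref = dplyr::n_distinct(.data$sample),
      n_distinct_alt = {
        len <- ifelse(is.na(.data$alt_len), -1L, .data$alt_len)
        distinct_allele_count(len, .data$motif, .data$var_class,
                              tol = len_tolerance)
      },
      .groups = "drop")
}

#' Concordance matrix across callers, with BAM support column
#'
#' One row per locus with a per-caller cell formatted `"N(a)"` (`N` samples
#' with a non-reference call, `a` distinct alternative alleles), an empty
#' cell where a caller never called the locus, and a final column listing
#' BAM-inspection support (`"All"` when every cohort sample differs from the
#' reference there).
#'
#' @inheritParams presence_table
#' @param callers Column order for callers (default: callers seen).
#' @param len_tolerance Passed to [allele_diversity()].
#' @return A tibble with locus columns, one column per caller, and `bam`.
#' @export
concordance_table <- function(locus_set, bam_evidence = NULL, samples = NULL,
                              callers = NULL, len_tolerance = 0) {
  if (is.null(samples)) {
    samples <- sort(unique(c(locus_set$calls$sample,
                             if (!is.null(bam_evidence)) bam_evidence$sample)))
  }
  if (is.null(callers)) callers <- sort(unique(locus_set$calls$caller))
  cells <- allele_diversity(locus_set, len_tolerance) |>
    dplyr::mutate(cell = sprintf("%d(%d)", .data$n_samples_nonref,
                                 .data$n_distinct_alt)) |>
    dplyr::select("locus_id", "caller", "cell") |>
    tidyr::pivot_wider(names_from = "caller", values_from = "cell",
                       values_fill = "")
  for (cl in setdiff(callers, names(cells))) cells[[cl]] <- ""
  bam_col <- locus_set$loci |>
    dplyr::select("locus_id") |>
    dplyr::mutate(bam = "")
  if (!is.null(bam_evidence) && nrow(bam_evidence) > 0L) {
    ev <- dplyr::filter(bam_evidence, .data$differs)
    pairs <- overlap_pairs(locus_set$loci, ev)
    if (nrow(pairs) > 0L) {
      counts <- tibble::tibble(
        locus_id = locus_set$loci$locus_id[pairs$x_idx],
        sample = ev$sample[pairs$y_idx]) |>
        dplyr::distinct() |>
        dplyr::count(.data$locus_id)
      bam_col <- bam_col |>
        dplyr::left_join(counts, by = "locus_id") |>
        dplyr::mutate(bam = dplyr::case_when(
          is.na(.data$n) ~ "",
          .data$n == length(samples) ~ "All",
          TRUE ~ as.character(.data$n))) |>
        dplyr::select("locus_id", "bam")
    }
  }
  locus_set$loci |>
    dplyr::left_join(cells, by = "locus_id") |>
    dplyr::left_join(bam_col, by = "locus_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(callers),
                                ~ dplyr::coalesce(.x, ""))) |>
    dplyr::select("locus_id", "chrom", "start", "end", "var_class",
                  dplyr::all_of(callers), "bam")
}
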