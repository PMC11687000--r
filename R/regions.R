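#' Build fixed-width target regions around GWAS lead SNPs
#'
#' Expands each lead SNP into a target region spanning `flank` bp on either
#' side, the window used to programme adaptive sampling. Regions are stored
#' as 0-based half-open intervals `[pos - flank, pos + flank)`, which have
#' width exactly `2 * flank` and contain the lead SNP; the stored
#' `start`/`end` pair is also the coordinate pair conventionally printed for
#' such windows.
#'
#' @param snps A tibble of lead SNPs with columns `chrom`, `pos` (1-based bp)
#'   and optionally `name` and `rsid` (see [an_lead_snps()]).
#' @param flank Flank size in bp on each side of the lead SNP (default
#'   100,000, giving 200 kb regions).
#' @return A tibble with columns `name`, `chrom`, `start`, `end`, `lead_pos`,
#'   `flank`.
#' @examples
#' build_target_regions(an_lead_snps())
#' @export
build_target_regions <- function(snps, flank = 100000L) {
  if (length(flank) != 1L || !is.finite(flank) || flank <= 0) {
    abort("`flank` must be a single positive number of base pairs.")
  }
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (any(snps$pos < 1)) abort("lead SNP positions must be >= 1 (1-based).")
  under <- snps$pos <= flank
  if (any(under)) {
    who <- if ("rsid" %in% names(snps)) snps$rsid[under] else which(under)
    abort(paste0(
      "region would underflow coordinate 0 for lead SNP(s): ",
      paste(who, collapse = ", "),
      " (pos <= flank)."))
  }
  name <- if ("name" %in% names(snps)) snps$name else {
    sprintf("region_%d", seq_len(nrow(snps)))
  }
  tibble::tibble(
    name = name,
    chrom = norm_chrom(snps$chrom),
    start = as.integer(snps$pos - flank),
    end = as.integer(snps$pos + flank),
    lead_pos = as.integer(snps$pos),
    flank = as.integer(flank)
  )
}

# Warn when regions overlap within a chromosome (allowed but suspicious).
warn_if_overlapping <- function(regions) {
  if (nrow(regions) < 2L) return(invisible(regions))
  pairs <- overlap_pairs(regions, regions)
  pairs <- pairs[pairs$x_idx < pairs$y_idx, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    warn(sprintf("%d pair(s) of target regions overlap within a chromosome.",
                 nrow(pairs)))
  }
  invisible(regions)
}

#' Write and read target regions as BED3+1
#'
#' `write_regions_bed()` serialises regions to a standard BED file (chrom,
#' 0-based start, exclusive end, name); `read_regions_bed()` reads one back.
#' The pair round-trips losslessly on those four columns. Overlapping regions
#' trigger a warning, not an error.
#'
#' @param regions A region tibble from [build_target_regions()] (or any tibble
#'   with `chrom`, `start`, `end`, `name`).
#' @param path File path.
#' @return `write_regions_bed()` returns `path` invisibly;
#'   `read_regions_bed()` returns a region tibble.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' write_regions_bed(build_target_regions(an_lead_snps()), p)
#' read_regions_bed(p)
#' @export
write_regions_bed <- function(regions, path) {
  warn_if_overlapping(regions)
  bed <- dplyr::select(regions, "chrom", "start", "end", "name")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name"),
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    name = readr::col_character()
                  )) |>
    dplyr::select("name", "chrom", "start", "end")
}

#' Extract target-region sequences from a reference FASTA
#'
#' Slices each region's sequence out of a reference, producing one record per
#' region (the file supplied to the sequencer's adaptive-sampling interface).
#' Record ids encode the region name and coordinates as
#' `name::chrom:start-end`.
#'
#' @param reference Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param regions A region tibble (`chrom`, `start`, `end`, `name`).
#' @param out Optional path; when given, records are also written as FASTA.
#' @return A [Biostrings::DNAStringSet] with one record per region, each of
#'   length `end - start`.
#' @export
extract_region_fasta <- function(reference, regions, out = NULL) {
  ref <- if (inherits(reference, "DNAStringSet")) reference else {
    Biostrings::readDNAStringSet(reference)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  missing <- setdiff(unique(regions$chrom), names(ref))
  if (length(missing) > 0L) {
    abort(paste0("reference lacks contig(s): ", paste(missing, collapse = ", ")))
  }
  widths <- Biostrings::width(ref)[match(regions$chrom, names(ref))]
  beyond <- regions$end > widths | regions$start < 0
  if (any(beyond)) {
    abort(paste0("region(s) out of contig bounds: ",
                 paste(regions$name[beyond], collapse = ", ")))
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(regions)), function(i) {
    Biostrings::subseq(ref[[regions$chrom[i]]],
                       start = regions$start[i] + 1L,
                       end = regions$end[i])
  }))
  names(seqs) <- sprintf("%s::%s:%d-%d", regions$name, regions$chrom,
                         regions$start, regions$end)
  if (!is.null(out)) Biostrings::writeXStringSet(seqs, out)
  seqs
}
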