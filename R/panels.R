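#' Lead SNPs of the eight anorexia nervosa GWAS risk loci
#'
#' The eight genome-wide significant lead SNPs of the anorexia nervosa
#' GWAS, with GRCh38 positions and the nearest coding gene, as used to define
#' the 200 kb target regions for adaptive-sampling nanopore sequencing.
#' Positions are 1-based.
#'
#' @return A tibble with columns `rsid`, `chrom`, `pos` (1-based bp), `gene`,
#'   and `name` (target-region label).
#' @examples
#' an_lead_snps()
#' build_target_regions(an_lead_snps())
#' @export
an_lead_snps <- function() {
  tibble::tribble(
    ~rsid,         ~chrom,  ~pos,       ~gene,            ~name,
    "rs9821797",   "chr3",  48680820L,  "NCKIPSD",        "region_1",
    "rs6589488",   "chr11", 115226236L, "CADM1",          "region_2",
    "rs2287348",   "chr2",  53812676L,  "ASB3/ERLEC1",    "region_3",
    "rs2008387",   "chr10", 129650500L, "MGMT",           "region_4",
    "rs9874207",   "chr3",  70970599L,  "FOXP1",          "region_5",
    "rs10747478",  "chr1",  96435899L,  "PTBP2",          "region_6",
    "rs370838138", "chr5",  25081736L,  "CDH10",          "region_7",
    "rs13100344",  "chr3",  94886263L,  "NSUN3",          "region_8"
  )
}

#' Per-sample sequencing QC from a published 10-sample targeted nanopore run
#'
#' Per-sample on/off-target averages (read length in bp, read quality on the
#' Phred scale, fold coverage) for a published adaptive-sampling nanopore
#' cohort of ten samples over eight 200 kb target regions. Useful as worked
#' input for [cohort_summary()], which reproduces the study's cohort mean and
#' standard-error row.
#'
#' @return A tibble with columns `sample`, `scope` (`"on_target"` or
#'   `"off_target"`), `avg_len`, `avg_qual`, `avg_cov`.
#' @examples
#' cohort_summary(nanopore_run_qc())
#' @export
nanopore_run_qc <- function() {
  on <- tibble::tribble(
    ~sample, ~avg_len, ~avg_qual, ~avg_cov,
    "S1",     8216,     22.5,      10.4,
    "S2",     8470,     22.6,      13.4,
    "S3",     9538,     21.3,      16.4,
    "S4",    12148,     22.6,      17.7,
    "S5",    12379,     22.4,      10.3,
    "S6",    14554,     22.2,      18.6,
    "S7",    14763,     22.2,      13.5,
    "S8",    14774,     22.0,      18.4,
    "S9",    15169,     22.5,      15.8,
    "S10",   15400,     22.9,      11.9
  )
  off <- tibble::tribble(
    ~sample, ~avg_len, ~avg_qual, ~avg_cov,
    "S1",     3091,     21.0,      2.8,
    "S2",     3195,     22.2,      2.9,
    "S3",     3192,     22.6,      3.4,
    "S4",     2745,     22.5,      3.6,
    "S5",     2678,     22.6,      2.2,
    "S6",     1968,     22.5,      3.7,
    "S7",     2407,     22.5,      4.0,
    "S8",     4021,     23.0,      4.6,
    "S9",     3625,     22.2,      4.7,
    "S10",    3609,     22.1,      3.5
  )
  dplyr::bind_rows(
    dplyr::mutate(on, scope = "on_target"),
    dplyr::mutate(off, scope = "off_target")
  ) |>
    dplyr::select("sample", "scope", "avg_len", "avg_qual", "avg_cov")
}

#' Summarise a combined call set by variant class
#'
#' Tallies SNVs against non-SNV structural variants and derives the non-SNV
#' fraction, either from a normalised call tibble or directly from counts.
#'
#' @param calls A variant-call tibble with a `var_class` column, or `NULL`
#'   when `n_snv`/`n_nonsnv` are given directly.
#' @param n_snv,n_nonsnv Optional counts overriding `calls`.
#' @return A one-row tibble with `n_total`, `n_snv`, `n_nonsnv`, and
#'   `frac_nonsnv` (unrounded).
#' @examples
#' variant_class_summary(n_snv = 17328, n_nonsnv = 5052)
#' @export
variant_class_summary <- function(calls = NULL, n_snv = NULL, n_nonsnv = NULL) {
  if (is.null(n_snv) || is.null(n_nonsnv)) {
    stopifnot(!is.null(calls), "var_class" %in% names(calls))
    n_snv <- sum(calls$var_class == "SNV")
    n_nonsnv <- sum(calls$var_class != "SNV")
  }
  tibble::tibble(
    n_total = n_snv + n_nonsnv,
    n_snv = n_snv,
    n_nonsnv = n_nonsnv,
    frac_nonsnv = n_nonsnv / (n_snv + n_nonsnv)
  )
}
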