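#' @name callset
#' @title Normalised variant-call model
#' @description
#' All readers in the package return calls in one tidy schema, one row per
#' call x alternative allele:
#' \itemize{
#'   \item `sample`, `caller` -- provenance;
#'   \item `chrom`, `start`, `end` -- 0-based half-open interval (VCF `POS`
#'     maps to `start = POS - 1`; insertions are points with
#'     `end = start + 1` and the inserted length carried in `alt_len`);
#'   \item `var_class` -- one of `"SNV"`, `"INS"`, `"DEL"`, `"STR"`, `"TE"`,
#'     `"COMPLEX"`;
#'   \item `ref_len`, `alt_len` -- reference/alternative allele lengths in bp
#'     (for STRs `alt_len` is the allele length `motif length x copies`);
#'   \item `motif`, `copy_number` -- STR allele description (`NA` otherwise);
#'   \item `qual` -- caller-native quality score (`NA` for no-quality
#'     sources such as STR locus tables, which are quality-filter exempt);
#'   \item `genotype` -- `"hom_ref"`, `"het"`, `"hom_alt"`, `"unresolved"`;
#'   \item `ref_seq`, `alt_seq` -- sequences when known;
#'   \item `source` -- opaque provenance string.
#' }
NULL

var_classes <- c("SNV", "INS", "DEL", "STR", "TE", "COMPLEX")
genotype_levels <- c("hom_ref", "het", "hom_alt", "unresolved")

# Canonical empty call tibble; also used to coerce partial builders.
call_tibble <- function(...) {
  proto <- tibble::tibble(
    sample = character(), caller = character(), chrom = character(),
    start = integer(), end = integer(), var_class = character(),
    ref_len = integer(), alt_len = integer(),
    motif = character(), copy_number = double(), qual = double(),
    genotype = character(), ref_seq = character(), alt_seq = character(),
    source = character())
  rows <- tibble::tibble(...)
  out <- dplyr::bind_rows(proto, rows)
  out$chrom <- norm_chrom(out$chrom)
  out
}

gt_to_genotype <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "" || g == ".") return("unresolved")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (all(alleles == ".")) return("unresolved")
    alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
    if (length(alleles) == 0L || any(is.na(alleles))) return("unresolved")
    if (all(alleles == 0L)) return("hom_ref")
    if (length(unique(alleles)) == 1L) return("hom_alt")
    "het"
  }, character(1), USE.NAMES = FALSE)
}

genotype_to_gt <- function(genotype) {
  unname(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
           unresolved = "./.")[genotype])
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  m
}

#' Read an SV-style or small-variant VCF into the normalised call model
#'
#' Parses a VCF (plain or bgzipped) with `vcfR` and converts records to the
#' tidy call schema. Symbolic alleles (`<INS>`, `<DEL>`) are resolved from
#' `SVTYPE`/`SVLEN`/`END`; sequence-explicit records are classed SNV when
#' both alleles have length 1, otherwise INS/DEL by length difference.
#' Missing genotypes (`./.`) become `"unresolved"` and are preserved, not
#' coerced to homozygous reference. Malformed records are skipped with a
#' warning and counted in the `n_skipped` attribute.
#'
#' @param path Path to a VCF file.
#' @param caller Caller tag recorded in the `caller` column.
#' @param sample Optional sample id override; defaults to the VCF sample
#'   column name (all sample columns are read).
#' @return A call tibble (see [callset]); attribute `n_skipped` counts
#'   skipped records.
#' @export
read_sv_vcf <- function(path, caller, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- call_tibble()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  has_gt <- ncol(vcf@gt) >= 2L
  sample_cols <- if (has_gt) colnames(vcf@gt)[-1] else "sample_1"
  if (!is.null(sample)) sample_cols <- rep(sample, length(sample_cols))

  svtype <- info_field(fix$INFO, "SVTYPE")
  svlen <- suppressWarnings(as.integer(info_field(fix$INFO, "SVLEN")))
  info_end <- suppressWarnings(as.integer(info_field(fix$INFO, "END")))
  pos <- suppressWarnings(as.integer(fix$POS))
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    rec <- tryCatch({
      ref <- fix$REF[i]
      alt <- fix$ALT[i]
      if (is.na(pos[i]) || is.na(alt) || alt == "" || alt == ".") {
        stop("missing POS/ALT")
      }
      start <- pos[i] - 1L
      if (!is.na(svtype[i]) || grepl("^<", alt)) {
        cls <- toupper(if (!is.na(svtype[i])) svtype[i] else gsub("[<>]", "", alt))
        if (!cls %in% var_classes) stop("unknown SVTYPE: ", cls)
        len <- abs(svlen[i])
        if (is.na(len) && !is.na(info_end[i])) len <- info_end[i] - start
        if (is.na(len)) stop("no SVLEN/END for symbolic allele")
        end <- if (cls %in% c("DEL", "STR", "TE", "COMPLEX")) {
          if (!is.na(info_end[i])) info_end[i] else start + len
        } else start + 1L
        list(start = start, end = as.integer(end), var_class = cls,
             ref_len = if (cls == "DEL") as.integer(len) else 1L,
             alt_len = as.integer(len),
             ref_seq = NA_character_, alt_seq = NA_character_)
      } else {
        rl <- nchar(ref); al <- nchar(alt)
        if (rl == 1L && al == 1L) {
          list(start = start, end = start + 1L, var_class = "SNV",
               ref_len = 1L, alt_len = 1L, ref_seq = ref, alt_seq = alt)
        } else if (al > rl) {
          list(start = start, end = start + 1L, var_class = "INS",
               ref_len = rl, alt_len = al - rl, ref_seq = ref, alt_seq = alt)
        } else {
          list(start = start, end = start + rl, var_class = "DEL",
               ref_len = rl, alt_len = rl - al, ref_seq = ref, alt_seq = alt)
        }
      }
    }, error = function(e) NULL)
    if (is.null(rec)) {
      n_skipped <- n_skipped + 1L
      next
    }
    gts <- if (has_gt) {
      fmt <- strsplit(vcf@gt[i, 1], ":")[[1]]
      gt_idx <- match("GT", fmt)
      vapply(seq_along(sample_cols), function(j) {
        cell <- vcf@gt[i, j + 1L]
        if (is.na(cell) || is.na(gt_idx)) NA_character_ else {
          strsplit(cell, ":")[[1]][gt_idx]
        }
      }, character(1))
    } else rep(NA_character_, length(sample_cols))
    rows[[i]] <- call_tibble(
      sample = sample_cols, caller = caller, chrom = fix$CHROM[i],
      start = rec$start, end = rec$end, var_class = rec$var_class,
      ref_len = rec$ref_len, alt_len = rec$alt_len,
      motif = info_field(fix$INFO[i], "MOTIF"),
      copy_number = suppressWarnings(as.numeric(info_field(fix$INFO[i], "CN"))),
      qual = qual[i], genotype = gt_to_genotype(gts),
      ref_seq = rec$ref_seq, alt_seq = rec$alt_seq,
      source = sprintf("%s:%s", basename(path), i))
  }
  if (n_skipped > 0L) {
    warn(sprintf("skipped %d malformed VCF record(s) in %s.",
                 n_skipped, basename(path)))
  }
  out <- dplyr::bind_rows(call_tibble(), rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a short-tandem-repeat locus table
#'
#' Parses a tab-separated STR genotyping table (the BED/TSV shape emitted by
#' repeat genotypers): one row per sample x locus x allele with the repeat
#' motif and a possibly fractional copy number. Each sample x locus becomes
#' one or more STR calls; alleles whose copy number equals the reference
#' copy number are reference alleles. STR-table calls carry no quality score
#' and are exempt from the caller-quality filter downstream. Rows with
#' `copy_number <= 0` are rejected with a warning.
#'
#' @param path Path to a TSV with columns `chrom`, `start`, `end`, `motif`,
#'   `ref_copies`, `sample`, `allele` (1/2), `copy_number`.
#' @param caller Caller tag (default `"straglr"`).
#' @return A call tibble with `var_class = "STR"`; one row per distinct
#'   non-reference allele (or a single `hom_ref` row).
#' @export
read_str_table <- function(path, caller = "straglr") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), motif = readr::col_character(),
    ref_copies = readr::col_double(), sample = readr::col_character(),
    allele = readr::col_integer(), copy_number = readr::col_double()))
  str_table_to_calls(tab, caller = caller, source = basename(path))
}

# Shared core: long allele table -> call tibble.
str_table_to_calls <- function(tab, caller, source = "str_table") {
  bad <- !is.na(tab$copy_number) & tab$copy_number <= 0
  if (any(bad)) {
    warn(sprintf("rejected %d STR allele row(s) with copy_number <= 0.",
                 sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) return(call_tibble())
  tab |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$motif,
                    .data$ref_copies, .data$sample) |>
    dplyr::group_modify(function(d, key) {
      n_alt <- sum(d$copy_number != key$ref_copies)
      genotype <- if (n_alt == 0L) "hom_ref"
        else if (n_alt >= 2L && dplyr::n_distinct(
          d$copy_number[d$copy_number != key$ref_copies]) == 1L) "hom_alt"
        else "het"
      alt <- unique(d$copy_number[d$copy_number != key$ref_copies])
      if (length(alt) == 0L) alt <- NA_real_
      tibble::tibble(genotype = genotype, copy_number = alt)
    }) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      sample = .data$sample, caller = caller, chrom = norm_chrom(.data$chrom),
      start = as.integer(.data$start), end = as.integer(.data$end),
      var_class = "STR",
      ref_len = as.integer(.data$end - .data$start),
      alt_len = ifelse(is.na(.data$copy_number), NA_integer_,
                       as.integer(round(.data$copy_number * nchar(.data$motif)))),
      motif = .data$motif, copy_number = .data$copy_number,
      qual = NA_real_, genotype = .data$genotype,
      ref_seq = NA_character_, alt_seq = NA_character_,
      source = source) |>
    call_tibble_from()
}

call_tibble_from <- function(df) dplyr::bind_rows(call_tibble(), df)

vcf_header <- function(extra_info = character(), sample_col = "CALL") {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"STR motif\">",
    "##INFO=<ID=CN,Number=1,Type=Float,Description=\"STR allele copy number\">",
    extra_info,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_col))
}

fmt_info <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.null(v) || is.na(v), logical(1))]
  if (length(kv) == 0L) return(".")
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, character(1))),
        collapse = ";")
}

# REF/ALT pair for one call row in SV-VCF dialect.
call_alleles <- function(row) {
  if (row$var_class == "SNV") {
    list(ref = if (!is.na(row$ref_seq)) row$ref_seq else "N",
         alt = if (!is.na(row$alt_seq)) row$alt_seq else "A")
  } else {
    list(ref = "N", alt = sprintf("<%s>", row$var_class))
  }
}

#' Write a single-sample caller-style VCF
#'
#' Serialises calls from one sample into the SV-VCF dialect the package
#' reads back with [read_sv_vcf()] (`SVTYPE`/`SVLEN`/`END` INFO keys,
#' symbolic alleles for non-SNVs). Used by the synthetic-cohort generator to
#' emit per-caller files.
#'
#' @param calls Call tibble for a single sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path) {
  stopifnot(dplyr::n_distinct(calls$sample) <= 1L)
  sample_id <- if (nrow(calls) > 0L) calls$sample[1] else "sample_1"
  calls <- dplyr::arrange(calls, .data$chrom, .data$start, .data$end)
  lines <- vcf_header(sample_col = sample_id)
  body <- vapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    al <- call_alleles(row)
    info <- if (row$var_class == "SNV") "." else fmt_info(
      SVTYPE = row$var_class,
      SVLEN = if (row$var_class == "DEL") -row$alt_len else row$alt_len,
      END = row$end, MOTIF = row$motif, CN = row$copy_number)
    paste(row$chrom, row$start + 1L, ".", al$ref, al$alt,
          ifelse(is.na(row$qual), ".", format(row$qual, digits = 10)),
          "PASS", info, "GT", genotype_to_gt(row$genotype), sep = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write and read a harmonised multi-caller VCF
#'
#' `write_harmonised_vcf()` serialises a normalised call set (any mix of
#' samples, callers and classes) to VCF 4.2, carrying class, caller and
#' sample provenance plus STR motif/copy number in INFO; coordinates are
#' converted back to 1-based `POS`. `read_harmonised_vcf()` inverts it:
#' `read(write(x))` recovers the retained fields exactly. Records identical
#' on their key (sample, caller, locus, class, allele) but conflicting on
#' quality or genotype raise an error naming the conflict.
#'
#' @param calls A call tibble.
#' @param path File path.
#' @return `write_harmonised_vcf()` returns `path` invisibly;
#'   `read_harmonised_vcf()` returns a call tibble.
#' @export
write_harmonised_vcf <- function(calls, path) {
  key <- c("sample", "caller", "chrom", "start", "end", "var_class",
           "alt_len", "motif", "copy_number")
  dup <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::filter(dplyr::n_distinct(paste(.data$qual, .data$genotype)) > 1L) |>
    dplyr::ungroup()
  if (nrow(dup) > 0L) {
    abort(paste0("conflicting records at identical key, e.g. ",
                 dup$chrom[1], ":", dup$start[1], " (", dup$sample[1], "/",
                 dup$caller[1], ")."))
  }
  calls <- dplyr::arrange(calls, .data$chrom, .data$start, .data$end,
                          .data$caller, .data$sample)
  extra <- c(
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Source caller\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=REFLEN,Number=1,Type=Integer,Description=\"Reference allele length\">")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    al <- call_alleles(row)
    info <- fmt_info(
      VCLASS = row$var_class, CALLER = row$caller, SAMPLE = row$sample,
      SVLEN = if (is.na(row$alt_len)) NA else {
        if (row$var_class == "DEL") -row$alt_len else row$alt_len
      },
      END = row$end, REFLEN = row$ref_len,
      MOTIF = row$motif, CN = row$copy_number)
    paste(row$chrom, row$start + 1L, ".", al$ref, al$alt,
          ifelse(is.na(row$qual), ".", format(row$qual, digits = 10)),
          "PASS", info, "GT", genotype_to_gt(row$genotype), sep = "\t")
  }, character(1))
  writeLines(c(vcf_header(extra), body), path)
  invisible(path)
}

#' @rdname write_harmonised_vcf
#' @export
read_harmonised_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(call_tibble())
  cls <- info_field(fix$INFO, "VCLASS")
  svlen <- suppressWarnings(as.integer(info_field(fix$INFO, "SVLEN")))
  gts <- vapply(seq_len(nrow(fix)), function(i) {
    if (ncol(vcf@gt) < 2L) NA_character_ else strsplit(vcf@gt[i, 2], ":")[[1]][1]
  }, character(1))
  pos <- as.integer(fix$POS)
  call_tibble(
    sample = info_field(fix$INFO, "SAMPLE"),
    caller = info_field(fix$INFO, "CALLER"),
    chrom = fix$CHROM,
    start = pos - 1L,
    end = as.integer(info_field(fix$INFO, "END")),
    var_class = cls,
    ref_len = suppressWarnings(as.integer(info_field(fix$INFO, "REFLEN"))),
    alt_len = abs(svlen),
    motif = info_field(fix$INFO, "MOTIF"),
    copy_number = suppressWarnings(as.numeric(info_field(fix$INFO, "CN"))),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    genotype = gt_to_genotype(gts),
    ref_seq = ifelse(cls == "SNV", fix$REF, NA_character_),
    alt_seq = ifelse(cls == "SNV", fix$ALT, NA_character_),
    source = sprintf("%s:%s", basename(path), seq_len(nrow(fix))))
}

#' Write an STR locus table
#'
#' Inverse of [read_str_table()] at the allele level: expands STR calls back
#' to one row per sample x locus x allele.
#'
#' @param calls STR call tibble (`var_class == "STR"`, `ref_copies` derived
#'   from `ref_len`/`motif`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_str_table <- function(calls, path) {
  stopifnot(all(calls$var_class == "STR"))
  rows <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    ref_copies <- row$ref_len / nchar(row$motif)
    cns <- switch(row$genotype,
      hom_ref = c(ref_copies, ref_copies),
      het = c(ref_copies, row$copy_number),
      hom_alt = c(row$copy_number, row$copy_number),
      unresolved = c(NA_real_, NA_real_))
    tibble::tibble(chrom = row$chrom, start = row$start, end = row$end,
                   motif = row$motif, ref_copies = ref_copies,
                   sample = row$sample, allele = c(1L, 2L), copy_number = cns)
  })
  rows <- rows[!is.na(rows$copy_number), , drop = FALSE]
  readr::write_tsv(rows, path)
  invisible(path)
}
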