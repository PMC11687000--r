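write_vcf_fixture <- function(body, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    body), path)
  path
}

test_that("SV VCF records map to the normalised call model", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(c(
    "chr1\t101\t.\tN\t<DEL>\t30\tPASS\tSVTYPE=DEL;SVLEN=-15;END=115\tGT\t0/1",
    "chr1\t501\t.\tN\t<INS>\t12\tPASS\tSVTYPE=INS;SVLEN=47\tGT\t1/1",
    "chr1\t901\t.\tA\tG\t40\tPASS\t.\tGT\t./."), path)
  calls <- read_sv_vcf(path, caller = "sniffles2")
  expect_equal(nrow(calls), 3L)
  del <- calls[calls$var_class == "DEL", ]
  expect_equal(del$start, 100L)       # POS 101 -> 0-based 100
  expect_equal(del$end, 115L)
  expect_equal(del$alt_len, 15L)
  expect_equal(del$genotype, "het")
  ins <- calls[calls$var_class == "INS", ]
  expect_equal(ins$end, ins$start + 1L)
  expect_equal(ins$alt_len, 47L)
  expect_equal(ins$genotype, "hom_alt")
  snv <- calls[calls$var_class == "SNV", ]
  expect_equal(snv$genotype, "unresolved")  # ./., preserved not coerced
  expect_equal(attr(calls, "n_skipped"), 0L)
})

test_that("malformed VCF records are skipped, warned about, and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(c(
    "chr1\t101\t.\tN\t<DEL>\t30\tPASS\tSVTYPE=DEL;SVLEN=-15\tGT\t0/1",
    "chr1\t201\t.\tN\t<DUQ>\t30\tPASS\tSVTYPE=DUQ\tGT\t0/1",
    "chr1\t301\t.\tN\t<INS>\t30\tPASS\tSVTYPE=INS\tGT\t0/1"), path)
  expect_warning(calls <- read_sv_vcf(path, caller = "x"), "skipped 2")
  expect_equal(nrow(calls) + attr(calls, "n_skipped"), 3L)
})

test_that("class inference: SNV iff both alleles length 1, indel by length", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(c(
    "chr2\t11\t.\tA\tT\t20\tPASS\t.\tGT\t0/1",
    "chr2\t21\t.\tA\tATTTT\t20\tPASS\t.\tGT\t0/1",
    "chr2\t31\t.\tACCTG\tA\t20\tPASS\t.\tGT\t0/1"), path)
  calls <- read_sv_vcf(path, caller = "clair3")
  expect_equal(calls$var_class, c("SNV", "INS", "DEL"))
  expect_equal(calls$alt_len, c(1L, 4L, 4L))
  expect_equal(calls$end[3] - calls$start[3], 5L)
})

test_that("STR locus tables become per-sample STR calls", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr3", start = 48729043L, end = 48729083L, motif = "T",
    ref_copies = 40, sample = rep(c("S1", "S2"), each = 2),
    allele = c(1L, 2L, 1L, 2L),
    copy_number = c(35, 40, 40, 40)), path)
  calls <- read_str_table(path)
  expect_equal(nrow(calls), 2L)
  s1 <- calls[calls$sample == "S1", ]
  expect_equal(s1$genotype, "het")           # one contraction + one ref
  expect_equal(s1$copy_number, 35)
  expect_equal(s1$alt_len, 35L)
  expect_true(is.na(s1$qual))                 # STR tables carry no QUAL
  expect_equal(calls$genotype[calls$sample == "S2"], "hom_ref")
})

test_that("empty and invalid STR tables are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    motif = character(), ref_copies = double(), sample = character(),
    allele = integer(), copy_number = double()), path)
  expect_equal(nrow(read_str_table(path)), 0L)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", start = 10L, end = 30L, motif = "AC", ref_copies = 10,
    sample = "S1", allele = 1L, copy_number = -2), path2)
  expect_warning(out <- read_str_table(path2), "copy_number")
  expect_equal(nrow(out), 0L)
})

test_that("an STR locus with three planted copy numbers yields the planted diversity", {
  copies <- rep(c(12, 14, 16), length.out = 10)   # 14 = reference
  tab <- purrr::map_dfr(1:10, function(i) tibble::tibble(
    chrom = "chr5", start = 100L, end = 170L, motif = "AAAAT",
    ref_copies = 14, sample = sprintf("S%d", i), allele = c(1L, 2L),
    copy_number = c(copies[i], 14)))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  calls <- read_str_table(path)
  expect_equal(nrow(calls), 10L)
  nonref <- calls[calls$genotype != "hom_ref", ]
  expect_equal(sort(unique(nonref$copy_number)), c(12, 16))
  expect_equal(dplyr::n_distinct(calls$alt_len, na.rm = TRUE), 2L)
})

test_that("harmonised VCF round-trips a mixed 50-call set field-identically", {
  b <- cached_bundle(seed = 1)
  set.seed(99)
  mix <- b$calls[sample(nrow(b$calls), 50), ]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_harmonised_vcf(mix, path)
  back <- read_harmonised_vcf(path)
  cols <- c("sample", "caller", "chrom", "start", "end", "var_class",
            "alt_len", "motif", "copy_number", "genotype")
  key <- function(d) dplyr::arrange(d[, cols], chrom, start,
                                    caller, sample, alt_len)
  expect_equal(as.data.frame(key(back)), as.data.frame(key(mix)))
  expect_equal(round(sort(back$qual), 6), round(sort(mix$qual), 6))
  # a third-party VCF parser accepts the file
  parsed <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(parsed@fix), 50L)
})

test_that("STR motif and copy number survive the harmonised VCF", {
  call <- make_call(var_class = "STR", start = 500L, end = 534L,
                    alt_len = 34L, motif = "AC", copy_number = 17,
                    qual = NA_real_, caller = "straglr")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_harmonised_vcf(call, path)
  line <- grep("^chr", readLines(path), value = TRUE)
  expect_match(line, "MOTIF=AC")
  expect_match(line, "CN=17")
  back <- read_harmonised_vcf(path)
  expect_equal(back$copy_number, 17)
  expect_equal(back$motif, "AC")
})

test_that("conflicting records at an identical key are refused", {
  a <- make_call(start = 100L, qual = 30, genotype = "het")
  conflicted <- dplyr::bind_rows(
    a, dplyr::mutate(a, genotype = "hom_alt"))
  path <- withr::local_tempfile(fileext = ".vcf")
  expect_error(write_harmonised_vcf(conflicted, path), "conflicting")
})

test_that("display coordinates reconstruct the VCF POS exactly", {
  b <- cached_bundle(seed = 1)
  sub <- dplyr::filter(b$calls, caller == "sniffles2", sample == "S3")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_caller_vcf(sub, path)
  pos <- as.integer(vcfR::read.vcfR(path, verbose = FALSE)@fix[, "POS"])
  expect_equal(sort(pos), sort(sub$start + 1L))
})
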