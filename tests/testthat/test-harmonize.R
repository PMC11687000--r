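test_that("jittered deletions merge; unrelated variant types stay apart", {
  calls <- dplyr::bind_rows(
    make_call(start = 1000L, var_class = "DEL", alt_len = 15L,
              caller = "sniffles2", source = "a"),
    make_call(start = 1003L, var_class = "DEL", alt_len = 15L,
              caller = "nanovar", source = "b"),
    make_call(start = 9000L, end = 9040L, var_class = "STR", alt_len = 35L,
              motif = "T", copy_number = 35, caller = "straglr",
              qual = NA_real_, source = "c"),
    make_call(start = 20000L, var_class = "SNV", alt_len = 1L,
              alt_seq = "G", caller = "clair3", source = "d"))
  ls <- cluster_calls(calls)
  expect_equal(nrow(ls$loci), 3L)
  dels <- ls$calls[ls$calls$var_class == "DEL", ]
  expect_equal(dplyr::n_distinct(dels$locus_id), 1L)
})

test_that("indel observations inside a repeat span join the repeat locus", {
  calls <- dplyr::bind_rows(
    make_call(start = 1000L, end = 1040L, var_class = "STR", alt_len = 35L,
              motif = "T", copy_number = 35, qual = NA_real_,
              caller = "straglr", source = "str"),
    make_call(start = 1018L, var_class = "INS", alt_len = 5L,
              caller = "sniffles2", source = "ins"),
    make_call(start = 1020L, var_class = "DEL", alt_len = 5L,
              caller = "clair3", source = "del"))
  ls <- cluster_calls(calls)
  expect_equal(nrow(ls$loci), 1L)
  expect_equal(ls$loci$var_class, "STR")
})

test_that("DEL-DEL reciprocal overlap boundary is inclusive at 0.5", {
  # 100 bp deletions offset by exactly 50 bp: overlap 50/100 = 0.5
  at_boundary <- dplyr::bind_rows(
    make_call(start = 1000L, var_class = "DEL", alt_len = 100L, source = "a"),
    make_call(start = 1050L, var_class = "DEL", alt_len = 100L,
              caller = "nanovar", source = "b"))
  expect_equal(nrow(cluster_calls(at_boundary)$loci), 1L)
  past_boundary <- dplyr::bind_rows(
    make_call(start = 1000L, var_class = "DEL", alt_len = 100L, source = "a"),
    make_call(start = 1051L, var_class = "DEL", alt_len = 100L,
              caller = "nanovar", source = "b"))
  expect_equal(nrow(cluster_calls(past_boundary)$loci), 2L)
})

test_that("clustering is a partition invariant under input order", {
  set.seed(23)
  for (i in 1:5) {
    calls <- random_call_set(15)
    ls1 <- cluster_calls(calls)
    shuffled <- calls[sample(nrow(calls)), ]
    ls2 <- cluster_calls(shuffled)
    expect_equal(nrow(ls1$calls), nrow(calls))      # every call in one locus
    sig1 <- partition_signature(ls1$calls$source, ls1$calls$locus_id)
    sig2 <- partition_signature(ls2$calls$source, ls2$calls$locus_id)
    expect_equal(sig1, sig2)
  }
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  set.seed(41)
  for (i in 1:10) {
    calls <- random_call_set(sample(5:20, 1))
    ls <- cluster_calls(calls)
    got <- partition_signature(ls$calls$source, ls$calls$locus_id)
    comp <- oracle_partition(calls)
    want <- partition_signature(calls$source, comp)
    expect_equal(got, want)
  }
})

test_that("over-long chained loci are split at their largest gap with a warning", {
  # insertion points chained every 400 bp across > 7 kb link transitively
  calls <- purrr::map_dfr(0:19, function(i) {
    make_call(start = 1000L + i * 400L, var_class = "INS", alt_len = 20L,
              source = sprintf("s%02d", i))
  })
  warnings <- testthat::capture_warnings(
    ls <- cluster_calls(calls, max_locus_span = 5000))
  expect_true(all(grepl("split over-long locus", warnings)))
  expect_gt(length(warnings), 0L)
  expect_gt(nrow(ls$loci), 1L)
  expect_true(all(ls$loci$end - ls$loci$start <= 5000))
  # every call still belongs to exactly one locus
  expect_equal(nrow(ls$calls), 20L)
})

test_that("presence follows the union rule: any caller or BAM evidence", {
  calls <- dplyr::bind_rows(
    make_call(start = 1000L, sample = "S1", genotype = "het", source = "a"),
    make_call(start = 1001L, sample = "S2", genotype = "unresolved",
              caller = "nanovar", source = "b"))
  ls <- cluster_calls(calls)
  lid <- ls$loci$locus_id[1]
  bam <- tibble::tibble(sample = "S3", chrom = "chr1", start = 995L,
                        end = 1020L, differs = TRUE)
  expect_true(variant_present(ls, lid, "S1"))          # caller support
  expect_false(variant_present(ls, lid, "S2"))         # unresolved only
  expect_true(variant_present(ls, lid, "S3", bam))     # BAM-only support
  no_ev <- tibble::tibble(sample = "S4", chrom = "chr1", start = 995L,
                          end = 1020L, differs = FALSE)
  expect_false(variant_present(ls, lid, "S4", no_ev))
})

test_that("presence is monotone under added evidence", {
  set.seed(53)
  calls <- random_call_set(12)
  ls <- cluster_calls(calls)
  base <- presence_table(ls)
  bam <- tibble::tibble(sample = "S1", chrom = ls$loci$chrom,
                        start = ls$loci$start, end = ls$loci$end,
                        differs = TRUE)
  more <- presence_table(ls, bam)
  joined <- dplyr::inner_join(base, more, by = c("locus_id", "sample"))
  expect_true(all(!joined$present.x | joined$present.y))
})

test_that("allele diversity counts samples and distinct alleles per caller", {
  # one caller: 47 bp x5 samples, 46 bp x1, 38 bp x1 -> 7(3)
  calls <- purrr::map_dfr(1:7, function(i) {
    len <- c(47L, 47L, 47L, 47L, 47L, 46L, 38L)[i]
    make_call(start = 2000L, var_class = "INS", alt_len = len,
              sample = sprintf("S%d", i), caller = "sniffles2",
              source = sprintf("v%d", i))
  })
  ls <- cluster_calls(calls)
  div <- allele_diversity(ls)
  expect_equal(div$n_samples_nonref, 7L)
  expect_equal(div$n_distinct_alt, 3L)
})

test_that("singleton diversity is 1(1) and duplicates collapse", {
  single <- make_call(start = 100L, var_class = "INS", alt_len = 20L)
  div <- allele_diversity(cluster_calls(single))
  expect_equal(div$n_samples_nonref, 1L)
  expect_equal(div$n_distinct_alt, 1L)

  dup <- dplyr::bind_rows(
    make_call(start = 100L, var_class = "INS", alt_len = 20L, source = "a"),
    make_call(start = 100L, var_class = "INS", alt_len = 20L, source = "b"))
  div2 <- allele_diversity(cluster_calls(dup))
  expect_equal(div2$n_distinct_alt, 1L)
})

test_that("diversity tallies equal brute-force enumeration on planted spectra", {
  b <- cached_bundle(seed = 4)
  ls <- cluster_calls(b$calls)
  div <- allele_diversity(ls)
  nonref <- ls$calls[ls$calls$genotype %in% c("het", "hom_alt"), ]
  for (i in sample(nrow(div), 20)) {
    row <- div[i, ]
    members <- nonref[nonref$locus_id == row$locus_id &
                        nonref$caller == row$caller, ]
    expect_equal(row$n_samples_nonref, length(unique(members$sample)))
    key <- paste(members$var_class, members$alt_len, members$motif)
    expect_equal(row$n_distinct_alt, length(unique(key)))
    expect_lte(row$n_distinct_alt, nrow(members))
  }
})

test_that("the concordance matrix formats cells and the BAM column", {
  samples <- sprintf("S%d", 1:10)
  calls <- dplyr::bind_rows(
    purrr::map_dfr(1:5, function(i) {
      make_call(start = 3000L, var_class = "DEL", alt_len = 28L,
                sample = samples[i], caller = "sniffles2",
                source = sprintf("a%d", i))
    }),
    make_call(start = 3002L, var_class = "DEL", alt_len = 30L,
              sample = "S1", caller = "nanovar", source = "n"),
    make_call(start = 9000L, var_class = "INS", alt_len = 20L,
              sample = "S2", caller = "clair3", source = "c"))
  ls <- cluster_calls(calls)
  bam <- tibble::tibble(sample = samples, chrom = "chr1", start = 2990L,
                        end = 3060L, differs = TRUE)
  tab <- concordance_table(ls, bam, samples = samples)
  del_row <- tab[tab$var_class == "DEL", ]
  expect_equal(del_row$sniffles2, "5(1)")
  expect_equal(del_row$nanovar, "1(1)")
  expect_equal(del_row$clair3, "")            # never called here
  expect_equal(del_row$bam, "All")
  ins_row <- tab[tab$var_class == "INS", ]
  expect_equal(ins_row$clair3, "1(1)")
  expect_equal(ins_row$bam, "")
})
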