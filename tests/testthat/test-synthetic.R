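test_that("the generator is deterministic given a seed", {
  a <- generate_cohort(seed = 9, include_reads = FALSE)
  b <- generate_cohort(seed = 9, include_reads = FALSE)
  expect_identical(a, b)
  c <- generate_cohort(seed = 10, include_reads = FALSE)
  expect_false(identical(a$calls, c$calls))
})

test_that("the default truth set plants 20 interesting variants among 120", {
  b <- cached_bundle(seed = 1)
  expect_equal(nrow(b$truth), 120L)
  expect_equal(sum(b$truth$interesting), 20L)
  interesting <- b$truth[b$truth$interesting, ]
  # the flag implies every cascade criterion
  expect_true(all(interesting$var_class != "SNV"))
  expect_true(all(interesting$impact == "HIGH"))
  expect_true(all(is.na(interesting$rsid)))
  indels <- interesting[interesting$var_class %in% c("INS", "DEL"), ]
  expect_true(all(vapply(indels$alt_alleles, max, 1) > 10))
  # inside their region
  regions <- b$regions
  for (i in seq_len(nrow(interesting))) {
    reg <- regions[regions$name == interesting$region[i], ]
    expect_true(interesting$start[i] >= reg$start &&
                  interesting$end[i] <= reg$end)
  }
  # inside the planted LD block, or in a lenient (blockless) region
  blocked <- interesting[!interesting$region %in%
                           b$params$blockless_regions, ]
  for (i in seq_len(nrow(blocked))) {
    blk <- b$ld_truth[b$ld_truth$region == blocked$region[i], ]
    expect_true(blocked$start[i] >= blk$start && blocked$end[i] <= blk$end)
  }
})

test_that("STR planting reproduces the requested allele spectra", {
  tv <- plant_str_locus("T", 40, c(35, 40), 48729043, chrom = "chr3")
  expect_equal(tv$end - tv$start, 40L)
  expect_equal(tv$alt_alleles[[1]], 35)        # contraction only
  expect_true(tv$polymorphic)
  expect_true(all(tv$alt_alleles[[1]] < 40))

  mono <- plant_str_locus("AC", 17, 17, 1000)
  expect_false(mono$polymorphic)
  expect_equal(length(mono$alt_alleles[[1]]), 0L)

  multi <- plant_str_locus("AAAAT", 14, c(12, 14, 16), 2000)
  expect_equal(multi$alt_alleles[[1]], c(12, 16))  # 2 non-reference alleles
  expect_equal(multi$end - multi$start, 70L)
})

test_that("composite TE truth emits the planted VNTR insertion lengths", {
  tv <- plant_composite_te(48733472, body_len = 1800,
                           vntr_allele_lens = c(38, 46, 47), chrom = "chr3")
  tv$variant_id <- "te1"; tv$region <- "region_1"; tv$interesting <- TRUE
  gts <- tibble::tibble(
    variant_id = "te1", sample = sprintf("S%d", 1:7),
    genotype = c(rep("het", 6), "hom_alt"),
    alt_value = c(38, 46, 47, 47, 47, 47, 47))
  calls <- simulate_caller_calls(tv, gts, no_noise_profiles())
  ins <- calls[calls$var_class == "INS", ]
  expect_setequal(unique(ins$alt_len), c(38L, 46L, 47L))
  # every VCF-style insertion lands inside the element
  expect_true(all(ins$start >= tv$start & ins$start < tv$end))
  # the repeat genotyper reports subunits over the element span
  strs <- calls[calls$var_class == "STR", ]
  expect_true(nrow(strs) > 0)
  expect_equal(unique(strs$motif), "CCCTCT")
})

test_that("no VNTR variation means no caller records at the locus", {
  tv <- plant_composite_te(1000, body_len = 1800,
                           vntr_allele_lens = numeric(0))
  tv$variant_id <- "te0"; tv$region <- "region_1"; tv$interesting <- FALSE
  gts <- tibble::tibble(variant_id = "te0",
                        sample = sprintf("S%d", 1:3),
                        genotype = "hom_ref", alt_value = NA_real_)
  calls <- simulate_caller_calls(tv, gts, no_noise_profiles())
  expect_equal(nrow(calls[calls$genotype != "hom_ref", ]), 0L)
})

test_that("genotype discordance 0.5 flips about half the genotypes", {
  tv <- plant_composite_te(5000, body_len = 1800,
                           vntr_allele_lens = c(47), chrom = "chr2")
  tv$variant_id <- "te1"; tv$region <- "region_1"; tv$interesting <- FALSE
  profiles <- no_noise_profiles()
  profiles$callers$geno_discord <- 0.5
  n_draws <- 10000
  gts <- tibble::tibble(variant_id = "te1",
                        sample = sprintf("S%d", seq_len(n_draws)),
                        genotype = "het", alt_value = 47)
  set.seed(101)
  calls <- simulate_caller_calls(tv, gts, profiles)
  vcf <- calls[calls$caller == "sniffles2", ]
  flip_rate <- mean(vcf$genotype == "hom_alt")
  expect_equal(flip_rate, 0.5, tolerance = 0.05)
})

test_that("in the no-noise limit every truth genotype appears at exact coordinates", {
  b <- cached_bundle(seed = 3, profiles = no_noise_profiles())
  nonref <- dplyr::inner_join(
    b$genotypes[b$genotypes$genotype != "hom_ref", ],
    b$truth, by = "variant_id")
  # sniffles2 supports every structural class at sensitivity 1
  sv <- nonref[nonref$var_class != "SNV", ]
  sn_calls <- b$calls[b$calls$caller == "sniffles2", ]
  found <- dplyr::semi_join(sv, sn_calls,
                            by = c("variant_id" = "source", "sample"))
  expect_equal(nrow(found), nrow(sv))
  # exact coordinates: STR observations stay inside the truth span,
  # indels and SNVs sit exactly on the truth start
  precise <- dplyr::inner_join(
    sn_calls, b$truth[, c("variant_id", "start", "end", "var_class")],
    by = c("source" = "variant_id"), suffix = c("", "_truth"))
  indel <- precise[precise$var_class_truth %in% c("INS", "DEL"), ]
  expect_true(all(indel$start == indel$start_truth))
  inside <- precise[precise$var_class_truth %in% c("STR", "TE"), ]
  expect_true(all(inside$start >= inside$start_truth &
                    inside$start < inside$end_truth))
})

test_that("planted on/off-target coverages are recovered within 5%", {
  b <- cached_bundle(seed = 2, include_reads = TRUE,
                     include_haplotypes = FALSE)
  expect_gt(nrow(b$reads), 5e4)
  kept <- filter_reads(b$reads)$kept
  qc <- sample_stats(kept, b$regions, genome_size = b$params$genome_size)
  truth <- b$reads_truth
  on <- dplyr::inner_join(qc[qc$scope == "on_target", ], truth, by = "sample")
  expect_true(all(abs(on$avg_cov - on$on_cov) / on$on_cov < 0.05))
  off <- dplyr::inner_join(qc[qc$scope == "off_target", ], truth,
                           by = "sample")
  expect_true(all(abs(off$avg_cov - off$off_cov) / off$off_cov < 0.05))
})

test_that("an infeasible spec is rejected", {
  expect_error(generate_cohort(seed = 1, interesting_per_region = 50,
                               include_reads = FALSE,
                               include_haplotypes = FALSE),
               "infeasible")
})

test_that("a written cohort re-ingests through the standard readers", {
  b <- cached_bundle(seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  regions <- read_regions_bed(file.path(dir, "regions.bed"))
  expect_equal(regions$name, b$regions$name)
  expect_equal(regions$start, b$regions$start)

  vcf <- read_sv_vcf(file.path(dir, "sniffles2_S1.vcf"),
                     caller = "sniffles2")
  orig <- dplyr::filter(b$calls, caller == "sniffles2", sample == "S1")
  expect_equal(nrow(vcf), nrow(orig))
  cols <- c("chrom", "start", "end", "var_class", "alt_len", "genotype")
  expect_equal(as.data.frame(dplyr::arrange(vcf[, cols], chrom, start)),
               as.data.frame(dplyr::arrange(orig[, cols], chrom, start)),
               ignore_attr = TRUE)

  strs <- read_str_table(file.path(dir, "straglr.tsv"))
  orig_str <- dplyr::filter(b$calls, caller == "straglr")
  expect_equal(sort(unique(strs$motif)), sort(unique(orig_str$motif)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(b$truth))
})
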