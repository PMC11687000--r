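#' Caller observation profiles for the synthetic cohort
#'
#' Describes how each emulated caller observes truth variants: which variant
#' classes it can call, its per-class sensitivity, breakpoint jitter (sd,
#' bp), genotype-discordance and unresolved-genotype probabilities, and its
#' caller-native quality distribution (log-normal, with a planted fraction
#' of calls below quality 9 to exercise the quality filter). The repeat
#' genotyper (`straglr`) emits locus tables without quality scores.
#'
#' `no_noise_profiles()` is the degenerate limit used for exact-recovery
#' checks: sensitivity 1 for every supported class, zero jitter, zero
#' discordance, no low-quality calls.
#'
#' @return A list with tibbles `callers` (per-caller noise/quality
#'   parameters) and `sensitivity` (caller x var_class).
#' @export
default_caller_profiles <- function() {
  callers <- tibble::tribble(
    ~caller,     ~jitter_sd, ~geno_discord, ~unresolved_rate, ~qual_meanlog, ~qual_sdlog, ~lowq_frac, ~emits_qual,
    "sniffles2",  8,          0.05,          0.05,             log(30),       0.35,        0.05,       TRUE,
    "nanovar",   12,          0.08,          0.02,             log(22),       0.45,        0.08,       TRUE,
    "clair3",     4,          0.05,          0.02,             log(18),       0.40,        0.10,       TRUE,
    "straglr",    0,          0.10,          0.00,             NA,            NA,          0,          FALSE)
  sensitivity <- tibble::tribble(
    ~caller,     ~var_class, ~sensitivity,
    "sniffles2", "INS", 0.95, "sniffles2", "DEL", 0.95,
    "sniffles2", "STR", 0.90, "sniffles2", "TE", 0.90,
    "nanovar",   "INS", 0.70, "nanovar",   "DEL", 0.70,
    "nanovar",   "STR", 0.40, "nanovar",   "TE", 0.80,
    "clair3",    "SNV", 0.98, "clair3",    "INS", 0.60,
    "clair3",    "DEL", 0.60, "clair3",    "STR", 0.50,
    "clair3",    "TE", 0.50,
    "straglr",   "STR", 0.90, "straglr",   "TE", 0.90)
  list(callers = callers, sensitivity = sensitivity)
}

#' @rdname default_caller_profiles
#' @export
no_noise_profiles <- function() {
  p <- default_caller_profiles()
  p$callers <- dplyr::mutate(p$callers, jitter_sd = 0, geno_discord = 0,
                             unresolved_rate = 0, lowq_frac = 0,
                             qual_meanlog = log(30), qual_sdlog = 0)
  p$sensitivity$sensitivity <- 1
  p
}

#' Plant a short-tandem-repeat truth locus
#'
#' Builds one STR truth variant: a motif repeated `ref_copies` times in the
#' reference, with the cohort's allele spectrum given as copy numbers
#' (values equal to `ref_copies` are reference alleles; smaller values are
#' contractions, larger expansions).
#'
#' @param motif Repeat unit (non-empty nucleotide string).
#' @param ref_copies Reference copy number (> 0; fractional allowed).
#' @param allele_copies Numeric vector of allele copy numbers in the cohort.
#' @param position 0-based start of the repeat.
#' @param chrom Chromosome label.
#' @return A one-row truth tibble with an `alt_alleles` list-column of
#'   non-reference copy numbers; `polymorphic` is `FALSE` for a monomorphic
#'   spectrum.
#' @examples
#' plant_str_locus("T", 40, c(35, 40), 48729043)
#' @export
plant_str_locus <- function(motif, ref_copies, allele_copies, position,
                            chrom = "chr1") {
  stopifnot(nchar(motif) >= 1, ref_copies > 0, all(allele_copies > 0))
  ref_len <- as.integer(round(nchar(motif) * ref_copies))
  alts <- sort(unique(allele_copies[allele_copies != ref_copies]))
  tibble::tibble(
    chrom = norm_chrom(chrom),
    start = as.integer(position),
    end = as.integer(position) + ref_len,
    var_class = "STR",
    motif = motif,
    ref_copies = ref_copies,
    ref_len = ref_len,
    alt_alleles = list(alts),
    polymorphic = length(alts) > 0L)
}

#' Plant a composite transposable-element truth locus
#'
#' Builds an SVA-like composite retrotransposon truth variant: a hexamer STR
#' head, a body (Alu-like element, VNTR, SINE-R), and a homopolymer tail.
#' Cohort variation is carried by the VNTR: each non-reference allele is an
#' insertion of the given length inside the VNTR subregion, which is how
#' VCF-based callers observe such elements (the repeat genotyper instead
#' reports repeat subunits across the element).
#'
#' @param position 0-based start of the element.
#' @param head_motif STR head motif (default the SVA hexamer `"CCCTCT"`).
#' @param head_copies Copies of the head motif (default 20).
#' @param body_len Combined Alu-like + VNTR + SINE-R length in bp.
#' @param tail_motif,tail_copies Poly-A style tail (defaults `"A"` x 30).
#' @param vntr_allele_lens Insertion lengths (bp) of the cohort's
#'   non-reference VNTR alleles.
#' @param chrom Chromosome label.
#' @return A one-row truth tibble (`var_class = "TE"`) with `alt_alleles`
#'   holding the VNTR insertion lengths.
#' @examples
#' plant_composite_te(48733472, body_len = 1800,
#'                    vntr_allele_lens = c(38, 46, 47))
#' @export
plant_composite_te <- function(position, head_motif = "CCCTCT",
                               head_copies = 20, body_len = 1800,
                               tail_motif = "A", tail_copies = 30,
                               vntr_allele_lens = c(38, 46, 47),
                               chrom = "chr1") {
  stopifnot(body_len > 0, head_copies > 0, tail_copies > 0)
  span <- as.integer(nchar(head_motif) * head_copies + body_len +
                       nchar(tail_motif) * tail_copies)
  tibble::tibble(
    chrom = norm_chrom(chrom),
    start = as.integer(position),
    end = as.integer(position) + span,
    var_class = "TE",
    motif = head_motif,
    ref_copies = NA_real_,
    ref_len = span,
    alt_alleles = list(sort(unique(vntr_allele_lens))),
    polymorphic = length(vntr_allele_lens) > 0L)
}

# Truth-variant prototype row for non-STR/TE classes.
plant_simple_variant <- function(chrom, position, var_class, sv_len,
                                 ref_seq = NA_character_,
                                 alt_seq = NA_character_) {
  end <- switch(var_class,
                SNV = position + 1L,
                INS = position + 1L,
                DEL = position + as.integer(sv_len))
  tibble::tibble(
    chrom = norm_chrom(chrom), start = as.integer(position),
    end = as.integer(end), var_class = var_class,
    motif = NA_character_, ref_copies = NA_real_,
    ref_len = if (var_class == "DEL") as.integer(sv_len) else 1L,
    alt_alleles = list(as.numeric(sv_len)),
    polymorphic = TRUE, ref_seq = ref_seq, alt_seq = alt_seq)
}

# Per-class interesting-variant recipes, cycled across regions.
interesting_recipe <- function(k, position, chrom) {
  motifs <- list(
    list(motif = "T", ref = 40, alts = c(33, 35, 37)),
    list(motif = "A", ref = 19, alts = c(16, 21)),
    list(motif = "AC", ref = 17, alts = c(14, 19, 21)),
    list(motif = "AT", ref = 18, alts = c(15, 20)),
    list(motif = "CT", ref = 14, alts = c(11, 16, 18)),
    list(motif = "AAAAT", ref = 14, alts = c(12, 16)),
    list(motif = "TCTT", ref = 21, alts = c(17, 24, 26)))
  cls <- c("STR", "TE", "STR", "STR", "DEL", "STR", "STR", "STR", "DEL",
           "STR", "DEL", "STR", "INS", "STR", "STR", "STR", "STR", "DEL",
           "STR", "STR")[((k - 1) %% 20) + 1]
  if (cls == "STR") {
    m <- motifs[[((k - 1) %% length(motifs)) + 1]]
    plant_str_locus(m$motif, m$ref, c(m$alts, m$ref), position, chrom)
  } else if (cls == "TE") {
    plant_composite_te(position, body_len = 1800,
                       vntr_allele_lens = c(38, 46, 47), chrom = chrom)
  } else if (cls == "DEL") {
    plant_simple_variant(chrom, position, "DEL",
                         sv_len = c(15, 28, 34, 58)[((k - 1) %% 4) + 1])
  } else {
    plant_simple_variant(chrom, position, "INS", sv_len = 49L)
  }
}

#' Generate a synthetic targeted-sequencing cohort with planted truth
#'
#' Builds a fully hermetic fixture bundle for every pipeline stage:
#' target regions around the lead-SNP panel, a truth variant set (SNVs plus
#' STR/indel/TE structural variants, a planted subset flagged `interesting`
#' because it satisfies every prioritisation criterion), per-caller observed
#' call sets under configurable noise profiles, BAM-inspection evidence,
#' per-read alignment summaries with planted on/off-target coverage,
#' impact/rsID annotations, functional-annotation tracks with planted
#' per-class window frequencies, and phased haplotype matrices with one
#' planted high-LD cassette per block-bearing region.
#'
#' Everything is deterministic given `seed`. A truth variant flagged
#' `interesting` is guaranteed at least one cascade-passing call (callers
#' only ever miss it in their noisier duplicates), because the flag is
#' defined as "satisfies all criteria". Non-interesting structural variants
#' each carry one planted disqualifier (SNV class, short indel, known rsID,
#' sub-HIGH impact, or position outside the LD block). Regions listed in
#' `blockless_regions` get haplotypes without an LD cassette, exercising the
#' lenient pass-through of the LD stage.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_samples Cohort size (default 10).
#' @param lead_snps Lead-SNP panel (default [an_lead_snps()]).
#' @param flank Region flank in bp (default 100,000).
#' @param n_snv Number of truth SNVs (default 93; together with the 27
#'   structural variants this gives the default 120-variant truth set with a
#'   non-SNV fraction near 0.226).
#' @param interesting_per_region Number of interesting variants per region
#'   (default `c(3, 8, 1, 2, 1, 1, 3, 1)`, 20 in total).
#' @param profiles Caller profiles ([default_caller_profiles()] or
#'   [no_noise_profiles()]).
#' @param coverage Planted mean coverages and read lengths:
#'   `list(on, off, on_len, off_len)`.
#' @param per_sample_cov_jitter Relative spread of per-sample planted
#'   coverages (default 0.15).
#' @param genome_size Declared genome size in bp (off-target denominator).
#' @param read_fail_frac Fraction of extra reads planted below the Q9 /
#'   500 bp read filter (default 0.1).
#' @param blockless_regions Region names without LD blocks.
#' @param include_reads,include_haplotypes Toggle the expensive components.
#' @return An `an_cohort` list bundle; see Details in the package vignette.
#' @export
generate_cohort <- function(seed,
                            n_samples = 10,
                            lead_snps = an_lead_snps(),
                            flank = 100000,
                            n_snv = 93,
                            interesting_per_region = c(3, 8, 1, 2, 1, 1, 3, 1),
                            profiles = default_caller_profiles(),
                            coverage = list(on = 15, off = 3,
                                            on_len = 12000, off_len = 3000),
                            per_sample_cov_jitter = 0.15,
                            genome_size = 4.8e6,
                            read_fail_frac = 0.1,
                            blockless_regions = c("region_6", "region_7",
                                                  "region_8"),
                            include_reads = TRUE,
                            include_haplotypes = TRUE) {
  regions <- build_target_regions(lead_snps, flank)
  n_regions <- nrow(regions)
  interesting_per_region <- rep_len(interesting_per_region, n_regions)
  samples <- sprintf("S%d", seq_len(n_samples))

  # Interesting variants sit on an 8 kb grid inside the +/-28 kb core of the
  # LD cassette around the lead SNP; the spacing keeps each variant's
  # annotation features out of its neighbours' +/-2.5 kb windows.
  core_slots <- seq(flank - 28000, flank + 28000, by = 8000)
  if (any(interesting_per_region > length(core_slots))) {
    abort("infeasible spec: more interesting variants than region capacity.")
  }

  with_seed(seed, {
    truth <- list(); genotypes <- list(); k_int <- 0L
    for (r in seq_len(n_regions)) {
      reg <- regions[r, ]
      n_int <- interesting_per_region[r]
      slots <- reg$start + core_slots[seq_len(n_int)]
      for (p in slots) {
        k_int <- k_int + 1L
        tv <- interesting_recipe(k_int, p, reg$chrom)
        tv$region <- reg$name
        tv$impact <- "HIGH"
        tv$rsid <- NA_character_
        tv$planted_fail <- NA_character_
        truth[[length(truth) + 1L]] <- tv
      }
    }
    # Decoy structural variants, each with one disqualifying attribute.
    decoys <- list(
      list(region = 1L, offset = 35000, class = "DEL", len = 6,
           impact = "HIGH", rsid = NA, fail = "short_indel"),
      list(region = 2L, offset = 35000, class = "INS", len = 8,
           impact = "HIGH", rsid = NA, fail = "short_indel"),
      list(region = 2L, offset = 40000, class = "STR", len = NA,
           impact = "HIGH", rsid = "rs7001", fail = "known_rsid"),
      list(region = 3L, offset = 35000, class = "STR", len = NA,
           impact = "HIGH", rsid = "rs7002", fail = "known_rsid"),
      list(region = 4L, offset = 35000, class = "STR", len = NA,
           impact = "MODERATE", rsid = NA, fail = "impact"),
      list(region = 5L, offset = 35000, class = "STR", len = NA,
           impact = "MODERATE", rsid = NA, fail = "impact"),
      list(region = 1L, offset = 20000, class = "STR", len = NA,
           impact = "HIGH", rsid = NA, fail = "outside_ld_block"))
    for (d in decoys) {
      reg <- regions[min(d$region, n_regions), ]
      p <- reg$start + d$offset
      tv <- if (d$class == "STR") {
        plant_str_locus("AC", 22, c(18, 22, 25), p, reg$chrom)
      } else {
        plant_simple_variant(reg$chrom, p, d$class, sv_len = d$len)
      }
      tv$region <- reg$name
      tv$impact <- d$impact
      tv$rsid <- if (is.na(d$rsid)) NA_character_ else d$rsid
      tv$planted_fail <- d$fail
      truth[[length(truth) + 1L]] <- tv
    }
    # SNVs on an offset grid, 2.5 kb clear of any structural slot.
    bases <- c("A", "C", "G", "T")
    snv_region <- rep_len(seq_len(n_regions), n_snv)
    snv_slot_pool <- seq(10000, 2 * flank - 10000, by = 5000) + 2500
    for (i in seq_len(n_snv)) {
      reg <- regions[snv_region[i], ]
      slot <- snv_slot_pool[(ceiling(i / n_regions) - 1) %%
                              length(snv_slot_pool) + 1]
      p <- reg$start + slot
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      tv <- plant_simple_variant(reg$chrom, p, "SNV", sv_len = 1,
                                 ref_seq = ref, alt_seq = alt)
      tv$region <- reg$name
      tv$impact <- sample(c("MODIFIER", "LOW", "MODERATE"), 1,
                          prob = c(0.7, 0.2, 0.1))
      tv$rsid <- if (runif(1) < 0.8) sprintf("rs%07d", sample.int(9e6, 1)) else
        NA_character_
      tv$planted_fail <- "snv"
      truth[[length(truth) + 1L]] <- tv
    }
    truth <- dplyr::bind_rows(truth)
    truth$variant_id <- sprintf("tv%03d", seq_len(nrow(truth)))
    truth$in_ld_block <- is.na(truth$planted_fail) |
      truth$planted_fail != "outside_ld_block"
    truth$interesting <- is.na(truth$planted_fail)
    truth <- dplyr::relocate(truth, "variant_id")

    # Per-sample truth genotypes and allele assignment.
    genotypes <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      tv <- truth[i, ]
      alts <- tv$alt_alleles[[1]]
      if (length(alts) == 0L) return(NULL)
      n_carriers <- if (tv$interesting && runif(1) < 0.5) n_samples else
        sample.int(n_samples, 1)
      carriers <- sort(sample(samples, n_carriers))
      tibble::tibble(
        variant_id = tv$variant_id, sample = samples,
        genotype = ifelse(samples %in% carriers,
                          ifelse(runif(n_samples) < 0.7, "het", "hom_alt"),
                          "hom_ref"),
        alt_value = ifelse(samples %in% carriers,
                           alts[(match(samples, carriers) - 1L) %%
                                  length(alts) + 1L],
                           NA_real_))
    })

    calls <- simulate_caller_calls(truth, genotypes, profiles)

    bam_evidence <- truth |>
      dplyr::filter(.data$interesting) |>
      dplyr::inner_join(dplyr::filter(genotypes,
                                      .data$genotype != "hom_ref"),
                        by = "variant_id") |>
      dplyr::transmute(sample = .data$sample, chrom = .data$chrom,
                       start = .data$start, end = .data$end, differs = TRUE,
                       note = .data$variant_id)

    # Phased haplotypes with one planted LD cassette per block-bearing region.
    haplotypes <- NULL
    ld_truth <- tibble::tibble(region = character(), chrom = character(),
                               start = integer(), end = integer(),
                               threshold = double(), anchor_pos = double())
    if (include_haplotypes) {
      haplotypes <- list()
      for (r in seq_len(n_regions)) {
        reg <- regions[r, ]
        blockless <- reg$name %in% blockless_regions
        hp <- plant_ld_region(reg, n_hap = 2L * n_samples,
                              cassette = !blockless)
        haplotypes[[reg$name]] <- hp$haps
        if (!blockless) {
          ld_truth <- dplyr::bind_rows(ld_truth, tibble::tibble(
            region = reg$name, chrom = reg$chrom,
            start = as.integer(min(hp$cassette_pos) - 1),
            end = as.integer(max(hp$cassette_pos)),
            threshold = 0.8, anchor_pos = as.numeric(reg$lead_pos)))
        }
      }
    }

    reads <- NULL
    reads_truth <- NULL
    if (include_reads) {
      rd <- generate_read_summaries(
        regions, samples, coverage = coverage,
        per_sample_cov_jitter = per_sample_cov_jitter,
        genome_size = genome_size, read_fail_frac = read_fail_frac)
      reads <- rd$reads
      reads_truth <- rd$truth
    }

    annotations <- dplyr::transmute(
      truth, variant_id = .data$variant_id, chrom = .data$chrom,
      start = .data$start, end = .data$end, impact = .data$impact,
      rsid = .data$rsid,
      consequence = ifelse(.data$var_class == "SNV", "intron_variant",
                           "non_coding_transcript_variant"))

    planted <- plant_annotation_tracks(truth, regions)

    structure(list(
      seed = seed, samples = samples, regions = regions,
      lead_snps = lead_snps, truth = truth, genotypes = genotypes,
      calls = calls, bam_evidence = bam_evidence,
      haplotypes = haplotypes, ld_truth = ld_truth,
      reads = reads, reads_truth = reads_truth,
      annotations = annotations, tracks = planted$tracks,
      annotation_truth = planted$truth,
      profiles = profiles,
      params = list(flank = flank, genome_size = genome_size,
                    coverage = coverage, read_fail_frac = read_fail_frac,
                    blockless_regions = blockless_regions)),
      class = "an_cohort")
  })
}

#' Simulate per-caller observations of a truth variant set
#'
#' Applies each caller's observation model to the truth genotypes:
#' detection with per-class sensitivity, breakpoint jitter, genotype
#' discordance and unresolved genotypes, and caller-native quality draws
#' with a planted low-quality fraction. VCF-style callers observe STRs as
#' length-change indels inside the repeat span and composite TEs as
#' insertions in the VNTR subregion; the repeat genotyper reports motif and
#' copy number over the locus span (genotyping every sample once it detects
#' a locus). Every `interesting` truth variant is guaranteed one
#' filter-passing anchor call.
#'
#' @param truth Truth tibble from [generate_cohort()] (or the `plant_*`
#'   helpers, with `variant_id`, `region`, `interesting` columns added).
#' @param genotypes Truth genotype tibble (`variant_id`, `sample`,
#'   `genotype`, `alt_value`).
#' @param profiles Caller profiles.
#' @return A call tibble (see [callset]).
#' @export
simulate_caller_calls <- function(truth, genotypes, profiles) {
  sens <- function(caller, cls) {
    s <- profiles$sensitivity$sensitivity[
      profiles$sensitivity$caller == caller &
        profiles$sensitivity$var_class == cls]
    if (length(s) == 0L) 0 else s[1]
  }
  out <- list()
  for (ci in seq_len(nrow(profiles$callers))) {
    prof <- profiles$callers[ci, ]
    vcf_style <- prof$caller != "straglr"
    for (i in seq_len(nrow(truth))) {
      tv <- truth[i, ]
      s <- sens(prof$caller, tv$var_class)
      if (s <= 0) next
      gts <- genotypes[genotypes$variant_id == tv$variant_id, ]
      if (vcf_style) {
        carriers <- gts[gts$genotype != "hom_ref", ]
        if (nrow(carriers) == 0L) next
        det <- runif(nrow(carriers)) < s
        for (j in which(det)) {
          out[[length(out) + 1L]] <-
            observe_vcf_call(tv, carriers[j, ], prof)
        }
      } else {
        if (runif(1) >= s) next
        out <- c(out, observe_str_rows(tv, gts, prof))
      }
    }
  }
  calls <- rows_to_calls(out)
  # Anchor guarantee: an interesting variant satisfies all criteria, so at
  # least one passing, exactly-placed call must exist for it.
  if ("interesting" %in% names(truth)) {
    for (i in which(truth$interesting)) {
      tv <- truth[i, ]
      gts <- genotypes[genotypes$variant_id == tv$variant_id &
                         genotypes$genotype != "hom_ref", ]
      if (nrow(gts) == 0L) next
      need_str <- tv$var_class %in% c("STR", "TE")
      have <- calls[calls$source == tv$variant_id &
                      calls$genotype %in% c("het", "hom_alt") &
                      (is.na(calls$qual) | calls$qual >= 9) &
                      (!need_str | calls$var_class == "STR"), ]
      # Repeat/TE truths need a repeat-class call (a length-change indel
      # observation alone could be shorter than the indel-length cutoff).
      if (nrow(have) == 0L) {
        anchor_prof <- profiles$callers[
          profiles$callers$caller ==
            if (tv$var_class %in% c("STR", "TE")) "straglr" else "sniffles2", ]
        anchor_prof$jitter_sd <- 0
        anchor_prof$geno_discord <- 0
        anchor_prof$unresolved_rate <- 0
        anchor_prof$lowq_frac <- 0
        anchor_prof$qual_meanlog <- log(30)
        anchor_prof$qual_sdlog <- 0
        add <- if (tv$var_class %in% c("STR", "TE")) {
          observe_str_rows(tv, gts, anchor_prof)
        } else {
          list(observe_vcf_call(tv, gts[1, ], anchor_prof))
        }
        calls <- dplyr::bind_rows(calls, rows_to_calls(add))
      }
    }
  }
  dplyr::arrange(calls, .data$chrom, .data$start, .data$caller, .data$sample)
}

# One VCF-style caller observation of one carrier sample.
observe_vcf_call <- function(tv, gt, prof) {
  jitter <- as.integer(round(rnorm(1, 0, prof$jitter_sd)))
  genotype <- gt$genotype
  if (runif(1) < prof$geno_discord) {
    genotype <- ifelse(genotype == "het", "hom_alt", "het")
  }
  if (runif(1) < prof$unresolved_rate) genotype <- "unresolved"
  qual <- if (!prof$emits_qual) NA_real_ else if (runif(1) < prof$lowq_frac) {
    runif(1, 1, 8.5)
  } else rlnorm(1, prof$qual_meanlog, prof$qual_sdlog)

  if (tv$var_class == "SNV") {
    cls <- "SNV"; start <- tv$start; end <- tv$end; alt_len <- 1L
    ref_seq <- tv$ref_seq; alt_seq <- tv$alt_seq
  } else if (tv$var_class == "STR") {
    delta <- round((gt$alt_value - tv$ref_copies) * nchar(tv$motif))
    cls <- if (delta > 0) "INS" else "DEL"
    mid <- tv$start + (tv$end - tv$start) %/% 2L
    start <- max(tv$start, min(tv$end - 1L, mid + jitter))
    end <- if (cls == "DEL") start + abs(as.integer(delta)) else start + 1L
    alt_len <- abs(as.integer(delta))
    ref_seq <- NA_character_; alt_seq <- NA_character_
  } else if (tv$var_class == "TE") {
    cls <- "INS"
    vntr <- tv$start + as.integer(round(0.55 * (tv$end - tv$start)))
    start <- max(tv$start, min(tv$end - 1L, vntr + jitter))
    end <- start + 1L
    alt_len <- as.integer(gt$alt_value)
    ref_seq <- NA_character_; alt_seq <- NA_character_
  } else {
    cls <- tv$var_class
    len <- as.integer(gt$alt_value)
    # Clamp breakpoint jitter so that observations of one truth indel always
    # satisfy the merge predicate (DEL reciprocal overlap >= 0.5) and always
    # overlap the padded annotation interval.
    cap <- if (cls == "DEL") min(100L, len %/% 4L) else 100L
    jitter <- max(-cap, min(cap, jitter))
    start <- max(0L, tv$start + jitter)
    end <- if (cls == "DEL") start + len else start + 1L
    alt_len <- len
    ref_seq <- NA_character_; alt_seq <- NA_character_
  }
  list(sample = gt$sample, caller = prof$caller, chrom = tv$chrom,
       start = as.integer(start), end = as.integer(end),
       var_class = cls, ref_len = tv$ref_len,
       alt_len = as.integer(alt_len),
       motif = NA_character_, copy_number = NA_real_, qual = qual,
       genotype = genotype, ref_seq = ref_seq, alt_seq = alt_seq,
       source = tv$variant_id)
}

# Assemble plain observation rows into the canonical call tibble.
rows_to_calls <- function(rows) {
  if (length(rows) == 0L) return(call_tibble())
  chr_f <- function(f) vapply(rows, function(r) as.character(r[[f]]), "")
  int_f <- function(f) vapply(rows, function(r) as.integer(r[[f]]), 1L)
  dbl_f <- function(f) vapply(rows, function(r) as.numeric(r[[f]]), 1)
  call_tibble(
    sample = chr_f("sample"), caller = chr_f("caller"), chrom = chr_f("chrom"),
    start = int_f("start"), end = int_f("end"), var_class = chr_f("var_class"),
    ref_len = int_f("ref_len"), alt_len = int_f("alt_len"),
    motif = chr_f("motif"), copy_number = dbl_f("copy_number"),
    qual = dbl_f("qual"), genotype = chr_f("genotype"),
    ref_seq = chr_f("ref_seq"), alt_seq = chr_f("alt_seq"),
    source = chr_f("source"))
}

# Repeat-genotyper observation: genotypes every sample at the locus.
observe_str_rows <- function(tv, gts, prof) {
  if (tv$var_class == "TE") {
    motif <- tv$motif
    ref_copies <- round((tv$end - tv$start) / nchar(motif), 1)
  } else {
    motif <- tv$motif
    ref_copies <- tv$ref_copies
  }
  lapply(seq_len(nrow(gts)), function(j) {
    if (gts$genotype[j] == "hom_ref") {
      cn <- NA_real_
      genotype <- "hom_ref"
    } else {
      cn <- if (tv$var_class == "TE") {
        ref_copies + round(gts$alt_value[j] / nchar(motif), 1)
      } else gts$alt_value[j]
      if (runif(1) < prof$geno_discord) {
        cn <- cn + sample(c(-1, 1), 1)
      }
      genotype <- gts$genotype[j]
    }
    list(sample = gts$sample[j], caller = prof$caller, chrom = tv$chrom,
         start = tv$start, end = tv$end, var_class = "STR",
         ref_len = tv$ref_len,
         alt_len = if (is.na(cn)) NA_integer_ else
           as.integer(round(cn * nchar(motif))),
         motif = motif, copy_number = cn, qual = NA_real_,
         genotype = genotype, ref_seq = NA_character_,
         alt_seq = NA_character_, source = tv$variant_id)
  })
}

# Haplotypes for one region: anchor + perfect-LD cassette + unlinked sites.
plant_ld_region <- function(reg, n_hap, cassette = TRUE,
                            cassette_halfwidth = 30000, n_cassette = 20,
                            n_unlinked = 16, max_r2_unlinked = 0.3) {
  anchor_pos <- reg$lead_pos
  repeat {
    anchor <- rbinom(n_hap, 1, 0.5)
    if (mean(anchor) >= 0.3 && mean(anchor) <= 0.7) break
  }
  cassette_pos <- numeric(0)
  cols <- list()
  pos <- numeric(0)
  if (cassette) {
    cassette_pos <- round(seq(anchor_pos - cassette_halfwidth,
                              anchor_pos + cassette_halfwidth,
                              length.out = n_cassette + 1))
    cassette_pos <- sort(unique(c(cassette_pos, anchor_pos)))
    for (p in cassette_pos) {
      cols[[length(cols) + 1L]] <- anchor
      pos <- c(pos, p)
    }
  } else {
    cols[[1L]] <- anchor
    pos <- anchor_pos
  }
  side <- c(seq(reg$start + 5000, anchor_pos - cassette_halfwidth - 12000,
                length.out = ceiling(n_unlinked / 2)),
            seq(anchor_pos + cassette_halfwidth + 12000, reg$end - 5000,
                length.out = floor(n_unlinked / 2)))
  for (p in round(side)) {
    repeat {
      v <- rbinom(n_hap, 1, 0.5)
      r2 <- suppressWarnings(r_squared(v, anchor))
      if (!is.na(r2) && r2 <= max_r2_unlinked) break
    }
    cols[[length(cols) + 1L]] <- v
    pos <- c(pos, p)
  }
  ord <- order(pos)
  mat <- do.call(cbind, cols)[, ord, drop = FALSE]
  list(haps = hap_matrix(mat, pos[ord]),
       cassette_pos = cassette_pos, anchor_pos = anchor_pos)
}

#' Generate per-read alignment summaries with planted coverage
#'
#' Samples read intervals directly (no sequence simulation): per sample, a
#' planted on-target and off-target fold coverage determines the number of
#' reads of gamma-distributed length placed uniformly inside the target
#' regions and inside off-target spans, so that total aligned bases divided
#' by the respective denominators recover the planted coverages up to
#' sampling error. An extra `read_fail_frac` of reads is planted below the
#' Q9 / 500 bp read filter (flagged `planted_fail`).
#'
#' @inheritParams generate_cohort
#' @param regions Region tibble.
#' @param samples Sample ids.
#' @return List with `reads` (read-summary tibble incl. `planted_fail`) and
#'   `truth` (per-sample planted coverages).
#' @export
generate_read_summaries <- function(regions, samples,
                                    coverage = list(on = 15, off = 3,
                                                    on_len = 12000,
                                                    off_len = 3000),
                                    per_sample_cov_jitter = 0.15,
                                    genome_size = 4.8e6,
                                    read_fail_frac = 0.1) {
  total_target <- sum(regions$end - regions$start)
  off_span_total <- genome_size - total_target
  stopifnot(off_span_total > 0)
  n_regions <- nrow(regions)
  off_span_each <- floor(off_span_total / n_regions)
  out <- list()
  truth <- list()
  for (s in samples) {
    on_cov <- coverage$on * runif(1, 1 - per_sample_cov_jitter,
                                  1 + per_sample_cov_jitter)
    off_cov <- coverage$off * runif(1, 1 - per_sample_cov_jitter,
                                    1 + per_sample_cov_jitter)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      sample = s, on_cov = on_cov, off_cov = off_cov)
    for (r in seq_len(n_regions)) {
      reg <- regions[r, ]
      width <- reg$end - reg$start
      n_on <- max(1L, round(on_cov * width / coverage$on_len))
      len_on <- pmin(width - 1L,
                     pmax(600L, round(rgamma(n_on, shape = 6,
                                             scale = coverage$on_len / 6))))
      start_on <- reg$start + floor(runif(n_on) * (width - len_on))
      q_on <- pmax(10, rnorm(n_on, 22.4, 0.6))
      n_off <- max(1L, round(off_cov * off_span_each / coverage$off_len))
      len_off <- pmax(600L, round(rgamma(n_off, shape = 6,
                                         scale = coverage$off_len / 6)))
      off_base <- reg$end + 100000L
      start_off <- off_base + floor(runif(n_off) * (off_span_each - len_off))
      q_off <- pmax(10, rnorm(n_off, 22.3, 0.6))
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = s,
        chrom = reg$chrom,
        start = as.integer(c(start_on, start_off)),
        read_len = as.integer(c(len_on, len_off)),
        mean_err = error_from_phred(c(q_on, q_off)),
        planted_fail = FALSE)
    }
    # Planted sub-threshold reads: half too short, half below Q9.
    n_kept <- sum(vapply(tail(out, n_regions), nrow, integer(1)))
    n_fail <- round(read_fail_frac * n_kept)
    if (n_fail > 0L) {
      short <- seq_len(n_fail) <= n_fail / 2
      reg <- regions[1, ]
      len <- ifelse(short, 100L + floor(runif(n_fail) * 400L),
                    pmax(600L, round(rgamma(n_fail, shape = 6,
                                            scale = coverage$off_len / 6))))
      q <- ifelse(short, rnorm(n_fail, 22, 0.6), runif(n_fail, 3, 8.5))
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = s, chrom = reg$chrom,
        start = as.integer(reg$start + floor(runif(n_fail) *
                                               (reg$end - reg$start - len))),
        read_len = as.integer(len),
        mean_err = error_from_phred(pmax(0.5, q)),
        planted_fail = TRUE)
    }
  }
  reads <- dplyr::bind_rows(out)
  reads$end <- reads$start + reads$read_len
  reads$read_id <- sprintf("read_%06d", seq_len(nrow(reads)))
  list(reads = dplyr::select(reads, "read_id", "sample", "chrom", "start",
                             "end", "read_len", "mean_err", "planted_fail"),
       truth = dplyr::bind_rows(truth))
}

# Functional-annotation tracks with planted per-class window frequencies.
plant_annotation_tracks <- function(truth, regions) {
  interesting <- truth[truth$interesting, , drop = FALSE]
  n <- nrow(interesting)
  tracks <- list()
  truth_rows <- list()
  if (n > 0L) {
    idx_enh <- seq_len(ceiling(0.6 * n))
    idx_tfbs <- seq_len(ceiling(0.7 * n))
    idx_ctcf <- which(seq_len(n) %% 2 == 1)
    idx_far <- utils::head(seq_len(n), 3)
    add <- function(i, cls, start, end, within) {
      tracks[[length(tracks) + 1L]] <<- tibble::tibble(
        chrom = interesting$chrom[i], start = as.integer(start),
        end = as.integer(end), feature_class = cls,
        label = sprintf("%s_%s", cls, interesting$variant_id[i]))
      truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
        variant_id = interesting$variant_id[i], feature_class = cls,
        within_window = within)
    }
    for (i in idx_enh) {
      add(i, "enhancer_distal", interesting$end[i] + 1200,
          interesting$end[i] + 1400, TRUE)
    }
    for (i in idx_tfbs) {
      add(i, "TFBS", interesting$start[i] - 1050,
          interesting$start[i] - 900, TRUE)
    }
    for (i in idx_ctcf) {
      add(i, "CTCF", interesting$start[i] - 50, interesting$end[i] + 50, TRUE)
    }
    for (i in idx_far) {
      add(i, "eQTL", interesting$end[i] + 2801, interesting$end[i] + 2901,
          FALSE)
    }
  }
  # GWAS-catalogue style point hits at each lead SNP.
  for (r in seq_len(nrow(regions))) {
    tracks[[length(tracks) + 1L]] <- tibble::tibble(
      chrom = regions$chrom[r], start = regions$lead_pos[r] - 1L,
      end = regions$lead_pos[r], feature_class = "GWAS_hit",
      label = paste0("lead_", regions$name[r]))
  }
  list(tracks = dplyr::bind_rows(tracks),
       truth = dplyr::bind_rows(tibble::tibble(variant_id = character(),
                                               feature_class = character(),
                                               within_window = logical()),
                                truth_rows))
}

#' @export
print.an_cohort <- function(x, ...) {
  cat(sprintf(paste0("<an_cohort> seed %d: %d samples, %d regions, ",
                     "%d truth variants (%d interesting), %d calls\n"),
              x$seed, length(x$samples), nrow(x$regions), nrow(x$truth),
              sum(x$truth$interesting), nrow(x$calls)))
  invisible(x)
}

#' Write a synthetic cohort bundle to standard file formats
#'
#' Serialises the bundle the way a real run would arrive on disk: regions
#' BED, per-caller single-sample VCFs, an STR locus table TSV, read-summary
#' TSV, BAM-evidence TSV, impact TSV, annotation-track BED, haplotype
#' matrices TSV, and the truth set as JSON.
#'
#' @param bundle An `an_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regions_bed(bundle$regions, file.path(dir, "regions.bed"))
  vcf_calls <- dplyr::filter(bundle$calls, .data$caller != "straglr")
  for (key in unique(paste(vcf_calls$caller, vcf_calls$sample))) {
    parts <- strsplit(key, " ")[[1]]
    sub <- dplyr::filter(vcf_calls, .data$caller == parts[1],
                         .data$sample == parts[2])
    write_caller_vcf(sub, file.path(dir, sprintf("%s_%s.vcf",
                                                 parts[1], parts[2])))
  }
  str_calls <- dplyr::filter(bundle$calls, .data$caller == "straglr",
                             .data$genotype != "unresolved")
  if (nrow(str_calls) > 0L) {
    write_str_table(str_calls, file.path(dir, "straglr.tsv"))
  }
  if (!is.null(bundle$reads)) {
    readr::write_tsv(dplyr::select(bundle$reads, -"planted_fail"),
                     file.path(dir, "reads.tsv"))
  }
  readr::write_tsv(bundle$bam_evidence, file.path(dir, "bam_evidence.tsv"))
  readr::write_tsv(bundle$annotations, file.path(dir, "impact.tsv"))
  readr::write_tsv(bundle$tracks, file.path(dir, "tracks.bed"),
                   col_names = FALSE)
  if (!is.null(bundle$haplotypes)) {
    for (nm in names(bundle$haplotypes)) {
      hp <- bundle$haplotypes[[nm]]
      readr::write_tsv(tibble::as_tibble(hp$alleles),
                       file.path(dir, sprintf("haplotypes_%s.tsv", nm)))
    }
  }
  truth_out <- bundle$truth
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
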