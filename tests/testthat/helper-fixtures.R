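# Shared fixture builders. Everything is generated in code at test time;
# bundles are cached per (seed, options) so slow generators run once.

.fixture_cache <- new.env(parent = emptyenv())

cached_bundle <- function(seed = 1, include_reads = FALSE,
                          include_haplotypes = TRUE, profiles = NULL) {
  key <- paste(seed, include_reads, include_haplotypes,
               if (is.null(profiles)) "default" else "noiseless")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(
      seed = seed, include_reads = include_reads,
      include_haplotypes = include_haplotypes,
      profiles = profiles %||% default_caller_profiles())
  }
  .fixture_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal normalised call row with sensible defaults.
make_call <- function(chrom = "chr1", start = 1000L, end = NULL,
                      var_class = "DEL", alt_len = 15L, sample = "S1",
                      caller = "sniffles2", qual = 30,
                      genotype = "het", motif = NA_character_,
                      copy_number = NA_real_, ref_seq = NA_character_,
                      alt_seq = NA_character_, source = "test") {
  if (is.null(end)) {
    end <- switch(var_class,
                  SNV = start + 1L, INS = start + 1L,
                  DEL = start + alt_len,
                  STR = start + alt_len, TE = start + alt_len)
  }
  tibble::tibble(
    sample = sample, caller = caller, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    var_class = var_class, ref_len = 1L, alt_len = as.integer(alt_len),
    motif = motif, copy_number = copy_number, qual = qual,
    genotype = genotype, ref_seq = ref_seq, alt_seq = alt_seq,
    source = source)
}

# Scalar match predicate written independently of the package's vectorised
# implementation, used by the brute-force clustering oracle.
oracle_match <- function(a, b, maxd = 500, ro = 0.5) {
  if (a$chrom != b$chrom) return(FALSE)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  cls <- sort(c(a$var_class, b$var_class))
  if (all(cls == "SNV")) {
    return(a$start == b$start && identical(a$alt_seq, b$alt_seq) &&
             !is.na(a$alt_seq))
  }
  if (all(cls == "INS")) return(abs(a$start - b$start) <= maxd)
  if (all(cls == "DEL")) {
    return(abs(a$start - b$start) <= maxd &&
             ov / max(1, a$end - a$start) >= ro &&
             ov / max(1, b$end - b$start) >= ro)
  }
  if ("STR" %in% cls && all(cls %in% c("STR", "INS", "DEL"))) return(ov >= 1)
  if ("TE" %in% cls && all(cls %in% c("TE", "INS"))) return(ov >= 1)
  if (all(cls == "COMPLEX")) return(ov >= 1)
  FALSE
}

# Brute-force transitive closure of the pairwise predicate (boolean matrix
# powers), returning a canonical partition signature.
oracle_partition <- function(calls, maxd = 500, ro = 0.5) {
  n <- nrow(calls)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && oracle_match(calls[i, ], calls[j, ], maxd, ro)) {
        adj[i, j] <- TRUE
      }
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  grp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      grp <- grp + 1L
      comp[reach[i, ]] <- grp
    }
  }
  comp
}

# Canonical signature of a partition: sorted groups of sorted member keys.
partition_signature <- function(keys, groups) {
  sig <- lapply(split(keys, groups), function(k) paste(sort(k), collapse = ","))
  sort(unlist(sig, use.names = FALSE))
}

random_call_set <- function(n, chrom_pool = c("chr1", "chr2")) {
  cls <- sample(c("SNV", "INS", "DEL", "STR", "TE"), n, replace = TRUE)
  start <- sample.int(5000, n, replace = TRUE)
  purrr::map_dfr(seq_len(n), function(i) {
    len <- sample(10:200, 1)
    make_call(chrom = sample(chrom_pool, 1), start = start[i],
              var_class = cls[i], alt_len = len,
              alt_seq = if (cls[i] == "SNV") sample(c("A", "C"), 1) else
                NA_character_,
              sample = sample(c("S1", "S2", "S3"), 1),
              caller = sample(c("sniffles2", "nanovar"), 1),
              source = sprintf("rc%03d", i))
  })
}
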