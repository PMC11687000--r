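---
title: "Targeted structural-variant prioritisation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted structural-variant prioritisation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosieve)
```

## The analysis problem

GWAS loci are tag positions, not causal variants. Around a lead SNP the
causal signal may be carried — via linkage disequilibrium — by structural
variation that short-read pipelines genotype poorly: tandem-repeat length
changes, medium indels, and transposable-element polymorphism.
Adaptive-sampling nanopore sequencing enriches user-supplied target
windows in real time, giving long reads over exactly those regions, but
the downstream analysis then has to (a) demonstrate the enrichment worked,
(b) reconcile the discordant outputs of several variant callers, and
(c) reduce tens of thousands of raw calls to a tractable, auditable
shortlist. `nanosieve` implements that post-sequencing pipeline as a set
of composable, tibble-in/tibble-out functions.

The package's worked defaults mirror a study of eight anorexia-nervosa
GWAS risk loci in ten case samples: `an_lead_snps()` carries the lead-SNP
panel, and `nanopore_run_qc()` the per-sample enrichment statistics of
that run, which `cohort_summary()` reduces to the cohort mean/SE row.

## Coordinates

All intervals in the package are **0-based half-open** `[start, end)`,
the BED convention; VCF `POS` maps to `start = POS − 1`, and insertions
are stored as width-1 points with the inserted length carried separately
(`alt_len`), matching VCF symbolic-allele practice. A target region built
from a lead SNP at 1-based position `p` with flank `f` is
`[p − f, p + f)`: width exactly `2f`, lead SNP inside, and the stored
`start`/`end` pair is the coordinate pair such windows are conventionally
printed with. Chromosome labels are normalised to the `chr` prefix on
input so that mixed-convention VCF/BED sources cannot silently fail to
overlap.

## Tunable parameters

All thresholds live in one `default_config()` list; defaults are the
study design's values.

| parameter | default | unit | role |
|---|---|---|---|
| `flank` | 100,000 | bp | half-width of each target region |
| `min_read_q`, `min_read_len` | 9, 500 | Phred, bp | read filter applied during sequencing; both boundaries inclusive on the keep side |
| `qual_min` | 9 | caller-native | per-call quality floor (stage 2) |
| `indel_min_len` | 10 | bp | indels kept only when **strictly** longer |
| `impact_pad` | 100 | bp | locus padding when matching annotation rows |
| `annotation_window` | 2,500 | bp | half-width of the functional-annotation window |
| `r2_threshold` | 0.8 | – | "high LD" with the lead SNP |
| `ld_max_gap` | 10,000 | bp | merge qualifying LD runs across gaps up to this size |
| `max_breakpoint_dist` | 500 | bp | INS/DEL breakpoint match distance |
| `min_reciprocal_overlap` | 0.5 | – | DEL–DEL reciprocal overlap floor |
| `genome_size` | declared | bp | off-target coverage denominator |

Two of these deserve comment. **Caller quality is not rescaled**: the four
callers score on different native scales, and the single threshold of 9 is
applied to each caller's own score, as a single-threshold design implies;
`qual_min` is the knob if a user wants per-caller values, and calls from
sources that emit no quality at all (STR locus tables) are exempt and
flagged `qual_exempt` rather than silently passed. **The off-target
coverage denominator is a declared genome size** minus the total target
length; there is no universally correct choice, and this one is stated
prominently because it scales the whole off-target coverage column.

## Read quality aggregation

Per-read quality is defined from the mean per-base error probability,
`Q = −10·log₁₀(p̄)`, and the per-sample average quality is computed by
averaging the per-read error probabilities first and converting the mean
to Phred — probability-space averaging, the platform convention for read
Q-scores. `sample_stats(..., qual_average = "phred")` switches to the
arithmetic mean of per-read Phred scores for users who prefer it; the two
differ by Jensen's inequality. Coverage is base-level: a read straddling a
region boundary contributes its inside bases to on-target coverage and
the remainder to off-target coverage, so aligned bases are conserved.

## Cross-caller clustering

No standard defines when two callers have reported "the same" variant.
The package uses single-linkage clustering under a class-compatibility
matrix: INS↔INS by breakpoint distance (≤ 500 bp), DEL↔DEL by breakpoint
distance **and** ≥ 50% reciprocal overlap, SNV↔SNV only at the exact
position with identical alleles, and repeat/TE loci matching any
length-change call that overlaps their span by ≥ 1 bp — because VCF-style
callers report repeat expansions/contractions as insertions or deletions
inside the repeat, and composite elements (e.g. SVA retrotransposons) as
insertions in their VNTR. These defaults follow common SV-merging
practice and are exposed as configuration.

Determinism matters for audits: calls are sorted by
(chrom, start, end, caller, sample) before linking, so the partition is
invariant to input order, and ties in locus labelling are broken by that
same order. Pathological chains (a locus spanning more than
`max_locus_span`) are split at their largest internal gap with a warning;
a chain with no positive gap cannot be split and is left intact. For up
to 20 calls the clustering is verified in the test suite against a
brute-force transitive closure of the pairwise predicate.

Genotypes reported as `./.` are kept as `unresolved`, not coerced to
homozygous reference (which is what some callers do when they cannot
resolve a genotype); unresolved calls still anchor a locus but do not by
themselves make a variant "present" in a sample. Presence follows the
union rule — any caller's non-reference genotype, or a human
BAM-inspection judgement supplied as an evidence table — with no majority
vote, because the design goal is presence/absence rather than consensus
genotype. BAM evidence is an input of human judgements; the package does
not re-derive it from alignments.

## The cascade and its audit

Stages run in a fixed order (region → quality → clustering → class →
impact/rsID → LD); configuration can disable but not reorder stages, which
keeps audit semantics simple — every stage reports `n_in`, `n_out`, and a
per-record exclusion reason, and `n_in = n_out + n_excluded` is a tested
invariant. Three design points:

* **Quarantine, not drop.** A locus with no annotation row is routed to a
  `needs_annotation` bin. Annotation tables come from external tools;
  their gaps should be visible, not silent.
* **Annotation matching pad.** Loci are padded by `impact_pad` (100 bp)
  before overlap with annotation rows. Callers jitter breakpoints; a
  point insertion reported 40 bp away from its annotated position would
  otherwise miss its own annotation row and be quarantined spuriously.
* **Lenient LD pass-through.** Regions with no declared LD blocks pass
  their loci through flagged `lenient_ld`. This mirrors the treatment of
  weak, non-coding GWAS signals where LD blocks cannot be confidently
  drawn; supplying a lower per-region `r2_threshold` is the alternative.

## LD from phased haplotypes

The LD module exists so stage 5 is testable hermetically: `r_squared()`
implements the standard composite measure on phased haplotypes
(`D = p_AB − p_A·p_B`; `r² = D²/(p_A(1−p_A)p_B(1−p_B))`), equal to the
squared Pearson correlation of the binary allele vectors (a tested
identity, to 1e−12). Monomorphic sites make r² undefined and return `NA`
with a warning — never 0, which would be a different claim. Blocks are
maximal runs of sites with `r² ≥ threshold` against the anchor, merged
across gaps of at most `ld_max_gap`, and span their member sites with no
padding. A run consisting of the anchor site alone is discarded: the
anchor is trivially in perfect LD with itself and such a "block" would
carry no information. Phasing is assumed (no EM estimation from
genotypes); the synthetic generator emits phase.

## Annotation windows and distances

Window hits are features intersecting the locus expanded by ±2.5 kb.
Signed distance is 0 iff the feature overlaps the locus; otherwise it is
the display-coordinate difference between the feature's nearest edge and
the nearest locus edge (positive downstream). Distance from the **edge**
rather than the midpoint is the convention of BED interval tools and is
conservative; `anchor = "midpoint"` is available since reported
variant-to-feature distances in the literature are sometimes
midpoint-anchored. The feature vocabulary is closed (enhancer, TFBS,
CTCF, eQTL, TSS, promoter, miRNA site, GWAS hit) with an `other`
catch-all so novel track labels degrade gracefully instead of failing.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces every input the pipeline consumes: regions,
truth variants with per-sample genotypes, per-caller observed calls, BAM
evidence, read summaries, impact tables, annotation tracks, and phased
haplotypes. Its defaults mirror the study conditions: 10 samples, 8
regions of 200 kb, a 120-variant truth set whose non-SNV fraction
(27/120 = 0.225) matches the published per-sample non-SNV frequency, 20
variants planted to satisfy every cascade criterion, on/off-target
coverages near 15×/3× with read lengths near 12 kb/3 kb and qualities
near Q22, and a 10% planted fraction of reads below the Q9/500 bp filter.
Caller noise profiles (per-class sensitivity, breakpoint jitter, genotype
discordance, unresolved genotypes, log-normal quality with a planted
sub-threshold fraction) emulate the observed discordance between calling
algorithms; `no_noise_profiles()` is the exact-recovery limit.

Two deliberate guarantees make planted-truth recovery a well-defined
test. First, a truth variant flagged `interesting` **is defined as**
satisfying all criteria, so the generator always emits at least one
cascade-passing call for it at exact coordinates (for repeat/TE truths, a
repeat-class call — a lone length-change observation could fall under the
indel-length cutoff); noise degrades the other observations. Second,
breakpoint jitter on indel observations is clamped (at `len/4` for
deletions) so that observations of one truth indel always satisfy the
merge predicate; without the clamp, rare large jitters would split one
true variant into two loci and "exactly 20 prioritised" would hold only
in probability. Non-interesting structural variants each carry exactly
one planted disqualifier (short indel, known rsID, sub-HIGH impact, or a
position outside the LD block), and regions 6–8 are generated without LD
cassettes to exercise the lenient pass-through.

The generator plants read *summaries*, not sequences: no signal
simulation, no basecalling error model, no alignment, no pore dynamics.
Off-target reads live in a compact declared genome (4.8 Mb against
1.6 Mb of targets) so that the planted 15×/3× coverages produce roughly
5×10⁴ reads per cohort — the scale at which coverage recovery is tested
to ±5%. Consequently, passing tests demonstrate the *pipeline's*
correctness on inputs with known truth; they say nothing about caller
accuracy on real signal-level data, about reference-genome artefacts in
repetitive regions, or about the true off-target coverage of a 3.1 Gb
genome.

## Numerical and formatting choices

* Report rounding is half-up at the printed precision (integer bp for
  lengths, 1 dp for quality/coverage, 2 dp for standard errors, 3 dp for
  the non-SNV fraction); `round_half_up()` is exported because R's
  `round()` rounds half to even.
* Cohort SEs use the sample standard deviation (n − 1) over samples;
  with fewer than two samples the SE is `NA` and flagged, never 0.
* Degenerate inputs are explicit: empty call sets flow through the whole
  cascade with an all-zero audit; zero-read scopes report `n_reads = 0`
  with `NA` means; `phred_from_error()` rejects probabilities outside
  (0, 1]; region construction rejects `pos ≤ flank` (coordinate
  underflow) and non-positive flanks; overlapping target regions warn
  but do not fail, since the tool should generalise beyond disjoint
  panels.

## Problem sizes used by the test suite

The suite exercises the default 10-sample/8-region cohort (~120 truth
variants, ~1,000 caller records) across multiple seeds, a 20-seed
cascade-invariant sweep, brute-force clustering oracles at ≤ 20 calls,
and one read-level bundle of ~5×10⁴ reads for enrichment recovery; these
sizes keep the full suite near a minute on one CPU while covering every
code path.

## Known limitations

* Cross-caller matching parameters are conventions, not ground truth;
  real merging tools disagree at the margins, and the defaults here are
  deliberately config-exposed.
* The quality filter compares caller-native scores against one threshold;
  callers with very differently scaled QUALs would need per-caller
  thresholds.
* LD blocks from small phased cohorts are noisy; the module is a
  hermetic stand-in for panel-based LD services, not a replacement.
* Impact/rsID annotations are consumed as input tables; the package does
  not compute functional consequences.
* The synthetic cohort cannot reproduce cohort-level variant counts of a
  real run (those depend on restricted raw data); it reproduces the
  *structure* of the analysis, with planted truth, at reduced scale.
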