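---
title: "Methods: NMD annotation, splicing quantification, and threshold somatic calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMD annotation, splicing quantification, and threshold somatic calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdmutscan)
```

This vignette documents the models and procedures the package implements,
the conventions and parameter choices behind them, what the synthetic-data
generators do and do not emulate, and the package's known limitations. The
scientific setting is the evaluation of recurrently reported *UPF1*
mutations in pancreatic adenosquamous carcinoma: whether they behave like
pathogenic drivers (functional consequences on NMD, driver-like allelic
fractions, absence from the population) or like standing germline
variation and passengers.

## Coordinate conventions

All genomic coordinates are **1-based, closed intervals**, the native
convention of R/Bioconductor containers (`GRanges`), GTF, SAM and VCF as
imported through `rtracklayer`, `Rsamtools` and `vcfR`. Transcript
("spliced") coordinates are 1-based offsets along the mature mRNA read
5'→3'. Junctions are identified by the genomic coordinates of their two
flanking exonic bases (`donor` = last base of the upstream exon in
transcript orientation, `acceptor` = first base of the downstream exon),
and deduplicated on `(chrom, donor, acceptor, strand)` because junction
read support is reported per junction.

## The 50-nt rule

A transcript is a predicted NMD substrate when its termination codon lies
more than 50 spliced nucleotides upstream of the last exon–exon junction.
Two details of this rule are underdetermined in the literature the package
follows, so they are fixed as documented conventions:

* **Distance endpoint.** `distance_nt` is measured from the **last base of
  the stop codon** to the last base before the final junction. The choice
  of endpoint shifts distances by two nucleotides; fixing it makes the
  boundary tests exact (50 nt → not a substrate, 51 nt → substrate, a
  strict inequality).
* **ORF choice.** An annotated CDS takes precedence; its genomic extent is
  treated as **including the termination codon** (GTF dialects that write
  separate `stop_codon` features are merged into the CDS extent by the
  reader). Without a CDS, and given a genome sequence, the ORF is the one
  starting at the 5'-most AUG of the spliced sequence and ending at the
  first in-frame stop. A transcript with no derivable ORF is reported with
  `status = "no_orf"` and `is_nmd_substrate = FALSE` — a flagged outcome,
  never a silent default.

Single-exon transcripts have no junction and are never substrates. The
correctness of the classifier is established against an independent
brute-force oracle in the test suite that spells out the spliced sequence
base by base, scans codons in a loop, and measures the distance directly;
the two agree on 1,000 random models including planted exact-boundary
cases.

## Junction enumeration and intron classes

Junction databases are built from **all co-linear donor/acceptor
combinations** within a gene — not only the junctions present in annotated
transcripts — so that diagnostic junctions of unannotated skipping
products (for example an exon-9→exon-12 junction diagnostic of a two-exon
deletion) exist in the database before any read supports them.

Intron class is assigned from the terminal dinucleotides in transcription
orientation: GT..AG → U2 (major spliceosome), AT..AC → U12 (minor),
anything else → `unknown`. The rare GC–AG class is deliberately classified
`unknown` and excluded downstream rather than folded into U2: downstream
burden summaries are restricted to U2-type introns to avoid confounding by
intron type, and a conservative exclusion is the safer reading of that
restriction.

## PSI estimation and the differential filter

An **informative read** is consistent with exactly one child isoform of an
event: all junctions it spans are junctions of that child and all its
aligned blocks lie in the child's exons. Reads compatible with several
children (e.g. contained in a shared exon) or with none are discarded.
PSI is a length-normalized count ratio,

$$\hat\Psi = \frac{r_i/p_i}{r_i/p_i + r_e/p_e},$$

where $p_i, p_e$ count the read-start positions that would produce an
informative read for each child (computed by brute force over the child's
spliced coordinates, given the read length). This deterministic point
estimator stands where a Bayesian isoform-quantification posterior would
sit in a larger pipeline; it is unbiased under the generator's sampling
model and recovers planted Ψ to within 0.03 at depth 200 in the tests.

The differential filter applies three criteria, all of which are reported
separately per event:

1. **Informative-read floor** (default 20). Whether the floor applies per
   sample or to the summed reads is not determined by the filter's usual
   one-line description; the package defaults to the **strictest reading
   (every sample)** because it is deterministic and conservative, and
   exposes `min_reads_scope = "total"` for the lenient reading. Events
   failing the floor are excluded *before* testing (`p_value = NA`).
2. **Effect size**: |ΔΨ| ≥ 0.10 (inclusive; compared with a 10⁻⁹ epsilon
   so the boundary case passes despite floating-point representation) *or*
   an isoform-expression fold change ≥ 2. The fold-change criterion is
   attested in two conflicting forms — linear ("absolute fold-change ≥ 2")
   and log ("absolute log fold-change ≥ 2") — so both are implemented:
   `fc_scale = "linear"` (default, the Methods-style wording) and
   `fc_scale = "log2"`.
3. **p ≤ 0.05** from a two-sided t-test on per-replicate Ψ. Student's
   pooled-variance form is the default (the conventional reading of
   "two-sided t-test"); Welch is available via `t_variant = "welch"`. Raw
   p-values are used throughout — the filter is a screening criterion, and
   **no multiplicity correction is applied anywhere by design**; the null
   calibration test verifies the raw false-positive rate is nominal
   (0.05 ± 0.02 over 2,000 null events).

Burden summaries join results to NMD-relevant, U2-only events and count
each significant event once, oriented by the NMD-substrate child: if the
substrate is the inclusion isoform, ΔΨ > 0 counts as `nmd_up`, and
vice versa.

## Threshold somatic calling

The caller reproduces deliberately permissive reanalysis criteria
literally: an alternate allele is called at depth ≥ 9 with ≥ 2 supporting
reads; a tumor call is somatic when the same position/allele is **not
called in the patient-matched normal under identical thresholds**. Fixed
conventions:

* **No base-quality filter by default** (`min_baseq = 0`): the published
  criteria specify counts only. A filter is available but off.
* Reads whose deletions or alignment gaps span a site contribute neither
  depth nor alternate support there; depth is the sum of A/C/G/T base
  counts.
* Reads flagged as duplicates are excluded when duplicate marks exist in
  the input; unmarked inputs count every read. Input-driven behavior keeps
  reruns reproducible.
* **No minimum normal depth is imposed** when asserting absence — the
  literal symmetric rule — but normals below the depth threshold flag the
  call `low_coverage` rather than vetoing it, so such calls are auditable.
* SNVs only; indels and structural events are out of scope.

Threshold choice is validated by **positive-control calibration**: with a
known hotspot driver (*KRAS* G12/G13) present in every tumor, the
thresholds must call a control-site variant in every sample
(`calibrate_sensitivity()`), which is exactly how the permissive values
were justified in the first place. Monotonicity (raising either threshold
never adds calls) and the exact decision boundary (9/2 calls; 8/2 and 9/1
do not) are asserted in the tests.

## Catalog overlap

Matching is by genomic key `(chrom, pos, ref, alt)`; HGVS-style labels
such as `IVS10+31G>A` are carried as opaque strings because intron-offset
parsing is unnecessary when coordinates are present. Three refinements
avoid silently misleading summaries:

* a mutation whose *reported alternate allele equals the reference base*
  (detectable when a reference genome is supplied) is flagged
  `in_reference` — such an entry cannot be a genuine somatic change and
  would otherwise inflate the "unmatched" count; an exact catalog match
  still takes precedence so mutation-level overlap fractions count it as
  matched;
* a catalog allele at the same position with a different base gives
  `position_only`, reported separately from `exact_allele`;
* allele frequency is ignored by default (presence in the population is
  the question); `min_af` optionally restricts matches to common variants.

Per-patient summaries flag patients with ≥ 1 exact match;
context-stratified summaries separate intronic from exonic mutations.

## Synthetic-data generators

Every generator is deterministic under a fixed seed (byte-identical
output) and returns a machine-readable truth table, so each downstream
stage is tested against known ground truth:

* `sim_transcripts()` builds transcript models **mRNA-first**: an
  ATG-free 5' UTR, a start codon, stop-free codons, and a termination
  codon placed at a *chosen* spliced distance from the last junction —
  including exact 50/51-nt boundary cases — then lays the mRNA onto a
  contig with canonical GT..AG introns (mirrored for minus-strand genes).
  NMD truth is therefore fixed by construction, independent of the
  classifier.
* `sim_splicing_events()` emits two-isoform events of all five classes
  (SE, RI, A5SS, A3SS, MXE) with per-child CDS placement controlling which
  child is the NMD substrate.
* `sim_event_counts()` draws informative reads binomially with inclusion
  probability implied by the true Ψ and the informative-position lengths —
  the exact inverse of the PSI estimator.
* `sim_locus_sam()`/`sim_tumor_normal_pair()` tile 50-nt reads (uniform
  random starts) at a target mean depth over toy loci standing in for the
  *UPF1*/*KRAS* regions; each read covering a planted variant carries the
  alternate with probability `vaf`, so allele counts are Binomial(coverage,
  VAF). Germline plants go into both samples, somatic plants into the
  tumor only. Sequencing error is **off by default** — the calling
  thresholds are the object under test — with an optional per-base
  substitution rate for stress-testing the ≥ 2-read criterion.
* `sim_variant_catalog()` engineers a catalog VCF so that an exact,
  pre-chosen subset of mutations is matched (overlap fraction by
  construction), with optional position-only entries and unrelated
  padding.

What the generators do **not** emulate: realistic base-quality and error
profiles, fragment-length and GC biases, alignment artifacts, multi-gene
interval structure, or the actual hg19 *UPF1*/*KRAS* sequences. Passing
tests therefore demonstrate that the implementations compute their defined
quantities correctly under the stated sampling models — not that the
thresholds are robust to real-data artifacts the upstream aligner and
trimming handle.

## Study conditions and problem sizes

The test and acceptance workloads mirror the analysis's operating points:
cohort counts 0/34 vs 18/23; calling thresholds 9/2; differential filter
(20 reads, 10 %, 2-fold, p ≤ 0.05) at 3 vs 3 replicates and 200
informative reads; 1,000 random transcript models for the 50-nt-rule
concordance; 200 simulated tumor–normal pairs (somatic VAF 0.2–0.6,
planted at locus-interior positions so realized depth honors the
depth ≥ 30 condition) for somatic recovery; passenger-like VAF 0.12 vs driver-like
0.34 plants (depth ≈ 60, 60 patients) for the median-VAF contrast; 2,000
null events for p-value calibration; and a 40-mutation / 18-patient
roster with 18 engineered exact matches covering 16 patients for the
overlap analysis. These sizes were chosen to give stable statistics at
desk scale.

## Statistical conventions and degenerate inputs

* "Binomial proportion test" is implemented as the **pooled two-proportion
  z-test without continuity correction**, with Fisher's exact test as the
  alternative; the headline cohort comparison is significant below 10⁻⁸
  under both, so nothing rests on the variant choice. Degenerate tables
  with zero pooled variance (k₁ = k₂ = 0 or both complete) return p = 1.
* Mann–Whitney U uses the exact null distribution for combined n ≤ 20
  without ties and the tie-corrected normal approximation otherwise.
* The t-test returns p = 1 when both samples are constant with equal
  means and p = 0 when constant with unequal means, rather than erroring
  on zero variance — sensible continuations for screening over thousands
  of events.
* Events with undefined Ψ (zero informative reads) in a replicate, or
  fewer than two defined-Ψ replicates per group, are excluded with an
  explicit `reason`, never silently dropped.

## Limitations

* The PSI estimator is a point estimate; no posterior uncertainty is
  propagated into the t-test beyond replicate variability.
* The caller has no genotype-likelihood model; it is a faithful
  reimplementation of literal count thresholds, and inherits their
  blindness to strand bias, mapping quality, and indel-adjacent artifacts.
* Catalog matching assumes both inputs share an assembly; no liftover is
  performed.
* The package consumes aligned SAM; trimming and alignment (and any manual
  IGV-style review) are upstream and out of scope.
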