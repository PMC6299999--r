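---
title: "Targeted tandem repeat genotyping from long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted tandem repeat genotyping from long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replong)
```

## The problem

Tandem repeats — head-to-tail arrays of a 1–50 bp unit — mutate orders of
magnitude faster than unique sequence, yet they are nearly invisible to
short-read sequencing: a 150–200 bp read rarely spans a repeat together with
enough unique flank to place it, so repeat expansions can hide in families
whose disease has resisted exome- and array-based analysis. The approach
implemented here targets that blind spot on the X chromosome: select
candidate repeats from a reference catalogue, capture them by hybridisation
with probes anchored in the unique flanks, sequence the captured 800–1000 bp
fragments with circular-consensus long reads, and measure each allele as the
distance between the two 20 bp flanking sequences inside a single read.
Candidate disease loci are then filtered through an X-linked pedigree
(affected/unaffected discordance, family segregation, cross-family
uniqueness) and a male control population, and a nearby gene's expression
can be ranked for deregulation in the patient.

`replong` implements the full pipeline as composable R functions, plus a
synthetic-data generator that emulates the capture + consensus-read design
so every stage is testable without any external data.

## Repeat discovery and the variability score

`find_tandem_repeats()` scans a sequence per unit size u by comparing the
sequence against itself at lag u. Each agreeing position scores +1 and each
disagreement −k (default k = 3). The candidate tracts for unit u are the
all-maximal-scoring subsequences of that score vector (Ruzzo–Tompa); this
makes "maximal" precise: a tract cannot be extended in either direction
without dropping its score, and tracts interrupted by isolated mismatches
merge exactly when the merged score beats the parts. The consensus unit is
the per-phase majority base (alphabetical tie-break), and purity is the
percentage of positions matching the best cyclic phase of a perfect unit
tiling (`compute_purity()`). N bases count as mismatches and as non-GC.
Overlapping candidates from different unit sizes are resolved
deterministically: highest score, then smallest unit, then leftmost.

Predicted variability is scored by a pluggable linear form in unit length,
log2 copy number and purity (`score_variability()`,
`serv_coefficients()`). The exact coefficients of the published variability
score are not reproduced here; the shipped defaults (intercept −1, 0.4 per
log2 copy, 1.0 per purity fraction, −0.05 per unit base) are chosen so that
long pure dinucleotide arrays land in the 1–3 "highly variable" band used
for genotyping-grade repeats, and they are overridable. The selection tiers
(`select_targets()`) apply threshold columns only — coding repeats ≤ 500 bp;
regulatory repeats with score ≥ 1 and ≤ 500 bp; regulatory repeats with
score in (0.4, 1); regulatory repeats within 1 kb of a disease-gene list;
then intronic (score > 0.8) and intergenic (score > 1) repeats with ≥ 15
copies, unit ≥ 2 bp, span ≤ 500 bp, GC 30–70% and ≥ 3 probes, thinned evenly
along the chromosome by a one-per-bin, round-robin-fill rule.

## Probe design

Each target gets up to four probe types (`generate_probes()`): left flank
(ending exactly at the repeat start), right flank, a spanning probe centred
on the repeat midpoint, and a double probe concatenating half-length
segments of both flanks. The uniqueness screen (`uniqueness_screen()`)
re-expresses a short-read-aligner screening recipe without the external
aligner: a genomic hit is any window on either strand with at most 3
substitutions in the probe's first 15 bases and at most 6 substitutions
overall; indels are not modelled. A probe is unique with exactly one hit
(its own locus), cluster-specific when all extra hits fall inside declared
duplication clusters, ambiguous otherwise. Failed flank/double probes are
rescued by shifting outward up to 500 bp (`shift_and_rescue()`): a 10 bp
coarse scan followed by 1 bp refinement returns the most proximal passing
shift. Probes with GC below 40% or above 70% are replicated fourfold
(`replicate_probes()`, strict inequalities); everything else keeps the base
replication.

## Read preparation

Reads arrive with 32-base adaptors on both ends; `trim_adaptors()` removes
them and drops reads of ≤ 64 bases. `align_to_windows()` assigns each read
its best local affine-gap placement among the target windows (target
± 1000 bp), with candidates prefiltered by shared 13-mers in both
orientations; the DP engine is `Biostrings::pairwiseAlignment` (match +1,
mismatch −3, gap open 5, gap extend 2, minimum score 30). Duplicate
placements — identical (chrom, start, end, strand) — collapse to the
highest-scoring read (`remove_duplicates()`).

`yield_summary()` reports the nested categories used to judge a run: total,
unmapped, within 1000 bases of a target, intersecting, spanning, and
"useful" (spanning with ≥ 20 bases of both flanks). A soft-clipped read
whose alignment covers one flank while its clipped tail re-matches the
opposite flank (≥ 20 bases, ≤ 10% mismatches) counts as spanning and
useful — that is what an allele too diverged for a contiguous alignment
looks like. Counting rescued reads in both categories keeps the chain
useful ⊆ spanning ⊆ intersecting ⊆ within-1000 ⊆ mapped exact by
construction.

## Flank-anchored genotyping

`build_locus_library()` records the 20 reference bases on each side of a
repeat (a truncated flank down to 12 bases is tolerated at contig edges).
`call_alleles()` finds both flanks in each read with up to ⌈0.1 · flank
length⌉ substitutions (no indels — indel-bearing flanks are the soft-clip
rescue's job), trying the reverse complement when the forward orientation
finds fewer flanks, and reports every call in reference orientation:

* both flanks found → a *spanning* call; allele length = distance between
  the flank inner edges. With multiple placements the outermost pair is
  used and the call flagged.
* one flank found → a *partial* call; the distance from the flank inner
  edge to the read end is a lower bound on the allele length.

`genotype_locus()` takes the modal spanning length (ties broken toward the
longer allele and flagged — a deliberate, conservative choice), pools calls
within ± 1 unit as stutter, and emits a genotype only at pooled support ≥ 5,
matching the 5× coverage floor used for reliable loci. The allele sequence
reported is the column-majority consensus of the modal-length reads, which
is what makes compound decomposition robust at a 1% per-base error rate. A
diploid mode calls up to two modes with a minor-allele fraction floor
(default 0.2), an explicit stand-in where the source material is silent;
males on the X are hemizygous and get exactly one allele.

`detect_expansion()` flags a locus when *no* read spans it and at least one
partial call implies more copies than the reference: the allele then
exceeds the captured fragment length and only its lower bound is
measurable. For a 26 bp unit with 15 reference copies (390 bp), partial
reads bounding 24–35 copies imply an allele of at least 910 bp — an
expansion detectable even though no fragment contains it. The complementary
constraint is instrument-side: a consensus read needs ≥ 6 passes, so 15 kb
polymerase reads cap measurable repeats at about 2.5 kb
(`max_measurable_repeat()`).

`decompose_compound()` parses a compound allele (motif₁)ᵃ separator
(motif₂)ᵇ greedily left to right; a mismatching residue ends a run, and a
missing separator falls back to the single-motif count with a warning.
Copy numbers are reported as reals (2 decimals); only decomposition uses
integers.

## The filtering cascade

`candidate_report()` runs the per-locus cascade and records one terminal
stage each: `outside_interval` (no overlap with the linkage intervals),
`concordant` (sequenced affected and unaffected males agree within one
unit), `non_segregating` (the proband allele fails the X-linked model:
every affected male must carry it, no unaffected male may, carrier females
must be heterozygous for it), `shared_across_families`,
`found_in_controls`, or `candidate`. Loci whose segregation cannot be
evaluated because a member genotype is missing stop at `non_segregating`
with the audit column reading "unevaluable" — the stage vocabulary stays
closed while the not-failed status remains visible.

Allele comparisons run at the finest resolution both sides share:
sub-repeat copy numbers for compound alleles with decompositions, total
length in bp otherwise (with an optional ± tolerance for
fragment-analysis-scale inputs, where instruments round lengths). This
matters: a (CT)₂₁TTT(GT)₃₃ allele of 111 bp collides with (CT)₁₇(GT)₃₇ and
(CT)₂₀(GT)₃₄ at total length, and only the sub-repeat comparison
(`control_screen(compare = "sub_repeat")`) resolves it — the deciding
observation of the case study this pipeline reproduces. The cascade is
monotone by construction: more controls can only shrink the candidate set,
and additional family members can break but never restore segregation.

Linkage intervals are inputs; LOD computation is an external concern.

## Expression deregulation

The ranking statistic is R = \|P − C\| / (C<sub>max</sub> −
C<sub>min</sub>): the distance from the patient value to the *closest*
control, in units of the control range (`deregulation_ratio()`). R is zero
iff the patient sits on a control value, scale- and shift-invariant, and
undefined (NA with a warning, never infinity) when the controls have zero
range. `rank_deregulated()` sorts genes by R with stable ties; upstream
differential-expression flags are consumed as an input column, not
recomputed. `target_enrichment()` compares the predicted-target proportion
of a deregulated gene set against an expected background rate with an exact
one-sided binomial test — the test choice is this package's, since only the
two percentages are given in the source material; 21 targets among 31
brain-expressed deregulated genes give 68% against an expected 30%
(p < 0.001). `relative_expression()` implements ΔΔCt with one or more
endogenous control genes, normalising each replicate's target Ct against
the arithmetic mean of the control Cts (equivalently, the geometric mean of
their linear expression) and reporting fold = 2^−ΔΔCt with a per-sample SD
over replicates.

## What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions: a reference chromosome with five
planted repeats (one compound (CT)ₙTTT(GT)ₘ causal locus placed 65 bp
downstream of a microRNA-like gene, one high-GC locus, three moderate
ones), an X-linked three-family pedigree (three affected males, two
unaffected, two carriers per family), normal allele pools of 11–20 CT and
24–37 GT copies with the proband expanded to 21 CT copies — one copy beyond
the entire pool — a 100-male control pool, 800–1000 bp fragments, 1%
residual substitution error, 0.05 per-read stutter probability (± 1 unit),
a ≥ 6-pass requirement against 15 kb log-normal polymerase reads, and a
logistic GC→capture-recovery curve with midpoint 0.70 and floor 0.30 (so
moderate-GC loci are recovered at ~99% and GC-rich ones near 30%,
reproducing the qualitative capture behaviour). Planted tracts carry
tiling-breaking guard bases so the truth coordinates are exactly maximal.

Haplotype structure is the important modelling choice: affected males share
the founder disease haplotype at *all* linked loci, so neutral linked
repeats segregate perfectly too — exactly why control screening, not
segregation, is the decisive filter. Fragments are placed to contain the
repeat with both flanks whenever their length allows, emulating what
flank-anchored capture enriches; alleles longer than the fragment can only
be covered partially.

Deliberate simplifications: substitution-only errors (no homopolymer or
indel model), no chimeric fragments, no bait thermodynamics, stutter
limited to ± 1 unit, and reads simulated only for hemizygous males (the
sequenced affected/unaffected pair; everyone else is compared at
fragment-analysis scale, mirroring the real workflow). Passing tests
therefore demonstrate the pipeline's logic under CCS-like residual error,
not robustness to raw-read indel noise.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; printed tables are 1-based
  inclusive (`coords_one_to_zero()`; chrX:45,606,270–45,606,355 spans 86 bp
  = 43 dinucleotide copies).
* Repeat-scan ties: overlapping calls resolve by score, then unit size,
  then position; equal-scoring adjacent segments do not merge.
* Flank matching tolerates ⌈10%⌉ substitutions; 3 mismatches in a 20-base
  flank is a non-match.
* Modal ties break toward the longer allele and are flagged.
* Zero informative reads, empty control tables, zero-range controls, and
  missing separators each produce an explicit no-call/error/warning rather
  than a silent number.
* The closest-control tie in R takes the larger control value (documented,
  arbitrary; R itself is unaffected).

## Problem sizes used in the shipped checks

The test-suite and the reproduction script run at desk scale, chosen so the
full suite completes in minutes on one core: oracle comparisons on
sequences of a few hundred bases, yield checks on 60–200 reads, noiseless
and noisy (1% error, 0.05 stutter, coverage 10) genotyping over 5 loci × 2
samples × ~10 replicates, and 100 seeded pedigree replicates with 50
controls for the sole-candidate recovery rate. Real studies are larger in
every dimension; nothing in the implementation depends on these sizes.

## Known limitations

* The uniqueness screen models substitutions only; a probe unique up to
  indels may be called ambiguous (conservative).
* The aligner searches target windows, not the whole genome: off-target
  reads are reported unmapped rather than placed elsewhere.
* The variability score is a stand-in with documented defaults, not the
  published regression; selections driven by score thresholds will differ
  from the original catalogue's counts.
* Diploid genotyping thresholds are explicit stand-ins; the hemizygous path
  is the validated one.
* `cross_family_unique()` compares carrier second alleles at bp resolution
  when no decomposition is available, which can over-reject in pedigrees
  rich in equal-length compound alleles.
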