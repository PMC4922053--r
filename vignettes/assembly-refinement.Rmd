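---
title: "Assembly refinement methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly refinement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(asmrefine)
```

This vignette is the package's own account of the science behind each
module: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not show
about real data.

## The problem

Highly heterozygous genomes defeat whole-genome shotgun assemblers: when
the two alleles of a locus diverge by a percent or more, the assembler
resolves them into two separate contigs ("uncollapsed haplotypes"),
inflating the assembly well past the haploid genome size. One remedy is
hierarchical sequencing — pools of large-insert clones (fosmids,
~36–40 kb) are sequenced and assembled separately, so that most loci are
seen in a single haplotype per pool — followed by several rounds of
merging, misassembly detection, deduplication, and polishing. This
package implements that downstream refinement stack.

## K-mer spectrum profiling

A k-mer spectrum is the histogram of how many distinct k-mer species
occur at each multiplicity in a read set. For a diploid sample sequenced
at k-mer depth *d*, k-mers spanning homozygous sequence peak at *d*
while k-mers overlapping a heterozygous site occur on only one haplotype
and peak near *d/2*. Sequencing errors produce a mass of low-multiplicity
species at the far left.

* **Counting.** Canonical k-mers (the lexicographic minimum of a k-mer
  and its reverse complement) are counted with a rolling 2-bit encoding
  in C++; k must be odd and at most 31 so a k-mer fits one machine word
  and is never its own reverse complement. K-mers containing non-ACGT
  bases are skipped. Counting is in-memory, which is appropriate at the
  package's desk scale (tens of megabases of reads); disk-based counting
  is out of scope.
* **Peak calling.** The histogram is smoothed with a centred moving
  average of window 3 — enough to stabilise sparse histograms without
  shifting well-separated peaks. The error cutoff is the first local
  minimum above depth 1, falling back to `min_depth = 3` for histograms
  with no error mass. The homozygous peak is the global mode above the
  cutoff, with one correction: in highly heterozygous samples the
  heterozygous peak can out-mass the homozygous one, so when another
  local maximum of at least a quarter of the mode's height sits at about
  twice the mode, the doubled depth is taken as the homozygous peak.
  (The cost of this correction is that a strong two-copy-repeat shoulder
  could in principle be mistaken for the homozygous peak; on spectra
  where the repeat tail is a monotone tail rather than a discrete bump
  it does not trigger.) A heterozygous peak is reported only when a
  local maximum exists within [0.35, 0.65] of the homozygous depth.
* **Genome size.** The total/peak estimator divides the total number of
  counted k-mer instances by the homozygous peak depth. It is exact for
  error-free uniform coverage and scale-equivariant by construction;
  tests verify recovery within 5% on simulated reads. Note the estimator
  returns full-precision values; rounding is presentation.
* **Heterozygosity.** The published analysis used a dedicated
  likelihood-based tool whose exact model is out of scope here; this
  package fits a deliberately simple approximation — two Gaussian
  components with means pinned at the detected het/hom depths and free
  masses and widths, least-squares on the histogram above the error
  cutoff. The heterozygosity proxy is the het component's share of the
  fitted species mass, and the corrected genome size counts
  het-component k-mer instances at half weight (two species per locus).
  On simulated diploid data the proxy lands within a factor of two of
  exact haplotype k-mer enumeration, which is the honest precision claim
  for this approximation.
* **C-value conversion** uses 1 pg = 978 Mbp.

## Insert-size statistics

Insert sizes are estimated from same-scaffold pairs in the expected
orientation (FR for paired-end, RF for mate-pair — configurable, since
junction-based mate-pair protocols can deliver either after trimming).
The insert is the outer distance `max(end) − min(pos)`. Because mismapped
pairs produce heavy tails, the mean and standard deviation are computed
after trimming 1% from each side; the consistency bounds are
`mu ± 3 sigma`. All coordinates in the package are 0-based half-open;
SAM input (1-based) is converted at the boundary by `read_sam_records()`.

Libraries whose fragment distribution is bimodal (a main mode plus a
short-insert contaminant mode) are handled in two steps. `detect_modes()`
finds smoothed-histogram local maxima, calling a minor mode only when it
is separated from the main mode by at least 25% of the main-mode
location and holds at least 5% of the mass (the mass floor keeps tail
noise from being called a mode). `filter_short_insert_pairs()` removes a
pair when a third read's alignment overlaps both of its mate intervals
by at least `min_overlap_bp` (default 10) — geometrically possible only
for short inserts. The overlap is coordinate-based, not sequence-based:
the filter runs after mapping and should not depend on the mapper's gap
conventions. The amount of overlap a connecting read needs is not fixed
by any published convention, so it is exposed as configuration.

`dedup_length_spectrum()` recovers a clone-length distribution from
extremely redundant observations (e.g. fosmid-end mappings at hundreds
of reads per clone): a length enters the deduplicated spectrum with
weight one only if observed at least `min_count` times (default 100).
This underestimates density amplitudes but leaves the mean essentially
unbiased, while the standard deviation tends to be overestimated.

## Read-pair consistency checking

Each pair votes on the assembly. A pair is *consistent* when both mates
map to the same scaffold, in the expected orientation, with an insert
inside `[mu − 3 sigma, mu + 3 sigma]`; it adds +1 to the consistent
vector *C* over its full span. Any other pair is *inconsistent*. The
published description assigns negative score to "regions" without
defining their extent; this package's localisation rule — each mate of
an inconsistent pair adds +1 to *I* over the interval extending
`mu + 3 sigma` bp from its alignment in the direction its mate should
lie — is our own choice, and places the blame where the missing evidence
should have been. Cross-scaffold pairs whose two mates both point toward
a scaffold end within `end_slack` (default: the upper insert bound) are
ignored, because that is exactly what correct scaffolding gaps look
like; a single mate near an end still counts, so misjoins near ends
remain detectable.

`break_assembly()` excises maximal runs where `N = C − I < 0` of length
at least `min_region` (default 50 bp, suppressing single-base flicker),
drops retained blocks shorter than 200 bp, and names the remaining
blocks `<scaffold>_partN`. Excision (rather than point-breaking) mirrors
the removal of unsupported sequence. Scores are unweighted (+1/−1): the
procedure is a simple majority of evidence, and profiles from several
libraries can be summed with `combine_profiles()`.

The test suite validates the pipeline end to end on a 1 Mb genome with
20 injected cut-and-swap misjoins and 30x spanning pairs: at least 90%
of truth junctions must fall inside an excised region (junction
containment is tested with a ±200 bp slack, since excision boundaries
are resolution-limited by the insert size), and a clean control assembly
must yield zero breaks.

## Overlap-based assembly merging

Overlap candidates come from shared window minimizers (canonical k-mer
hashes, k = 15, window 10, scrambled with a 64-bit mixer so minima are
not biased toward poly-A; minimizers occurring at more than 200
positions are dropped as repeat seeds). For each candidate pair the
diagonal (offset of one contig within the other) is estimated as the
median of the densest ±100 bp cluster of minimizer offsets, requiring at
least 3 clustered hits; the implied overlap region is then verified with
a banded global edit-distance alignment (band scaled to the divergence
cap, widened once and the candidate rejected if the optimum still
escapes). Identical substrings short-circuit the alignment. Overlaps are
accepted when the length reaches `min_overlap` and the edit distance
over the overlap length (our reading of the "edit distance percent"
criterion) is at most `max_divergence`. The default two-round schedule
is 2,400 bp at 1.5% followed by 4,000 bp at 10% — a stringent round that
merges near-identical sequence, then a laxer round that merges allelic
variants.

Merging itself is a string graph: oriented contig nodes, dovetail edges
with reverse-complement twins, containment absorption (ties on equal
length broken toward the lexicographically smaller name, for
determinism), and transitive-edge removal. The reduction is path-based:
an edge is redundant when its target is reachable through other
out-neighbours with matching accumulated extension (±200 bp fuzz), which
also removes multi-hop transitive edges so that chains interrupted by a
sub-threshold overlap do not masquerade as branches. Unitigs extend
through a branch only when the scaffold link set (contig adjacencies
carried over from the input assemblies) supports exactly one outgoing
branch; otherwise the walk stops and the repeat stays collapsed as a
single copy. Across each merged overlap the longer contig's bases are
kept — the merge is assembly reconciliation, not base-level polishing.
`tip_merge()` absorbs dead-end contigs (at most one overlap neighbour)
into longer paths down to 250 bp overlaps; interior nodes are never
modified. `collapse_haplotypes()` is the same machinery run against an
assembly's self-overlaps at 4 kb / 3% divergence (a single divergence
cap standing in for the original mapper's separate error and mismatch
rates, which have no meaning outside that mapper), so only close matches
— uncollapsed haplotypes, duplicated artifacts, near-identical repeats —
merge, and total length never increases. The intermediate scaffolding
and gap-filling that external tools performed between merge rounds is
reduced to a link-reinsertion step: links whose endpoints survive as
output sequences with their relative orientation preserved are rejoined
with N-gaps (minimum 10 N).

Tests reconstruct a 500 kb genome from 96 simulated mini-pool
assemblies (576 contigs, ~14x tiling redundancy), requiring the merged
length within 10% of truth and N50 at least three times the input mean,
and verify idempotence, self-merge identity, and agreement of
`find_overlaps()` with an independent ends-free full-DP alignment oracle
on 16 contigs of up to 4.5 kb (within the suite's ≤50 × ≤5 kb oracle
budget).

## Screening and read partitioning

Masking replaces contaminant hit intervals (unioned) with Ns, preserving
coordinates. Whole-scaffold deletion triggers when hits cover at least
`drop_fraction` of the scaffold (default 0.5 — the published pipeline
reports outcomes, not its threshold, so this is configuration) or when
mean depth reaches ~6,000x together with an organelle-class hit
(organelles are sequenced orders of magnitude above the nuclear depth).
Terminal hit regions are excised, interior ones masked. Exploding
scaffolds splits at N-runs of any length, erodes 50 bp from each contig
end, and drops contigs under 200 bp. "Reads that did not map" is
interpreted as pairs with both mates unmapped; reads whose mate mapped
are preserved separately as singletons rather than discarded. Read
recruitment passes a mate if it is mapped with a clipped fraction (soft
plus hard clips over the full read length, hard clips counted because
they also represent unaligned read sequence) at most 1/3, and emits a
pair only when both mates pass. The unique-mapping filter keeps records
whose second-best score is absent or at least `margin` (default 1) below
the best, so ties are never unique; without score tags it falls back to
a mapping-quality threshold with a warning.

## Polishing

Only PASS (or unfiltered) homozygous-alternative genotypes are applied:
heterozygous calls would force an arbitrary allele choice, and half
calls are conservatively treated as heterozygous. Multiallelic records
keep the genotype-selected allele. Application is left-to-right per
scaffold with reference-allele verification (mismatches are rejected and
reported, not fatal) and a deterministic leftmost-wins rule for
overlapping records. A round-trip test mutates a genome at 500 sites,
applies the variants, and requires the positional diff against the
original to equal the applied set exactly.

## The simulator and what it does (and does not) emulate

The generators define the study conditions used throughout the tests:

* diploid genomes with substitution-only heterozygosity (default
  emulation of a high-heterozygosity sample; indel heterozygosity is
  deliberately excluded so truth coordinates stay alignable),
  optional duplicated-segment repeat families, and exact truth tables;
* fosmid pools of 1,600 clones with truncated-Normal lengths
  (36.7 kb ± 4.97 kb, the fosmid-end estimate) on a 1.38 Gb genome;
  overlap statistics are computed by endpoint sweeps, never per-base
  arrays, so paper-scale pools run in milliseconds. Because published
  wording does not fix whether re-sequenced bases are counted once or
  per clone, both `overlapped_base_fraction` (clone bases at depth ≥2)
  and `redundant_base_fraction` (the (k−1)/k counting) are reported; at
  the paper's scale they evaluate to ≈4.2% and ≈2.1%, bracketing the
  published "mean of 2.5%", with half of overlapped positions carrying
  both alleles, and both converge to their Lander–Waterman closed forms
  (`1 − exp(−c)` and `1 − (1 − exp(−c))/c` with `c = nL/G`);
* paired reads with a main Normal insert component plus an optional
  short-insert contaminant mode (emulating the bimodal 725 bp / 300 bp
  library structure), FR or RF orientation, uniform substitution
  errors, and truth alignments emitted alongside;
* misjoin injection by cut-and-swap between scaffolds with exact
  junction truth and a block map for lifting read coordinates into the
  misjoined assembly (mates straddling a block boundary are dropped, as
  their real-world alignments would be clipped).

What passing these tests does *not* show about real data: no coverage
biases, chimeric pairs, PCR duplicates, quality-dependent errors,
structural variation, or cloning bias are simulated, and repeats are
simple duplications rather than nested families. The simulator
establishes correctness of the algorithms under their stated models, not
robustness to every artifact of real libraries.

All generators are deterministic under a fixed seed.

## Duplication diagnostics

Reciprocal best hits require mutual unique top bitscores; ties form no
pair and are surfaced in a tie list for audit. "More similar to each
other than to the best cross-species hit" is evaluated on bitscores
(identity is available as configuration) with a strict inequality, and
genes lacking any cross-species hit leave the denominator. Quantiles are
nearest-rank. Welch's statistic is
`t = (m1 − m2) / sqrt(s1²/n1 + s2²/n2)` with Welch–Satterthwaite degrees
of freedom (delegated to `stats::t.test`). The genome-wide published
counts (34,195 closer-paralog genes; 14,437 RBH pairs; 10,711 shared
best hits) depend on external proteome databases, so the package
exercises them as printed-count worked examples through the same code
paths rather than recomputing them from sequence. The logic of the
SNV-count contrast — genes duplicated in the genome but collapsed in the
assembly accumulate excess heterozygous SNVs, while uncollapsed
haplotypes show the opposite — is validated in simulation by
constructing the artifact case and observing the reversed sign.

## Problem sizes and runtime

The test suite runs the full stack at reduced but structurally faithful
scales, chosen so the whole suite completes in a couple of minutes on
one core: 50–100 kb genomes for spectrum and polishing tests, a 1 Mb
genome with 20 misjoins and ~41,000 pairs for the consistency check,
576 contigs tiling 500 kb for the merge, and 50 pools at the full
1.38 Gb / 1,600-clone design for the sweep-based pool statistics (the
sweep makes full scale cheaper than any per-base shortcut).

## Known limitations

* The overlap finder's divergence estimate depends on the minimizer
  diagonal; for overlaps with large indel offsets the banded alignment
  can reject a true overlap (it widens the band once before giving up).
* `estimate_het_ratio()` is a two-Gaussian approximation; it is
  accurate to a factor of ~2, not a replacement for likelihood-based
  spectrum models.
* The consistency check consumes alignments; it does not re-map reads,
  and its inconsistent-evidence localisation is a modelling choice (see
  above), so breakpoint boundaries are insert-size-resolution estimates.
* Merging keeps the longer contig's bases across an overlap; no
  base-level consensus is attempted at merge time (polishing handles
  base errors downstream).
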