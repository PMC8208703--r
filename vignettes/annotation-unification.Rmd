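---
title: "Unifying bacterial annotation resources into a transcript and operon atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unifying bacterial annotation resources into a transcript and operon atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonatlas)
library(dplyr)
```

## The problem

A bacterial genome like that of *Bacillus subtilis* is described by
several annotation resources at once: a reference gene annotation,
curated databases of promoters, terminators and operon gene lists, a
tiling-array transcriptome study with thousands of coarse predictions,
term-seq riboswitch calls, and covariance-model scans for structured
RNAs. Each resource is partial, they disagree in coordinates, and none
annotates complete transcripts with their untranslated regions (UTRs).
`operonatlas` implements the integration procedure that turns these
heterogeneous inputs into one non-redundant atlas: merged genes, a
unified promoter/terminator map, inferred 5′/3′/internal UTRs, and
transcripts organized into classified operons.

All stages are deterministic given their inputs. Randomness exists only
in the synthetic-fixture generator, whose seed is an explicit argument.

## Gene merging

Every overlapping same-strand annotation pair is scored with the
Jaccard index over base pairs (coordinates are 1-based inclusive
throughout, so an interval `[s, e]` covers `e − s + 1` bp). Pairs are
matched when (i) J ≥ 0.8, (ii) both are non-coding and J ≥ 0.5, or
(iii) a non-coding annotation is fully contained in the other. The
looser non-coding threshold reflects the coarse resolution of
array-derived ncRNA calls, which routinely deviate tens of bp from the
curated coordinates of the same molecule. Two guards apply: riboswitch
overlaps with coding genes never match (the riboswitch is part of the
mRNA leader, not the gene), and a configurable do-not-merge list keeps
known divergently annotated duplicates apart (four such genes by
default: cotT, yoyG, yqjU, yrzH).

Matching propagates: groups are connected components of the pair graph,
so correspondence found through an intermediate annotation merges all
three, across and within resources, in a single step — an iterative
scheme would depend on merge order. Each group emits one annotation
with the highest-priority member's coordinates; when several members
tie at the best priority the bounding interval of the tied members is
used (not of the whole group — absorbed lower-priority members should
not widen a curated coordinate). Antisense overlaps score J = 0 by
construction so asRNA/mRNA pairs always stay separate.

Priorities are per-resource configuration, split into coding and
non-coding ranks, encoding: curated over predicted, high resolution
over low, newer reference curation over older. Biotypes resolve to the
most specific label in the group, with the fixed preference asRNA ≻
sRNA ≻ riboswitch for the genuinely ambiguous cases (a term-seq
riboswitch call overlapping an annotated sRNA is most usefully reported
as the sRNA). A group mixing a CDS with a *specific* ncRNA biotype
indicates an upstream matching error and is refused; putative ncRNA
calls, by contrast, may be absorbed into a coding gene via containment,
which is how spurious array predictions inside ORFs disappear.
Meta-information is never filtered: conflicting values are all kept,
each tagged with its resource of origin.

## Site unification

TSS and TTS annotations differ in positional resolution. Curated sites
are nucleotide-resolution (half-width 0); tiling-array predictions are
trusted only within ±22 bp — twice the array's probe interval — giving
a 45 bp window in which the true position should lie. Unification runs
separately per site type and strand: windows that overlap form
single-linkage groups (the sweep is ordered by window start, which is
what makes the single-linkage closure exact), and within each group
only the members at the group's minimal half-width are kept. Distinct
positions at equal best resolution all survive — collapsing them would
discard genuinely separate promoters. Sigma-factor labels travel from
the best-resolution member that has one; labels of discarded members
are retained as provenance, as are the discarded site ids.

## TU complementation and UTR inference

Transcription-unit gene lists from different resources are incomplete
and name genes against different catalogues, so they are first
re-expressed against the merged gene set and then complemented: a
merged gene joins a TU when it is fully contained in the TU region,
contains it, or overlaps it by at least 70 % of the gene's own length.
TUs spanning more than a quarter of the genome are discarded as
erroneous, duplicates (identical gene sets) are collapsed, and
configuration-listed TUs are excluded from downstream inference — the
motivating case being the sigK sporulation locus, whose internal 10 kb
are excised DNA and never transcribed.

Sites then associate to genes: each TSS to the same-strand gene with
the closest 5′ end within 2000 bp (about the maximal observed UTR
length), each TTS to the closest 3′ end, tolerating a 25 bp overlap
into the gene to absorb resolution limits and terminator hairpin
extent. Sites flagged as having had no transcribed region in their
source study are held to a stricter 200 bp cut-off, since a distant
association for them is much more likely spurious. Equidistant ties
break toward a gene that leads a known TU, then toward the smaller
start coordinate — arbitrary but deterministic.

An association at distance ≥ 15 bp yields a UTR filling the space
between site and gene end; a single ≥ 15 bp rule is used for flanking
and internal UTRs alike, since one minimum-length filter governs the
final map and a shorter element would be mostly annotation noise.
When a 5′ association lands on a riboswitch or similar cis-regulatory
structure, the UTR extends across the structure up to the next coding
gene on the strand: the structure is itself part of that gene's
untranslated leader. If no downstream coding gene exists the UTR
truncates at the structure's end, with a warning. Internal UTRs fill
≥ 15 bp gaps between consecutive TU genes, measured against the merged
footprint of the genes seen so far so that nested or overlapping genes
never create spurious gaps; identical gaps shared by several TUs are
emitted once.

## Transcripts and operons

Per TU a directed acyclic graph connects TSSs through 5′ UTRs to genes,
genes through internal UTRs (or directly, when the gap is sub-minimal)
to the next gene, and genes through 3′ UTRs to TTSs. A TU with no
associated TSS anywhere receives a dummy TSS exactly at its first
gene's 5′ end (symmetrically for TTSs), so a transcript can still be
formed; dummy-bounded transcripts have no UTR on that side. Every
directed TSS→TTS path is one transcript. Path counts are capped (64
per TU by default) purely as a diagnostic guard against malformed
inputs; the cap names the offending TU.

Transcript gene sets not matching any known TU become novel TUs, unless
an adjacently located known TU already starts (for an internal TSS) or
ends (for an internal TTS) at the same boundary gene — in that case the
internal site is better explained by the neighbour. Operons are
connected components of the bipartite transcript–gene graph (edge when
the gene is in the transcript's gene set and fully inside its
interval). Classification counts isoforms as distinct (TSS, TTS)
boundary pairs, not distinct gene sets: two transcripts differing only
in 5′ UTR length are distinct isoforms, which is what makes a
monocistronic operon with alternative promoters `complex` rather than
`simple`. The class partition is exactly simple/traditional/complex.

## The synthetic fixture generator

`generate_truth()` lays out operons along a simulated genome with, by
default: 1–3 genes of 300–900 bp (ncRNA operons: one 80–200 bp sRNA,
20 % of operons), intra-operon gaps of 0–80 bp so that both direct
gene–gene joins (< 15 bp) and internal UTRs (≥ 15 bp) occur, 5′/3′ UTRs
of 20–150 bp, 300–800 bp between operon envelopes, and a 30 %
probability each of one extra TSS or TTS per operon (alternative
upstream boundaries for monocistronic operons, internal sites
otherwise) — the mechanism that produces isoforms and complex operons.
Extra boundary positions are kept ≥ 100 bp from their primary
counterparts so that resolution windows never bridge distinct true
sites.

`emit_resource_views()` derives three input views: *curated* (exact
coordinates, nucleotide-resolution sites with sigma factors, TU lists
that occasionally omit an internal gene, exercising complementation),
*array* (gene coordinates jittered by a truncated integer Gaussian,
sites jittered within ±22 bp at half-width 22, specific ncRNA biotypes
degraded to putative, 20 % dropout, 10 % orphan-flagging) and
*redundant* (duplicated ncRNAs with small jitter). The array jitter is
truncated at ±15 bp per coordinate: for the shortest default genes this
keeps the Jaccard index against truth above the merge thresholds, which
is precisely the regime in which the method promises exact recovery.
Under these conditions `score_recovery()` reports 1.0 for every metric
— gene coordinates, site map, per-class UTR sets, transcript count,
operon partition and classes.

What the fixtures do *not* emulate: real coordinate disagreements that
exceed the merge tolerances (the four do-not-merge genes exist because
real resources disagree irreconcilably), systematic biases of array
boundary calls, overlapping operons on one strand, condition-dependent
transcription, and the idiosyncrasies of converting proprietary
database dumps. Passing recovery tests therefore demonstrates
correctness of the integration logic under the method's stated
tolerances, not fidelity of any specific resource conversion.

## Evidence statistics

`compute_ml2()` scores an annotation by the mean over its positions of
the per-position maximum log2 signal across all conditions — an
annotation transcribed in any condition scores high even if silent in
most. Signals are used as-is; no normalization is applied, following
the position of the array's designers that none is needed for this
design. `ml2_percentiles()` reports the values exceeded by 90 % and
50 % of a set, using linear-interpolation percentiles (R quantile type
7), and states the method in its output since threshold comparisons
across tools are otherwise ambiguous. `biotype_agreement()` compares
two UTR sets under ≥ 1 bp same-strand overlap, counting each source
annotation exactly once (agree / single other class / both / no
overlap), so row sums always equal the source class sizes.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere; lengths are
  `end − start + 1`. Wrap-around (origin-crossing) features are not
  modeled and must be pre-split.
* All thresholds live in `pipeline_config()` with the standard values
  as defaults; nothing is hard-coded in the stages.
* Tie-breaks are deterministic throughout (lexicographic ids, smaller
  start coordinates), and exports sort by (start, end, id), so repeated
  runs on identical inputs produce byte-identical GFF3.
* Sequence lookup (`locate_unique_sequence()`) searches both strands
  and requires a unique exact occurrence; a palindromic match at one
  locus counts once. Binding-site motifs are double-stranded, so
  single-strand search would miss half the placements.
* In test suites the problem sizes are kept at desk scale — property
  checks on 10⁴ random interval pairs, 200–300 random sites/hits, and
  a 50-operon end-to-end recovery — sizes at which the brute-force
  oracles are still exact and fast.

## Known limitations

The association step anchors a structure-extended 5′ UTR on the
structure, not on the downstream coding gene; transcript paths
therefore enter at the structure's gene. Orphan status is taken from
the ingest schema, not re-derived. The tiling-study's split-UTR
segmentation is deliberately not reproduced. Full-scale replication of
a published atlas depends on faithful conversion of the archived
resource dumps into the ingest schema — the conversion, not the
method, is the dominant source of count deviations there.
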