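---
title: "Designing and evaluating UCE probe sets in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating UCE probe sets in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ultraconserved elements (UCEs) are short regions that stay nearly invariant
across deeply divergent taxa, flanked by progressively more variable
sequence. Because the core hybridises reliably across species while the
flanks accumulate informative substitutions, a single bait set can enrich
hundreds to thousands of orthologous loci across a clade. Bait sets are
lineage-specific in practice, so groups without a tailored set need a
design pipeline: find conserved loci across available assemblies, tile
baits over them under composition constraints, and validate the set by
simulated capture. `uceprobe` implements this pipeline and pairs it with a
synthetic-genome generator so every stage can be checked against planted
ground truth.

## Locus discovery

```{r, eval = FALSE}
loci <- discover_loci(reference, others, discovery_params())
```

Each non-reference assembly is decomposed into error-free reads
(`read_length` = 100 bp, stride = `read_length`/2 so interior positions are
covered twice) which are mapped to the reference with a *fitting* alignment:
the whole read must align, and it qualifies only when identity ≥ 1 −
`max_divergence` (default 0.05). Reads with more than one qualifying
location are discarded rather than assigned, which mirrors the intent of
keeping putatively orthologous, single-copy regions without a paralog
model. The error-free-read formulation makes "conserved" operational: a
region is conserved in a taxon exactly when its reads survive the
divergence ceiling.

A reference position becomes part of a candidate locus when the number of
supporting taxa reaches `ceiling(occupancy_fraction * n_taxa_total)`; the
reference always supports its own positions. The ceiling rule reproduces
the usual field arithmetic (90% of 20 taxa → 18); because published panels
sometimes report thresholds that are not exactly reproducible from their
taxon counts, the integer threshold can also be set directly
(`occupancy_count`). Candidates separated by gaps *strictly* below
`merge_gap` (100 bp) merge; loci shorter than 160 bp or with repeat
fraction above 0.25 are removed. Two conventions worth stating: coordinates
are 0-based half-open everywhere (conversion to 1-based happens only in
human-readable output), and `N` bases are excluded from the GC denominator
but count as unmasked for repeat content — `N` records ambiguity, not
repeat annotation.

The per-locus `occupancy_count` is the maximum support observed inside the
locus; after gap-merging a locus can contain sub-threshold positions, so
the maximum (rather than the minimum) reflects the evidence that triggered
the call.

## The local matcher

Every matching step delegates to one seeded local aligner (Rcpp). Scoring
is pinned package-wide — match +1, mismatch −1, gap open −2, gap extend −1,
with a gap of length L costing 2 + (L − 1) — because the identity/coverage
contracts only make sense relative to a fixed scheme. Identity counts every
alignment column, gaps included; this is the conservative reading, chosen
because the upstream tools this role replaces do not document theirs.
Query coverage is the aligned query span over the query length.

Seeding uses exact 12-mers clustered by diagonal; each cluster is verified
by a banded affine dynamic program over a window around the cluster, and
contigs at or below `small_cutoff` skip seeding entirely and are verified
exhaustively (this path is what the test suite compares against an
independent Smith–Waterman oracle). Overlapping hits of one query on one
target region collapse to the best-scoring hit so repeated seeding is never
double-counted as extra capture. A consequence worth knowing: hit-set
monotonicity in the thresholds holds for the per-locus counts the pipeline
uses, but the collapse step means it is not a theorem for raw hits in
adversarial cases.

## Bait design and deduplication

For a locus of length L, stride = `probe_length %/% tiling_density`
(120/3 = 40 bp) and the two bait starts are
`mid − probe_length + stride %/% 2` and that plus one stride, clamped into
`[0, L − probe_length]`:

```
locus   |----------------------m----------------------|
bait 1              [==========|=========]
bait 2                  [======|=============]
                               ^ both overlap the midpoint
```

This realises "two baits at 3× tiling density overlapping the middle" while
guaranteeing the midpoint overlap for any locus length; at L = 120 both
starts clamp to 0 and collapse to one bait. Filters (GC within
[0.30, 0.70] inclusive, repeat fraction ≤ 0.25 — strictly *more than* 25%
is removed) drop individual baits, not loci; a locus whose baits all fail
is reported as undesignable rather than silently vanishing.

Deduplication builds a similarity graph and keeps one probe per connected
component — the probe whose source taxon comes earliest in the priority
order, then the lexicographically smallest id, so builds are deterministic.
An edge requires, in either orientation, a maximal-scoring local alignment
with identity ≥ 0.5 covering ≥ 0.5 of one of the two probes **and scoring
at least `min_score` (default 40)**. The score floor needs a word of
justification: under the lenient pinned scoring, the optimal local
alignment of two *unrelated* 120-mers can meander through gaps to ~50%
identity at ~50% coverage with a score near 10, so a bare 50/50 screen
connects random probes at a fraction of a percent per pair and, at
master-set scale, fuses unrelated loci. Seed-and-extend aligners avoid this
by reporting only alignments above a significance threshold; `min_score`
= 40 (a third of a bait) plays that role. Genuine duplicates at divergences
a capture experiment could ever bridge score far above it.

One deliberate consequence: the two midpoint-overlapping baits of a locus
share 80 of 120 bp exactly (coverage 0.67 at identity 1.0), so the 50/50
self-screen collapses them to one representative. The graph-component
contract — no retained pair may be similar — is enforced verbatim even
though it thins the per-locus tiling; self-capture completeness is
unaffected because one bait suffices to recover its locus.

## Master, subset and mixed sets

The temporary (reference-only) set is matched to every assembly at identity
0.50 / coverage 0.83; loci present in at least `min_species_for_final`
(15) assemblies survive. For the master set, each surviving locus is
located in each assembly by the best qualifying hit of the *locus*
sequence, and baits are designed from that assembly's own sequence —
provenance (`source_taxon`) is preserved so the set can later be subset to
chosen source taxa. Merging two sets (the genome-based and
transcriptome-based designs) prefixes colliding id namespaces, screens the
union at identity 0.5 / coverage 0.5, and favours the first set's probes as
representatives.

## In-silico capture

`capture_taxon()` matches probes at `match_identity` (default 0.50; 0.75 is
the convention for genome-derived probes against genomes) and the design
coverage default 0.83, collapses per-locus hits to maximal target spans,
slices each span ± `flank` (clipped at contig ends — padding invented
sequence is not defensible for assemblies), reverse-complements
minus-strand slices so all output is probe-oriented, and re-matches the
full probe set against the slices at coverage 0.67 / identity 0.80.
Conflicts are then resolved at locus granularity: a slice matching probes
of more than one *locus* is removed (matches within one locus's own bait
cohort are expected — the baits overlap by design — and do not count), and
a locus matched by more than one slice in the same assembly is removed as
putatively multi-copy. Slices that re-match nothing fail validation.

Efficiency is captured loci over the probe set's distinct target loci; the
mean can exclude configured taxa (degraded assemblies are conventionally
excluded from the headline mean), and exclusions are logged. Occupancy
matrices drop loci seen in fewer than 3 taxa; the shared-locus matrix
`S[i, j]` counts loci present in both taxa, with per-taxon counts on the
diagonal.

## The synthetic panel

`generate_panel()` builds one ancestral chromosome of alternating random
spacers (400–800 bp) and conserved cores (defaults: 200 cores of
300–600 bp), then evolves each taxon by independent per-site substitution:
cores at a per-taxon rate drawn from 1–3%, background at 15%. Taxon 1 is
the unevolved reference. A configurable fraction of spacers carries a
soft-masked tandem-repeat tract; optional dropout replaces a core with
unrelated sequence in chosen taxa; transcriptome views export expressed
cores ± 80 bp native flank as contigs, guaranteeing the substring
containment the capture tests rely on.

These defaults are the study conditions of the test suite: 20 taxa and 200
loci keep discovery near 20 s and the full design under two minutes on one
CPU while leaving enough loci for stable rates. Substitution-only evolution
(no indels) is the default because it keeps coordinate truth exact across
taxa; an indel-free panel cannot probe alignment gap handling end-to-end,
which is why the aligner is separately tested on gapped fixtures against an
exhaustive oracle. What the synthetic panel does *not* emulate — assembly
fragmentation and gaps, paralogy, rate heterogeneity along the sequence,
GC-biased composition, real repeat families — bounds what green tests mean:
they verify the machinery and its contracts, not field performance on real
assemblies, whose efficiencies are far below the synthetic 100%.

Determinism is strict: a panel is byte-identical for a given (seed,
params), every derived seed is drawn inside the master seed's RNG scope,
and design itself contains no randomness, so a fixed config reproduces
identical probe FASTAs and reports.

## Numerical and degenerate-input choices

* Occupancy threshold above the taxon count, empty probe sets, all-`N`
  sequences and zero-length masks are errors, not warnings.
* A locus shorter than one bait yields zero baits with a warning record.
* Merging at `max_gap = 0` unions only overlapping intervals (the strict
  gap rule); coverage runs are unioned separately so adjacency is handled
  where it matters.
* Ties in dedupe representatives resolve by taxon priority then probe id;
  ties in hit ordering by (contig, start) — both total orders, so output
  never depends on hash or insertion order.

## Limitations

The matcher is a desk-scale tool: it is exact on small targets and
seed-limited on large ones, so sensitivity below ~70% identity depends on a
shared 12-mer surviving — adequate for capture-relevant divergences, not a
replacement for a production aligner on gigabase genomes. The conflict
rules operate per locus, so a biological tandem duplication and an assembly
artefact are indistinguishable and both cost the locus for that taxon.
Downstream phylogenetics (alignment, trimming, tree inference) is out of
scope; capture output is written as per-locus FASTA bundles for external
tools.
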