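---
title: "In silico PCR mining of GMO detection-method amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR mining of GMO detection-method amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimine)
```

## The problem

Control laboratories verify genetically modified organisms (GMOs) in food and
feed with validated real-time PCR assays. Each assay is a primer pair, often
with an internal TaqMan probe, and is classed by the specificity of its
target: *event*-specific assays target a unique transgene/genome integration
junction, *construct*-specific assays an artificial junction between elements
of a transgenic construct, *element*-specific assays a single genetic element
(a promoter, terminator or marker gene, often also present in its donor
organism), and *taxon*-specific assays an endogenous species gene.

Given such a panel and a collection of nucleotide sequences, `amplimine`
predicts which assays would amplify which records, extracts the predicted
products (amplicons) with their edit annotations, verifies probe annealing,
builds non-redundant amplicon sets, and summarises the consistency of the
screen per dataset and assay class. The amplicon collection built this way is
the substrate for downstream uses such as similarity searching, annotation of
poorly described GM sequences, and triage of candidate (possibly
unauthorized) events from screening calls.

## The in silico PCR model

A primer *binding site* is a target window to which the primer aligns **end
to end** (full primer coverage) with at most `n_max` mismatches and at most
`g_max` indel columns. The engine enumerates all such windows by a
feasibility dynamic program whose cell state is the set of still-attainable
(mismatch, gap) count pairs, encoded as a bitmask; the bounded budgets make
this exact and fast. IUPAC ambiguity codes in primers match at zero cost any
target base whose ambiguity set is a subset of the primer's; a target `N`
never matches, so binding sites are not hallucinated inside the N-runs of
draft records.

Because indel budgets make windows overlapping a real site alignable too
(e.g. the window one base longer than an exact match, absorbed by one gap),
qualifying windows are reduced to reported **hits** by greedy selection:
windows are ranked by (fewer total edits, fewer gap columns, length closest
to the primer length, leftmost position) and accepted only if they do not
overlap an already accepted hit. A single physical site therefore yields a
single hit with the minimal-edit annotation, while distinct,
non-overlapping sites are all reported. The corner case of two genuinely
distinct loci that physically overlap is resolved in favour of the
better-scoring one; we accept this as the price of unambiguous per-site
reporting.

Hits of the forward and reverse primer on opposite strands are paired when
they are convergent (3' ends facing inward), their footprints do not
overlap, and the outer-to-outer span lies within the product-size window
`[d_min, d_max]`. Both amplicon orientations are considered; extracted
product sequences are normalised to read forward-primer to reverse-primer.
Finally, products whose summed primer edits (mismatches + gaps over both
primers) exceed `total_edit_max` are discarded. The probe is deliberately
excluded from this cap: probe edits are annotated, not filtered, because
products with an imperfect probe site remain informative and are only
dropped by the *strict* screening mode downstream. Primer 3'-end mismatches
receive no special treatment; the model is a pure edit-distance one, with no
thermodynamics, melting temperatures or primer-dimer checks.

Default tolerances follow established in silico PCR practice for GMO method
screening: `d_min = 50`, `d_max = 500` bp, `n_max = 2`, `g_max = 2`,
`total_edit_max = 2`. All of them surface on the command line (`-d MIN-MAX`,
`-n`, `-g`, `--total-edits`) and in the YAML config.

## Probe verification

When an assay carries a probe, each amplicon is searched on both strands by
local (Smith-Waterman) alignment with affine gaps: match +1, mismatch -2,
and a gap run of length *k* costing 2 + *k*. Among equal-score alignments
the one with fewer gap columns, then fewer mismatches, then fewer gap opens
is chosen, which makes the reported counts unique; strand ties resolve to
the plus strand. An alignment is reported only when it covers at least 50%
of the probe (`probe_scoring(min_coverage = )`). The probe status is
`perfect` (full coverage, zero edits), `mismatched` (found, but with edits
or partial coverage), `not_found`, or `no_probe`. These scoring constants
and the coverage floor are our defaults, exposed as configuration: the
pipeline needs edit annotation, not similarity statistics, so no E-values
are computed.

## Species and provenance

Species assignment is an offline join against a record-to-species TSV
mapping; records missing from the map are `unknown`. When no map is given, a
fallback parses `[Genus species]`-style organism tokens from FASTA
descriptions. This keeps the artifact free of network lookups. Every record
also carries the label of the dataset it came from, which is what the
consistency summaries group by.

## Non-redundant sets

Two groupings are built. Exact deduplication partitions amplicons by
identical sequence; the group count is the number of distinct amplicon
sequences, and group representatives (first member in input order) define
the non-redundant set. Greedy incremental clustering emulates the cd-hit
approach: sequences are taken longest first (ties in input order) and join
the first cluster whose representative they match at identity >= 0.9 with
aligned coverage >= 0.9 of both the longer (`aL`) and the shorter (`aS`)
sequence, else found a new cluster. Identity is defined as matches divided
by alignment columns (gap columns included), stated explicitly because
identity definitions vary between tools; pairwise comparison reuses the
probe aligner's scoring. The 0.9 identity threshold accompanies the
coverage thresholds as the package's reading of "90% identity and 90%
coverage" non-redundancy. cd-hit's word-filter heuristics are not
reproduced — correctness, not throughput, is the contract at this scale —
and comparison is single-orientation, which is sufficient because pipeline
amplicons are orientation-normalised; clustering arbitrary external
sequences with reverse-complement redundancy is out of scope.

## Screening summaries and candidate triage

The screening matrix counts amplicons per record and method. In **strict**
mode only perfect products count: zero mismatches and gaps in both primers
and, for probe assays, a perfect probe. Per dataset and specificity class
the summaries report the fraction of the class's methods detecting at least
one record, the fraction of the dataset's records detected, the amplicon
count, the number of detected (target) records, and the amplicon-to-record
ratio. The ratio's denominator is the *detected* record count, so
event-specific assays on well-formed data show the expected 1:1 ratio;
fractions with empty denominators are reported as absent (`NA`), never as
zero. `candidate_events()` formalises the triage workflow: records whose
strict detection pattern covers all observed positive calls are shortlisted
and ranked by how many observed negative calls they also satisfy.

## The synthetic corpus

Real screening corpora (public nucleotide collections, patent divisions,
transgenic divisions) cannot ship with a package, so every stage is
validated on generated fixtures with planted ground truth. A planted site is
a concrete primer-pair block — forward primer instance, spacer (carrying the
probe instance when the assay has one), reverse-complemented reverse primer
instance — embedded in i.i.d. background at a chosen GC fraction (default
0.40, plant-like). Edits are planted deliberately: substitutions replace a
base by one outside the primer base's IUPAC set, and indel edits delete
interior bases; all edit positions sit at least 4 positions apart and away
from the oligo ends, so the minimal alignment of the oligo against its
instance has exactly the planted counts and a local aligner has no
incentive to trim them away. Sites within one record are separated by more
than `d_max` of background so they cannot cross-pair. Backgrounds are
rejection-sampled: the full panel is scanned and the background redrawn
until the observed amplicon table equals the ground truth exactly, which
guarantees no unintended binding sites at the cost of stochastic (in
practice ~1 attempt) generator runtime. An engine defect that loses a
planted site cannot be masked by this loop — the generator then fails loudly
after its attempt limit.

The default corpus (`fixture_spec()`) emulates the class structure of
public data at desk scale: 12 transgenic-like records (one event-specific
site each, every second record also an element site, every third a
construct site; no taxon sites), 12 plant-like records (one taxon site
each), and 4 patent-like constructs emitted in 5 near-identical copies
(byte-identical planted region, fresh background) to exercise
deduplication. The synthetic panel (6/3/4/4 event/construct/element/taxon
methods, roughly the published class proportions scaled down) gives
quantitative assays a probe and leaves qualitative ones without; one
element-specific primer carries a degenerate base so IUPAC handling is
exercised end to end. All planted sites in the default corpus are
edit-free, so the strict and relaxed screens agree on it and the class
signature is analytically forced: GM-specific detection is zero on
plant-like data, taxon-specific detection is zero on transgenic-like data,
and the event-specific amplicon-to-record ratio is exactly 1.

What passing on this corpus shows — and does not show. The fixtures prove
the search, pairing, filtering, annotation and bookkeeping are exact under
the stated model on clean backgrounds. They do not emulate biological
sequence composition (repeats, low-complexity runs, homopolymers), real
promoter/terminator sequences, sequencing error, or the heavy redundancy
structure of real patent data, so they say nothing about assay performance
in the laboratory or about hit rates on real databases.

## Validation strategy and problem sizes

The engine is checked against an independent brute-force oracle — a pure-R
dynamic program that aligns the primer against every explicit window and
applies the same bounds and reduction — over 200+ random instances covering
the full mismatch/indel grid (targets of 300-800 bp, primers 15-30 nt,
sizes chosen so the deliberately slow oracle completes in minutes), and the
probe aligner against an exhaustive local-alignment DP on 100+ random
pairs. Planted-recovery, strand-involution, parameter-monotonicity,
partition and set-cardinality properties run on generated fixtures,
including a 10 000-amplicon deduplication case. `scripts/acceptance.R`
re-runs the full pipeline on the default corpus and reports its headline
quantities.

## Known limitations

- Edit-distance annealing only; no thermodynamic model, no 3'-anchor rule.
- Whether a combined-edit cap should include the probe is debatable; here it
  does not (probe edits are annotated and handled by strict mode), and the
  cap is configurable.
- Overlapping distinct loci are resolved to the better-scoring hit.
- Greedy clustering order follows the longest-first convention; cluster
  counts can differ from other greedy orders within the documented
  tie-break, and comparisons are single-orientation.
- The fixture generator plants substitution and deletion edits; insertion
  edits into primer instances are not generated (the engine itself handles
  them — they arise in the random-instance oracle tests).
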