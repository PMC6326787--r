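---
title: "Mapping embedded ribonucleotides: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping embedded ribonucleotides: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnmpmapr)
```

## The mapping problem

Four library chemistries capture ribonucleoside monophosphates (rNMPs)
embedded in genomic DNA, and each places the rNMP at a fixed offset and
strand relative to the 5′-most base of sequencing read 1:

* **ribose-seq** ligates the rNMP itself together with its upstream
  neighbours, so the rNMP is the reverse complement of the tagged
  nucleotide;
* **HydEn-seq** and **Pu-seq** hydrolyse the backbone on the 3′ side of the
  rNMP and capture the downstream fragment, so the rNMP is one nucleotide
  upstream of the tagged nucleotide, on the same strand;
* **emRiboSeq** uses RNase H2 incision on the 5′ side and captures the
  upstream fragment, so the rNMP is one nucleotide downstream of the reverse
  complement of the tagged nucleotide.

Because instruments sequence from the fragment's 5′ side and may not reach
its 3′ end, only the 5′ read end carries positional information: for a `+`
alignment the 5′ base is the BED start, for a `−` alignment it is `end − 1`.
`calc_site()` encodes the three geometries as integer arithmetic on
zero-based half-open intervals; 1-based SAM positions are converted once, at
ingestion, and everything downstream is BED arithmetic. HydEn-seq and Pu-seq
share one code path because their arithmetic is identical.

### The biological-relevance screen

For every technique except ribose-seq the computed site lies *outside* the
read footprint, so a read aligned flush to a chromosome's 5′-most end (on
either strand) implies a coordinate of `−1` or `length + 1` — biologically
meaningless, and poison for downstream tools. `screen_sites()` accepts a
site iff `start >= 0` and `end <= chromosome length` and returns the
rejects with their originating read names, so losses are auditable rather
than silent. Ribose-seq sites are one of the read's own bases and can never
be rejected; the test suite asserts this as a property.

## De-duplication model

PCR amplifies molecules unevenly, and rNMP sites are concentrated, so
un-deduplicated counts distort apparent incorporation rates. The package
follows the standard UMI argument: reads that share a 5′ alignment position
*and* a UMI descend from one molecule (keep one); reads that share the
position but differ in UMI are distinct molecules (keep both). Design
choices, each made where the convention is genuinely open:

* **Exact UMI matching**, no edit-distance clustering. Directional network
  clustering exists to absorb sequencing errors in UMIs; this package's
  validation regime is error-free by construction, and exact matching is
  deterministic and auditable. Clustering is a deliberate non-goal.
* **The 5′ position, not the whole interval, is the positional key**: reads
  of different lengths sharing a 5′ end and UMI are duplicates (3′ ends
  vary with fragment length, the 5′ end is the tagged position).
* **Tie-break**: the lexicographically smallest read name represents each
  group, making re-runs byte-identical.
* **Barcode matching is exact** (0 mismatches), with the read structure
  fixed as UMI-then-barcode at the 5′ end. A tolerance would trade
  auditability for yield with no principled setting to anchor it.
* Alignment hygiene (unmapped/secondary/supplementary removal, read-1-only,
  MAPQ threshold, default 0) is applied at SAM/BAM ingestion, delegated to
  `GenomicAlignments`.

## Counting and normalization

`count_sites()` collapses screened sites to unique `(chrom, start, strand)`
rows with raw multiplicities and **reads per hundred**
(`raw / library total × 100`). The denominator is the whole-library total —
the unit's purpose is cross-library comparability, which a per-chromosome
denominator would break; per-chromosome normalization exists behind the
`normalization: chromosome` config switch and is labelled as such in output
filenames. Coverage tracks are sparse (zero runs omitted, adjacent
equal-valued runs merged), matching BedGraph convention and keeping
browser uploads small.

## Sequence context

`profile_context()` tabulates base frequencies at relative positions
`−w..+w` around each site, always read 5′→3′ on the site's own strand (a
`−` strand site at `p` maps relative position `i` to the complement of
reference base `p − i`). Raw frequencies are divided by background base
frequencies, so 1 means "indistinguishable from the genome". Conventions:

* **Background is computed per organelle group** (nuclear vs mitochondrial),
  matching the organelle-split reporting: mitochondrial genomes have very
  different composition, and a whole-genome background would fold that
  difference into every mitochondrial profile.
* **Both strands are pooled in the background**, forcing
  `freq(A)=freq(T)` and `freq(C)=freq(G)`. Sites live on either strand and
  are read on their own strand, so the strand-symmetric null is the right
  denominator.
* `N` bases are excluded from numerators and denominators everywhere —
  their identity is undefined, and counting them as a fifth base would
  deflate real frequencies.
* **Sites are weighted by raw count** by default (each count is one
  observed incorporation event); `weight_by_count = FALSE` gives unique-site
  mode. The per-type filters (`rnmp_filter` = rAMP/rCMP/rGMP/rUMP)
  recombine exactly, count-weighted, to the unfiltered profile — a tested
  invariant.
* **Windows truncated at chromosome ends contribute nothing at the missing
  positions** — per-position denominators shrink instead of absorbing
  zeros, so edge sites do not bias flank frequencies.
* Position 0 is the ribonucleotide, so its T is displayed as U in outputs;
  flanking positions are DNA and stay T. Default half-widths are 100
  (zoomed-out) and 15 (zoomed-in), both configurable.

## The simulator: what it emulates, what it does not

`simulate_alignments()` is the exact inverse of `calc_site()`: a truth site
at `p` on `+` becomes a `−` read `[p+1−L, p+1)` under ribose-seq, a `+`
read `[p+1, p+1+L)` under HydEn-seq/Pu-seq, a `−` read `[p−L, p)` under
emRiboSeq, and the strand-mirrored cases for `−` sites. This makes
coordinate recovery an identity round trip, which the suite checks at 100%
sensitivity and precision for all four techniques with 0.5 PCR duplication.
The simulator emulates: planted site positions/strands/base identities
(with an optional identity bias to mimic, e.g., rCMP-skewed
incorporation), technique-specific read placement, 5′ UMI+barcode read
structure, PCR duplication (one verbatim extra copy per molecule at the
given rate), and deliberate end-aligned contamination reads
(`simulate_end_reads()`) that must fail the relevance screen.

It does **not** emulate base-call errors, adapter contamination, paired-end
structure, alignment ambiguity or mappability gaps — the mapping logic is
positional, not sequence-correcting, so error-free reads exercise every
branch of it. Consequently a green round trip demonstrates the correctness
of the arithmetic, screening, de-duplication and bookkeeping, but says
nothing about aligner behaviour on repetitive or error-laden real reads;
the aligner itself is out of scope and its output is consumed as
SAM/BAM/BED. Sites whose implied read would overhang a chromosome end are
skipped and removed from the effective truth set (reported in the
`skipped` attribute), so truth and simulation always agree by construction.

Simulated alignments carry the UMIs and duplicates directly (the primary
test path, aligner-free); `emit_fastq()` serializes whatever alignment list
it is given — UMI + barcode + oriented genomic sequence, constant quality
"I" — so the FASTQ leg exercises demultiplexing and UMI extraction against
the same truth.

## Numerical and degenerate-input choices

* Coordinates are `integer` throughout; the only floating-point quantities
  are frequencies and percentages, compared in tests at `1e-6`–`1e-9`.
* Empty inputs are valid: empty site tables, empty tracks and empty
  BedGraphs propagate as empty, not errors; an empty *filtered* profile
  warns (a user probably filtered everything away) and returns zero totals.
* Per-position profile denominators of zero yield `NA` frequencies
  ("absent"), never 0.
* All randomness (genome generation, site planting, UMIs, duplication)
  flows through explicit seeds, and seeded helpers restore the caller's RNG
  state, so pipelines are byte-reproducible end to end — a tested contract.

## Scale of the validation runs

The bundled tests and the acceptance script run on synthetic genomes of
2–100 kb with 10–10,000 planted sites — sizes chosen so every property
(round trip at ≥1,000 sites per technique, the 10,000-site flat-profile
null within 1.0 ± 0.1, screening edge cases at exact chromosome lengths
including an 813,184 bp chromosome) is checked in seconds while remaining
statistically meaningful. Nothing in the implementation is specific to
these sizes; the per-chromosome data structures stream naturally to
real-genome scale.

## Known limitations

* Barcode and UMI recognition is exact-match; heavily error-laden 5′ tags
  will reduce yield rather than be rescued.
* The candidate enumeration in `plant_rnmps()` materializes the
  `(chrom, pos, strand)` space and is intended for desk-scale synthetic
  genomes, not gigabase references.
* Pu-seq's native windowed-CSV reporting is not emulated; Pu-seq data are
  handled at single-nucleotide resolution like the other techniques.
* Hotspot/peak statistics are out of scope: the distribution module reports
  and plots normalized coverage, it does not call enriched regions.
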