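---
title: "Methods: conservation scoring and track rendering in protplot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation scoring and track rendering in protplot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protplot)
```

## What the package computes

protplot draws amino-acid variants on a horizontal protein schematic so
that spatial patterns — above all, clustering of mutations inside or
near particular domains — become visible at a glance. The motivating
case is the RET receptor tyrosine kinase: disease mutations overall are
spread across the protein, but the subset causing Multiple Endocrine
Neoplasia 2A (MEN2A) concentrates in a handful of extracellular
cysteines immediately N-terminal of the transmembrane segment. A
text table hides that contrast; two lollipop tracks over the same
backbone show it immediately.

The pipeline is: parse tabular inputs (mutations, domain architecture,
PTM sites) and optionally an aligned multi-FASTA; score conservation
per reference position; annotate each variant against domains and PTM
sites; lay out and render the figure.

## The conservation score

Given a multiple sequence alignment and a user-designated reference
row, each reference residue `p` occupies one alignment column. The
score at `p` is

    s = n / t

where `t` is the number of non-reference sequences in the alignment and
`n` the number of them whose character in that column equals the
reference residue. Two modelling choices deserve justification, because
the verbal definition ("the total number of sequences queried at that
position") admits alternatives:

* **The reference is excluded from both `n` and `t`.** The score's
  intended endpoints are 0 = "no other sequence matches" and 1 = "all
  sequences match". If the reference counted itself, `s` could never
  fall below `1/t` and the zero endpoint would be unreachable, so
  self-exclusion is the only reading consistent with the endpoints.
* **`t` is constant across positions.** The alternative — shrinking `t`
  at columns where some sequences carry gaps — would *raise* the score
  exactly where the alignment is least trustworthy. Keeping `t` fixed
  means a gap counts as a mismatch, and poorly aligned regions are
  penalized on the conservation track, which matches the visual intent.
  The per-column variant is deliberately not implemented.

Comparison is case-insensitive (sequences are uppercased on read), and
`'.'` gaps are normalized to `'-'`. Columns where the *reference* is
gapped have no protein coordinate and are dropped from the profile; the
profile length therefore always equals the reference's non-gap residue
count, and a supplied protein length that disagrees with it is a hard
error rather than a silent truncation.

```{r score-endpoints}
aln <- alignment_set(c(human = "CDE", mouse = "CDA", rat = "CQE"), "human")
conservation_scores(aln)
```

## Input conventions

All three tabular formats are tab-separated, 1-based and inclusive on
both interval ends (a signal peptide "from 1 to 24" starts at residue 1
and residue 24 is inside it; a domain `D 5 5` has width one). Lines
starting with `#` are comments. A single header row is auto-detected —
a non-integer in the numeric column of the first data line, with at
least two data lines following — and skipped, so both headered and
headerless dialects parse without a flag; the two-line guard prevents a
lone malformed record from being silently eaten as a "header".
Mutations whose reference and alternate residue are identical describe
no change; they are dropped with a warning rather than aborting a batch
run. The reference alphabet is the 20 standard residues plus `X`
(unknown); the alternate additionally admits `*` for stop gains, which
real mutation collections contain.

Validation (`validate_inputs()`) never throws: it returns a report of
out-of-range records so that library users can decide what to do, while
the command-line `plot`/`annotate` subcommands treat a non-empty report
as fatal (exit status 1).

## Annotation

A mutation is *in* a domain when `start <= position <= end`; all
containing domains are reported, in architecture-file order, and the
exported table joins them with semicolons (`"none"` when empty). PTM
overlap is exact-position equality. Every input mutation appears in the
table, annotated or not, so row counts are stable between input and
output. The implementation is a direct per-interval scan; the test
suite checks it against an independently written brute-force oracle on
randomized domain sets.

## Layout and rendering

The figure is a vertical stack of tracks: title, optional second
mutation track, primary mutation track, backbone with domain boxes, PTM
marks, optional reference-sequence letters, conservation letters,
optional score bars, and a residue-number axis. Each enabled track gets
a disjoint horizontal band of fixed height on an 864-unit-wide canvas.

Residue `p` maps to a horizontal coordinate affinely over the current
window (the whole protein, or the zoom window): residue units
`[start - 0.5, end + 0.5]` span the drawable width, so a width-1 domain
still occupies one full residue slot and remains visible. Zooming
(`zoom_view()`) only sets the window; nothing is filtered until render
time, so a domain straddling a window edge is clipped, not dropped,
while point features (markers, PTM sites, letters) are drawn only when
their position lies inside the window.

Numerical and tie-break choices:

* Mutation markers are lollipops labeled `<ref><position><alt>`
  (e.g. `C634R`). Multiple mutations at one position stack their heads
  upward in input order.
* Label collision handling is deterministic, driven by the minimum
  horizontal gap between distinct marker positions versus the widest
  label: labels sit above the heads when they fit, alternate
  above/below when the gap falls under the label width, and rotate 90
  degrees when it falls under half of it.
* Conservation letters use a three-bin color scale (`s = 1`;
  `0.5 <= s < 1`; `s < 0.5`); the numeric score, when requested, is a
  per-position bar of height proportional to `s`.
* Letter tracks (reference sequence, conservation) are only legible on
  narrow windows, so they are drawn as letters for windows of at most
  200 residues. Above that, the reference-sequence track is suppressed
  with a notice, and the conservation track falls back to a
  per-position color strip carrying the same three-bin encoding.
* Domain boxes cycle a fixed qualitative palette in architecture-file
  order, keyed to the file index so a domain keeps its color under
  zoom. Colors, raster geometry (default 12 inches wide at 150 dpi) and
  label visibility are overridable through a flat `key = value`
  configuration file.

SVG is the canonical backend: it is written directly by the package
with fixed numeric formatting (two decimals), no timestamps and no
generated ids, so a given spec always produces byte-identical output —
which is what makes figure structure testable by parsing. Marker,
domain and track groups carry `class` and `data-*` attributes for that
purpose. PDF and PNG replay the same display list onto the standard R
graphics devices; they share all geometry with the SVG but inherit the
device's font rendering, and determinism is only promised for SVG.

## The synthetic-fixture generator

The generator exists so that every stage is testable without licensed
mutation databases or downloads; its defaults mirror the published RET
case study.

* `make_ret_like_fixture()` emits the four annotated RET domains
  (Signal Peptide 1–24, Cadherin 191–270, Transmembrane 636–653,
  Tyrosine Kinase 724–1005) exactly, a 40-mutation background set
  spread uniformly over the protein (standing in for the ~200 broadly
  distributed disease mutations, scaled down to keep figures and tests
  fast), and the six classic MEN2A hotspot cysteines (609, 611, 618,
  620, 630, 634) as the clustered secondary track. The protein length
  defaults to 1114 residues — the length of the RET isoform the
  published coordinates refer to — but is a parameter, not a constant.
* `simulate_mutations()` draws positions uniformly, optionally sending
  a configurable fraction into a cluster window, with ref/alt residues
  uniform over the 20 amino acids and ref ≠ alt.
* `simulate_alignment()` draws a uniform reference sequence and makes
  each non-reference sequence match it at position `p` independently
  with probability `q_p` (otherwise a uniformly chosen different
  residue, optionally replaced by a gap at a configurable rate). Under
  this model the computed score at `p` is Binomial(`t`, `q_p`)/`t`, so
  recovery of `q_p` within binomial standard error is a sharp,
  closed-form check on the whole read–map–score path; the test suite
  runs it at `q_p = 0.5` with 200 non-reference sequences, where three
  standard errors are about 0.106.

Every generator call runs on its own seeded stream and restores the
caller's RNG state, so fixtures are reproducible and never perturb user
code.

What the generator does **not** emulate: phylogenetic correlation
between sequences (real orthologs are not independent draws),
insertion/deletion structure and alignment error from a real aligner,
residue-specific substitution preferences, and the actual spectrum of
curated disease mutations. Passing tests therefore demonstrate that the
arithmetic, coordinate mapping and rendering are correct under the
stated model — not that any biological conclusion transfers to a
particular real protein.

## Problem sizes used by the test suite

Oracle-equivalence checks run 500 random alignments (up to 10 sequences
by 50 columns) and 500 random domain sets (up to 20 intervals); the
statistical-recovery check uses 100 positions by 201 sequences. These
sizes give the properties room to fail while keeping the default suite
around twenty seconds on one CPU.

## Known limitations

* Conservation is exact-match proportion only; no substitution-matrix
  or entropy weighting.
* Positions must arrive pre-mapped to protein coordinates; there is no
  VCF/HGVS parsing and no database retrieval.
* The per-column-`t` gap convention is documented but unimplemented.
* PDF/PNG output depends on the local graphics device for fonts and is
  not guaranteed byte-stable across platforms.
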