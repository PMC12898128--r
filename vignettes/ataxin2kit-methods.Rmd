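---
title: "Methods: repeat, motif, and architecture analysis for Ataxin-2 family proteins"
author: "ataxin2kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat, motif, and architecture analysis for Ataxin-2 family proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataxin2kit)
```

## Background

Ataxin-2 family proteins (human ATXN2 and ATXN2L, plant CID3/CID4, yeast
PBP1) share a three-part core — an LSm RNA-binding fold, the family-defining
LSm-associated domain (LSmAD), and the 14-residue PAM2 motif that binds the
MLLE/CTC domain of poly(A)-binding protein — embedded in long intrinsically
disordered regions (IDR1 before LSm, IDR2 between LSmAD and PAM2, IDR3
after PAM2). The IDRs carry homopolymer repeats, most prominently the polyQ
tract whose CAG-encoded expansion causes SCA2 and contributes to ALS risk.
This package implements the sequence-level operations such a family survey
needs: repeat calling with interruption profiling, codon-level analysis of
repeat-encoding DNA, tandem-duplication detection, degenerate motif
scanning, internal-start isoform enumeration, architecture chimerism
classification with enrichment statistics, and offline ortholog-candidate
tier classification with consensus bootstrapping. All coordinates are
1-based inclusive, matching database residue numbering.

## Homopolymer repeat detection

`find_repeats()` uses a seed-and-merge rule. For a target residue (default
set Q, A, P, S, G):

1. every maximal pure run of at least `seed_min` residues (default 3) is a
   seed;
2. consecutive runs separated by at most `max_gap` non-target residues
   (default 2, accommodating single and double interrupting residues) are
   chained greedily, so calls are maximal — no call can be extended or
   merged further without exceeding `max_gap`;
3. a chain is reported when it contains at least one seed and its *target
   count* reaches `min_total` (default 6).

`min_total` counts target residues only, not tract width, because repeat
sizes in this family are conventionally quoted as the number of target
residues (a "73Q" tract with three interruptions contains 73 glutamines).
No purity threshold is applied by default: heavily interrupted tracts (a
41Q tract interrupted at 11 positions is a documented case) would fail any
naive purity cut-off, so purity is reported for the caller to filter on.
Interruption runs may contain any residues; the flank is the single residue
immediately outside the tract, with `^`/`$` sentinels at the termini.
`flank_interruption_stats()` counts interrupting residues per residue (a
"PP" run contributes 2 to proline), matching how interrupter preferences
are quoted in the field, and breaks ties alphabetically.

With `max_gap = 0` the detector provably reduces to maximal-run scanning,
which is the brute-force oracle used in the test suite.

## Codon run-length analysis

Repeat-encoding DNA is printed in the literature as run-length codon
notation, e.g. `(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_` for the 22Q
healthy-allele template. `parse_runlength()` accepts the three dialect
forms that occur in print — `(XYZ)_n_`, `(XYZ)n`, and bare codons — and
ignores hyphens, whitespace, and `**` bold markers, because published
strings mix all of these (including a line-break hyphen inside one printed
string and bolded `ATG` triplets marking Met interruptions). Parsing
preserves textual run order so printed forms can be echoed verbatim;
`canonicalize_runs()` merges adjacent equal-codon runs, and
`decompose_codons()` inverts `expand_runs()` up to canonicalization (a
property-tested round trip). Translation uses the standard nuclear genetic
code via Biostrings; all printed examples are nuclear, so no organellar
code variants are offered. `summarize_repeat_dna()` reports the target
count, maximal non-target interruption events, target codon usage (the
CAA/CAG balance), and the longest pure run; its totals are consistent with
`find_repeats()` on the translated peptide whenever `max_gap` covers the
longest interruption event.

## Tandem duplications

`find_tandem_duplications()` reports maximal tandem arrays of primitive
units (unit lengths 2–12 by default). Units with an internal period are
reduced to that period; arrays whose primitive period is below `min_unit`
are dropped, which delegates homopolymers to the repeat finder. A maximal
periodic tract can be longer than an integer number of copies, which makes
the reported phase a genuine choice: this package anchors the phase at the
**right** edge of the periodic tract. The rationale is mechanistic — a
tandem duplication event inserts the new copy immediately after the
original unit, so the novel junction lies at the right end of the
periodicity — and it reproduces the published unit decompositions of the
pathogenic ATXN2 dup21 and dup9 variants (e.g. `ARPA PGCPRPA PGCPRPA CEPV`,
whose periodicity actually begins two residues earlier than the printed
unit). `unit_len_nt = 3 * unit_len_aa` is reported for direct comparison
with base-pair phrasing of coding-sequence duplications. Implementation is
a per-period run-length scan; the test suite checks it bit-exactly against
an exhaustive position-by-unit-length scanner on sequences up to 200
residues.

## Degenerate motif scanning

PAM2 consensus sequences are printed with conservation encoded by letter
case. `consensus_model()` maps uppercase positions to weight 1.0, lowercase
to 0.25, and `.` to zero; a window's score is the weighted fraction of
case-insensitively matching positions. The printed notation defines no
numeric weights, so the 1.0/0.25 two-tier scheme and the default reporting
threshold of 0.60 are package choices, all configurable. Three presets
ship: the 23-position degenerate consensus for low organisms
(`PAM2_FULL_23`), the plant tandem-duplicated consensus
(`PAM2_PLANT_TANDEM`), and a curated 10-residue trypanosomatid core
(`PAM2_CORE_10`) constructed as a design choice from the five reported
precursor candidates. Windows are fixed-length (PAM2 is a fixed-length
linear motif); no indels are modelled. A motif planted with *k* mutated
lowercase positions scores exactly `(W - 0.25 k) / W` with `W` the total
pattern weight, which the generator and tests exploit as a closed form.

## Isoform candidates and zones

`enumerate_isoforms()` treats every Met as a candidate internal translation
start — small bands on immunoblots and short database entries indicate such
isoforms are real — and classifies each annotated domain as `full`
(start at or before the domain start; a Met exactly at the domain start
founds the domain-initial isoform), `truncated` (inside), or `lost`
(after). Zones are named by the nearest annotated core landmarks; when a
core domain is missing from the annotation its two flanking zones merge
(e.g. `LSm_to_PAM2` when no LSmAD is annotated). No Kozak-like context
filtering is applied; the protein sequence alone provides none.

## Architecture classification and enrichment

`classify_architecture()` implements the rule table: LSmAD missing means at
most `partial` (LSmAD is the unique family-defining feature); an extra
domain entirely upstream of the first core domain makes `chimeric_N`,
entirely downstream of the last `chimeric_C`, both sides `chimeric_both`;
an extra overlapping a core span gets side `internal` and verdict
`irregular` (a guard — curated architectures show none); all three core
domains in order with no extras is `canonical`. Proteins longer than 1000
residues (the usual screen for chimeric orthologs) are flagged
`unusual_length`. `enrich_categories()` tests each extra-domain functional
category with the two-sided Fisher exact test under the
"sum of tables at most as probable as observed" convention (not the
doubling convention), via `stats::fisher.test`, cross-checked in the test
suite against an explicit hypergeometric enumeration; Benjamini–Hochberg
adjustment is applied across categories and no significance filter is
imposed, since chimera counts are small and enrichment is reported
qualitatively.

## Ortholog tiers and bootstrapping

The tier rules are anchored to the two E-value thresholds in routine use
for this family — 1e-10 for high-significance LSmAD hits and 5e-7 for
looser homology — and to the LSmAD-defines-the-family principle: `tier1`
needs a strict LSmAD hit plus at least one supporting-domain hit (LSm or
PAM2, any E-value), `tier2` a strict LSmAD hit alone, `tier3` an LSmAD hit
between the thresholds, and everything else (including taxonomy-filtered
subjects) is `rejected`. Published tier definitions are not enumerated
anywhere, so this rule table is a package design choice with both
thresholds and the supporting set configurable; only E-value evidence is
used, as identity/coverage rules are not documented.

`bootstrap_iterate()` runs the iterative consensus search fully offline:
the search and fetch backends are injected functions, so tests use
synthetic backends and no network access occurs anywhere in the package.
Each round searches with the current query, assigns tiers, and rebuilds the
query as the column-wise majority consensus of the tier1 subjects'
pre-aligned sequences (alignment itself is out of scope; inputs are assumed
pre-aligned, ties go to the alphabetically first residue, and the gap
character wins only on strict majority). The loop stops when a round
returns the same tier1 subject set as the previous round; that confirming
round is not counted, so a backend that returns constant hits converges
with `iterations = 1`, and a two-round recruitment scenario converges with
`iterations = 2`. An oscillating backend stops unconverged at `max_iter`
(default 10).

## Synthetic data and what the tests show

The generators in `sim_repeat_cohort()`, `sim_motif_cohort()`,
`sim_tandem_cohort()`, `sim_architecture_cohort()`, and
`sim_blast_strata()` are pure functions of their arguments including the
seed; each draws from its own stream derived from the master seed with a
fixed offset, so adding a generator never perturbs another's fixtures.
Defaults emulate the study conditions the analyses assume: a 23Q tract with
proline flanks in a 200-residue IDR-like background (disorder-promoting
composition, glutamine at 0.02), a 5% chimera fraction among 100 proteins
with canonical lengths of 700–1000 residues and chimeric lengths above
1100, LSm spans of 78 residues, LSmAD spans of 69 residues separated from
LSm by a 50–60 residue bridge, 14-residue PAM2 spans at three-fifths of
protein length, and E-value strata drawn log-uniformly inside the tier
ranges. Planting writes a short non-target guard around repeat tracts and
breaks periodicity at tandem-array borders so truth tables are exactly
recoverable.

What the synthetic cohorts deliberately do not emulate: phylogenetic
correlation between sequences, sequencing error and fragmentary database
entries, InterPro/Pfam annotation failure (which affects about a third of
LSm domains in low organisms), and approximate tandem copies with
mismatches. Passing recovery tests therefore demonstrates correctness of
the detectors under their own models, not detection power on real,
noisier database material.

Test and reproduction problem sizes were chosen to keep the whole suite
fast on a single CPU: cohorts of 5–200 sequences of 120–300 residues,
oracle comparisons on sequences up to 200 residues, and Fisher checks on
2×2 tables with margins up to 30. The worked reference quantities (the
five printed codon decompositions and the dup21 unit length) are computed
from printed inputs in well under a second.

## Numerical and degenerate-input choices

* Empty FASTA files parse to empty record lists; header-only tables to
  zero-row data frames; empty notation strings to empty run lists.
* `0.0` E-values are preserved exactly; scientific notation is accepted.
* Strict alphabet mode (default) rejects ambiguity codes; lenient mode maps
  unknown protein residues to `X` and lets `N`-containing codons translate
  to `X`, with a warning.
* Ranked tables break count ties alphabetically; consensus columns break
  residue ties alphabetically.
* Fisher p-values are clamped to at most 1; BH q-values are monotone in
  p-rank by construction.
* Reports are pure functions of inputs and configuration; provenance
  records a configuration hash, the seed, and input file digests, and is
  excluded from body-identity comparisons.

## Known limitations

* The repeat merge rule requires a seed run; a tract composed entirely of
  sub-seed runs (e.g. alternating QQ P QQ P QQ) is not called even if its
  total reaches `min_total`. This is intentional — such sequences are
  better described as degenerate tandem repeats — but callers should know.
* Tier classification uses E-values only; identity and coverage filters, if
  wanted, must be applied upstream.
* The consensus builder assumes pre-aligned, equal-length input; it is not
  an aligner.
* Chimera prevalence estimates from `classify_cohort()` depend entirely on
  the completeness of the input domain annotations; unannotated extra
  domains are invisible.
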