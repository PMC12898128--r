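# ataxin2kit

Sequence-analysis toolkit for surveying the **Ataxin-2 protein family**
(human ATXN2/ATXN2L, plant CID3/CID4, yeast PBP1) across species. The
family's core is an LSm RNA-binding fold, the family-defining LSm-associated
domain (LSmAD), and the 14-residue PAM2 motif, embedded in long
intrinsically disordered regions that carry polyQ and related homopolymer
repeats — the repeats whose CAG-encoded expansion causes spinocerebellar
ataxia type 2 (SCA2) and contributes to ALS risk. The package is for
bioinformaticians running desk-scale family surveys: everything works
offline on FASTA files, InterPro-style domain tables, and BLAST tabular hit
files.

## What it computes

* **Repeat tracts** — `find_repeats()` calls homopolymer tracts (polyQ,
  polyA, polyP, polyS, polyG) with a seed-and-merge rule: pure runs of
  length ≥ `seed_min` seed a tract, runs separated by ≤ `max_gap`
  non-target residues merge, and a tract is reported when its target count
  reaches `min_total`. Repeat size is the target count *n* in the field's
  "nQ" notation, not tract width; purity, interruptions, and flanks are
  reported. `flank_interruption_stats()` ranks flanking and interrupting
  residues (counted per residue).
* **Codon decompositions** — `parse_runlength()` reads printed run-length
  codon notation such as `(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_`;
  `expand_runs()`, `translate_dna()`, `decompose_codons()`, and
  `summarize_repeat_dna()` connect DNA-level CAG/CAA structure to
  protein-level repeat calls.
* **Tandem duplications** — `find_tandem_duplications()` reports maximal
  arrays of primitive units (2–12 residues), phase-anchored at the right
  edge of the periodic tract, with `unit_len_nt = 3 × unit_len_aa` for
  comparison with base-pair phrasing of pathogenic variants (dup21, dup9).
* **PAM2 motif scanning** — `scan_motif()` scores windows against
  case-encoded consensus models (`score = Σ w·match / Σ w`, uppercase
  weight 1.0, lowercase 0.25); presets `PAM2_FULL_23`, `PAM2_PLANT_TANDEM`,
  `PAM2_CORE_10`.
* **Isoform candidates** — `enumerate_isoforms()` treats every Met as a
  candidate internal translation start and classifies retained domains
  (full / truncated / lost) and landmark zones; `zone_census()` tallies
  starts per zone.
* **Architecture chimerism** — `classify_architecture()` labels proteins
  canonical / partial / chimeric_N / chimeric_C / chimeric_both / irregular
  (LSmAD missing ⇒ at most partial) and flags unusual length (> 1000
  residues); `enrich_categories()` runs two-sided Fisher exact tests with
  BH adjustment over extra-domain functional categories.
* **Ortholog tiers** — `assign_tiers()` stratifies BLAST hits by LSmAD
  E-value (strict 1e-10, loose 5e-7) plus supporting-domain evidence;
  `bootstrap_iterate()` runs the iterative consensus search against
  injected (offline) search/fetch backends.
* **Synthetic cohorts** — `sim_repeat_cohort()`, `sim_motif_cohort()`,
  `sim_tandem_cohort()`, `sim_architecture_cohort()`, `sim_blast_strata()`
  generate seeded inputs with planted features and exact truth tables.

## Worked example

```r
library(ataxin2kit)

# the healthy-allele polyQ template: parse, expand, translate, count
runs <- parse_runlength("(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_")
summarize_repeat_dna(runs, target = "Q")
#> <repeat_codon_summary: 22Q over 22 codons, 0 interruption event(s), longest pure run 22>

# repeat calling on the human ATXN2 polyQ context (residues 156-202)
rec <- seq_record("Q99700_156_202",
                  reference_peptides()[["human_polyQ_context"]], "protein")
find_repeats(rec, repeat_config(target_residues = "Q"))
#>      sequence_id target_residue start end count_target n_interruptions
#> 1 Q99700_156_202              Q    11  33           23               0
#>   interruptions purity left_flank right_flank
#> 1                    1          P           P

# the pathogenic 21-bp tandem duplication in the exon-1A peptide
dup <- seq_record("dup21", reference_peptides()[["dup21_peptide"]], "protein")
find_tandem_duplications(dup)
#>   sequence_id    unit start copies unit_len_aa unit_len_nt
#> 1       dup21 PGCPRPA     5      2           7          21
```

The 23Q tract sits at local positions 11–33 flanked by prolines on both
sides — the proline framing that is characteristic of this repeat across
evolution — and the duplicated 7-residue unit corresponds to 21 coding base
pairs, matching the clinical description of the dup21 variant.

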