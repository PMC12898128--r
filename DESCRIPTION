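Package: ataxin2kit
Title: Repeat, Motif, and Domain-Architecture Analysis for Ataxin-2 Family Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-analysis toolkit for surveying Ataxin-2 (ATXN2) family
    proteins across species. Detects homopolymer repeat tracts (polyQ, polyA,
    polyP, polyS, polyG) with bounded interruptions and profiles their flanking
    and interrupting residues; parses, expands, and summarizes run-length codon
    notation for repeat-encoding DNA (CAG/CAA decompositions); finds tandem
    duplications of primitive peptide units; scans for degenerate PAM2-like
    short linear motifs with a case-encoded consensus; enumerates internal
    methionine translation starts and classifies the retained domain content of
    the resulting isoform candidates; classifies per-protein domain
    architectures as canonical, partial, or chimeric with Fisher-exact
    functional-category enrichment; and stratifies BLAST tabular hits into
    ortholog-candidate quality tiers with an offline, backend-injected
    consensus-bootstrapping loop. Seeded synthetic-data generators produce
    cohorts with planted features and truth tables so every stage is testable
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
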