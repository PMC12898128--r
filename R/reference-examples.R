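# Curated printed reference inputs from the Ataxin-2 family literature:
# run-length codon decompositions of polyQ-encoding DNA as reported for
# database entries, and short peptides around documented repeat/duplication
# features. These strings are the worked inputs used in examples, tests, and
# the reproduction script; they are inputs, not computed results.

#' Reference run-length codon strings for polyQ-encoding DNA
#'
#' Named character vector of repeat codon decompositions as printed in
#' sequence reports (the parser's notation dialect, including subscript
#' markup, bold markers around ATG, and line-break hyphens):
#' \describe{
#'   \item{canonical_healthy_allele}{The human ATXN2 healthy-allele repeat
#'     template, a CAA-interrupted CAG run encoding 22Q.}
#'   \item{gracilariopsis_chorda}{Uninterrupted 30Q repeat of the red alga
#'     (UniProt A0A2V3IVX2), mixed CAA/CAG usage.}
#'   \item{symbiodinium_necroappetens}{73Q repeat of the dinoflagellate
#'     (A0A813ABV5), interrupted at three positions by single Met residues
#'     (ATG triplets marked in bold).}
#'   \item{condylostylus_longicornis}{Uninterrupted 45Q repeat of the fly
#'     (NCBI XP_055375020.1 / XM_055519045.1).}
#'   \item{dictyostelium_discoideum}{Pure (CAA)29 run of the slime mold
#'     (Q55DE7), 29Q.}
#' }
#'
#' @return Named character vector of notation strings.
#' @export
reference_codon_strings <- function() {
  c(canonical_healthy_allele = "(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_",
    gracilariopsis_chorda = paste0(
      "(CAA)_3_CAG(CAA)_2_(CAG)_2_(CAA)_2_(CAG)_2_(CAA)_5_(CAG)_6_CAA",
      "(CAG)_2_(CAA)_4_"),
    symbiodinium_necroappetens = paste0(
      "CAG(CAA)_2_(CAG)_2_CAA**ATG**(CAG)_2_CAA(CAG)_2_CAA(CAG)_2_CAA",
      "(CAG)_2_CAA(CAG)_4_CAA(CAG)_2_CAA(CAG)_6_CAA(CAG)_3_CAA**ATG**",
      "(CAG)_2_CAA(CAG)_2_(CAA)_2_(CAG)_2_CAA(CAG)_2_CAA(CAG)_4_(CAA)_2_",
      "(CAG)_3_(CAA)_3_(CAG)_3_CAA(CAG)_2_CAA(CAG)_3_**ATG**CAG"),
    condylostylus_longicornis = paste0(
      "(CAA)_2_CAG(CAA)_7_CAG(CAA)_8_(CAG)_3_(CAA)_4_CAG(CAA)_5_CAG",
      "(CAA)_3_CAGCAA-(CAG)_3_(CAA)_4_"),
    dictyostelium_discoideum = "(CAA)_29_")
}

#' Reference peptides around documented repeat and duplication features
#'
#' Named character vector of printed peptides:
#' \describe{
#'   \item{human_polyQ_context}{Residues 156-202 of human ATXN2 (Q99700): the
#'     23Q repeat with its Pro-rich flanks.}
#'   \item{ostrich_polyA}{The polyAla analog of the repeat start in
#'     \emph{Struthio camelus} (XP_068766831.1), "MSLKQAAAAAQAA".}
#'   \item{primate_repeat_start}{The mammalian translation-start repeat
#'     context "MSLKPQQQQQQQQQQQQQQQQPPAAA" (XP_054298120.1).}
#'   \item{dup21_peptide}{Local 22-residue context of the pathogenic ATXN2
#'     21-bp tandem duplication (unit of 7 residues repeated twice).}
#'   \item{dup9_peptide}{Local 14-residue context of the 9-bp tandem
#'     duplication (unit "SGR" repeated twice).}
#' }
#'
#' @return Named character vector of peptide strings.
#' @export
reference_peptides <- function() {
  c(human_polyQ_context =
      "YGPLTMSLKPQQQQQQQQQQQQQQQQQQQQQQQPPPAAANVRKPGGS",
    ostrich_polyA = "MSLKQAAAAAQAA",
    primate_repeat_start = "MSLKPQQQQQQQQQQQQQQQQPPAAA",
    dup21_peptide = "ARPAPGCPRPAPGCPRPACEPV",
    dup9_peptide = "PARRSGRSGRGGGG")
}

#' Reported trypanosomatid PAM2 precursor core candidates
#'
#' The five candidate 10-residue PAM2 precursor cores reported for
#' euglenozoan Ataxin-2 family members, used to motivate the
#' `PAM2_CORE_10` preset.
#'
#' @return Named character vector of core sequences.
#' @export
reference_pam2_cores <- function() {
  c(perkinsela = "LNPNATAFLP",
    leishmania = "PNPSATPFVP",
    trypanosoma = "FNPAATPYTP",
    phytomonas = "PNPAAAPFVP",
    leptomonas = "PNPSATPFVP")
}
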