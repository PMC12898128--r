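# Tandem duplication detection in protein sequences.
#
# A tandem array is a stretch equal to a unit repeated >= 2 times. Units must
# be primitive (not themselves periodic); homopolymer arrays are left to the
# repeat finder via min_unit >= 2. Within each maximal periodic tract the
# reported phase is anchored at the RIGHT edge: a tandem duplication event
# appends the new copy after the original unit, so the novel junction sits at
# the right end of the periodicity (this reproduces decompositions like
# "ARPA PGCPRPA PGCPRPA CEPV" for the pathogenic ATXN2 dup21 variant, whose
# periodic tract extends further left than the duplicated unit itself).

primitive_period <- function(unit) {
  u <- nchar(unit)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        unit == paste(rep(substr(unit, 1L, p), u / p), collapse = ""))
      return(p)
  }
  u
}

#' Find tandem duplications of primitive peptide units
#'
#' Reports all maximal tandem arrays whose primitive unit length lies in
#' `[min_unit, max_unit]`. Arrays whose primitive period is below `min_unit`
#' (e.g. homopolymer stretches at `min_unit >= 2`) are dropped. `unit_len_nt`
#' is `3 * unit_len_aa` for direct comparison with base-pair phrasing of
#' coding-sequence duplications ("21 base pairs", "nine bases").
#'
#' @param record Protein [seq_record()].
#' @param min_unit Minimal unit length in residues (default 2).
#' @param max_unit Maximal unit length in residues (default 12).
#' @return Data frame with columns `sequence_id, unit, start, copies,
#'   unit_len_aa, unit_len_nt`, sorted by start then unit length.
#' @export
#' @examples
#' rec <- seq_record("dup21_peptide", "ARPAPGCPRPAPGCPRPACEPV", "protein")
#' find_tandem_duplications(rec)
find_tandem_duplications <- function(record, min_unit = 2L, max_unit = 12L) {
  assert_protein(record, "find_tandem_duplications")
  min_unit <- as.integer(min_unit); max_unit <- as.integer(max_unit)
  stopifnot(min_unit >= 1L, max_unit >= min_unit)
  s <- strsplit(record$residues, "", fixed = TRUE)[[1L]]
  n <- length(s)
  rows <- list()
  for (u in seq.int(min_unit, max_unit)) {
    if (2L * u > n) break
    eq <- s[seq_len(n - u)] == s[seq_len(n - u) + u]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u)) {
      reg_start <- starts[k]
      reg_end <- ends[k] + u           # periodic tract [reg_start, reg_end]
      reg_len <- reg_end - reg_start + 1L
      copies <- reg_len %/% u
      arr_start <- reg_end - copies * u + 1L
      unit <- paste(s[arr_start:(arr_start + u - 1L)], collapse = "")
      if (primitive_period(unit) != u) next  # reported at its primitive period
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = record$id, unit = unit, start = arr_start,
        copies = copies, unit_len_aa = u, unit_len_nt = 3L * u,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence_id = character(0), unit = character(0),
                      start = integer(0), copies = integer(0),
                      unit_len_aa = integer(0), unit_len_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$unit_len_aa), , drop = FALSE]
  rownames(df) <- NULL
  df
}
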