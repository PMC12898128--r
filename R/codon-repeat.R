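# Run-length codon notation: parse, expand, translate, summarize, decompose.
#
# The notation dialect mirrors how repeat-encoding DNA is printed in the
# Ataxin-2 literature: "(CAG)_8_" (subscript markup), "(CAG)8", and bare
# codons like "CAA" or "ATG", optionally joined by hyphens, whitespace, or
# "**" bold markers (all ignored), e.g. the canonical healthy-allele polyQ
# template "(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_".

#' Construct a codon run-length object
#' @param codon Character vector of 3-letter DNA codons.
#' @param count Positive integer vector of run lengths.
#' @return Data frame of class `codon_runs` with columns `codon`, `count`.
#' @export
codon_runs <- function(codon = character(0), count = integer(0)) {
  codon <- toupper(codon)
  count <- as.integer(count)
  stopifnot(length(codon) == length(count))
  if (length(codon)) {
    stopifnot(all(nchar(codon) == 3L),
              all(strsplit(paste(codon, collapse = ""), "")[[1L]] %in%
                    DNA_ALPHABET),
              all(count >= 1L))
  }
  df <- data.frame(codon = unname(codon), count = unname(count),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("codon_runs", "data.frame"))
}

#' Parse run-length codon notation
#'
#' Accepts tokens `(XYZ)_n_`, `(XYZ)n`, and bare `XYZ`; hyphens, whitespace,
#' and `**` bold markers are ignored. Textual run order is preserved (no
#' merging of adjacent equal codons; see [canonicalize_runs()]).
#'
#' @param text Notation string.
#' @return A [codon_runs()] object (empty for an empty string).
#' @export
#' @examples
#' parse_runlength("(CAG)_8_-CAA-(CAG)_4_-CAA-(CAG)_8_")
parse_runlength <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  cleaned <- gsub("\\*|-|\\s", "", text)
  n <- nchar(cleaned)
  codons <- character(0); counts <- integer(0)
  i <- 1L
  while (i <= n) {
    rest <- substr(cleaned, i, n)
    if (startsWith(rest, "(")) {
      close <- regexpr(")", rest, fixed = TRUE)
      if (close < 0L)
        stop(sprintf("parse error at offset %d: unclosed '('", i),
             call. = FALSE)
      codon <- substr(rest, 2L, close - 1L)
      if (nchar(codon) != 3L)
        stop(sprintf("parse error at offset %d: codon '%s' is not 3 bases",
                     i, codon), call. = FALSE)
      if (!all(strsplit(toupper(codon), "")[[1L]] %in% DNA_ALPHABET))
        stop(sprintf("parse error at offset %d: illegal base in '%s'",
                     i, codon), call. = FALSE)
      after <- substr(rest, close + 1L, nchar(rest))
      m <- regmatches(after, regexpr("^_?[0-9]+_?", after))
      if (!length(m))
        stop(sprintf("parse error at offset %d: missing run count after (%s)",
                     i + close, codon), call. = FALSE)
      cnt <- as.integer(gsub("_", "", m))
      if (is.na(cnt) || cnt < 1L)
        stop(sprintf("parse error at offset %d: run count must be >= 1",
                     i + close), call. = FALSE)
      codons <- c(codons, toupper(codon)); counts <- c(counts, cnt)
      i <- i + close + nchar(m)
    } else {
      codon <- substr(rest, 1L, 3L)
      if (nchar(codon) < 3L)
        stop(sprintf("parse error at offset %d: trailing token '%s' shorter than a codon",
                     i, codon), call. = FALSE)
      if (!all(strsplit(toupper(codon), "")[[1L]] %in% DNA_ALPHABET))
        stop(sprintf("parse error at offset %d: illegal base in '%s'",
                     i, codon), call. = FALSE)
      codons <- c(codons, toupper(codon)); counts <- c(counts, 1L)
      i <- i + 3L
    }
  }
  codon_runs(codons, counts)
}

#' Merge adjacent equal-codon runs into canonical form
#' @param runs A [codon_runs()] object.
#' @return A [codon_runs()] object in which adjacent runs have distinct codons.
#' @export
canonicalize_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(codon_runs(runs$codon, runs$count))
  grp <- cumsum(c(1L, as.integer(runs$codon[-1L] != runs$codon[-nrow(runs)])))
  codon_runs(tapply(runs$codon, grp, `[`, 1L),
             as.integer(tapply(runs$count, grp, sum)))
}

#' Expand codon runs to a DNA record
#' @param runs A [codon_runs()] object.
#' @param id Identifier for the resulting record.
#' @return A DNA [seq_record()] of length `3 * sum(count)`.
#' @export
expand_runs <- function(runs, id = "expanded") {
  seqs <- rep(runs$codon, runs$count)
  res <- paste(seqs, collapse = "")
  if (!nzchar(res)) res <- ""
  structure(list(id = id, description = "", alphabet = "dna",
                 residues = res), class = "seq_record")
}

#' Translate a DNA record with the standard genetic code
#'
#' Length must be a multiple of three. In strict mode an internal stop codon
#' is an error; in lenient mode codons containing `N` translate to `X`.
#'
#' @param dna DNA [seq_record()].
#' @param strict Logical; default `TRUE`.
#' @return A protein [seq_record()].
#' @export
translate_dna <- function(dna, strict = TRUE) {
  assert_dna(dna, "translate_dna")
  n <- nchar(dna$residues)
  if (n %% 3L != 0L)
    stop(sprintf("record '%s': length %d not divisible by 3", dna$id, n),
         call. = FALSE)
  if (n == 0L)
    return(structure(list(id = dna$id, description = dna$description,
                          alphabet = "protein", residues = ""),
                     class = "seq_record"))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna$residues),
    if.fuzzy.codon = if (strict) "error" else "X"))
  if (grepl("*", aa, fixed = TRUE)) {
    if (strict)
      stop(sprintf("record '%s': stop codon at codon %d", dna$id,
                   regexpr("*", aa, fixed = TRUE)[1L]), call. = FALSE)
    warning(sprintf("record '%s': stop codon retained as '*'", dna$id),
            call. = FALSE)
  }
  seq_record(dna$id, aa, "protein", description = dna$description,
             strict = FALSE)
}

#' Decompose a DNA record into canonical codon runs
#'
#' Inverse of [expand_runs()] up to canonicalization:
#' `expand_runs(decompose_codons(d))` reproduces `d`.
#'
#' @param dna DNA [seq_record()] with length divisible by 3.
#' @return A canonical [codon_runs()] object.
#' @export
decompose_codons <- function(dna) {
  assert_dna(dna, "decompose_codons")
  n <- nchar(dna$residues)
  if (n %% 3L != 0L)
    stop(sprintf("record '%s': length %d not divisible by 3", dna$id, n),
         call. = FALSE)
  if (n == 0L) return(codon_runs())
  starts <- seq.int(1L, n, by = 3L)
  cods <- substring(dna$residues, starts, starts + 2L)
  r <- rle(cods)
  codon_runs(r$values, r$lengths)
}

#' Summarize repeat-encoding DNA at codon level
#'
#' Expands and translates the runs, then reports the repeat structure with
#' respect to a target amino acid: total target count, maximal non-target
#' interruption events, codon usage among target-encoding codons, and the
#' longest pure target run.
#'
#' @param runs A [codon_runs()] object.
#' @param target Single amino-acid letter, default `"Q"`.
#' @return List of class `repeat_codon_summary` with elements `target`,
#'   `total_target`, `interruption_events` (data frame `codon_start`,
#'   `codon_end`, `residues`), `codon_usage` (named integer vector),
#'   `longest_pure_run`, `total_codons`.
#' @export
summarize_repeat_dna <- function(runs, target = "Q") {
  stopifnot(nchar(target) == 1L)
  target <- toupper(target)
  dna <- expand_runs(runs)
  prot <- translate_dna(dna)
  aa <- strsplit(prot$residues, "", fixed = TRUE)[[1L]]
  total_codons <- length(aa)
  is_t <- aa == target
  events <- data.frame(codon_start = integer(0), codon_end = integer(0),
                       residues = character(0), stringsAsFactors = FALSE)
  longest <- 0L
  if (total_codons) {
    r <- rle(is_t)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    nt <- which(!r$values)
    if (length(nt)) {
      events <- data.frame(
        codon_start = starts[nt], codon_end = ends[nt],
        residues = vapply(nt, function(k) {
          paste(aa[starts[k]:ends[k]], collapse = "")
        }, character(1L)),
        stringsAsFactors = FALSE)
    }
    if (any(r$values)) longest <- max(r$lengths[r$values])
  }
  starts3 <- seq_len(total_codons) * 3L - 2L
  cods <- substring(dna$residues, starts3, starts3 + 2L)
  usage_tab <- table(cods[is_t])
  usage <- stats::setNames(as.integer(usage_tab), names(usage_tab))
  structure(list(target = target, total_target = sum(is_t),
                 interruption_events = events, codon_usage = usage,
                 longest_pure_run = as.integer(longest),
                 total_codons = total_codons),
            class = "repeat_codon_summary")
}

#' @export
print.repeat_codon_summary <- function(x, ...) {
  cat(sprintf("<repeat_codon_summary: %d%s over %d codons, %d interruption event(s), longest pure run %d>\n",
              x$total_target, x$target, x$total_codons,
              nrow(x$interruption_events), x$longest_pure_run))
  invisible(x)
}
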