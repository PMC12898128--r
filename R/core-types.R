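#' @title Sequence records and shared coordinate conventions
#'
#' @description All coordinates in this package are 1-based inclusive, matching
#'   residue numbering in protein databases (e.g. the human ATXN2 LSmAD at
#'   residues 409-477). Internal code may use 0-based half-open intervals but
#'   never exposes them.
#' @name coordinates
NULL

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                      "M","N","P","Q","R","S","T","V","W","Y","X")
DNA_ALPHABET <- c("A","C","G","T")

#' Create a sequence record
#'
#' A `seq_record` is the package's basic container: a named protein or DNA
#' sequence with an alphabet tag. Residues are stored uppercase.
#'
#' @param id Character identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param residues Character scalar of residues over the declared alphabet.
#' @param alphabet Either `"protein"` or `"dna"`.
#' @param description Free-text description (rest of the FASTA header).
#' @param strict If `TRUE` (default), residues outside the declared alphabet
#'   are an error. If `FALSE`, unknown protein residues are mapped to `X`
#'   (DNA keeps `N`, which translates to `X`), with a warning.
#' @return An object of class `seq_record`.
#' @export
#' @examples
#' seq_record("x", "acgt", "dna")
seq_record <- function(id, residues, alphabet = c("protein", "dna"),
                       description = "", strict = TRUE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else DNA_ALPHABET
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    if (strict) {
      stop(sprintf("record '%s': illegal %s residue '%s' at position %d",
                   id, alphabet, chars[bad[1L]], bad[1L]), call. = FALSE)
    }
    if (alphabet == "protein") {
      chars[bad] <- "X"
      residues <- paste(chars, collapse = "")
      warning(sprintf("record '%s': %d unknown residue(s) mapped to X",
                      id, length(bad)), call. = FALSE)
    } else {
      nonN <- bad[chars[bad] != "N"]
      if (length(nonN)) {
        stop(sprintf("record '%s': illegal dna base '%s' at position %d",
                     id, chars[nonN[1L]], nonN[1L]), call. = FALSE)
      }
      warning(sprintf("record '%s': contains N; affected codons translate to X",
                      id), call. = FALSE)
    }
  }
  structure(list(id = id, description = description,
                 alphabet = alphabet, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  res <- x$residues
  shown <- if (nchar(res) > 60L) paste0(substr(res, 1L, 57L), "...") else res
  cat(sprintf("<seq_record %s [%s, %d] %s>\n",
              x$id, x$alphabet, nchar(x$residues), shown))
  invisible(x)
}

#' Sequence length of a record
#' @param x A `seq_record`.
#' @return Integer number of residues.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "seq_record"))
  nchar(x$residues)
}

is_protein <- function(x) inherits(x, "seq_record") && x$alphabet == "protein"
is_dna     <- function(x) inherits(x, "seq_record") && x$alphabet == "dna"

assert_protein <- function(x, fun) {
  if (!inherits(x, "seq_record"))
    stop(sprintf("%s() expects a seq_record", fun), call. = FALSE)
  if (x$alphabet != "protein")
    stop(sprintf("%s() requires a protein record, got alphabet '%s' for '%s'",
                 fun, x$alphabet, x$id), call. = FALSE)
  invisible(TRUE)
}

assert_dna <- function(x, fun) {
  if (!inherits(x, "seq_record"))
    stop(sprintf("%s() expects a seq_record", fun), call. = FALSE)
  if (x$alphabet != "dna")
    stop(sprintf("%s() requires a dna record, got alphabet '%s' for '%s'",
                 fun, x$alphabet, x$id), call. = FALSE)
  invisible(TRUE)
}

res_at <- function(record, pos) substr(record$residues, pos, pos)

#' Validate domain annotations against a sequence record
#'
#' Domain annotations are rows of a data frame with columns `protein_id`,
#' `label`, `start`, `end` (1-based inclusive) and optionally `source`.
#'
#' @param domains Data frame of domain annotations.
#' @param record Optional `seq_record` the annotations must fit inside.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_domains <- function(domains, record = NULL) {
  req <- c("protein_id", "label", "start", "end")
  miss <- setdiff(req, names(domains))
  if (length(miss))
    stop("domain table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  bad <- which(is.na(domains$start) | is.na(domains$end) |
                 domains$start < 1L | domains$start > domains$end)
  if (length(bad))
    stop(sprintf("domain table row %d: invalid coordinates (start %s, end %s)",
                 bad[1L], domains$start[bad[1L]], domains$end[bad[1L]]),
         call. = FALSE)
  if (!is.null(record)) {
    n <- seq_length(record)
    out <- which(domains$end > n)
    if (length(out))
      stop(sprintf(
        "domain '%s' (%d-%d) exceeds length %d of record '%s'",
        domains$label[out[1L]], domains$start[out[1L]], domains$end[out[1L]],
        n, record$id), call. = FALSE)
  }
  domains
}
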