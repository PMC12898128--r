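# File I/O: FASTA via Biostrings, domain tables as header TSV, BLAST hits as
# 12-column outfmt-6 tabular.

#' Read a FASTA file into sequence records
#'
#' Order is preserved, residues are uppercased, CRLF line endings and any
#' line-wrapping are tolerated.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param strict Passed to [seq_record()]: reject residues outside the
#'   alphabet (`TRUE`, default) or coerce them with a warning.
#' @return List of [seq_record()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), strict = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    if (is.na(header) || !nzchar(trimws(header)))
      stop(sprintf("malformed FASTA header for record %d in %s", i, path),
           call. = FALSE)
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    out[[i]] <- seq_record(id, as.character(set[[i]]), alphabet,
                           description = desc, strict = strict)
  }
  out
}

#' Write sequence records to FASTA
#'
#' Output is wrapped at 60 columns.
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, character(1L))
  hdrs <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1L))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a domain annotation table
#'
#' Tab-separated file with header columns `protein_id`, `label`, `start`,
#' `end` and optionally `source`. Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations in file order (zero rows for a
#'   header-only file).
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  req <- c("protein_id", "label", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("domain table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"source" %in% names(df)) df$source <- rep("", nrow(df))
  if (nrow(df) == 0L) return(df[, c(req, "source")])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end | df$start < 1L)
  if (length(bad))
    stop(sprintf("%s row %d: start > end or non-integer coordinates",
                 path, bad[1L]), call. = FALSE)
  df[, c(req, "source")]
}

#' Write a domain annotation table
#' @param domains Data frame with `protein_id`, `label`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(domains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity", "align_length",
                 "mismatches", "gap_opens", "query_start", "query_end",
                 "subject_start", "subject_end", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Twelve tab-separated columns in the standard order; scientific-notation
#' E-values are accepted and `0.0` is preserved.
#'
#' @param path Path to the hit table.
#' @return Data frame of hits in file order, columns named
#'   `query_id, subject_id, percent_identity, align_length, mismatches,
#'   gap_opens, query_start, query_end, subject_start, subject_end, evalue,
#'   bitscore`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12L),
                                        BLAST6_COLS))
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop(sprintf("%s line %d: expected 12 tab-separated columns, found %d",
                 path, bad[1L], nf[bad[1L]]), call. = FALSE)
  m <- do.call(rbind, fields)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   percent_identity = as.numeric(m[, 3L]),
                   align_length = as.integer(m[, 4L]),
                   mismatches = as.integer(m[, 5L]),
                   gap_opens = as.integer(m[, 6L]),
                   query_start = as.integer(m[, 7L]),
                   query_end = as.integer(m[, 8L]),
                   subject_start = as.integer(m[, 9L]),
                   subject_end = as.integer(m[, 10L]),
                   evalue = as.numeric(m[, 11L]),
                   bitscore = as.numeric(m[, 12L]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$evalue) || any(df$evalue < 0))
    stop(path, ": non-numeric or negative E-value", call. = FALSE)
  if (any(df$query_start > df$query_end) ||
      any(df$subject_start > df$subject_end))
    stop(path, ": start > end on query or subject axis", call. = FALSE)
  df
}

#' Read an optional taxonomy mapping
#'
#' Tab-separated file with header columns `subject_id` and `taxon`.
#' @param path Path to the TSV file.
#' @return Named character vector mapping subject ids to taxa.
#' @export
read_taxonomy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "taxon") %in% names(df)))
    stop("taxonomy table needs columns subject_id, taxon", call. = FALSE)
  stats::setNames(as.character(df$taxon), df$subject_id)
}
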