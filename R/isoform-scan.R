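# Internal translation-start (Met) enumeration and isoform classification.
#
# Every methionine is a candidate internal start. For each candidate, each
# annotated domain is "full" if the start lies at or before the domain start,
# "truncated" if it lies inside the domain, and "lost" if it lies after the
# domain end. The candidate's zone is computed from the core-domain landmarks
# (LSm, LSmAD, PAM2) that are actually annotated: when a core domain is
# missing, its two flanking zones merge, and zone names always reflect the
# nearest annotated landmarks (e.g. with no LSmAD annotation the region
# between LSm and PAM2 is the single zone "LSm_to_PAM2").

CORE_DOMAIN_ORDER <- c("LSm", "LSmAD", "PAM2")

#' Enumerate candidate internal translation starts
#'
#' @param record Protein [seq_record()].
#' @param domains Data frame of domain annotations for this record
#'   (`protein_id`, `label`, `start`, `end`); may be missing core domains.
#' @param core_labels Core landmark labels in N-to-C order; default
#'   `c("LSm", "LSmAD", "PAM2")`.
#' @return Data frame with one row per Met in position order: `protein_id,
#'   met_position, length_aa, zone`, plus one `status_<label>` column per
#'   annotated core domain (values `full`, `truncated`, `lost`) and
#'   `retained_domains` (comma-joined `label:status` over all annotated
#'   domains).
#' @export
enumerate_isoforms <- function(record, domains,
                               core_labels = CORE_DOMAIN_ORDER) {
  assert_protein(record, "enumerate_isoforms")
  domains <- validate_domains(domains, record)
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1L]]
  mets <- which(chars == "M")
  core <- domains[domains$label %in% core_labels, , drop = FALSE]
  core <- core[order(core$start), , drop = FALSE]
  n <- seq_length(record)
  empty <- data.frame(protein_id = character(0), met_position = integer(0),
                      length_aa = integer(0), zone = character(0),
                      retained_domains = character(0),
                      stringsAsFactors = FALSE)
  if (!length(mets)) return(empty)
  zone_of <- function(pos) {
    if (nrow(core) == 0L) return("no_core_annotation")
    for (i in seq_len(nrow(core))) {
      if (pos < core$start[i]) {
        return(if (i == 1L) paste0("pre_", core$label[i])
               else paste0(core$label[i - 1L], "_to_", core$label[i]))
      }
      if (pos <= core$end[i]) return(paste0("within_", core$label[i]))
    }
    paste0("post_", core$label[nrow(core)])
  }
  status_of <- function(pos, d_start, d_end) {
    if (pos <= d_start) "full" else if (pos <= d_end) "truncated" else "lost"
  }
  rows <- lapply(mets, function(pos) {
    statuses <- character(0)
    if (nrow(domains)) {
      statuses <- vapply(seq_len(nrow(domains)), function(i) {
        status_of(pos, domains$start[i], domains$end[i])
      }, character(1L))
    }
    out <- data.frame(protein_id = record$id, met_position = pos,
                      length_aa = n - pos + 1L, zone = zone_of(pos),
                      retained_domains = paste(
                        paste0(domains$label, ":", statuses), collapse = ","),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(core)))
      out[[paste0("status_", core$label[i])]] <-
        status_of(pos, core$start[i], core$end[i])
    out
  })
  do.call(rbind, rows)
}

#' Count isoform candidates per zone
#'
#' @param candidates Data frame from [enumerate_isoforms()].
#' @return Named integer vector, one entry per observed zone; counts sum to
#'   the number of candidates.
#' @export
zone_census <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(candidates$zone)
  stats::setNames(as.integer(tab), names(tab))
}
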