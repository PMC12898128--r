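# Quality-tier classification of ortholog candidates and the offline
# LSmAD-anchored consensus-bootstrapping loop.
#
# Tier rules are anchored to the two E-value thresholds in routine use for
# this family (1e-10 for high-significance LSmAD hits, 5e-7 for looser
# homology) and to the principle that LSmAD defines the family:
#   tier1: best LSmAD E-value <= strict AND at least one supporting-domain
#          hit (any E-value) among `supporting_labels`;
#   tier2: best LSmAD E-value <= strict, no supporting hit;
#   tier3: strict < best LSmAD E-value <= loose;
#   rejected: no LSmAD hit, LSmAD E-value > loose, or taxonomy-filtered.
# Thresholds and the supporting set are configurable.

#' Tier classification configuration
#'
#' @param strict_threshold High-significance LSmAD E-value bound
#'   (default `1e-10`).
#' @param loose_threshold Looser homology bound (default `5e-7`).
#' @param supporting_labels Query domain labels that promote tier2 to tier1
#'   (default `c("LSm", "PAM2")`).
#' @param taxonomy_include,taxonomy_exclude Optional taxon sets; with a
#'   non-empty include set, subjects outside it are rejected; subjects in the
#'   exclude set are always rejected.
#' @param max_iter Maximal bootstrap iterations (default 10).
#' @return List of class `tier_config`.
#' @export
tier_config <- function(strict_threshold = 1e-10, loose_threshold = 5e-7,
                        supporting_labels = c("LSm", "PAM2"),
                        taxonomy_include = character(0),
                        taxonomy_exclude = character(0),
                        max_iter = 10L) {
  stopifnot(strict_threshold <= loose_threshold, strict_threshold >= 0,
            max_iter >= 1L)
  structure(list(strict_threshold = strict_threshold,
                 loose_threshold = loose_threshold,
                 supporting_labels = supporting_labels,
                 taxonomy_include = taxonomy_include,
                 taxonomy_exclude = taxonomy_exclude,
                 max_iter = as.integer(max_iter)),
            class = "tier_config")
}

#' Assign quality tiers to BLAST hit subjects
#'
#' One assignment per distinct subject; the best (minimal) E-value per
#' (subject, query domain label) is used, so the result is invariant to
#' hit-row order.
#'
#' @param hits Data frame from [read_blast_tabular()] (needs `query_id`,
#'   `subject_id`, `evalue`).
#' @param query_labels Named character vector mapping every query id to a
#'   domain label (e.g. `c(q_lsmad = "LSmAD", q_lsm = "LSm")`).
#' @param config A [tier_config()].
#' @param taxonomy Optional named character vector mapping subject ids to
#'   taxa for include/exclude filtering.
#' @return Data frame `subject_id, tier, lsmad_evalue, supporting_labels,
#'   taxonomy_ok, evidence` (evidence: comma-joined `label=best_evalue`),
#'   sorted by subject id.
#' @export
assign_tiers <- function(hits, query_labels, config = tier_config(),
                         taxonomy = NULL) {
  unmapped <- setdiff(unique(hits$query_id), names(query_labels))
  if (length(unmapped))
    stop("unmapped query id(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  subjects <- sort(unique(hits$subject_id))
  rows <- lapply(subjects, function(sid) {
    h <- hits[hits$subject_id == sid, , drop = FALSE]
    labs <- unname(query_labels[h$query_id])
    best <- tapply(h$evalue, labs, min)
    lsmad_e <- if ("LSmAD" %in% names(best)) unname(best[["LSmAD"]]) else NA_real_
    supp <- intersect(names(best), config$supporting_labels)
    tax_ok <- TRUE
    if (!is.null(taxonomy)) {
      taxon <- if (sid %in% names(taxonomy)) taxonomy[[sid]] else NA_character_
      if (length(config$taxonomy_include) &&
          !(isTRUE(taxon %in% config$taxonomy_include))) tax_ok <- FALSE
      if (isTRUE(taxon %in% config$taxonomy_exclude)) tax_ok <- FALSE
    }
    tier <- if (!tax_ok || is.na(lsmad_e) ||
                lsmad_e > config$loose_threshold) {
      "rejected"
    } else if (lsmad_e <= config$strict_threshold) {
      if (length(supp)) "tier1" else "tier2"
    } else {
      "tier3"
    }
    data.frame(subject_id = sid, tier = tier, lsmad_evalue = lsmad_e,
               supporting_labels = paste(sort(supp), collapse = ","),
               taxonomy_ok = tax_ok,
               evidence = paste(sprintf("%s=%g", names(best),
                                        as.numeric(best)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Column-wise majority consensus of pre-aligned sequences
#'
#' Ties are broken by the alphabetically first residue. The gap character
#' `"-"` wins a column only if it is a strict majority; otherwise the most
#' common residue wins.
#'
#' @param seqs Character vector of equal-length (pre-aligned) sequences.
#' @param gap Gap character, default `"-"`.
#' @return Consensus string.
#' @export
build_consensus <- function(seqs, gap = "-") {
  stopifnot(length(seqs) >= 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("consensus input sequences must have equal length", call. = FALSE)
  if (length(seqs) == 1L) return(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cols <- apply(mat, 2L, function(col) {
    tab <- table(col)
    n <- length(col)
    if (gap %in% names(tab) && tab[[gap]] * 2L > n) return(gap)
    res <- tab[names(tab) != gap]
    if (!length(res)) return(gap)
    winners <- names(res)[res == max(res)]
    sort(winners)[1L]
  })
  paste(cols, collapse = "")
}

#' Iterative consensus bootstrapping over a pluggable search backend
#'
#' Repeats: search with the current query, assign tiers, rebuild the query as
#' the consensus of the tier1 subjects' (pre-aligned) sequences. Stops when a
#' search round returns the same tier1 subject set as the previous round
#' (fixpoint) or after `max_iter` rounds. The confirming round is not counted:
#' `iterations` is the number of productive update rounds before the fixpoint
#' was observed.
#'
#' @param seed_query Initial query string.
#' @param search Function `query -> hits data frame` (BLAST tabular schema).
#' @param fetch Function `subject_id -> aligned sequence string`.
#' @param config A [tier_config()].
#' @param query_labels Mapping from the backend's query ids to domain labels;
#'   by default every query id reported by the backend is treated as the
#'   LSmAD anchor.
#' @param taxonomy Optional taxonomy mapping, as in [assign_tiers()].
#' @return List `tiers` (final tier table), `iterations`, `converged`,
#'   `final_query`.
#' @export
bootstrap_iterate <- function(seed_query, search, fetch,
                              config = tier_config(), query_labels = NULL,
                              taxonomy = NULL) {
  query <- seed_query
  prev_t1 <- NULL
  tiers <- NULL
  for (i in seq_len(config$max_iter)) {
    hits <- tryCatch(search(query), error = function(e) {
      stop(sprintf("search backend failed at iteration %d: %s",
                   i, conditionMessage(e)), call. = FALSE)
    })
    labels <- query_labels
    if (is.null(labels)) {
      qids <- unique(hits$query_id)
      labels <- stats::setNames(rep("LSmAD", length(qids)), qids)
    }
    tiers <- assign_tiers(hits, labels, config, taxonomy)
    t1 <- sort(tiers$subject_id[tiers$tier == "tier1"])
    if (!is.null(prev_t1) && identical(t1, prev_t1)) {
      return(list(tiers = tiers, iterations = i - 1L, converged = TRUE,
                  final_query = query))
    }
    prev_t1 <- t1
    if (length(t1)) {
      seqs <- vapply(t1, function(sid) {
        tryCatch(fetch(sid), error = function(e) {
          stop(sprintf("fetch backend failed at iteration %d for '%s': %s",
                       i, sid, conditionMessage(e)), call. = FALSE)
        })
      }, character(1L))
      query <- build_consensus(unname(seqs))
    }
  }
  list(tiers = tiers, iterations = config$max_iter, converged = FALSE,
       final_query = query)
}
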