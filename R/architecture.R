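# Domain-architecture chimerism classification and functional-category
# enrichment.
#
# The Ataxin-2 family is defined by the LSmAD domain; a protein without an
# annotated LSmAD is at most "partial". An "extra" is any annotated domain
# outside the core label set (IDRs are never annotated domains). Extras lying
# entirely upstream of the first core domain make the protein an N-terminal
# chimera; entirely downstream of the last core domain, a C-terminal chimera;
# extras overlapping a core span get side "internal" and verdict "irregular"
# (not observed in curated architectures; a guard). Proteins longer than
# `long_threshold` residues (default 1000, the usual screen for orthologs
# carrying further domains of known function) are flagged `unusual_length`.

#' Classify one protein's domain architecture
#'
#' @param record_length Protein length in residues.
#' @param domains Data frame of domain annotations for this protein
#'   (`protein_id`, `label`, `start`, `end`).
#' @param core_labels Core domain labels; default `c("LSm","LSmAD","PAM2")`.
#' @param long_threshold Length above which `unusual_length` is `TRUE`
#'   (default 1000).
#' @return List of class `architecture_call`: `protein_id, length_aa,
#'   core_present, core_in_order, extras` (data frame `label`, `side`),
#'   `verdict` (one of canonical, partial, chimeric_N, chimeric_C,
#'   chimeric_both, irregular), `unusual_length`.
#' @export
classify_architecture <- function(record_length, domains,
                                  core_labels = CORE_DOMAIN_ORDER,
                                  long_threshold = 1000L) {
  domains <- validate_domains(domains)
  record_length <- as.integer(record_length)
  if (any(domains$end > record_length))
    stop("domain exceeds protein length", call. = FALSE)
  protein_id <- if (nrow(domains)) domains$protein_id[1L] else NA_character_
  is_core <- domains$label %in% core_labels
  core <- domains[is_core, , drop = FALSE]
  extras <- domains[!is_core, , drop = FALSE]
  core_present <- intersect(core_labels, core$label)
  core_by_start <- core$label[order(core$start)]
  core_in_order <- identical(unique(core_by_start),
                             intersect(core_labels, unique(core_by_start)))
  side <- character(0)
  if (nrow(extras)) {
    first_core_start <- if (nrow(core)) min(core$start) else Inf
    last_core_end <- if (nrow(core)) max(core$end) else -Inf
    side <- vapply(seq_len(nrow(extras)), function(i) {
      if (extras$end[i] < first_core_start) "N"
      else if (extras$start[i] > last_core_end) "C"
      else "internal"
    }, character(1L))
  }
  extras_df <- data.frame(label = extras$label, side = side,
                          stringsAsFactors = FALSE)
  has_lsmad <- "LSmAD" %in% core_present
  verdict <- if (any(side == "internal")) {
    "irregular"
  } else if (!has_lsmad) {
    "partial"
  } else if (any(side == "N") && any(side == "C")) {
    "chimeric_both"
  } else if (any(side == "N")) {
    "chimeric_N"
  } else if (any(side == "C")) {
    "chimeric_C"
  } else if (setequal(core_present, core_labels) && core_in_order) {
    "canonical"
  } else {
    "partial"
  }
  structure(list(protein_id = protein_id, length_aa = record_length,
                 core_present = core_present, core_in_order = core_in_order,
                 extras = extras_df, verdict = verdict,
                 unusual_length = record_length > long_threshold),
            class = "architecture_call")
}

#' Classify a cohort of architectures
#'
#' @param lengths Named integer vector or data frame (`protein_id`,
#'   `length_aa`) of protein lengths.
#' @param domains Domain annotation data frame covering the cohort.
#' @param core_labels,long_threshold As in [classify_architecture()].
#' @return Data frame with one row per protein: `protein_id, length_aa,
#'   verdict, unusual_length, n_extras, extra_labels, extra_sides,
#'   core_present`.
#' @export
classify_cohort <- function(lengths, domains,
                            core_labels = CORE_DOMAIN_ORDER,
                            long_threshold = 1000L) {
  if (is.data.frame(lengths))
    lengths <- stats::setNames(as.integer(lengths$length_aa),
                               lengths$protein_id)
  rows <- lapply(names(lengths), function(pid) {
    d <- domains[domains$protein_id == pid, , drop = FALSE]
    call <- classify_architecture(lengths[[pid]], d, core_labels,
                                  long_threshold)
    data.frame(protein_id = pid, length_aa = call$length_aa,
               verdict = call$verdict,
               unusual_length = call$unusual_length,
               n_extras = nrow(call$extras),
               extra_labels = paste(call$extras$label, collapse = ","),
               extra_sides = paste(call$extras$side, collapse = ","),
               core_present = paste(call$core_present, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Functional-category enrichment among chimeric extra domains
#'
#' For each category observed among chimera extras, a two-sided Fisher exact
#' test ("sum of tables at most as probable as the observed one") compares
#' category membership among chimera extras against a background census, with
#' Benjamini-Hochberg adjustment across categories. No significance filter is
#' applied; all observed categories are reported.
#'
#' @param calls Data frame from [classify_cohort()] (or any table with
#'   `verdict` and `extra_labels`).
#' @param category_map Named character vector mapping extra-domain labels to
#'   functional categories; unmapped labels fall into `"other"`.
#' @param background Named integer vector: category census of a reference
#'   domain population.
#' @return Data frame `category, count_in_chimeras, total_chimera_extras,
#'   count_in_background, total_background, p_value, q_value`, ordered by
#'   p-value.
#' @export
enrich_categories <- function(calls, category_map, background) {
  if (is.null(background) || !length(background) || sum(background) == 0)
    stop("empty background census", call. = FALSE)
  chim <- calls[grepl("^chimeric", calls$verdict), , drop = FALSE]
  labels <- unlist(strsplit(chim$extra_labels[nzchar(chim$extra_labels)],
                            ",", fixed = TRUE), use.names = FALSE)
  if (!length(labels)) {
    return(data.frame(category = character(0), count_in_chimeras = integer(0),
                      total_chimera_extras = integer(0),
                      count_in_background = integer(0),
                      total_background = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cats <- ifelse(labels %in% names(category_map),
                 unname(category_map[labels]), "other")
  total_chim <- length(cats)
  total_bg <- sum(background)
  obs <- table(cats)
  rows <- lapply(names(obs), function(cat) {
    a <- as.integer(obs[[cat]])
    bg_cat <- if (cat %in% names(background)) as.integer(background[[cat]])
              else 0L
    tab <- matrix(c(a, total_chim - a, bg_cat, total_bg - bg_cat), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(category = cat, count_in_chimeras = a,
               total_chimera_extras = total_chim,
               count_in_background = bg_cat, total_background = total_bg,
               p_value = min(p, 1), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  df <- df[order(df$p_value, df$category), , drop = FALSE]
  rownames(df) <- NULL
  df
}
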