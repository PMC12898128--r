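# Cohort report assembly: a deterministic bundle of per-module result tables
# with a provenance block. TSV is the authoritative on-disk form; JSON mirrors
# it exactly.

REPORT_SECTION_ORDER <- c("repeats", "flank_stats", "codon_summaries",
                          "tandem", "motif", "isoforms", "zone_census",
                          "architecture", "enrichment", "tiers")

#' Assemble a cohort report
#'
#' @param sections Named list of result tables (data frames); recognised
#'   names: `repeats, flank_stats, codon_summaries, tandem, motif, isoforms,
#'   zone_census, architecture, enrichment, tiers`. Missing sections are
#'   omitted, not nulled.
#' @param config Optional list of configuration objects used to produce the
#'   results; hashed into the provenance block.
#' @param seed Optional seed recorded in provenance.
#' @param input_files Optional character vector of input paths; their md5
#'   digests are recorded.
#' @param ids_universe Optional character vector of known sequence/protein
#'   ids; ids appearing in section tables but absent from the universe are an
#'   error (listed in the message).
#' @return List of class `cohort_report` with elements `sections` (in
#'   deterministic order) and `provenance`.
#' @export
build_report <- function(sections, config = list(), seed = NULL,
                         input_files = character(0), ids_universe = NULL) {
  stopifnot(is.list(sections), length(sections) >= 1L)
  unknown <- setdiff(names(sections), REPORT_SECTION_ORDER)
  if (length(unknown))
    stop("unknown report section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ordered <- sections[intersect(REPORT_SECTION_ORDER, names(sections))]
  if (!is.null(ids_universe)) {
    bad <- character(0)
    for (nm in names(ordered)) {
      tab <- ordered[[nm]]
      idcol <- intersect(c("sequence_id", "protein_id"), names(tab))
      if (length(idcol))
        bad <- c(bad, setdiff(tab[[idcol[1L]]], ids_universe))
    }
    bad <- sort(unique(bad))
    if (length(bad))
      stop("sequence id(s) not in the declared universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg_hash <- {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    saveRDS(config, tmp, version = 2L)
    unname(tools::md5sum(tmp))
  }
  digests <- if (length(input_files)) {
    stats::setNames(unname(tools::md5sum(input_files)),
                    basename(input_files))
  } else character(0)
  prov <- list(tool = "ataxin2kit",
               version = as.character(utils::packageVersion("ataxin2kit")),
               config_hash = cfg_hash, seed = seed,
               input_digests = as.list(digests))
  structure(list(sections = ordered, provenance = prov),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' One TSV per section plus a single JSON mirror (`report.json`).
#'
#' @param report A [build_report()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  json_body <- list()
  for (nm in names(report$sections)) {
    tab <- report$sections[[nm]]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (is.data.frame(tab)) {
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      json_body[[nm]] <- tab
    } else {
      df <- data.frame(key = names(tab), value = unname(unlist(tab)),
                       stringsAsFactors = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      json_body[[nm]] <- as.list(tab)
    }
    paths <- c(paths, p)
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(sections = json_body,
                            provenance = report$provenance),
                       jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}
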