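# Homopolymer repeat detection with bounded interruptions.
#
# Seed-and-merge rule: maximal pure runs of the target residue of length >=
# seed_min act as seeds; consecutive runs separated by <= max_gap non-target
# residues are chained greedily. A chain is reported when it contains at least
# one seed and its target-residue count reaches min_total. Tract width counts
# interruption residues, but repeat size is reported as the target count
# (polyQ tracts are sized by Q count, e.g. a 73Q tract with 3 interruptions).

#' Repeat detection configuration
#'
#' @param target_residues Amino acids to scan for; default the five repeat
#'   types common in Ataxin-2 N-terminal regions (Q, A, P, S, G).
#' @param seed_min Minimal pure run length that can seed a tract (default 3).
#' @param max_gap Maximal length of an interrupting non-target run that may be
#'   bridged (default 2, accommodating single or double interrupting residues).
#' @param min_total Minimal number of target residues for a reported tract
#'   (default 6, i.e. tracts with more than five residues).
#' @return A list of class `repeat_config`.
#' @export
repeat_config <- function(target_residues = c("Q", "A", "P", "S", "G"),
                          seed_min = 3L, max_gap = 2L, min_total = 6L) {
  seed_min <- as.integer(seed_min); max_gap <- as.integer(max_gap)
  min_total <- as.integer(min_total)
  stopifnot(seed_min >= 1L, max_gap >= 0L, min_total >= seed_min)
  target_residues <- toupper(target_residues)
  stopifnot(all(target_residues %in% PROTEIN_ALPHABET))
  structure(list(target_residues = target_residues, seed_min = seed_min,
                 max_gap = max_gap, min_total = min_total),
            class = "repeat_config")
}

# maximal pure runs of `target` in a character vector; data.frame(start,end,len)
pure_runs <- function(chars, target) {
  r <- rle(chars == target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

find_repeats_one_target <- function(record, target, config) {
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1L]]
  runs <- pure_runs(chars, target)
  if (nrow(runs) == 0L) return(NULL)
  # chain consecutive runs whose separating gap is <= max_gap
  gaps <- if (nrow(runs) > 1L) runs$start[-1L] - runs$end[-nrow(runs)] - 1L
          else integer(0)
  chain_id <- cumsum(c(1L, as.integer(gaps > config$max_gap)))
  out <- list()
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    if (!any(runs$len[idx] >= config$seed_min)) next
    tr_start <- runs$start[idx[1L]]
    tr_end <- runs$end[idx[length(idx)]]
    count_target <- sum(runs$len[idx])
    if (count_target < config$min_total) next
    ints <- list()
    if (length(idx) > 1L) {
      for (j in seq_len(length(idx) - 1L)) {
        gs <- runs$end[idx[j]] + 1L
        ge <- runs$start[idx[j + 1L]] - 1L
        ints[[j]] <- list(position = gs,
                          run = paste(chars[gs:ge], collapse = ""))
      }
    }
    width <- tr_end - tr_start + 1L
    out[[length(out) + 1L]] <- list(
      sequence_id = record$id, target_residue = target,
      start = tr_start, end = tr_end, count_target = count_target,
      interruptions = ints, purity = count_target / width,
      left_flank = if (tr_start == 1L) "^" else chars[tr_start - 1L],
      right_flank = if (tr_end == length(chars)) "$" else chars[tr_end + 1L])
  }
  out
}

#' Find homopolymer repeat tracts in a protein sequence
#'
#' @param record Protein [seq_record()].
#' @param config A [repeat_config()].
#' @return Data frame of repeat calls sorted by start (ties by target
#'   residue), one row per tract, with columns `sequence_id, target_residue,
#'   start, end, count_target, n_interruptions, interruptions
#'   (semicolon-joined "pos:run"), purity, left_flank, right_flank`. Tracts of
#'   distinct target residues may overlap; both are reported. Terminal flanks
#'   are the sentinels `"^"` (N-terminus) and `"$"` (C-terminus).
#' @export
#' @examples
#' rec <- seq_record("ostrich_Nterm", "MSLKQAAAAAQAA", "protein")
#' find_repeats(rec, repeat_config(target_residues = "A", max_gap = 1))
find_repeats <- function(record, config = repeat_config()) {
  assert_protein(record, "find_repeats")
  calls <- list()
  for (target in sort(config$target_residues)) {
    calls <- c(calls, find_repeats_one_target(record, target, config))
  }
  df <- repeat_calls_df(calls)
  df[order(df$start, df$target_residue), , drop = FALSE]
}

repeat_calls_df <- function(calls) {
  if (!length(calls)) {
    return(data.frame(sequence_id = character(0), target_residue = character(0),
                      start = integer(0), end = integer(0),
                      count_target = integer(0), n_interruptions = integer(0),
                      interruptions = character(0), purity = numeric(0),
                      left_flank = character(0), right_flank = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    sequence_id = vapply(calls, `[[`, character(1L), "sequence_id"),
    target_residue = vapply(calls, `[[`, character(1L), "target_residue"),
    start = vapply(calls, `[[`, integer(1L), "start"),
    end = vapply(calls, `[[`, integer(1L), "end"),
    count_target = vapply(calls, `[[`, integer(1L), "count_target"),
    n_interruptions = vapply(calls, function(x) length(x$interruptions),
                             integer(1L)),
    interruptions = vapply(calls, function(x) {
      if (!length(x$interruptions)) return("")
      paste(vapply(x$interruptions,
                   function(i) paste0(i$position, ":", i$run), character(1L)),
            collapse = ";")
    }, character(1L)),
    purity = vapply(calls, `[[`, numeric(1L), "purity"),
    left_flank = vapply(calls, `[[`, character(1L), "left_flank"),
    right_flank = vapply(calls, `[[`, character(1L), "right_flank"),
    stringsAsFactors = FALSE, row.names = NULL)
}

parse_interruptions <- function(field) {
  if (!nzchar(field)) return(data.frame(position = integer(0),
                                        run = character(0)))
  parts <- strsplit(strsplit(field, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(position = vapply(parts, function(p) as.integer(p[1L]),
                               integer(1L)),
             run = vapply(parts, `[[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}

rank_table <- function(counts) {
  if (!length(counts)) {
    return(data.frame(residue = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(residue = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$residue), , drop = FALSE]
}

#' Rank flanking and interrupting residues across repeat calls
#'
#' Interruption runs are counted per residue (a run of two prolines
#' contributes 2 to P), matching the per-residue phrasing of reported
#' interrupter preferences (Pro >>> His >> Ala ...). Terminus sentinels are
#' tallied separately and excluded from the residue rankings. Ties are broken
#' alphabetically.
#'
#' @param calls Data frame from [find_repeats()].
#' @return List with data frames `left`, `right`, `interrupting` (columns
#'   `residue`, `count`, sorted by decreasing count) and integer counts
#'   `n_left_terminus`, `n_right_terminus`.
#' @export
flank_interruption_stats <- function(calls) {
  empty <- data.frame(residue = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(left = empty, right = empty, interrupting = empty,
                n_left_terminus = 0L, n_right_terminus = 0L))
  }
  left <- calls$left_flank
  right <- calls$right_flank
  int_res <- unlist(lapply(calls$interruptions, function(f) {
    runs <- parse_interruptions(f)$run
    unlist(strsplit(runs, "", fixed = TRUE))
  }), use.names = FALSE)
  list(left = rank_table(table(left[left != "^"])),
       right = rank_table(table(right[right != "$"])),
       interrupting = rank_table(table(int_res)),
       n_left_terminus = sum(left == "^"),
       n_right_terminus = sum(right == "$"))
}
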