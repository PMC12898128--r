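# Degenerate short-linear-motif scanning with a case-encoded consensus.
#
# Conservation is encoded by letter case, as PAM2 consensus sequences are
# printed in the Ataxin-2 literature: uppercase = strongly conserved position,
# lowercase = weakly conserved, "." = unconstrained. The score of a window is
# the weighted fraction of matching positions (case-insensitive comparison),
# with "." positions carrying zero weight. The two-tier weighting (1.0 vs
# 0.25) and the default reporting threshold of 0.60 are package defaults; the
# consensus notation itself carries no numeric weights.

#' Build a case-encoded consensus model
#'
#' @param pattern Consensus string; uppercase = strongly conserved,
#'   lowercase = weakly conserved, `"."` = any residue. Hyphens are stripped.
#' @param weight_high Weight of uppercase positions (default 1.0).
#' @param weight_low Weight of lowercase positions (default 0.25).
#' @param name Model name.
#' @return List of class `consensus_model` with per-position `weights`.
#' @export
consensus_model <- function(pattern, weight_high = 1.0, weight_low = 0.25,
                            name = "custom") {
  pattern <- gsub("-", "", pattern, fixed = TRUE)
  stopifnot(nzchar(pattern), weight_high > 0, weight_low > 0,
            weight_low <= weight_high)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(grepl("^[A-Za-z.]$", chars)))
    stop("consensus pattern may contain only letters and '.'", call. = FALSE)
  weights <- ifelse(chars == ".", 0,
                    ifelse(chars == toupper(chars), weight_high, weight_low))
  structure(list(pattern = pattern, chars = chars, weights = weights,
                 weight_high = weight_high, weight_low = weight_low,
                 name = name),
            class = "consensus_model")
}

#' Shipped PAM2 consensus presets
#'
#' `PAM2_FULL_23` is the 23-position degenerate consensus compiled across
#' excavate/amoebozoan/algal Ataxin-2 family members; `PAM2_PLANT_TANDEM` is
#' the plant-type tandem-duplicated consensus; `PAM2_CORE_10` is a curated
#' 10-residue core preset for the trypanosomatid precursor candidates
#' (constructed in this package by majority vote over the five reported
#' candidate cores; a design choice, not a literature claim).
#'
#' @param name One of `"PAM2_FULL_23"`, `"PAM2_PLANT_TANDEM"`,
#'   `"PAM2_CORE_10"`.
#' @param ... Passed to [consensus_model()] (weights).
#' @return A [consensus_model()].
#' @export
pam2_preset <- function(name = c("PAM2_FULL_23", "PAM2_PLANT_TANDEM",
                                 "PAM2_CORE_10"), ...) {
  name <- match.arg(name)
  pattern <- switch(name,
    PAM2_FULL_23 = "pksksKLNPNAKpFsLNiNAKeF",
    PAM2_PLANT_TANDEM = "sekstLNPNAKEFkLNPNAKSFtps",
    PAM2_CORE_10 = "lNPnAtpFvP")
  consensus_model(pattern, name = name, ...)
}

#' Score one window against a consensus model
#'
#' `score = sum(w_i * match_i) / sum(w_i)` with case-insensitive matching;
#' `"."` positions contribute zero weight.
#'
#' @param window Residue string, same length as the model pattern.
#' @param model A [consensus_model()].
#' @return Score in `[0, 1]`.
#' @export
score_window <- function(window, model) {
  stopifnot(inherits(model, "consensus_model"))
  if (nchar(window) != length(model$chars))
    stop(sprintf("window length %d != pattern length %d",
                 nchar(window), length(model$chars)), call. = FALSE)
  wchars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  match_i <- wchars == toupper(model$chars)
  denom <- sum(model$weights)
  if (denom == 0) return(0)
  sum(model$weights[match_i]) / denom
}

#' Scan a protein record for consensus motif hits
#'
#' Every window of pattern length is scored; windows at or above the
#' threshold are reported. Overlapping hits are allowed.
#'
#' @param record Protein [seq_record()].
#' @param model A [consensus_model()].
#' @param threshold Minimal score to report (default 0.60).
#' @return Data frame `sequence_id, start, end, score, matched` sorted by
#'   start. A sequence shorter than the pattern yields zero rows with a
#'   warning.
#' @export
scan_motif <- function(record, model, threshold = 0.60) {
  assert_protein(record, "scan_motif")
  stopifnot(inherits(model, "consensus_model"),
            threshold >= 0, threshold <= 1)
  L <- length(model$chars)
  n <- seq_length(record)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      matched = character(0), stringsAsFactors = FALSE)
  if (n < L) {
    warning(sprintf("record '%s' (%d aa) shorter than pattern '%s' (%d)",
                    record$id, n, model$name, L), call. = FALSE)
    return(empty)
  }
  chars <- strsplit(toupper(record$residues), "", fixed = TRUE)[[1L]]
  pat <- toupper(model$chars)
  w <- model$weights
  denom <- sum(w)
  starts <- seq_len(n - L + 1L)
  scores <- if (denom == 0) rep(0, length(starts)) else
    vapply(starts, function(i) {
      win <- chars[i:(i + L - 1L)]
      sum(w[win == pat]) / denom
    }, numeric(1L))
  keep <- which(scores >= threshold)
  if (!length(keep)) return(empty)
  data.frame(sequence_id = record$id, start = starts[keep],
             end = starts[keep] + L - 1L, score = scores[keep],
             matched = vapply(starts[keep], function(i) {
               substr(record$residues, i, i + L - 1L)
             }, character(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}
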