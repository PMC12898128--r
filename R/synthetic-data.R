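# Seeded synthetic-data generators.
#
# Every generator is a pure function of its arguments including `seed`: the
# same call yields byte-identical output. Each generator draws from its own
# stream, derived from the master seed with a fixed per-generator offset, so
# adding a generator never perturbs the fixtures of another. Planted features
# are returned together with a truth table so analysis tests assert equality
# against truth rather than re-deriving expectations.

GEN_SEED_OFFSETS <- c(repeats = 101L, motif = 211L, tandem = 307L,
                      architecture = 401L, blast = 503L)

AA20 <- setdiff(PROTEIN_ALPHABET, "X")

gen_seed <- function(seed, stream) {
  (as.integer(seed) + GEN_SEED_OFFSETS[[stream]]) %% .Machine$integer.max
}

random_background <- function(len, freqs = NULL) {
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / 20, 20L), AA20)
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

#' IDR-like background residue frequencies
#'
#' Disorder-promoting residues (P, S, G, A, E, K) dominate, emulating the
#' composition of the intrinsically disordered regions in which Ataxin-2
#' repeats are embedded; the glutamine frequency is a separate knob.
#'
#' @param q_freq Background glutamine frequency (default 0.02).
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
idr_background_freqs <- function(q_freq = 0.02) {
  base <- c(P = 0.12, S = 0.12, G = 0.10, A = 0.10, E = 0.08, K = 0.08,
            R = 0.06, T = 0.06, D = 0.05, N = 0.05, L = 0.04, V = 0.04,
            I = 0.02, F = 0.02, H = 0.02, M = 0.015, Y = 0.01, W = 0.005,
            C = 0.01, Q = 0.02)
  base["Q"] <- q_freq
  base / sum(base)
}

compose_tract <- function(target, segments, interruption_runs) {
  stopifnot(length(interruption_runs) == length(segments) - 1L ||
              (length(segments) == 1L && length(interruption_runs) == 0L))
  parts <- character(0)
  for (i in seq_along(segments)) {
    parts <- c(parts, strrep(target, segments[i]))
    if (i < length(segments)) parts <- c(parts, interruption_runs[i])
  }
  paste(parts, collapse = "")
}

#' Generate a repeat cohort with planted homopolymer tracts
#'
#' Each sequence receives one planted tract (pure-run segments joined by
#' interruption runs) at a uniform random valid offset, with the requested
#' flanking residues written immediately outside the tract and a short
#' non-target guard beyond the flanks so the planted call is exactly
#' recoverable under the detector's merge rule.
#'
#' @param n_sequences Number of sequences.
#' @param length_aa Sequence length.
#' @param target Repeat residue (default `"Q"`).
#' @param segments Pure-run lengths of the planted tract (default a pure 23).
#' @param interruption_runs Residue runs between segments (default none).
#' @param flanks Length-2 character vector, left and right flank residues.
#' @param background_freqs Named residue frequency vector; default IDR-like
#'   with Q at 0.02.
#' @param guard Non-target guard width beyond each flank (default 3).
#' @param seed Master seed.
#' @return List `records` (list of [seq_record()]) and `truth` (data frame in
#'   the [find_repeats()] call schema).
#' @export
sim_repeat_cohort <- function(n_sequences = 10L, length_aa = 200L,
                              target = "Q", segments = 23L,
                              interruption_runs = character(0),
                              flanks = c("P", "P"),
                              background_freqs = idr_background_freqs(),
                              guard = 3L, seed = 1L) {
  set.seed(gen_seed(seed, "repeats"))
  tract <- compose_tract(target, segments, interruption_runs)
  width <- nchar(tract)
  pad <- guard + 1L  # flank + guard
  if (width + 2L * pad > length_aa)
    stop("planted tract (plus flanks and guard) longer than sequence",
         call. = FALSE)
  guard_res <- if (target == "V") "L" else "V"
  records <- vector("list", n_sequences)
  truth <- vector("list", n_sequences)
  for (k in seq_len(n_sequences)) {
    chars <- strsplit(random_background(length_aa, background_freqs), "",
                      fixed = TRUE)[[1L]]
    start <- sample(seq.int(pad + 1L, length_aa - width - pad + 1L), 1L)
    chars[start:(start + width - 1L)] <- strsplit(tract, "", fixed = TRUE)[[1L]]
    chars[start - 1L] <- flanks[1L]
    chars[start + width] <- flanks[2L]
    for (g in seq_len(guard - 1L)) {
      if (chars[start - 1L - g] == target) chars[start - 1L - g] <- guard_res
      if (chars[start + width + g] == target) chars[start + width + g] <- guard_res
    }
    id <- sprintf("sim_repeat_%03d", k)
    records[[k]] <- seq_record(id, paste(chars, collapse = ""), "protein")
    int_pos <- integer(0)
    if (length(segments) > 1L) {
      off <- start - 1L
      cum <- 0L
      for (i in seq_len(length(segments) - 1L)) {
        cum <- cum + segments[i]
        int_pos <- c(int_pos, off + cum + 1L)
        cum <- cum + nchar(interruption_runs[i])
      }
    }
    truth[[k]] <- data.frame(
      sequence_id = id, target_residue = target, start = start,
      end = start + width - 1L, count_target = sum(segments),
      n_interruptions = length(int_pos),
      interruptions = if (length(int_pos)) {
        paste(paste0(int_pos, ":", interruption_runs), collapse = ";")
      } else "",
      purity = sum(segments) / width,
      left_flank = flanks[1L], right_flank = flanks[2L],
      stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate sequences with one planted consensus motif each
#'
#' The motif instance is the model's own letters with `n_mutations` randomly
#' chosen lowercase (weakly conserved) positions substituted, so its score
#' has the closed form `(W - k * w_low) / W` with `W` the total weight.
#'
#' @param n_sequences,length_aa Cohort shape.
#' @param model A [consensus_model()].
#' @param n_mutations Number of lowercase positions to mutate (default 0).
#' @param seed Master seed.
#' @return List `records` and `truth` (`sequence_id, start, end, score`).
#' @export
sim_motif_cohort <- function(n_sequences = 10L, length_aa = 200L,
                             model = pam2_preset("PAM2_FULL_23"),
                             n_mutations = 0L, seed = 1L) {
  set.seed(gen_seed(seed, "motif"))
  L <- length(model$chars)
  low_idx <- which(model$chars != "." &
                     model$chars == tolower(model$chars))
  stopifnot(n_mutations <= length(low_idx), length_aa >= L)
  W <- sum(model$weights)
  expected_score <- (W - n_mutations * model$weight_low) / W
  records <- vector("list", n_sequences)
  truth <- vector("list", n_sequences)
  for (k in seq_len(n_sequences)) {
    chars <- strsplit(random_background(length_aa), "", fixed = TRUE)[[1L]]
    start <- sample(seq_len(length_aa - L + 1L), 1L)
    win <- toupper(model$chars)
    win[win == "."] <- sample(AA20, sum(win == "."), replace = TRUE)
    if (n_mutations > 0L) {
      mut <- sample(low_idx, n_mutations)
      win[mut] <- vapply(win[mut], function(orig) {
        sample(setdiff(AA20, orig), 1L)
      }, character(1L))
    }
    chars[start:(start + L - 1L)] <- win
    id <- sprintf("sim_motif_%03d", k)
    records[[k]] <- seq_record(id, paste(chars, collapse = ""), "protein")
    truth[[k]] <- data.frame(sequence_id = id, start = start,
                             end = start + L - 1L, score = expected_score,
                             stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate sequences with one planted tandem array each
#'
#' A random primitive unit of the requested length is repeated `copies`
#' times; the residues immediately outside the array are forced to break the
#' periodicity so the planted array is the exact maximal tract.
#'
#' @param n_sequences,length_aa Cohort shape.
#' @param unit_len Unit length in residues (2-12 sensible).
#' @param copies Number of tandem copies (>= 2).
#' @param seed Master seed.
#' @return List `records` and `truth` (`sequence_id, unit, start, copies,
#'   unit_len_aa, unit_len_nt`).
#' @export
sim_tandem_cohort <- function(n_sequences = 10L, length_aa = 120L,
                              unit_len = 7L, copies = 2L, seed = 1L) {
  set.seed(gen_seed(seed, "tandem"))
  stopifnot(copies >= 2L, unit_len >= 1L,
            unit_len * copies + 2L <= length_aa)
  records <- vector("list", n_sequences)
  truth <- vector("list", n_sequences)
  for (k in seq_len(n_sequences)) {
    repeat {
      unit <- paste(sample(AA20, unit_len, replace = TRUE), collapse = "")
      if (primitive_period(unit) == unit_len) break
    }
    arr <- strrep(unit, copies)
    alen <- nchar(arr)
    chars <- strsplit(random_background(length_aa), "", fixed = TRUE)[[1L]]
    start <- sample(seq.int(2L, length_aa - alen), 1L)
    chars[start:(start + alen - 1L)] <- strsplit(arr, "", fixed = TRUE)[[1L]]
    # break periodicity on both sides
    if (chars[start - 1L] == chars[start + unit_len - 1L])
      chars[start - 1L] <- sample(setdiff(AA20, chars[start + unit_len - 1L]), 1L)
    after <- start + alen
    if (after <= length_aa && chars[after] == chars[after - unit_len])
      chars[after] <- sample(setdiff(AA20, chars[after - unit_len]), 1L)
    id <- sprintf("sim_tandem_%03d", k)
    records[[k]] <- seq_record(id, paste(chars, collapse = ""), "protein")
    truth[[k]] <- data.frame(sequence_id = id, unit = unit, start = start,
                             copies = copies, unit_len_aa = unit_len,
                             unit_len_nt = 3L * unit_len,
                             stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate a domain-architecture cohort with a planted chimera fraction
#'
#' Canonical proteins carry LSm, LSmAD, and PAM2 in order; a `partial_fraction`
#' of proteins lack PAM2; a `chimera_fraction` carry one extra domain of known
#' function at the N- or C-terminus, with its functional category drawn from
#' `chimera_category_probs`. Chimeric proteins are drawn long (> 1000
#' residues), emulating the unusual-length screen used to find them.
#'
#' @param n_proteins Cohort size.
#' @param chimera_fraction Fraction carrying an extra domain (default 0.05,
#'   the approximate prevalence among Ataxin-2 orthologs).
#' @param partial_fraction Fraction lacking PAM2 (default 0.10).
#' @param chimera_category_probs Named probability vector over functional
#'   categories for chimera extras.
#' @param background_category_counts Named integer census of a background
#'   domain population (returned unchanged, for enrichment testing).
#' @param seed Master seed.
#' @return List `lengths` (data frame `protein_id, length_aa`), `domains`
#'   (annotation data frame), `category_map`, `background`, `truth`
#'   (`protein_id, verdict`).
#' @export
sim_architecture_cohort <- function(n_proteins = 100L,
                                    chimera_fraction = 0.05,
                                    partial_fraction = 0.10,
                                    chimera_category_probs =
                                      c(`rRNA processing` = 0.5,
                                        `lipid metabolism` = 0.3,
                                        other = 0.2),
                                    background_category_counts =
                                      c(`rRNA processing` = 10L,
                                        `lipid metabolism` = 15L,
                                        other = 75L),
                                    seed = 1L) {
  stopifnot(chimera_fraction >= 0, chimera_fraction <= 1,
            chimera_fraction + partial_fraction <= 1)
  set.seed(gen_seed(seed, "architecture"))
  n_chim <- round(n_proteins * chimera_fraction)
  n_part <- round(n_proteins * partial_fraction)
  kinds <- sample(c(rep("chimeric", n_chim), rep("partial", n_part),
                    rep("canonical", n_proteins - n_chim - n_part)))
  cats <- names(chimera_category_probs)
  lengths <- vector("list", n_proteins)
  domains <- list()
  truth <- vector("list", n_proteins)
  category_map <- character(0)
  for (k in seq_len(n_proteins)) {
    pid <- sprintf("sim_prot_%03d", k)
    kind <- kinds[k]
    len <- if (kind == "chimeric") sample(1100:1400, 1L)
           else sample(700:1000, 1L)
    lsm_start <- sample(80:160, 1L)
    lsm <- c(lsm_start, lsm_start + 77L)
    lsmad <- c(lsm[2L] + sample(50:60, 1L), 0L)
    lsmad[2L] <- lsmad[1L] + 68L
    pam2_start <- round(len * 0.6)
    rows <- data.frame(protein_id = pid,
                       label = c("LSm", "LSmAD", "PAM2"),
                       start = c(lsm[1L], lsmad[1L], pam2_start),
                       end = c(lsm[2L], lsmad[2L], pam2_start + 13L),
                       source = "sim", stringsAsFactors = FALSE)
    verdict <- "canonical"
    if (kind == "partial") {
      rows <- rows[rows$label != "PAM2", , drop = FALSE]
      verdict <- "partial"
    } else if (kind == "chimeric") {
      cat_k <- sample(cats, 1L, prob = chimera_category_probs)
      lab <- sprintf("extra_%03d", k)
      category_map[lab] <- cat_k
      side <- sample(c("N", "C"), 1L)
      extra <- if (side == "N") c(5L, lsm[1L] - 10L)
               else c(max(rows$end) + 10L, len - 5L)
      rows <- rbind(rows, data.frame(protein_id = pid, label = lab,
                                     start = extra[1L], end = extra[2L],
                                     source = "sim",
                                     stringsAsFactors = FALSE))
      verdict <- if (side == "N") "chimeric_N" else "chimeric_C"
    }
    lengths[[k]] <- data.frame(protein_id = pid, length_aa = len,
                               stringsAsFactors = FALSE)
    domains[[k]] <- rows
    truth[[k]] <- data.frame(protein_id = pid, verdict = verdict,
                             stringsAsFactors = FALSE)
  }
  list(lengths = do.call(rbind, lengths),
       domains = do.call(rbind, domains),
       category_map = category_map,
       background = background_category_counts,
       truth = do.call(rbind, truth))
}

#' Generate a BLAST hit table with planted E-value strata
#'
#' Each stratum corresponds to a tier under the given [tier_config()]:
#' subjects get an LSmAD-query hit with log-uniform E-value inside the
#' stratum range; tier1 subjects additionally get a supporting LSm hit.
#' Stratum ranges must not straddle the configured thresholds.
#'
#' @param counts Named integer vector over `tier1, tier2, tier3, rejected`.
#' @param config A [tier_config()].
#' @param seed Master seed.
#' @return List `hits` (BLAST tabular schema), `truth`
#'   (`subject_id, tier`), `query_labels`.
#' @export
sim_blast_strata <- function(counts = c(tier1 = 10L, tier2 = 10L,
                                        tier3 = 5L, rejected = 5L),
                             config = tier_config(), seed = 1L) {
  set.seed(gen_seed(seed, "blast"))
  ranges <- list(
    tier1 = c(1e-30, config$strict_threshold),
    tier2 = c(1e-30, config$strict_threshold),
    tier3 = c(config$strict_threshold * 1.01, config$loose_threshold),
    rejected = c(config$loose_threshold * 10, 1e-2))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    straddles <- function(th) r[1L] < th && r[2L] > th
    if (straddles(config$strict_threshold) ||
        straddles(config$loose_threshold))
      stop("stratum '", nm, "' straddles a tier threshold", call. = FALSE)
  }
  hits <- list()
  truth <- list()
  i <- 0L
  for (tier in names(counts)) {
    for (k in seq_len(counts[[tier]])) {
      i <- i + 1L
      sid <- sprintf("subj_%s_%03d", tier, k)
      r <- ranges[[tier]]
      ev <- 10^stats::runif(1L, log10(r[1L]), log10(r[2L]))
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = "q_lsmad", subject_id = sid, percent_identity = 80,
        align_length = 69L, mismatches = 10L, gap_opens = 0L,
        query_start = 1L, query_end = 69L, subject_start = 400L,
        subject_end = 468L, evalue = ev, bitscore = 120,
        stringsAsFactors = FALSE)
      if (tier == "tier1") {
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = "q_lsm", subject_id = sid, percent_identity = 60,
          align_length = 78L, mismatches = 25L, gap_opens = 1L,
          query_start = 1L, query_end = 78L, subject_start = 100L,
          subject_end = 177L, evalue = 10^stats::runif(1L, -8, -3),
          bitscore = 60, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sid, tier = tier, stringsAsFactors = FALSE)
    }
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else NULL,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(subject_id = character(0), tier = character(0)),
       query_labels = c(q_lsmad = "LSmAD", q_lsm = "LSm"))
}
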