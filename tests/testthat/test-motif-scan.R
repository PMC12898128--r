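test_that("window scoring follows the weighted-fraction formula", {
  m <- pam2_preset("PAM2_FULL_23")
  expect_equal(sum(m$weights == 1.0), 14L)   # strongly conserved positions
  expect_equal(sum(m$weights == 0.25), 9L)   # weakly conserved positions

  self <- toupper(m$pattern)
  expect_equal(score_window(self, m), 1.0)

  # mutate every lowercase position: only the 14 strong positions match
  chars <- strsplit(self, "", fixed = TRUE)[[1L]]
  low <- which(m$weights == 0.25)
  chars[low] <- vapply(chars[low], function(x) if (x == "A") "G" else "A",
                       character(1L))
  expect_equal(score_window(paste(chars, collapse = ""), m),
               14 / (14 + 9 * 0.25))

  # no position matches
  flipped <- vapply(strsplit(self, "")[[1L]],
                    function(x) if (x == "A") "G" else "A", character(1L))
  expect_equal(score_window(paste(flipped, collapse = ""), m), 0)

  expect_error(score_window("SHORT", m), "length")
})

test_that("scores are case-invariant and '.' positions carry no weight", {
  m <- consensus_model("Ab.D")
  expect_equal(score_window("abxd", m), 1.0)
  expect_equal(score_window("ABQD", m), 1.0)
  expect_equal(score_window("AXXD", m), 2 / 2.25)
})

test_that("scanning equals per-window scoring and reports planted matches", {
  set.seed(5)
  m <- pam2_preset("PAM2_CORE_10")
  sim <- sim_motif_cohort(n_sequences = 6L, length_aa = 200L, model = m,
                          n_mutations = 0L, seed = 5L)
  for (i in seq_along(sim$records)) {
    rec <- sim$records[[i]]
    hits <- scan_motif(rec, m, threshold = 0.0)
    # oracle: score every window independently
    n <- seq_length(rec); L <- nchar(m$pattern)
    want <- vapply(seq_len(n - L + 1L), function(s) {
      oracle_window_score(substr(rec$residues, s, s + L - 1L), m$pattern)
    }, numeric(1L))
    expect_equal(hits$score, want)
    planted <- hits[hits$start == sim$truth$start[i], ]
    expect_equal(planted$score, 1.0)
  }
})

test_that("the trypanosomatid precursor core is found once in background", {
  set.seed(23)
  bg <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                     200, replace = TRUE), collapse = "")
  core <- reference_pam2_cores()[["leishmania"]]  # PNPSATPFVP
  seq <- paste0(substr(bg, 1, 90), core, substr(bg, 101, 200))
  m <- pam2_preset("PAM2_CORE_10")
  hits <- scan_motif(seq_record("tryp", seq, "protein"), threshold = 0.75,
                     model = m)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 91L)
  expect_equal(hits$score,
               oracle_window_score(core, m$pattern))
})

test_that("random sequences carry no high-scoring full-model hits", {
  set.seed(99)
  seq <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                      200, replace = TRUE), collapse = "")
  hits <- scan_motif(seq_record("rand", seq, "protein"),
                     pam2_preset("PAM2_FULL_23"), threshold = 0.9)
  expect_equal(nrow(hits), 0L)
})

test_that("lowering the threshold never removes hits", {
  sim <- sim_motif_cohort(n_sequences = 3L, model = pam2_preset("PAM2_FULL_23"),
                          n_mutations = 3L, seed = 8L)
  for (rec in sim$records) {
    hi <- scan_motif(rec, pam2_preset("PAM2_FULL_23"), threshold = 0.8)
    lo <- scan_motif(rec, pam2_preset("PAM2_FULL_23"), threshold = 0.5)
    expect_true(all(hi$start %in% lo$start))
  }
})

test_that("planted motifs with k lowercase mutations score the closed form", {
  m <- pam2_preset("PAM2_FULL_23")
  W <- sum(m$weights)
  for (k in 0:4) {
    sim <- sim_motif_cohort(n_sequences = 4L, model = m, n_mutations = k,
                            seed = 100L + k)
    expected <- (W - k * 0.25) / W
    for (i in seq_along(sim$records)) {
      hits <- scan_motif(sim$records[[i]], m, threshold = expected - 1e-9)
      planted <- hits[hits$start == sim$truth$start[i], ]
      expect_equal(planted$score, expected)
    }
  }
})

test_that("short sequences warn and return zero hits", {
  expect_warning(h <- scan_motif(seq_record("s", "MK", "protein"),
                                 pam2_preset("PAM2_CORE_10")), "shorter")
  expect_equal(nrow(h), 0L)
})
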