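test_that("the human ATXN2 polyQ context yields the 23Q call with Pro flanks", {
  rec <- seq_record("Q99700_156_202",
                    reference_peptides()[["human_polyQ_context"]], "protein")
  calls <- find_repeats(rec, repeat_config(target_residues = "Q"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 11L)
  expect_equal(calls$end, 33L)
  expect_equal(calls$count_target, 23L)
  expect_equal(calls$n_interruptions, 0L)
  expect_equal(calls$left_flank, "P")
  expect_equal(calls$right_flank, "P")
  expect_equal(calls$purity, 1)
})

test_that("the ostrich polyA analog merges across a single Gln interruption", {
  rec <- seq_record("ostrich", reference_peptides()[["ostrich_polyA"]],
                    "protein")
  calls <- find_repeats(rec, repeat_config(target_residues = "A",
                                           max_gap = 1, min_total = 6))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 6L)
  expect_equal(calls$end, 13L)
  expect_equal(calls$count_target, 7L)
  expect_equal(calls$interruptions, "11:Q")
  # residue 5 is the Gln immediately left of the tract; the tract reaches the
  # C-terminus, so the right flank is the terminus sentinel
  expect_equal(calls$left_flank, "Q")
  expect_equal(calls$right_flank, "$")
})

test_that("sequences without the target residue yield no calls", {
  rec <- seq_record("a", "AAAA", "protein")
  expect_equal(nrow(find_repeats(rec, repeat_config("Q"))), 0L)
})

test_that("dna records are rejected", {
  expect_error(find_repeats(seq_record("d", "ACGT", "dna")), "protein")
})

test_that("with max_gap 0 calls equal the brute-force maximal-run scanner", {
  set.seed(42)
  cfg <- repeat_config("Q", seed_min = 3, max_gap = 0, min_total = 6)
  for (k in 1:25) {
    seq <- paste(sample(c("Q", "P", "A", "S"), 150, replace = TRUE,
                        prob = c(0.35, 0.3, 0.2, 0.15)), collapse = "")
    calls <- find_repeats(seq_record("r", seq, "protein"), cfg)
    runs <- oracle_pure_runs(seq, "Q", 6L)
    expect_equal(calls$start, runs$start)
    expect_equal(calls$end, runs$end)
    expect_true(all(calls$n_interruptions == 0L))
  }
})

test_that("target count plus interruption residues equals tract width", {
  set.seed(7)
  cfg <- repeat_config("Q", max_gap = 2, min_total = 6)
  for (k in 1:20) {
    seq <- paste(sample(c("Q", "P", "H"), 200, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)), collapse = "")
    calls <- find_repeats(seq_record("r", seq, "protein"), cfg)
    for (i in seq_len(nrow(calls))) {
      int_res <- sum(nchar(strsplit(calls$interruptions[i], ";")[[1L]]) > 0) # nolint
      runs <- if (nzchar(calls$interruptions[i])) {
        sum(nchar(sub("^[0-9]+:", "",
                      strsplit(calls$interruptions[i], ";")[[1L]])))
      } else 0L
      expect_equal(calls$count_target[i] + runs,
                   calls$end[i] - calls$start[i] + 1L)
      # every interruption run respects max_gap
      if (nzchar(calls$interruptions[i])) {
        lens <- nchar(sub("^[0-9]+:", "",
                          strsplit(calls$interruptions[i], ";")[[1L]]))
        expect_true(all(lens <= 2L))
      }
    }
  }
})

test_that("output does not depend on target-set order", {
  rec <- seq_record("r", "QQQQQQPPPPPPAAAAAAQQQQQQ", "protein")
  a <- find_repeats(rec, repeat_config(c("Q", "P", "A")))
  b <- find_repeats(rec, repeat_config(c("A", "P", "Q")))
  expect_equal(a, b)
  expect_equal(nrow(a), 4L)  # two Q tracts (split by 12 non-Q), one P, one A
})

test_that("flank and interruption statistics count residues, not runs", {
  calls <- data.frame(
    sequence_id = c("a", "b", "c"), target_residue = "Q",
    start = c(10L, 10L, 10L), end = c(20L, 20L, 20L),
    count_target = c(9L, 8L, 10L), n_interruptions = c(1L, 1L, 1L),
    interruptions = c("12:P", "13:PP", "14:H"),
    purity = 1, left_flank = c("P", "P", "H"),
    right_flank = c("P", "$", "M"), stringsAsFactors = FALSE)
  st <- flank_interruption_stats(calls)
  expect_equal(st$left, data.frame(residue = c("P", "H"), count = c(2L, 1L)),
               ignore_attr = TRUE)
  expect_equal(st$interrupting,
               data.frame(residue = c("P", "H"), count = c(3L, 1L)),
               ignore_attr = TRUE)
  expect_equal(st$n_right_terminus, 1L)
  expect_equal(st$right$residue, c("M", "P"))  # alphabetical at equal counts

  empty <- flank_interruption_stats(calls[0, ])
  expect_equal(nrow(empty$left), 0L)
  expect_equal(empty$n_left_terminus, 0L)
})
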