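mk_hit <- function(query, subject, evalue) {
  data.frame(query_id = query, subject_id = subject, percent_identity = 50,
             align_length = 60L, mismatches = 20L, gap_opens = 0L,
             query_start = 1L, query_end = 60L, subject_start = 1L,
             subject_end = 60L, evalue = evalue, bitscore = 100,
             stringsAsFactors = FALSE)
}
LABELS <- c(qA = "LSmAD", qL = "LSm", qP = "PAM2")

test_that("tier rules follow the two-threshold, LSmAD-anchored table", {
  hits <- rbind(mk_hit("qA", "s1", 1e-12), mk_hit("qL", "s1", 1e-5),
                mk_hit("qA", "s2", 1e-8),
                mk_hit("qA", "s3", 1e-3),
                mk_hit("qA", "s4", 1e-15),
                mk_hit("qL", "s5", 1e-20))
  t <- assign_tiers(hits, LABELS)
  tier_of <- function(s) t$tier[t$subject_id == s]
  expect_equal(tier_of("s1"), "tier1")     # strict LSmAD + supporting LSm
  expect_equal(tier_of("s2"), "tier3")     # between strict and loose
  expect_equal(tier_of("s3"), "rejected")  # above loose
  expect_equal(tier_of("s4"), "tier2")     # strict LSmAD alone
  expect_equal(tier_of("s5"), "rejected")  # no LSmAD evidence at all
})

test_that("assignment uses best per-label evalue and ignores row order", {
  hits <- rbind(mk_hit("qA", "s1", 1e-4), mk_hit("qA", "s1", 1e-12),
                mk_hit("qP", "s1", 1e-6))
  a <- assign_tiers(hits, LABELS)
  b <- assign_tiers(hits[rev(seq_len(nrow(hits))), ], LABELS)
  expect_equal(a, b)
  expect_equal(a$tier, "tier1")
  expect_equal(a$lsmad_evalue, 1e-12)
  expect_error(assign_tiers(mk_hit("mystery", "s", 1e-12), LABELS),
               "mystery")
})

test_that("taxonomy include/exclude filters reject subjects", {
  hits <- rbind(mk_hit("qA", "s1", 1e-12), mk_hit("qA", "s2", 1e-12))
  tax <- c(s1 = "eukaryota", s2 = "bacteria")
  cfg <- tier_config(taxonomy_exclude = "bacteria")
  t <- assign_tiers(hits, LABELS, cfg, tax)
  expect_equal(t$tier[t$subject_id == "s2"], "rejected")
  expect_false(t$taxonomy_ok[t$subject_id == "s2"])
  expect_equal(t$tier[t$subject_id == "s1"], "tier2")
})

test_that("tightening the strict threshold never promotes a subject", {
  sim <- sim_blast_strata(seed = 21L)
  rank <- c(rejected = 0L, tier3 = 1L, tier2 = 2L, tier1 = 3L)
  loosecfg <- tier_config(strict_threshold = 1e-10)
  tightcfg <- tier_config(strict_threshold = 1e-14)
  a <- assign_tiers(sim$hits, sim$query_labels, loosecfg)
  b <- assign_tiers(sim$hits, sim$query_labels, tightcfg)
  expect_true(all(rank[b$tier] <= rank[a$tier]))
})

test_that("planted evalue strata are recovered exactly", {
  sim <- sim_blast_strata(counts = c(tier1 = 12L, tier2 = 8L, tier3 = 6L,
                                     rejected = 4L), seed = 9L)
  t <- assign_tiers(sim$hits, sim$query_labels)
  merged <- merge(t, sim$truth, by = "subject_id")
  expect_equal(merged$tier.x, merged$tier.y)
})

test_that("majority consensus applies the stated tie-break and gap rules", {
  expect_equal(build_consensus(c("QQP", "QQP", "QAP")), "QQP")
  expect_equal(build_consensus("SINGLE"), "SINGLE")
  expect_equal(build_consensus(c("AB", "BA")), "AA")  # ties alphabetical
  # gap wins only on strict majority
  expect_equal(build_consensus(c("-A", "-A", "QA", "QA")), "QA")
  expect_equal(build_consensus(c("-A", "-A", "-A", "QA")), "-A")
  expect_error(build_consensus(c("AB", "ABC")), "equal length")
})

test_that("bootstrapping converges on recruiting and constant backends", {
  # subjects: o1..o3 are true orthologs, all aligned length 5
  seqs <- c(o1 = "QQPAA", o2 = "QQPAA", o3 = "QQPAT", far = "YYYYY")
  fetch <- function(sid) seqs[[sid]]
  # round 1 with the seed query finds o1, o2; the consensus then also
  # recruits o3; afterwards the hit set is stable
  search_recruiting <- function(query) {
    found <- if (query == "SEED") c("o1", "o2") else c("o1", "o2", "o3")
    do.call(rbind, lapply(found, function(s) {
      rbind(mk_hit("qA", s, 1e-12), mk_hit("qL", s, 1e-5))
    }))
  }
  res <- bootstrap_iterate("SEED", search_recruiting, fetch,
                           query_labels = LABELS)
  expect_true(res$converged)
  expect_equal(res$iterations, 2L)
  expect_setequal(res$tiers$subject_id[res$tiers$tier == "tier1"],
                  c("o1", "o2", "o3"))

  search_constant <- function(query) {
    rbind(mk_hit("qA", "o1", 1e-12), mk_hit("qL", "o1", 1e-5))
  }
  res <- bootstrap_iterate("SEED", search_constant, fetch,
                           query_labels = LABELS)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
})

test_that("an oscillating backend stops unconverged at max_iter", {
  seqs <- c(a = "AAAA", b = "CCCC")
  state <- new.env(); state$flip <- FALSE
  search_osc <- function(query) {
    state$flip <- !state$flip
    s <- if (state$flip) "a" else "b"
    rbind(mk_hit("qA", s, 1e-12), mk_hit("qL", s, 1e-5))
  }
  cfg <- tier_config(max_iter = 6L)
  res <- bootstrap_iterate("SEED", search_osc, function(s) seqs[[s]],
                           config = cfg, query_labels = LABELS)
  expect_false(res$converged)
  expect_equal(res$iterations, 6L)
})

test_that("deterministic backends make the whole loop bit-reproducible", {
  run_once <- function() {
    sim <- sim_blast_strata(seed = 14L)
    seqs <- stats::setNames(rep("QQPAA", nrow(sim$truth)), sim$truth$subject_id)
    search <- function(query) sim$hits
    res <- bootstrap_iterate("SEED", search, function(s) seqs[[s]],
                             query_labels = sim$query_labels)
    res
  }
  expect_identical(run_once(), run_once())
})
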