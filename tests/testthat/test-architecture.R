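arch_domains <- function(pid, labels, starts, ends) {
  data.frame(protein_id = pid, label = labels, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

test_that("verdicts follow the chimera/partial/canonical rule table", {
  # N-terminal fusion of a fatty-acid synthase domain before the core,
  # on an unusually long protein
  d <- arch_domains("chlorella_like", c("KCS", "LSm", "LSmAD", "PAM2"),
                    c(10L, 400L, 520L, 800L), c(300L, 478L, 590L, 813L))
  call <- classify_architecture(1200L, d)
  expect_equal(call$verdict, "chimeric_N")
  expect_true(call$unusual_length)
  expect_equal(call$extras$side, "N")

  d <- arch_domains("plain", c("LSm", "LSmAD", "PAM2"),
                    c(100L, 250L, 540L), c(177L, 318L, 553L))
  call <- classify_architecture(900L, d)
  expect_equal(call$verdict, "canonical")
  expect_false(call$unusual_length)

  # LSm + LSmAD coexisting without further elements
  d <- arch_domains("trunc", c("LSm", "LSmAD"), c(30L, 150L), c(107L, 218L))
  expect_equal(classify_architecture(500L, d)$verdict, "partial")

  # the family is defined by LSmAD: without it, never more than partial
  d <- arch_domains("nolsmad", c("LSm", "PAM2"), c(30L, 300L), c(107L, 313L))
  expect_equal(classify_architecture(500L, d)$verdict, "partial")

  # extras on both sides
  d <- arch_domains("both", c("helicase", "LSm", "LSmAD", "RRM"),
                    c(5L, 200L, 320L, 700L), c(150L, 277L, 388L, 800L))
  expect_equal(classify_architecture(900L, d)$verdict, "chimeric_both")

  # extra overlapping a core span is irregular
  d <- arch_domains("odd", c("LSm", "LSmAD", "mystery"),
                    c(100L, 250L, 240L), c(177L, 318L, 300L))
  call <- classify_architecture(600L, d)
  expect_equal(call$verdict, "irregular")
  expect_equal(call$extras$side, "internal")
})

test_that("verdicts are invariant to domain row order", {
  d <- arch_domains("p", c("KCS", "LSm", "LSmAD", "PAM2"),
                    c(10L, 400L, 520L, 800L), c(300L, 478L, 590L, 813L))
  set.seed(2)
  base <- classify_architecture(1200L, d)$verdict
  for (k in 1:5) {
    perm <- d[sample(nrow(d)), , drop = FALSE]
    expect_equal(classify_architecture(1200L, perm)$verdict, base)
  }
})

test_that("Fisher enrichment p equals the hypergeometric-sum oracle", {
  calls <- data.frame(
    protein_id = sprintf("c%02d", 1:10),
    verdict = "chimeric_N",
    extra_labels = c(rep("rrna_dom", 6L), rep("lipid_dom", 4L)),
    stringsAsFactors = FALSE)
  cmap <- c(rrna_dom = "R", lipid_dom = "L")
  bg <- c(R = 10L, L = 90L)
  enr <- enrich_categories(calls, cmap, bg)
  row <- enr[enr$category == "R", ]
  expect_equal(row$count_in_chimeras, 6L)
  expect_equal(row$p_value, oracle_fisher_two_sided(6L, 4L, 10L, 90L),
               tolerance = 1e-10)

  # all 2x2 tables with margins <= 30
  set.seed(31)
  for (k in 1:40) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d_ <- sample(0:15, 1)
    if (a + b == 0L || c_ + d_ == 0L || a + c_ == 0L) next
    got <- stats::fisher.test(matrix(c(a, b, c_, d_), 2L))$p.value
    expect_equal(got, oracle_fisher_two_sided(a, b, c_, d_),
                 tolerance = 1e-7, info = paste(a, b, c_, d_))
  }
})

test_that("identical minimal proportions give p = 1 and empty input is empty", {
  calls <- data.frame(protein_id = "c1", verdict = "chimeric_C",
                      extra_labels = "x", stringsAsFactors = FALSE)
  enr <- enrich_categories(calls, c(x = "A"), c(A = 1L, B = 1L))
  expect_equal(enr$p_value, 1.0)

  none <- data.frame(protein_id = "p", verdict = "canonical",
                     extra_labels = "", stringsAsFactors = FALSE)
  expect_equal(nrow(enrich_categories(none, c(x = "A"), c(A = 1L))), 0L)
  expect_error(enrich_categories(calls, c(x = "A"), integer(0)), "background")
})

test_that("BH q-values are monotone in p rank and unmapped labels fall to other", {
  calls <- data.frame(
    protein_id = sprintf("c%02d", 1:12), verdict = "chimeric_N",
    extra_labels = c(rep("a", 6L), rep("b", 4L), rep("zzz", 2L)),
    stringsAsFactors = FALSE)
  enr <- enrich_categories(calls, c(a = "catA", b = "catB"),
                           c(catA = 5L, catB = 40L, other = 55L))
  expect_true("other" %in% enr$category)
  expect_true(all(diff(enr$q_value) >= -1e-12))
  expect_true(all(enr$q_value >= enr$p_value - 1e-12))
})

test_that("cohort classification recovers the planted chimera fraction", {
  sim <- sim_architecture_cohort(n_proteins = 120L, chimera_fraction = 0.10,
                                 seed = 4L)
  calls <- classify_cohort(sim$lengths, sim$domains)
  merged <- merge(calls, sim$truth, by = "protein_id")
  expect_equal(merged$verdict.x, merged$verdict.y)
  frac <- mean(grepl("^chimeric", calls$verdict))
  expect_equal(frac, 0.10, tolerance = 1e-12)  # planted count is exact
})

test_that("a concentrated chimera category ranks first in enrichment", {
  sim <- sim_architecture_cohort(
    n_proteins = 200L, chimera_fraction = 0.10,
    chimera_category_probs = c(`rRNA processing` = 0.9,
                               `lipid metabolism` = 0.05, other = 0.05),
    background_category_counts = c(`rRNA processing` = 33L,
                                   `lipid metabolism` = 33L, other = 34L),
    seed = 12L)
  calls <- classify_cohort(sim$lengths, sim$domains)
  enr <- enrich_categories(calls, sim$category_map, sim$background)
  expect_equal(enr$category[1L], "rRNA processing")
})
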