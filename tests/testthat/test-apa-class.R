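test_that("RED arithmetic matches hand computation and inverts under swap", {
  r <- compute_red(10, 10, 10, 10, pseudocount = 0)
  expect_equal(r$red_ratio, 1)
  expect_equal(r$red_log2, 0)

  r2 <- compute_red(20, 20, 30, 10, pseudocount = 0)
  expect_equal(r2$red_ratio, 1 / 3)
  expect_equal(r2$red_log2, log2(1 / 3))
  expect_equal(r2$red_log2, log2(r2$red_ratio))

  set.seed(1)
  for (i in 1:25) {
    x <- rpois(4, 30)
    a <- compute_red(x[1], x[2], x[3], x[4])$red_log2
    b <- compute_red(x[3], x[4], x[1], x[2])$red_log2
    expect_identical(a, -b)
  }

  # an all-zero gene is flagged, not computed
  expect_true(is.na(compute_red(0, 0, 0, 0)$red_ratio))
})

test_that("Fisher exact p matches hypergeometric enumeration examples", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70,
               tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_two_sided(0, 5, 0, 7), 1)
})

test_that("Fisher exact p agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:200) {
    x <- rpois(4, sample(c(2, 10, 40), 1))
    if (sum(x) == 0) next
    mine <- fisher_exact_two_sided(x[1], x[2], x[3], x[4])
    ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(mine, min(ref, 1), tolerance = 1e-8)
  }
})

test_that("BH adjustment reproduces worked examples and references", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), p.adjust(p, "BH"))
  }
  # NA passthrough
  q <- adjust_bh(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.5), "BH"))
})

test_that("APA classification applies strict RED thresholds under the FDR gate", {
  expect_identical(classify_apa(1.3, 0.01), "lengthen")
  expect_identical(classify_apa(0.80, 0.01), "shorten")
  expect_identical(classify_apa(0.5, 0.2), "nc")
  # exact boundary values are nc (strict inequalities)
  expect_identical(classify_apa(1.2, 1e-6), "nc")
  expect_identical(classify_apa(5 / 6, 1e-6), "nc")
  # failed read filter forces nc regardless of signal
  expect_identical(classify_apa(3, 1e-6, passed_min_reads = FALSE), "nc")
})

test_that("table-level classification is antisymmetric under condition swap", {
  co <- mixed_cohort()
  a <- classify_apa_table(co$counts, ref = "SC", alt = "MT")
  b <- classify_apa_table(co$counts, ref = "MT", alt = "SC")
  expect_identical(a$gene, b$gene)
  expect_equal(a$red_log2, -b$red_log2)
  swap <- c(shorten = "lengthen", lengthen = "shorten", nc = "nc")
  expect_identical(unname(swap[a$apa_class]), b$apa_class)
  expect_identical(a$p_value, b$p_value)
})

test_that("read filters gate classification by mode", {
  counts <- data.frame(
    gene = rep(c("gA", "gB"), each = 2),
    condition = rep(c("SC", "MT"), 2),
    replicate = 1L,
    p_count = c(4L, 20L, 40L, 200L),
    d_count = c(4L, 2L, 40L, 20L))
  # gA has 30 < 50 total reads in quantseq mode
  res_q <- classify_apa_table(counts, mode = "quantseq")
  expect_false(res_q$passed_min_reads[res_q$gene == "gA"])
  expect_identical(res_q$apa_class[res_q$gene == "gA"], "nc")
  expect_identical(res_q$apa_class[res_q$gene == "gB"], "shorten")
  # rnaseq mode: every isoform needs > 5 reads in some sample
  counts$d_count <- c(4L, 2L, 40L, 20L)
  res_r <- classify_apa_table(counts, mode = "rnaseq")
  expect_false(res_r$passed_min_reads[res_r$gene == "gA"])
  expect_true(res_r$passed_min_reads[res_r$gene == "gB"])
})

test_that("reproducibility requires per-replicate sign concordance", {
  mk <- function(p_sc1, d_sc1, p_mt1, d_mt1, p_sc2, d_sc2, p_mt2, d_mt2)
    data.frame(gene = "g",
               condition = rep(c("SC", "MT"), 2),
               replicate = rep(1:2, each = 2),
               p_count = c(p_sc1, p_mt1, p_sc2, p_mt2),
               d_count = c(d_sc1, d_mt1, d_sc2, d_mt2))
  concordant <- mk(100, 100, 190, 55, 100, 100, 210, 45)
  res <- classify_apa_table(concordant)
  expect_identical(res$apa_class, "shorten")
  expect_true(res$reproducible)

  discordant <- mk(100, 100, 190, 25, 100, 100, 90, 105)
  res2 <- classify_apa_table(discordant)
  expect_false(res2$reproducible)

  single <- mk(100, 100, 190, 55, 100, 100, 210, 45)
  single <- single[single$replicate == 1, ]
  res3 <- classify_apa_table(single)
  expect_true(is.na(res3$reproducible))
})

test_that("recapitulation fraction is plain set arithmetic", {
  expect_equal(recapitulation_fraction(letters[1:5], letters[1:5]), 100)
  expect_equal(recapitulation_fraction(letters[1:5], LETTERS[1:5]), 0)
  ref <- sprintf("g%02d", 1:50)
  expect_equal(recapitulation_fraction(ref, ref[1:34]), 68)
  expect_error(recapitulation_fraction(character(0), "a"), "empty")
})

test_that("shortening-factor selection is a strict -0.8 cutoff, ascending", {
  expect_identical(select_shortening_factors(c(A = -1.0, B = -0.5)), "A")
  expect_identical(select_shortening_factors(setNames(numeric(0),
                                                      character(0))),
                   character(0))
  expect_identical(select_shortening_factors(c(A = -0.8)), character(0))
  expect_identical(
    select_shortening_factors(c(cfi68 = -1.4, pcf11 = -0.9, cstf64 = -2.1)),
    c("cstf64", "cfi68", "pcf11"))
})
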