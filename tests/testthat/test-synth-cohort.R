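test_that("planted class counts follow deterministic rounding, not sampling", {
  co <- generate_gene_models(cohort_config(n_genes = 1000, frac_shorten = 0.1,
                                           frac_lengthen = 0.1, seed = 5),
                             sequences = FALSE)
  tab <- table(co$models$class)
  expect_identical(as.integer(tab[c("shorten", "lengthen", "nc")]),
                   c(100L, 100L, 800L))
  expect_identical(co$models$class, co$truth$genes$planted_class)
})

test_that("an empty cohort is valid and empty everywhere", {
  co <- generate_gene_models(cohort_config(n_genes = 0), sequences = FALSE)
  expect_identical(nrow(co$models), 0L)
  expect_identical(nrow(co$truth$genes), 0L)
  co <- simulate_isoform_counts(co)
  expect_identical(nrow(co$counts), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(frac_shorten = 0.7, frac_lengthen = 0.6),
               "fractions")
  expect_error(cohort_config(autr_len_range = c(20, 100)), "50 nt")
  expect_error(cohort_config(internal_priming_rate = 1.5), "probabilities")
  expect_error(cohort_config(depth_per_gene = -1), "non-negative")
})

test_that("site probabilities exceeding peak probabilities warn and clip", {
  expect_warning(
    cfg <- cohort_config(p_site_by_class = c(shorten = 0.9, lengthen = 0.16,
                                             nc = 0.14)),
    "clipping")
  expect_equal(cfg$p_site_by_class[["shorten"]],
               cfg$p_peak_by_class[["shorten"]])
})

test_that("identical config and seed regenerate byte-identical cohorts", {
  cfg <- cohort_config(n_genes = 30, frac_shorten = 0.3, seed = 99,
                       depth_per_gene = 40)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("truth and models are untouched when counts/reads use new seeds", {
  co <- mixed_cohort()
  co2 <- simulate_isoform_counts(co, seed = 987654L)
  co2 <- simulate_end_reads(co2, seed = 13L)
  expect_identical(co2$truth, co$truth)
  expect_identical(co2$models, co$models)
  expect_false(identical(co2$counts, co$counts))
})

test_that("null-cohort RED is centered on zero and symmetric in sign", {
  co <- generate_gene_models(cohort_config(n_genes = 2000, frac_shorten = 0,
                                           frac_lengthen = 0,
                                           depth_per_gene = 300, seed = 21),
                             sequences = FALSE)
  co <- simulate_isoform_counts(co)
  agg <- function(cond, col) tapply(
    co$counts[[col]][co$counts$condition == cond],
    co$counts$gene[co$counts$condition == cond], sum)
  red <- compute_red(agg("SC", "p_count"), agg("SC", "d_count"),
                     agg("MT", "p_count"), agg("MT", "d_count"))$red_log2
  expect_lt(abs(mean(red)), 0.05)
  signs <- sign(red[red != 0])
  expect_gt(binom.test(sum(signs > 0), length(signs))$p.value, 0.01)
})

test_that("a planted -1 log2 effect reproduces a halved RED ratio", {
  co <- generate_gene_models(cohort_config(n_genes = 200, frac_shorten = 1,
                                           frac_lengthen = 0,
                                           depth_per_gene = 300,
                                           effect_red_log2 = 1, seed = 8),
                             sequences = FALSE)
  co <- simulate_isoform_counts(co)
  agg <- function(cond, col) tapply(
    co$counts[[col]][co$counts$condition == cond],
    co$counts$gene[co$counts$condition == cond], sum)
  red <- compute_red(agg("SC", "p_count"), agg("SC", "d_count"),
                     agg("MT", "p_count"), agg("MT", "d_count"))$red_log2
  gm <- 2^mean(red)
  expect_gt(gm, 0.45)
  expect_lt(gm, 0.56)
})

test_that("untemplated-T evidence follows the internal-priming rate", {
  cfg0 <- cohort_config(n_genes = 40, internal_priming_rate = 0,
                        depth_per_gene = 100, seed = 4)
  co0 <- generate_gene_models(cfg0, sequences = FALSE)
  co0 <- simulate_end_reads(simulate_isoform_counts(co0))
  expect_true(all(co0$reads$n_unaligned_T >= 2))

  cfg <- cohort_config(n_genes = 50, internal_priming_rate = 0.2,
                       depth_per_gene = 100, seed = 4)
  co <- generate_gene_models(cfg, sequences = FALSE)
  co <- simulate_end_reads(simulate_isoform_counts(co))
  n <- nrow(co$reads)
  expect_gt(n, 5000)
  frac <- mean(co$reads$n_unaligned_T >= 2)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 0.002)

  co_zero <- generate_gene_models(cohort_config(n_genes = 10,
                                                depth_per_gene = 0, seed = 1),
                                  sequences = FALSE)
  co_zero <- simulate_end_reads(simulate_isoform_counts(co_zero))
  expect_identical(nrow(co_zero$reads), 0L)
})

test_that("planted sites sit inside planted elevated peaks inside aUTRs", {
  co <- mixed_cohort()
  ts <- co$truth$sites
  tp <- co$truth$peaks
  m <- co$models
  expect_gt(nrow(ts), 0)
  for (i in seq_len(nrow(ts))) {
    g <- ts$gene[i]
    pk <- tp[tp$gene == g, ]
    expect_true(any(ts$start[i] >= pk$start & ts$end[i] <= pk$end))
    j <- match(g, m$gene)
    expect_gte(ts$start[i], m$autr_start[j])
    expect_lte(ts$end[i], m$autr_end[j])
  }
  # elevated peaks themselves lie within their gene's aUTR
  j <- match(tp$gene, m$gene)
  expect_true(all(tp$start >= m$autr_start[j] & tp$end <= m$autr_end[j]))
})

test_that("conservation is pinned at planted sites over background", {
  co <- mixed_cohort()
  ts <- co$truth$sites
  v <- vapply(seq_len(nrow(ts)), function(i)
    mean_conservation(co$conservation, ts$chrom[i], ts$start[i], ts$end[i]),
    numeric(1))
  expect_true(all(v == co$config$site_conservation))
  # background away from any footprint
  expect_equal(mean_conservation(co$conservation, "chrS", 0, 500),
               co$config$background_conservation)
})

test_that("planted sequences actually carry the candidate at the truth locus", {
  co <- mixed_cohort()
  ts <- co$truth$sites
  m <- co$models
  for (i in seq_len(nrow(ts))) {
    j <- match(ts$gene[i], m$gene)
    g_seq <- substr(co$sequences[["chrS"]], ts$start[i] + 1L, ts$end[i])
    sense <- if (m$strand[j] == "+") g_seq else
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(g_seq, "")[[1]]), collapse = ""))
    expect_identical(sense, ts$sequence[i])
  }
})

test_that("knockdown overlap planting hits its rate and is seeded", {
  genes <- sprintf("g%04d", 1:4000)
  q1 <- simulate_knockdown_overlap(genes, 0.67, seed = 77)
  q2 <- simulate_knockdown_overlap(genes, 0.67, seed = 77)
  expect_identical(q1, q2)
  frac <- length(q1) / length(genes)
  expect_lt(abs(frac - 0.67), 3 * sqrt(0.67 * 0.33 / 4000))
})
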