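test_that("poly(A) evidence filter applies the untemplated-T threshold", {
  reads <- data.frame(pos = c(10, 20, 30), n_unaligned_T = c(1, 2, 5))
  kept <- filter_polya_evidence(reads)
  expect_identical(kept$pos, c(20, 30))
  expect_identical(nrow(filter_polya_evidence(reads[0, ])), 0L)
  expect_identical(filter_polya_evidence(reads, min_T = 0), reads)
})

test_that("end-site clustering picks max support with a 5'-ward tie-break", {
  s <- cluster_end_sites(c(100, 100, 102, 100), window = 24, strand = "+")
  expect_identical(s$coord, 100L)
  expect_identical(s$support, 4L)

  s2 <- cluster_end_sites(c(100, 150), window = 24)
  expect_identical(nrow(s2), 2L)

  expect_identical(cluster_end_sites(500L)$support, 1L)

  # tie: equal support at 200 and 210 -> 5'-most depends on strand
  tie <- c(200, 200, 210, 210)
  expect_identical(cluster_end_sites(tie, strand = "+")$coord, 200L)
  expect_identical(cluster_end_sites(tie, strand = "-")$coord, 210L)
})

test_that("clustering is invariant to read order", {
  set.seed(42)
  pos <- sample(c(rep(1000, 5), rep(1010, 3), 1200, rep(1500, 7)))
  a <- cluster_end_sites(pos)
  b <- cluster_end_sites(rev(pos))
  c <- cluster_end_sites(sort(pos))
  expect_identical(a, b)
  expect_identical(a, c)
})

test_that("top-two isoform selection orders by support then strandwise position", {
  model_p <- data.frame(strand = "+", cds_end = 500, last_exon_start = 400,
                        last_exon_end = 2000)
  sites <- data.frame(coord = c(1000, 1500, 1800),
                      support = c(500, 300, 100))
  top <- select_top_two_isoforms(sites, model_p)
  expect_identical(top$proximal$coord, 1000)
  expect_identical(top$distal$coord, 1500)

  model_m <- data.frame(strand = "-", cds_end = 6000, last_exon_start = 4000,
                        last_exon_end = 6200)
  sites_m <- data.frame(coord = c(5000, 4400), support = c(400, 350))
  top_m <- select_top_two_isoforms(sites_m, model_m)
  expect_identical(top_m$proximal$coord, 5000)
  expect_identical(top_m$distal$coord, 4400)

  expect_error(
    select_top_two_isoforms(data.frame(coord = 1000, support = 9), model_p),
    class = "apamir_no_alt_pa")
  # sites outside the 3'UTR do not count
  expect_error(
    select_top_two_isoforms(data.frame(coord = c(450, 1000),
                                       support = c(5, 5)), model_p),
    class = "apamir_no_alt_pa")
})

test_that("annotated-site assignment uses nearest-within-tolerance with 5' ties", {
  model <- data.frame(strand = "+", pa_proximal = 1000, pa_distal = 1500)
  counts <- assign_reads_to_annotated_pas(data.frame(pos = 1003), model)
  expect_identical(unname(counts), c(1L, 0L))

  counts2 <- assign_reads_to_annotated_pas(data.frame(pos = 1250), model)
  expect_identical(unname(counts2), c(0L, 0L))

  model_tie <- data.frame(strand = "+", pa_proximal = 1240, pa_distal = 1260)
  counts3 <- assign_reads_to_annotated_pas(data.frame(pos = 1250), model_tie)
  expect_identical(unname(counts3), c(1L, 0L))

  # wrong-strand reads are ignored (990 would otherwise count to 1000) and
  # out-of-tolerance reads are discarded, so totals never exceed the input
  reads <- data.frame(pos = c(1001, 1499, 1250, 990),
                      strand = c("+", "+", "+", "-"))
  counts4 <- assign_reads_to_annotated_pas(reads, model)
  expect_identical(unname(counts4), c(1L, 1L))
  reads$strand <- "+"
  expect_identical(unname(assign_reads_to_annotated_pas(reads, model)),
                   c(2L, 1L))
  expect_lte(sum(counts4), nrow(reads))
})

test_that("the SAM reader derives untemplated-T counts from soft clips", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrA\tLN:10000",
    # forward alignment, leading clip TTTG -> reading inward: T,T,T -> but
    # boundary-adjacent run is G? clip string is TTTG; inward = G,T,T,T
    paste("r1", 0, "chrA", 101, 60, "4S20M", "*", 0, 0,
          paste0("GTTT", strrep("A", 20)), "*", sep = "\t"),
    # forward alignment, clip TTT fully untemplated
    paste("r2", 0, "chrA", 201, 60, "3S20M", "*", 0, 0,
          paste0("TTT", strrep("C", 20)), "*", sep = "\t"),
    # reverse alignment: untemplated tail appears as trailing As
    paste("r3", 16, "chrA", 301, 60, "20M5S", "*", 0, 0,
          paste0(strrep("C", 20), "AAAAA"), "*", sep = "\t"),
    # unmapped read is skipped
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "*", sep = "\t"),
    # no soft clip -> zero evidence
    paste("r5", 0, "chrA", 401, 60, "20M", "*", 0, 0,
          strrep("C", 20), "*", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  reads <- read_end_reads_sam(path)
  expect_identical(nrow(reads), 4L)
  r <- function(g) reads[reads$gene == g, ]
  # r1: clipped prefix GTTT; adjacent to boundary inward: T,T,T then G stops
  expect_identical(r("r1")$n_unaligned_T, 3L)
  expect_identical(r("r1")$strand, "-")
  expect_identical(r("r1")$pos, 100L)  # 0-based alignment start
  expect_identical(r("r2")$n_unaligned_T, 3L)
  expect_identical(r("r3")$n_unaligned_T, 5L)
  expect_identical(r("r3")$strand, "+")
  expect_identical(r("r3")$pos, 320L)  # 0-based exclusive alignment end
  expect_identical(r("r5")$n_unaligned_T, 0L)
})

test_that("per-gene site recovery finds planted coordinates on both strands", {
  co <- mixed_cohort()
  rec <- recover_pa_sites(co$reads, co$models)
  m <- co$models
  ok <- rec$status == "ok"
  expect_gt(mean(ok), 0.95)
  hit <- ok & abs(rec$proximal - m$pa_proximal) <= 5 &
    abs(rec$distal - m$pa_distal) <= 5
  expect_gt(mean(hit), 0.9)
  expect_gt(sum(hit & m$strand == "-"), 0)
})
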