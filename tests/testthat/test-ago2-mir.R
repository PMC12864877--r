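test_that("fold-change flagging applies the pseudocount and strict threshold", {
  autrs <- data.frame(gene = "g1", chrom = "chrA", start = 100, end = 800,
                      strand = "+")
  peaks <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      chrom = "chrA",
                      start = c(150, 300, 500, 2000),
                      end = c(210, 360, 560, 2060),
                      cov_ref = c(4, 2, 1.5, 1),
                      cov_alt = c(10, 2, 3.5, 9))
  fl <- flag_increased_peaks(peaks, autrs)
  # p4 does not overlap the aUTR and is dropped
  expect_identical(sort(fl$peaks$peak_id), c("p1", "p2", "p3"))
  # (10 + .5)/(4 + .5) = 2.333... -> increased
  expect_equal(fl$peaks$fc[fl$peaks$peak_id == "p1"], 10.5 / 4.5)
  expect_true(fl$peaks$increased[fl$peaks$peak_id == "p1"])
  # equal coverage -> fc 1
  expect_false(fl$peaks$increased[fl$peaks$peak_id == "p2"])
  # fc exactly 2 is NOT increased (strict)
  expect_equal(fl$peaks$fc[fl$peaks$peak_id == "p3"], 2)
  expect_false(fl$peaks$increased[fl$peaks$peak_id == "p3"])
  expect_true(fl$gene_flags$increased_peak[1])
})

test_that("candidate scanning is exact, peak-restricted and per-candidate", {
  seq <- paste0(strrep("C", 37), "ACATTCC", strrep("C", 156))
  autr <- data.frame(gene = "g1", chrom = "chrA", start = 1000, end = 1200,
                     strand = "+", sequence = seq)
  peaks <- data.frame(peak_id = "pk1", chrom = "chrA", gene = "g1",
                      start = 1020, end = 1080, increased = TRUE)
  hits <- scan_candidate_sequences(autr, peaks)
  expect_identical(hits$autr_offset, 37L)
  expect_identical(hits$mirna, "miR-1/206-7mer")
  expect_identical(hits$start, 1037)
  expect_identical(hits$peak_id, "pk1")

  # motif-free sequence
  autr2 <- autr
  autr2$sequence <- strrep("C", 200)
  expect_identical(nrow(scan_candidate_sequences(autr2, peaks)), 0L)

  # a hit outside every increased peak is not reported
  peaks_far <- peaks
  peaks_far$start <- 1100; peaks_far$end <- 1160
  expect_identical(nrow(scan_candidate_sequences(autr, peaks_far)), 0L)

  # overlapping candidates are each reported
  autr3 <- autr
  autr3$sequence <- paste0(strrep("C", 37), "ACATTCCA", strrep("C", 155))
  hits3 <- scan_candidate_sequences(autr3, peaks)
  expect_setequal(hits3$mirna, c("miR-1/206-7mer", "miR-1/206-8mer"))
  expect_true(all(hits3$autr_offset == 37L))

  expect_error(scan_candidate_sequences(autr, peaks, candidates =
                                          myomir_candidates()[0, ]),
               "empty candidate")
})

test_that("planted sites are recalled perfectly; scrambles never match", {
  co <- mixed_cohort()
  autrs <- derive_autrs(co$models, co$sequences)
  fl <- flag_increased_peaks(co$peaks, autrs)
  sc <- scan_cohort_candidates(autrs, fl, co$config$candidates)
  ts <- co$truth$sites
  expect_gt(nrow(ts), 0)
  key_t <- paste(ts$gene, ts$start, ts$end)
  key_h <- paste(sc$hits$gene, sc$hits$start, sc$hits$end)
  expect_true(all(key_t %in% key_h))           # recall = 1
  expect_true(all(sc$hits$gene %in% ts$gene))  # no off-truth genes

  scrambled <- co$config$candidates
  scrambled$sequence <- vapply(strsplit(scrambled$sequence, ""),
                               function(x) paste(rev(x), collapse = ""),
                               character(1))
  sc0 <- scan_cohort_candidates(autrs, fl, scrambled)
  expect_identical(nrow(sc0$hits), 0L)
})

test_that("every reported hit satisfies the containment chain", {
  co <- mixed_cohort()
  autrs <- derive_autrs(co$models, co$sequences)
  fl <- flag_increased_peaks(co$peaks, autrs)
  sc <- scan_cohort_candidates(autrs, fl, co$config$candidates)
  inc <- fl$peaks[fl$peaks$increased, ]
  for (i in seq_len(nrow(sc$hits))) {
    h <- sc$hits[i, ]
    pk <- inc[inc$peak_id == h$peak_id, ]
    a <- autrs[autrs$gene == h$gene, ]
    expect_true(h$start >= pk$start && h$end <= pk$end)
    expect_true(pk$start >= a$start && pk$end <= a$end)
  }
})

test_that("proportions are order-invariant and survive peak fragmentation", {
  co <- mixed_cohort()
  autrs <- derive_autrs(co$models, co$sequences)
  fl <- flag_increased_peaks(co$peaks, autrs)
  cls <- setNames(co$models$class, co$models$gene)
  flags <- setNames(fl$gene_flags$increased_peak, fl$gene_flags$gene)
  p1 <- class_proportions(flags, cls)

  perm <- rev(seq_along(cls))
  p2 <- class_proportions(flags[perm], cls[perm])
  expect_identical(p1, p2)

  # split every peak at its midpoint: footprints unchanged, flags unchanged
  pk <- co$peaks
  mid <- floor((pk$start + pk$end) / 2)
  frag <- rbind(
    transform(pk, end = mid, peak_id = paste0(peak_id, "a")),
    transform(pk, start = mid, peak_id = paste0(peak_id, "b")))
  fl2 <- flag_increased_peaks(frag, autrs)
  expect_identical(
    fl2$gene_flags[order(fl2$gene_flags$gene), ],
    fl$gene_flags[order(fl$gene_flags$gene), ])
})

test_that("class proportions report counts and handle empty classes", {
  flags <- setNames(c(rep(TRUE, 7), rep(FALSE, 3)), sprintf("g%02d", 1:10))
  cls <- setNames(rep("shorten", 10), names(flags))
  p <- class_proportions(flags, cls)
  expect_equal(p$proportion[p$class == "shorten"], 70)
  expect_identical(p$n_flagged[p$class == "shorten"], 7L)
  expect_true(is.na(p$proportion[p$class == "lengthen"]))
  expect_error(class_proportions(flags[1:5], cls), "both a class and a flag")
})
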