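# Shared fixtures: cohorts are generated once per test run and cached, so
# several test files can probe the same simulated data without repaying
# the simulation cost.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) assign(key, maker(), .fixture_cache)
  get(key, .fixture_cache)
}

# A mixed-class cohort with all layers (sequences, reads, peaks, track).
mixed_cohort <- function() {
  cached("mixed", function() {
    simulate_cohort(cohort_config(n_genes = 120, frac_shorten = 0.5,
                                  frac_lengthen = 0.2, depth_per_gene = 60,
                                  seed = 11))
  })
}

# Single-class 1000-gene cohorts at generator defaults (used by the
# planted-truth recovery checks; counts layers omitted where not needed).
class_cohort <- function(class) {
  key <- paste0("class_", class)
  seed <- c(shorten = 101L, lengthen = 102L, nc = 103L)[[class]]
  cached(key, function() {
    simulate_cohort(cohort_config(
      n_genes = 1000,
      frac_shorten = as.numeric(class == "shorten"),
      frac_lengthen = as.numeric(class == "lengthen"),
      depth_per_gene = 0, seed = seed), reads = FALSE)
  })
}

# Detection-side proportions for a cohort: AGO2 peak flags and myomiR site
# flags computed by the analysis operations (never read from truth).
detect_flags <- function(co) {
  autrs <- derive_autrs(co$models, co$sequences)
  fl <- flag_increased_peaks(co$peaks, autrs)
  sc <- scan_cohort_candidates(autrs, fl, co$config$candidates)
  list(autrs = autrs, flagged = fl, scanned = sc,
       pct_peak = 100 * mean(fl$gene_flags$increased_peak),
       pct_site = 100 * mean(sc$gene_flags$has_site))
}

# A tiny two-gene reference for hand-computable interval work: one plus
# and one minus gene with known sequences.
toy_reference <- function() {
  seqs <- c(chrA = paste(rep("C", 400), collapse = ""))
  model_plus <- data.frame(gene = "gp", chrom = "chrA", strand = "+",
                           last_exon_start = 10, last_exon_end = 320,
                           cds_end = 50, stringsAsFactors = FALSE)
  model_minus <- data.frame(gene = "gm", chrom = "chrA", strand = "-",
                            last_exon_start = 10, last_exon_end = 320,
                            cds_end = 300, stringsAsFactors = FALSE)
  list(sequences = seqs, plus = model_plus, minus = model_minus)
}

# Patch specific bases of a chromosome string (1-based positions).
patch_seq <- function(seqs, chrom, at, replacement) {
  s <- seqs[[chrom]]
  substr(s, at, at + nchar(replacement) - 1L) <- replacement
  seqs[[chrom]] <- s
  seqs
}
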