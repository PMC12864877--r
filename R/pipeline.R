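#' Pipeline run configuration
#'
#' Collects paths, thresholds and the mode of a full pipeline run. In
#' synthetic mode a [cohort_config()] block is required and every input is
#' generated; in real mode per-gene counts (TSV) are required and peaks
#' (BED6+2), a genome (FASTA), gene models (TSV) and a conservation track
#' (bedGraph) are optional — stages whose inputs are absent are skipped.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param out Output directory.
#' @param cohort `cohort_config` block (synthetic mode).
#' @param counts,models,genome,peaks,conservation Input paths (real mode).
#' @param apa_mode Classification mode, see [classify_apa_table()].
#' @param alpha FDR threshold.
#' @param fc_threshold AGO2 peak fold-change threshold.
#' @param pseudocount RED / coverage pseudocount.
#' @param seed Run seed (synthetic mode; defaults to the cohort seed).
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("synthetic", "real"), out = tempfile("apamir_"),
                       cohort = cohort_config(), counts = NULL, models = NULL,
                       genome = NULL, peaks = NULL, conservation = NULL,
                       apa_mode = "quantseq", alpha = 0.05, fc_threshold = 2,
                       pseudocount = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || fc_threshold <= 0) stop("thresholds must be positive")
  if (mode == "synthetic" && !inherits(cohort, "cohort_config"))
    stop("synthetic mode requires a cohort_config block")
  if (!is.null(seed) && mode == "synthetic") cohort$seed <- as.integer(seed)
  structure(list(mode = mode, out = out, cohort = cohort, counts = counts,
                 models = models, genome = genome, peaks = peaks,
                 conservation = conservation, apa_mode = apa_mode,
                 alpha = alpha, fc_threshold = fc_threshold,
                 pseudocount = pseudocount),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full APA / myomiR analysis pipeline
#'
#' Executes simulate (synthetic mode) -> pA-site recovery -> APA
#' classification -> aUTR features -> AGO2/myomiR scanning -> conservation
#' -> expression metrics in dependency order, writing every intermediate
#' table plus a machine-readable `report.json` and a run manifest (file
#' MD5 sums and parameters) into `config$out`. The same config and seed
#' give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "synthetic") {
    cohort <- .stage("simulate", simulate_cohort(config$cohort))
    .stage("write", write_cohort(cohort, config$out))
    models <- cohort$models
    counts <- cohort$counts
    peaks <- cohort$peaks
    sequences <- cohort$sequences
    track <- cohort$conservation
    truth <- cohort$truth
    expression <- cohort$expression
  } else {
    for (f in c("counts")) if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop(sprintf("[stage inputs] missing required input: %s", f))
    for (f in c("models", "genome", "peaks", "conservation"))
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        stop(sprintf("[stage inputs] input file not found: %s", config[[f]]))
    counts <- .stage("inputs", read_counts_tsv(config$counts))
    models <- if (!is.null(config$models)) .read_tsv(config$models)
    sequences <- if (!is.null(config$genome))
      read_fasta_sequences(config$genome)
    peaks <- if (!is.null(config$peaks)) read_peaks_bed(config$peaks)
    track <- if (!is.null(config$conservation))
      read_bedgraph(config$conservation)
    truth <- NULL
    expression <- NULL
  }

  report <- list(package_version = as.character(packageVersion("apamir")),
                 mode = config$mode,
                 parameters = list(alpha = config$alpha,
                                   fc_threshold = config$fc_threshold,
                                   apa_mode = config$apa_mode,
                                   seed = if (config$mode == "synthetic")
                                     config$cohort$seed else NA))

  ## APA classification
  results <- .stage("classify",
                    classify_apa_table(counts, mode = config$apa_mode,
                                       alpha = config$alpha,
                                       pseudocount = config$pseudocount))
  .write_tsv(results, file.path(config$out, "apa_results.tsv"))
  report$class_counts <- as.list(table(results$apa_class))
  report$n_genes_analyzed <- nrow(results)

  ## pA-site recovery from read evidence (synthetic mode)
  if (config$mode == "synthetic" && !is.null(cohort$reads) &&
      nrow(cohort$reads) > 0L) {
    rec <- .stage("pa_sites", recover_pa_sites(cohort$reads, models))
    .write_tsv(rec, file.path(config$out, "pa_sites.tsv"))
    ok <- rec$status == "ok"
    hit <- ok & abs(rec$proximal - models$pa_proximal) <= 5L &
      abs(rec$distal - models$pa_distal) <= 5L
    report$pa_recovery <- list(n_genes = nrow(rec),
                               n_recovered = sum(hit, na.rm = TRUE),
                               rate = mean(hit, na.rm = FALSE))
  }

  ## aUTR features
  autrs <- NULL
  if (!is.null(models) && !is.null(sequences)) {
    autrs <- .stage("autr", derive_autrs(models, sequences))
    .write_tsv(autrs[, setdiff(names(autrs), "sequence")],
               file.path(config$out, "autr.tsv"))
    cls <- setNames(results$apa_class, results$gene)[autrs$gene]
    report$ugua <- list(
      mean_freq_shorten = mean(autrs$ugua_freq[cls == "shorten"]),
      mean_freq_nc = mean(autrs$ugua_freq[cls == "nc"]))
  }

  ## AGO2 peaks + myomiR candidate scan
  if (!is.null(autrs) && !is.null(peaks) && nrow(peaks) > 0L) {
    flagged <- .stage("ago2", flag_increased_peaks(peaks, autrs,
                                                   config$fc_threshold,
                                                   config$pseudocount))
    cands <- if (config$mode == "synthetic") config$cohort$candidates
             else myomir_candidates()
    scanned <- .stage("mir", scan_cohort_candidates(autrs, flagged, cands))
    .write_tsv(flagged$gene_flags, file.path(config$out, "gene_flags.tsv"))
    .write_tsv(scanned$hits, file.path(config$out, "target_hits.tsv"))
    cls_tab <- setNames(results$apa_class, results$gene)
    prop_peaks <- class_proportions(
      setNames(flagged$gene_flags$increased_peak, flagged$gene_flags$gene),
      cls_tab[autrs$gene])
    prop_sites <- class_proportions(
      setNames(scanned$gene_flags$has_site, scanned$gene_flags$gene),
      cls_tab[autrs$gene])
    names(prop_peaks)[4] <- "pct_increased_peak"
    names(prop_sites)[4] <- "pct_with_site"
    .write_tsv(merge(prop_peaks[, c(1, 2, 4)], prop_sites[, c(1, 2, 4)]),
               file.path(config$out, "proportions.tsv"))
    report$proportions <- list(
      increased_peak = setNames(prop_peaks$pct_increased_peak,
                                prop_peaks$class),
      with_site = setNames(prop_sites$pct_with_site, prop_sites$class))
  }

  ## Conservation metaprofile and PAS comparison (needs truth or track)
  if (!is.null(track) && config$mode == "synthetic" &&
      nrow(truth$sites) > 0L) {
    sites <- truth$sites
    sites$strand <- models$strand[match(sites$gene, models$gene)]
    prof <- .stage("conservation", site_metaprofile(track, sites, flank = 50L))
    .write_tsv(prof, file.path(config$out, "site_metaprofile.tsv"))
    inside <- prof$offset >= 0 & prof$offset < min(sites$end - sites$start)
    report$conservation <- list(
      site_mean = mean(prof$mean[inside]),
      flank_mean = mean(prof$mean[prof$offset < -5]))
    pas_scores <- vapply(seq_len(nrow(models)), function(i) {
      c0 <- models$pa_proximal[i]
      iv <- if (models$strand[i] == "+") c(c0 - 21L, c0 - 15L)
            else c(c0 + 15L, c0 + 21L)
      mean_conservation(track, models$chrom[i], iv[1], iv[2])
    }, numeric(1))
    sh <- models$class == "shorten"
    if (any(sh) && any(!sh)) {
      cmp <- compare_score_distributions(pas_scores[sh], pas_scores[!sh])
      report$conservation$pas_shorten_vs_other_p <- cmp$p_value
    }
  }

  ## Expression metrics by class
  if (!is.null(expression)) {
    em <- .stage("expr", .expression_metrics(expression, results))
    .write_tsv(em$per_gene, file.path(config$out, "expression_metrics.tsv"))
    .write_tsv(em$summary$summary,
               file.path(config$out, "expression_summary.tsv"))
    report$delta_pe_tests <- em$summary$tests
  }

  ## Recapitulation of shortening under CFI knockdown (synthetic mode)
  if (config$mode == "synthetic") {
    ref_short <- truth$genes$gene[truth$genes$planted_class == "shorten"]
    if (length(ref_short) > 0L) {
      rates <- config$cohort$cfi_recap
      report$recapitulation <- lapply(seq_along(rates), function(j) {
        q <- simulate_knockdown_overlap(ref_short, rates[[j]],
                                        config$cohort$seed + 10L + j)
        recapitulation_fraction(ref_short, q)
      })
      names(report$recapitulation) <- names(rates)
    }
  }

  jsonlite::write_json(report, file.path(config$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- setdiff(list.files(config$out, full.names = TRUE),
                   file.path(config$out, "manifest.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(config$out, "manifest.tsv"))
  invisible(report)
}

.expression_metrics <- function(expression, results) {
  conds <- .apamir_conditions
  get <- function(fraction, condition) {
    sub <- expression[expression$fraction == fraction &
                        expression$condition == condition, ]
    setNames(sub$rpkm, sub$gene)
  }
  genes <- unique(expression$gene)
  pe1 <- polysome_enrichment(get("polysome", conds[["ref"]])[genes],
                             get("input", conds[["ref"]])[genes])
  pe2 <- polysome_enrichment(get("polysome", conds[["alt"]])[genes],
                             get("input", conds[["alt"]])[genes])
  cn1 <- cn_ratio(get("cytoplasm", conds[["ref"]])[genes],
                  get("nucleus", conds[["ref"]])[genes])
  cn2 <- cn_ratio(get("cytoplasm", conds[["alt"]])[genes],
                  get("nucleus", conds[["alt"]])[genes])
  per_gene <- data.frame(gene = genes, pe_ref = pe1, pe_alt = pe2,
                         delta_pe = delta_pe(pe2, pe1),
                         cn_ref = cn1, cn_alt = cn2,
                         delta_cn = delta_cn(cn2, cn1),
                         stringsAsFactors = FALSE, row.names = NULL)
  cls <- setNames(results$apa_class, results$gene)[genes]
  list(per_gene = per_gene,
       summary = group_summary(per_gene$delta_pe, cls))
}

#' Intersection pattern counts for multiple event sets
#'
#' Upset-style summary: for two or more named sets, the count of elements
#' realizing every non-empty membership pattern, ordered by pattern
#' cardinality (descending) then by pattern label.
#'
#' @param sets Named list (>= 2) of vectors.
#' @return Data.frame: pattern (labels joined by `&`), degree, count.
#' @export
compare_event_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    stop("need a named list of at least two sets")
  labels <- names(sets)
  universe <- unique(unlist(sets))
  mem <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  mem <- matrix(mem, nrow = length(universe))
  pattern <- apply(mem, 1L, function(r) paste(labels[r], collapse = "&"))
  tab <- table(pattern[pattern != ""])
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$degree <- lengths(strsplit(out$pattern, "&", fixed = TRUE))
  out <- out[order(-out$degree, out$pattern), c("pattern", "degree", "count")]
  rownames(out) <- NULL
  out
}
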