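#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (length/1000) / (library_size/1e6)`; linear in counts,
#' inversely linear in gene length.
#'
#' @param count Read count (vectorized).
#' @param gene_length_nt Gene (or region) length in nt, > 0.
#' @param library_size Total mapped reads, > 0.
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, gene_length_nt, library_size) {
  if (any(gene_length_nt <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count / (gene_length_nt / 1000) / (library_size / 1e6)
}

#' Cytoplasm-to-nucleus ratio and its cross-condition change
#'
#' `cn_ratio = (cytoplasmic + eps)/(nuclear + eps)`, a proxy for nuclear
#' export; `delta_cn` is the log2 change of the ratio between two
#' conditions and negates exactly under condition swap.
#'
#' @param cyto_rpkm,nuc_rpkm Compartment RPKM values.
#' @param pseudocount Stabilizing pseudocount (default 0.1 RPKM).
#' @return Ratio (or log2 change).
#' @export
cn_ratio <- function(cyto_rpkm, nuc_rpkm, pseudocount = 0.1) {
  stopifnot(all(cyto_rpkm >= 0), all(nuc_rpkm >= 0))
  (cyto_rpkm + pseudocount) / (nuc_rpkm + pseudocount)
}

#' @rdname cn_ratio
#' @param ratio_cond2,ratio_cond1 C/N ratios in comparison and reference
#'   conditions.
#' @export
delta_cn <- function(ratio_cond2, ratio_cond1) {
  log2(ratio_cond2 / ratio_cond1)
}

#' Polysome enrichment and its cross-condition change
#'
#' `pe = (polysome + eps)/(input + eps)`, a proxy for translational
#' engagement; `delta_pe` is its log2 change between conditions.
#'
#' @param poly_rpkm,input_rpkm Fraction RPKM values.
#' @param pseudocount Stabilizing pseudocount (default 0.1 RPKM).
#' @return Enrichment (or log2 change).
#' @export
polysome_enrichment <- function(poly_rpkm, input_rpkm, pseudocount = 0.1) {
  stopifnot(all(poly_rpkm >= 0), all(input_rpkm >= 0))
  (poly_rpkm + pseudocount) / (input_rpkm + pseudocount)
}

#' @rdname polysome_enrichment
#' @param pe_cond2,pe_cond1 Enrichment in comparison and reference
#'   conditions.
#' @export
delta_pe <- function(pe_cond2, pe_cond1) {
  log2(pe_cond2 / pe_cond1)
}

#' Split shortened genes into shortening-magnitude tertiles
#'
#' Ranks genes by |red_log2| descending (stable tie-break on gene id) and
#' assigns high/middle/low groups whose sizes differ by at most one; when
#' the count is not divisible by three, the extra members go to the
#' higher-magnitude groups first.
#'
#' @param genes Gene ids.
#' @param red_log2 Matching RED log2 values.
#' @return Named factor (levels high/middle/low) indexed by gene.
#' @export
tertile_split <- function(genes, red_log2) {
  n <- length(genes)
  if (n < 3L) stop("need at least 3 genes for a tertile split")
  o <- order(-abs(red_log2), genes)
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- base + (seq_len(3L) <= extra)
  grp <- rep(c("high", "middle", "low"), times = sizes)
  out <- factor(character(n), levels = c("high", "middle", "low"))
  out[o] <- grp
  names(out) <- genes
  out
}

#' Per-class summary statistics with pairwise rank-sum tests
#'
#' Median, quartiles (linear interpolation, type 7) and Tukey whisker
#' bounds (most extreme values within 1.5 IQR of the box) per class, plus
#' pairwise two-sided Wilcoxon rank-sum p-values via
#' [compare_score_distributions()]. Empty classes are excluded with a
#' warning.
#'
#' @param values Numeric vector.
#' @param classes Matching class labels.
#' @return List with `summary` and `tests` data.frames.
#' @export
group_summary <- function(values, classes) {
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes[keep])
  lev <- unique(classes)
  empty <- setdiff(unique(stats::na.omit(classes)), lev)
  groups <- split(values, classes)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < length(unique(classes)))
    warning("empty class(es) excluded from summary")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(class = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(groups) >= 2L) combn(names(groups), 2L) else
    matrix(character(0), nrow = 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    cmp <- compare_score_distributions(groups[[pairs[1, j]]],
                                       groups[[pairs[2, j]]])
    data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  }))
  if (is.null(tests))
    tests <- data.frame(class_a = character(0), class_b = character(0),
                        p_value = numeric(0))
  list(summary = summ, tests = tests)
}

#' Normalized log2 fold change of expression
#'
#' Library-size-normalized log2 fold change for heatmap-style reporting of
#' 3'-processing-factor expression. This is a descriptive quantity, not a
#' differential-expression test.
#'
#' @param count2,count1 Raw counts in comparison and reference samples.
#' @param libsize2,libsize1 Library sizes.
#' @param pseudocount Count pseudocount (default 0.5).
#' @return log2 fold change.
#' @export
normalized_log2fc <- function(count2, count1, libsize2, libsize1,
                              pseudocount = 0.5) {
  log2(((count2 + pseudocount) / libsize2) /
         ((count1 + pseudocount) / libsize1))
}
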