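#' Relative expression difference (RED) between two conditions
#'
#' RED is the cross-condition ratio of distal-to-proximal isoform odds:
#' `((d2 + c)/(p2 + c)) / ((d1 + c)/(p1 + c))`, condition 1 being the
#' reference (proliferating cells) and condition 2 the comparison
#' (differentiated myotubes). Its log2 is the delta-log2(d-pA/p-pA) form;
#' the printed classification thresholds 1.2 and 5/6 correspond to
#' +/- log2(6/5) ~ 0.263 on the log scale. The pseudocount applies to RED
#' only, never to the Fisher test counts.
#'
#' @param p1,d1 Proximal/distal counts in the reference condition.
#' @param p2,d2 Proximal/distal counts in the comparison condition.
#' @param pseudocount Added to every count (default 0.5).
#' @return List with `red_ratio` and `red_log2` (vectorized).
#' @export
compute_red <- function(p1, d1, p2, d2, pseudocount = 0.5) {
  stopifnot(all(c(p1, d1, p2, d2) >= 0))
  c0 <- pseudocount
  all_zero <- (p1 + d1 + p2 + d2) == 0
  ratio <- ((d2 + c0) / (p2 + c0)) / ((d1 + c0) / (p1 + c0))
  ratio[all_zero] <- NA_real_
  # summed-log form: swapping the two conditions negates red_log2 exactly
  # (bit for bit), which log2(ratio) does not guarantee in floating point
  lg <- (log2(d2 + c0) - log2(p2 + c0)) - (log2(d1 + c0) - log2(p1 + c0))
  lg[all_zero] <- NA_real_
  list(red_ratio = ratio, red_log2 = lg)
}

#' Two-sided Fisher exact test for a 2x2 isoform table
#'
#' Exact two-sided p-value by hypergeometric enumeration with fixed
#' margins: the sum of probabilities of all tables whose probability does
#' not exceed the observed one (with relative tolerance 1e-7 on the
#' comparison, the standard guard against floating-point ties).
#' Degenerate margins (an all-zero row or column) return p = 1.
#'
#' @param p1,d1,p2,d2 Non-negative integer counts, rows = conditions,
#'   columns = proximal/distal.
#' @return Two-sided p-value.
#' @export
fisher_exact_two_sided <- function(p1, d1, p2, d2) {
  stopifnot(p1 >= 0, d1 >= 0, p2 >= 0, d2 >= 0)
  m <- p1 + d1          # row 1 margin
  n2 <- p2 + d2         # row 2 margin
  k <- p1 + p2          # column margin (proximal)
  if (m == 0 || n2 == 0 || k == 0 || (d1 + d2) == 0) return(1)
  pv <- .fisher_pvec(m, n2, k)
  pv[[match(p1, max(0L, k - n2):min(k, m))]]
}

# Two-sided p for every feasible table with margins (m, n2, k), in support
# order x = max(0, k - n2) .. min(k, m). Shared by the scalar front-end.
.fisher_pvec <- function(m, n2, k) {
  x <- max(0L, k - n2):min(k, m)
  pmf <- dhyper(x, m, n2, k)
  thr <- pmf * (1 + 1e-7)
  vapply(seq_along(x), function(i) min(1, sum(pmf[pmf <= thr[i]])),
         numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up q-values: `q_(i) = min_{j >= i} p_(j) * n / j`, capped
#' at 1, returned in the input order.
#'
#' @param p Vector of p-values in \[0, 1\] (NA passed through).
#' @return Vector of q-values.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n > 0L) {
    o <- order(pv)
    qs <- pv[o] * n / seq_len(n)
    qs <- rev(cummin(rev(qs)))
    q[ok][o] <- pmin(qs, 1)
  }
  q
}

#' Classify an APA event from RED, q-value and read filters
#'
#' Lengthen iff `red_ratio > 6/5`, shorten iff `red_ratio < 5/6`, in both
#' cases requiring `q < alpha` and the mode-specific read filter;
#' everything else (including exact boundary values, which the strict
#' inequalities leave out) is "nc". Genes failing the filter are "nc" with
#' `passed_min_reads = FALSE`.
#'
#' @param red_ratio RED ratio (vectorized).
#' @param q_value BH-adjusted p-value.
#' @param passed_min_reads Logical read-filter flag.
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector in `c("shorten", "lengthen", "nc")`.
#' @export
classify_apa <- function(red_ratio, q_value, passed_min_reads = TRUE,
                         alpha = 0.05) {
  out <- rep("nc", length(red_ratio))
  ok <- passed_min_reads & !is.na(red_ratio) & !is.na(q_value) &
    q_value < alpha
  out[ok & red_ratio > 6 / 5] <- "lengthen"
  out[ok & red_ratio < 5 / 6] <- "shorten"
  out
}

#' Classify APA events for a whole count table
#'
#' Pools replicates per gene and condition into one 2x2 table, computes
#' RED (with pseudocount), the two-sided Fisher exact p-value (raw counts,
#' no pseudocount), BH q-values across the genes passing the mode-specific
#' read filter, and the shorten/lengthen/nc class. Filters:
#' `quantseq` requires >= `min_reads` (default 50) total reads over both
#' conditions; `rnaseq` requires each isoform to exceed 5 reads in at
#' least one sample of the compared pair.
#'
#' @param counts Data.frame: gene, condition, replicate, p_count, d_count.
#' @param mode `"quantseq"` or `"rnaseq"`.
#' @param alpha FDR threshold.
#' @param pseudocount RED pseudocount.
#' @param min_reads QuantSeq-mode minimum total reads per gene.
#' @param ref,alt Condition labels (default: order of first appearance).
#' @return Data.frame: gene, p1, d1, p2, d2, red_ratio, red_log2, p_value,
#'   q_value, passed_min_reads, apa_class, reproducible.
#' @export
classify_apa_table <- function(counts, mode = c("quantseq", "rnaseq"),
                               alpha = 0.05, pseudocount = 0.5,
                               min_reads = 50L, ref = NULL, alt = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "condition", "replicate", "p_count", "d_count")
                %in% names(counts)))
  conds <- unique(counts$condition)
  if (is.null(ref)) ref <- conds[1]
  if (is.null(alt)) alt <- setdiff(conds, ref)[1]
  if (is.na(alt)) stop("need two conditions")

  agg <- function(cond, col) {
    sub <- counts[counts$condition == cond, ]
    v <- tapply(sub[[col]], sub$gene, sum)
    v
  }
  genes <- sort(unique(counts$gene))
  p1 <- .at(agg(ref, "p_count"), genes); d1 <- .at(agg(ref, "d_count"), genes)
  p2 <- .at(agg(alt, "p_count"), genes); d2 <- .at(agg(alt, "d_count"), genes)

  red <- compute_red(p1, d1, p2, d2, pseudocount)

  passed <- if (mode == "quantseq") {
    (p1 + d1 + p2 + d2) >= min_reads
  } else {
    # each isoform > 5 reads in at least one sample of the compared pair
    pmax_s <- tapply(counts$p_count, counts$gene, max)
    dmax_s <- tapply(counts$d_count, counts$gene, max)
    .at(pmax_s, genes) > 5 & .at(dmax_s, genes) > 5
  }
  passed <- passed & (p1 + d1 + p2 + d2) > 0

  p_value <- rep(NA_real_, length(genes))
  idx <- which(passed)
  p_value[idx] <- vapply(idx, function(i)
    fisher_exact_two_sided(p1[i], d1[i], p2[i], d2[i]), numeric(1))
  q_value <- adjust_bh(p_value)

  res <- data.frame(
    gene = genes, p1 = p1, d1 = d1, p2 = p2, d2 = d2,
    red_ratio = red$red_ratio, red_log2 = red$red_log2,
    p_value = p_value, q_value = q_value, passed_min_reads = passed,
    apa_class = classify_apa(red$red_ratio, q_value, passed, alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$reproducible <- reproducible_events(counts, res, ref = ref, alt = alt,
                                          pseudocount = pseudocount)
  res
}

.at <- function(tab, keys) {
  v <- as.numeric(tab[keys])
  v[is.na(v)] <- 0
  v
}

#' Flag reproducible APA events across replicate pairs
#'
#' An event is reproducible when the pooled-count classification is
#' significant (non-nc) and every replicate pair's RED log2 has the same
#' sign as the pooled RED log2. Cohorts with a single replicate pair get
#' an undefined (NA) flag.
#'
#' @param counts Replicate-level count table (as in
#'   [classify_apa_table()]).
#' @param results Pooled classification results for the same genes.
#' @param ref,alt Condition labels.
#' @param pseudocount RED pseudocount for the per-replicate REDs.
#' @return Logical vector aligned with `results$gene` (NA if < 2 replicate
#'   pairs).
#' @export
reproducible_events <- function(counts, results, ref, alt,
                                pseudocount = 0.5) {
  reps <- sort(intersect(
    unique(counts$replicate[counts$condition == ref]),
    unique(counts$replicate[counts$condition == alt])))
  if (length(reps) < 2L) return(rep(NA, nrow(results)))
  sign_mat <- sapply(reps, function(r) {
    sub <- counts[counts$replicate == r, ]
    g <- function(cond, col) .at(
      tapply(sub[[col]][sub$condition == cond],
             sub$gene[sub$condition == cond], sum), results$gene)
    red <- compute_red(g(ref, "p_count"), g(ref, "d_count"),
                       g(alt, "p_count"), g(alt, "d_count"), pseudocount)
    sign(red$red_log2)
  })
  sign_mat <- matrix(sign_mat, nrow = nrow(results))
  pooled_sign <- sign(results$red_log2)
  concordant <- apply(sign_mat == pooled_sign, 1L, all)
  results$apa_class != "nc" & !is.na(concordant) & concordant
}

#' Fraction of reference events recapitulated in a query set
#'
#' `100 * |reference intersect query| / |reference|` — e.g. the percentage
#' of differentiation-induced shortening events that also shorten upon
#' depletion of a 3'-processing factor.
#'
#' @param reference Non-empty vector of reference gene ids.
#' @param query Vector of query gene ids.
#' @return Percentage (0-100).
#' @export
recapitulation_fraction <- function(reference, query) {
  if (length(reference) == 0L) stop("reference set is empty")
  100 * length(intersect(reference, query)) / length(unique(reference))
}

#' Select factors whose depletion induces global 3'UTR shortening
#'
#' Keeps the factors whose global log2(long/short) summary is strictly
#' below -0.8, sorted ascending (most shortening first).
#'
#' @param factor_summaries Named numeric vector: factor -> log2(L/S).
#' @return Character vector of factor names.
#' @export
select_shortening_factors <- function(factor_summaries) {
  hit <- factor_summaries[!is.na(factor_summaries) & factor_summaries < -0.8]
  names(hit)[order(hit)]
}
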