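#' Flag differentiation-increased AGO2 peaks within aUTRs
#'
#' Computes the normalized-coverage fold change
#' `fc = (cov_alt + c)/(cov_ref + c)` for every peak, keeps peaks that
#' overlap an aUTR by at least one base, marks a peak increased iff
#' `fc > fc_threshold` (strict, so fc exactly 2 is not increased), and
#' flags a gene iff at least one increased peak lies in its aUTR.
#'
#' @param peaks Data.frame: peak_id, chrom, start, end, cov_ref, cov_alt
#'   (0-based half-open intervals).
#' @param autrs aUTR table from [derive_autrs()].
#' @param fc_threshold Fold-change threshold (default 2).
#' @param pseudocount Coverage pseudocount guarding division by zero.
#' @return List with `peaks` (input rows overlapping an aUTR, plus `fc`,
#'   `increased` and the matched `gene`) and `gene_flags`
#'   (gene, increased_peak) covering every aUTR gene.
#' @export
flag_increased_peaks <- function(peaks, autrs, fc_threshold = 2,
                                 pseudocount = 0.5) {
  fc <- (peaks$cov_alt + pseudocount) / (peaks$cov_ref + pseudocount)
  gr_p <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L,
                                                  peaks$end))
  gr_a <- GenomicRanges::GRanges(autrs$chrom,
                                 IRanges::IRanges(autrs$start + 1L,
                                                  autrs$end))
  ov <- GenomicRanges::findOverlaps(gr_p, gr_a)
  kept <- peaks[S4Vectors::queryHits(ov), , drop = FALSE]
  kept$fc <- fc[S4Vectors::queryHits(ov)]
  kept$increased <- kept$fc > fc_threshold
  kept$gene <- autrs$gene[S4Vectors::subjectHits(ov)]
  rownames(kept) <- NULL
  flagged <- unique(kept$gene[kept$increased])
  gene_flags <- data.frame(gene = autrs$gene,
                           increased_peak = autrs$gene %in% flagged,
                           stringsAsFactors = FALSE)
  list(peaks = kept, gene_flags = gene_flags)
}

#' Scan increased AGO2 peaks for myomiR candidate target sequences
#'
#' Exact substring matches of each candidate sequence on the aUTR
#' sense-strand sequence, restricted to the footprints of increased peaks
#' (clipped to the aUTR): every reported hit satisfies
#' hit within peak within aUTR. All occurrences are reported.
#'
#' @param autr One aUTR record (with `sequence`).
#' @param peaks Increased peaks overlapping this gene's aUTR (e.g. the
#'   `peaks` element of [flag_increased_peaks()] filtered to
#'   `increased == TRUE`).
#' @param candidates Candidate table (`mirna`, `sequence`); empty input is
#'   a configuration error.
#' @return Data.frame: gene, mirna, sequence, autr_offset, start, end,
#'   peak_id (zero rows when nothing matches).
#' @export
scan_candidate_sequences <- function(autr, peaks,
                                     candidates = myomir_candidates()) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("empty candidate set: supply at least one candidate sequence")
  empty <- data.frame(gene = character(0), mirna = character(0),
                      sequence = character(0), autr_offset = integer(0),
                      start = integer(0), end = integer(0),
                      peak_id = character(0), stringsAsFactors = FALSE)
  pk <- peaks[peaks$chrom == autr$chrom &
                peaks$end > autr$start & peaks$start < autr$end, ,
              drop = FALSE]
  if (isTRUE(nrow(pk) == 0L)) return(empty)
  s <- chartr("Uu", "Tt", toupper(autr$sequence))
  plus <- autr$strand == "+"
  out <- list()
  for (ci in seq_len(nrow(candidates))) {
    motif <- chartr("Uu", "Tt", toupper(candidates$sequence[ci]))
    k <- nchar(motif)
    m <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    off <- as.integer(m) - 1L
    gs <- if (plus) autr$start + off else autr$end - off - k
    ge <- gs + k
    for (j in seq_along(off)) {
      within <- gs[j] >= pmax(pk$start, autr$start) &
        ge[j] <= pmin(pk$end, autr$end)
      if (any(within)) {
        pid <- if ("peak_id" %in% names(pk)) pk$peak_id[which(within)[1]]
               else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          gene = autr$gene, mirna = candidates$mirna[ci], sequence = motif,
          autr_offset = off[j], start = gs[j], end = ge[j], peak_id = pid,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Scan every aUTR of a cohort for candidate hits
#'
#' @param autrs aUTR table.
#' @param flagged Result of [flag_increased_peaks()] on the same aUTRs.
#' @param candidates Candidate table.
#' @return List with `hits` (all target hits) and `gene_flags`
#'   (gene, has_site).
#' @export
scan_cohort_candidates <- function(autrs, flagged,
                                   candidates = myomir_candidates()) {
  inc <- flagged$peaks[flagged$peaks$increased, , drop = FALSE]
  hits <- lapply(seq_len(nrow(autrs)), function(i) {
    scan_candidate_sequences(
      autrs[i, ], inc[inc$gene == autrs$gene[i], , drop = FALSE],
      candidates)
  })
  hits <- do.call(rbind, hits)
  gene_flags <- data.frame(gene = autrs$gene,
                           has_site = autrs$gene %in% hits$gene,
                           stringsAsFactors = FALSE)
  list(hits = hits, gene_flags = gene_flags)
}

#' Per-class proportions of flagged genes
#'
#' Percentage of genes carrying a flag (increased AGO2 peak, myomiR site,
#' ...) within each 3'UTR-change class; classes with no genes get a
#' missing proportion. Counts are returned for downstream confidence
#' intervals.
#'
#' @param flags Named logical vector or data.frame (gene, flag in second
#'   column).
#' @param classes Named character vector or data.frame (gene, class in
#'   second column).
#' @param levels Class levels to report.
#' @return Data.frame: class, n_genes, n_flagged, proportion (percent).
#' @export
class_proportions <- function(flags, classes,
                              levels = c("shorten", "lengthen", "nc")) {
  if (is.data.frame(flags)) flags <- setNames(flags[[2]], flags[[1]])
  if (is.data.frame(classes)) classes <- setNames(classes[[2]], classes[[1]])
  genes <- names(classes)
  if (!all(genes %in% names(flags)))
    stop("every gene needs both a class and a flag")
  fl <- flags[genes]
  out <- lapply(levels, function(cl) {
    sel <- classes == cl
    n <- sum(sel)
    k <- sum(fl[sel])
    data.frame(class = cl, n_genes = n, n_flagged = k,
               proportion = if (n > 0) 100 * k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
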