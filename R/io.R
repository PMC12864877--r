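# Tabular and track I/O. Standard formats go through Biostrings /
# rtracklayer; the package's own tables are plain TSV with a header line.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write cohort artifacts to a directory
#'
#' Serializes every layer of a synthetic cohort: gene models (TSV plus a
#' BED6 of last exons), chromosome sequences (FASTA), end reads, counts,
#' truth tables and candidate sequences (TSV), peaks (BED6 + two coverage
#' columns) and the conservation track (bedGraph).
#'
#' @param cohort An `apa_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(dir, f)

  paths["models"] <- .write_tsv(cohort$models, p("models.tsv"))
  if (nrow(cohort$models) > 0L) {
    gr <- GenomicRanges::GRanges(
      cohort$models$chrom,
      IRanges::IRanges(cohort$models$last_exon_start + 1L,
                       cohort$models$last_exon_end),
      strand = cohort$models$strand)
    S4Vectors::mcols(gr)$name <- cohort$models$gene
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, p("last_exons.bed"), format = "BED")
    paths["last_exons"] <- p("last_exons.bed")
  }
  if (!is.null(cohort$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(cohort$sequences), p("genome.fa"))
    paths["genome"] <- p("genome.fa")
  }
  if (!is.null(cohort$counts))
    paths["counts"] <- .write_tsv(cohort$counts, p("counts.tsv"))
  if (!is.null(cohort$reads))
    paths["reads"] <- .write_tsv(cohort$reads, p("end_reads.tsv"))
  if (!is.null(cohort$peaks)) {
    bed <- data.frame(chrom = cohort$peaks$chrom, start = cohort$peaks$start,
                      end = cohort$peaks$end, name = cohort$peaks$peak_id,
                      score = 0L, strand = cohort$peaks$strand,
                      cov_ref = cohort$peaks$cov_ref,
                      cov_alt = cohort$peaks$cov_alt)
    write.table(bed, p("peaks.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths["peaks"] <- p("peaks.bed")
    paths["peaks_tsv"] <- .write_tsv(cohort$peaks, p("peaks.tsv"))
  }
  if (!is.null(cohort$conservation)) {
    paths["conservation"] <-
      write_bedgraph(cohort$conservation, p("conservation.bedgraph"))
  }
  if (!is.null(cohort$expression))
    paths["expression"] <- .write_tsv(cohort$expression, p("expression.tsv"))
  paths["truth_genes"] <- .write_tsv(cohort$truth$genes, p("truth_genes.tsv"))
  paths["truth_sites"] <- .write_tsv(cohort$truth$sites, p("truth_sites.tsv"))
  paths["truth_peaks"] <- .write_tsv(cohort$truth$peaks, p("truth_peaks.tsv"))
  paths["candidates"] <- .write_tsv(cohort$config$candidates,
                                    p("candidates.tsv"))
  invisible(paths)
}

#' Read / write a bedGraph track
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()]
#' converting to/from the package's 0-based half-open
#' (chrom, start, end, value) data.frame representation.
#'
#' @param path bedGraph file path.
#' @return `read_bedgraph`: a track data.frame; `write_bedgraph`: the path,
#'   invisibly.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track Track data.frame (chrom, start, end, value).
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a peaks BED6+2 file (two trailing normalized-coverage columns)
#'
#' @param path BED path (no header; chrom, start, end, name, score,
#'   strand, cov_ref, cov_alt).
#' @return Peak data.frame as used by [flag_increased_peaks()].
#' @export
read_peaks_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop("expected BED6 plus two coverage columns")
  names(df)[1:8] <- c("chrom", "start", "end", "peak_id", "score", "strand",
                      "cov_ref", "cov_alt")
  df[, c("peak_id", "chrom", "start", "end", "strand", "cov_ref", "cov_alt")]
}

#' Read an isoform count table
#'
#' @param path TSV with columns gene, condition, replicate, p_count,
#'   d_count.
#' @return Count data.frame.
#' @export
read_counts_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene", "condition", "replicate", "p_count", "d_count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  df
}
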