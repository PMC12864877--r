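# Minimal SAM support for 3'-end reads.
#
# Rsamtools reads BAM; 3'-end pipelines frequently hand around small SAM
# text excerpts, so a purpose-built line reader is provided that derives
# the untemplated-T evidence from soft-clips. Conventions (documented, not
# configurable): a 3'-end read carries the reverse complement of the
# poly(A) tail at one end of the aligned sequence.
#
# * FLAG bit 0x10 unset: the aligned read points rightward, its 5' end (and
#   any untemplated Ts) sit in the LEADING soft-clip; the mRNA 3' end is at
#   the alignment start, so the gene lies on the minus strand. n_unaligned_T
#   counts consecutive 'T' in the clipped prefix reading inward from the
#   alignment boundary; the cleavage coordinate is the 0-based alignment
#   start (the start of the last transcribed base, the minus-strand
#   convention used throughout this package).
# * FLAG bit 0x10 set: the read was reverse-complemented by the aligner;
#   untemplated Ts appear as 'A's in the TRAILING soft-clip. The gene lies
#   on the plus strand and the cleavage coordinate is the 0-based exclusive
#   alignment end (BED-end convention).

.cigar_ref_len <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) return(0L)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

.soft_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^(\\d+)S" else "(\\d+)S$"
  m <- regmatches(cigar, regexec(pat, cigar))[[1]]
  if (length(m) < 2L) 0L else as.integer(m[2])
}

.run_length_from_boundary <- function(chars, base) {
  n <- 0L
  for (ch in chars) {
    if (ch != base) break
    n <- n + 1L
  }
  n
}

#' Read 3'-end reads from a SAM file
#'
#' Parses aligned records of a (headered or headerless) SAM text file into
#' the end-read table used by [filter_polya_evidence()] and
#' [recover_pa_sites()], deriving `n_unaligned_T` from soft-clipped
#' untemplated tails (T on the 5' clip for forward alignments, complemented
#' A on the 3' clip for reverse alignments; see the source header for the
#' full convention).
#'
#' @param path Path to a SAM file.
#' @return Data.frame: chrom, pos, strand, n_unaligned_T, gene (from the
#'   query name).
#' @export
read_end_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_unaligned_T = integer(0),
                      gene = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(f, function(x) {
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    cigar <- x[6]
    seq <- x[10]
    pos1 <- as.integer(x[4])
    if (bitwAnd(flag, 16L) == 0L) {
      clip <- .soft_clip(cigar, "left")
      prefix <- if (clip > 0L)
        rev(strsplit(substr(seq, 1L, clip), "")[[1]]) else character(0)
      nT <- .run_length_from_boundary(prefix, "T")
      data.frame(chrom = x[3], pos = pos1 - 1L, strand = "-",
                 n_unaligned_T = nT, gene = x[1], stringsAsFactors = FALSE)
    } else {
      clip <- .soft_clip(cigar, "right")
      suffix <- if (clip > 0L)
        strsplit(substr(seq, nchar(seq) - clip + 1L, nchar(seq)), "")[[1]]
      else character(0)
      nT <- .run_length_from_boundary(suffix, "A")
      data.frame(chrom = x[3], pos = pos1 - 1L + .cigar_ref_len(cigar),
                 strand = "+", n_unaligned_T = nT, gene = x[1],
                 stringsAsFactors = FALSE)
    }
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_unaligned_T = integer(0),
                      gene = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
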