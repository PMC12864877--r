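#' Derive the strand-aware alternative UTR (aUTR)
#'
#' The aUTR is the 3'UTR segment between the proximal and distal cleavage
#' coordinates, present only in the long isoform. On the plus strand it is
#' the half-open genomic interval `[proximal, distal)`; on the minus strand
#' `[distal, proximal)` with the sequence reverse-complemented so the
#' returned sequence always reads 5' to 3' on the mRNA. UGUA content is
#' annotated on construction.
#'
#' @param model Gene-model row (gene, chrom, strand).
#' @param proximal,distal Cleavage coordinates (BED-end convention).
#' @param sequences Named character vector of chromosome sequences.
#' @return One-row data.frame: gene, chrom, start, end, strand, length,
#'   sequence, ugua_count, ugua_freq.
#' @export
derive_autr <- function(model, proximal, distal, sequences) {
  if (proximal == distal) stop("proximal and distal sites coincide")
  plus <- model$strand == "+"
  if (plus && distal < proximal)
    stop("inverted site order for a plus-strand gene")
  if (!plus && distal > proximal)
    stop("inverted site order for a minus-strand gene")
  iv <- sort(c(proximal, distal))
  seq <- substr(sequences[[model$chrom]], iv[1] + 1L, iv[2])
  if (!plus) seq <- .revcomp(seq)
  u <- ugua_frequency(seq)
  data.frame(gene = model$gene, chrom = model$chrom,
             start = iv[1], end = iv[2], strand = model$strand,
             length = iv[2] - iv[1], sequence = seq,
             ugua_count = u$count, ugua_freq = u$frequency,
             stringsAsFactors = FALSE)
}

#' Derive aUTRs for all genes of a cohort
#'
#' @param models Gene-model table with `pa_proximal` / `pa_distal` columns
#'   (or supply a recovered-site table via `sites`).
#' @param sequences Chromosome sequences.
#' @param sites Optional data.frame (gene, proximal, distal) overriding the
#'   model coordinates; genes with NA sites are skipped.
#' @return Data.frame of aUTR records.
#' @export
derive_autrs <- function(models, sequences, sites = NULL) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    p <- models$pa_proximal[i]; d <- models$pa_distal[i]
    if (!is.null(sites)) {
      j <- match(models$gene[i], sites$gene)
      if (is.na(j) || is.na(sites$proximal[j])) return(NULL)
      p <- sites$proximal[j]; d <- sites$distal[j]
    }
    derive_autr(models[i, ], p, d, sequences)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      sequence = character(0), ugua_count = integer(0),
                      ugua_freq = numeric(0), stringsAsFactors = FALSE)
  out
}

#' UGUA (CFIm) motif count and frequency
#'
#' Counts sliding-window matches of UGUA on the sense (mRNA) strand — the
#' input may use U or T interchangeably — and normalizes by sequence
#' length. Overlapping matches are counted, which is moot for UGUA (it has
#' no self-overlap shorter than its own length).
#'
#' @param sequence Non-empty nucleotide string.
#' @return List with `count` and `frequency` (= count / length).
#' @export
ugua_frequency <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty sequence")
  s <- chartr("Uu", "Tt", toupper(sequence))
  m <- gregexpr("(?=TGTA)", s, perl = TRUE)[[1]]
  count <- if (m[1] == -1L) 0L else length(m)
  list(count = count, frequency = count / nchar(s))
}

#' Locate the polyadenylation signal hexamer upstream of a cleavage site
#'
#' Scans the upstream window (by default the 40 nt ending 1 nt before the
#' cleavage coordinate, supplied as a sense-strand string) for any of the
#' PAS hexamer variants. Offsets are reported for the motif's 5' base
#' relative to the cleavage coordinate, so a hit spanning -25..-20 reports
#' offset -25. With multiple hits the one closest to the cleavage site
#' (largest offset) wins.
#'
#' @param sequence_upstream Sense-strand window ending at cleavage - 1.
#' @param variants Motif set (default [pas_hexamers()]).
#' @return List `(motif, offset)` or NULL when absent.
#' @export
locate_pas_hexamer <- function(sequence_upstream, variants = pas_hexamers()) {
  w <- nchar(sequence_upstream)
  if (is.na(sequence_upstream) || w < 6L)
    stop("upstream window must be at least 6 nt")
  s <- chartr("Uu", "Tt", toupper(sequence_upstream))
  best <- NULL
  for (v in variants) {
    m <- gregexpr(v, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    off <- max(as.integer(m)) - 1L - w  # motif start relative to cleavage
    if (is.null(best) || off > best$offset)
      best <- list(motif = v, offset = off)
  }
  best
}

#' Extract the sense-strand window upstream of a cleavage coordinate
#'
#' @param sequences Chromosome sequences.
#' @param chrom,strand Gene coordinates.
#' @param cleavage Cleavage coordinate (BED-end convention).
#' @param width Window width (nt, default 40).
#' @return Sense-strand string of length `width`.
#' @export
pas_upstream_window <- function(sequences, chrom, strand, cleavage,
                                width = 40L) {
  if (strand == "+") {
    substr(sequences[[chrom]], cleavage - width + 1L, cleavage)
  } else {
    .revcomp(substr(sequences[[chrom]], cleavage + 1L, cleavage + width))
  }
}

#' Mean coverage over an aUTR
#'
#' Arithmetic mean of per-base track values over the aUTR interval; bases
#' without track data are excluded from numerator and denominator, and a
#' fully uncovered interval yields NA.
#'
#' @param track Coverage data.frame (chrom, start, end, value) with sorted
#'   non-overlapping intervals.
#' @param autr One aUTR record (chrom, start, end).
#' @return Mean coverage, or NA when no base is covered.
#' @export
coverage_on_autr <- function(track, autr) {
  .interval_mean(track, autr$chrom, autr$start, autr$end)
}

# Length-weighted mean of track values over [start, end); NA if uncovered.
.interval_mean <- function(track, chrom, start, end) {
  t <- track[track$chrom == chrom & track$end > start & track$start < end, ,
             drop = FALSE]
  if (nrow(t) == 0L) return(NA_real_)
  w <- pmin(t$end, end) - pmax(t$start, start)
  sum(t$value * w) / sum(w)
}
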