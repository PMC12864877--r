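# Low-level sequence scaffolding for the synthetic generator.
#
# Scaffold sequences are scrubbed of a reserved k-mer list (UGUA/TGTA, the
# PAS hexamer variants, the myomiR candidate sequences and their reversals)
# so that every motif counted downstream was planted deliberately: motif
# recovery then tests the analysis, not the random background.

.rand_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

.reverse_str <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# Closed under reverse complement: the sense-strand sequence of a minus
# gene is the reverse complement of the genomic scaffold, so keeping both
# orientations clean guarantees motif-free sense sequences on both strands.
.reserved_kmers <- function(config) {
  cand <- toupper(config$candidates$sequence)
  base <- unique(c("TGTA", pas_hexamers(), cand, .reverse_str(cand)))
  unique(c(base, .revcomp(base)))
}

# Find (start, width) of all occurrences of any k-mer in `kmers`.
.find_kmers <- function(seq, kmers) {
  out <- lapply(kmers, function(k) {
    m <- gregexpr(k, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    cbind(start = as.integer(m), width = nchar(k))
  })
  do.call(rbind, out)
}

# Mutate unmasked bases until no reserved k-mer survives outside planted
# (fully masked) footprints. The replacement base is chosen
# deterministically (no RNG use) as the first of A/C/G/T that leaves the
# local window free of reserved k-mers, so scrubbing cannot oscillate
# between two motifs.
.scrub_block <- function(seq, mask, kmers, max_iter = 60L) {
  kmax <- max(nchar(kmers))
  for (iter in seq_len(max_iter)) {
    hits <- .find_kmers(seq, kmers)
    if (is.null(hits)) return(seq)
    dirty <- FALSE
    for (i in seq_len(nrow(hits))) {
      idx <- hits[i, "start"]:(hits[i, "start"] + hits[i, "width"] - 1L)
      free <- idx[!mask[idx]]
      if (length(free) == 0L) next  # sanctioned planting
      # an earlier mutation in this pass may already have destroyed it
      cur <- substr(seq, hits[i, "start"],
                    hits[i, "start"] + hits[i, "width"] - 1L)
      if (!(cur %in% kmers)) next
      best <- NULL
      for (p in free) {
        lo <- max(1L, p - kmax + 1L)
        hi <- min(nchar(seq), p + kmax - 1L)
        for (b in c("A", "C", "G", "T")) {
          if (b == substr(seq, p, p)) next
          trial <- seq
          substr(trial, p, p) <- b
          # count only matches that are not fully masked plantings
          n_local <- 0L
          for (k in kmers) {
            m <- gregexpr(k, substr(trial, lo, hi), fixed = TRUE)[[1]]
            if (m[1] == -1L) next
            for (s0 in as.integer(m)) {
              span <- (lo + s0 - 1L):(lo + s0 + nchar(k) - 2L)
              if (any(!mask[span])) n_local <- n_local + 1L
            }
          }
          if (is.null(best) || n_local < best$n)
            best <- list(p = p, b = b, n = n_local)
          if (n_local == 0L) break
        }
        if (!is.null(best) && best$n == 0L) break
      }
      substr(seq, best$p, best$p) <- best$b
      dirty <- TRUE
    }
    if (!dirty) return(seq)
  }
  stop("sequence scrub failed to converge")
}

# Write `motif` (sense-strand, transcription coordinates) into a gene block.
# tx_start is 0-based within the transcript; block is the genomic-plus
# strand sequence of length B.
.plant_tx <- function(block, strand, tx_start, motif) {
  k <- nchar(motif)
  B <- nchar(block$seq)
  if (strand == "+") {
    g0 <- tx_start + 1L
    ins <- motif
  } else {
    g0 <- B - tx_start - k + 1L
    ins <- .revcomp(motif)
  }
  substr(block$seq, g0, g0 + k - 1L) <- ins
  block$mask[g0:(g0 + k - 1L)] <- TRUE
  block
}

# Genomic 0-based half-open interval of a transcript-coordinate interval.
.tx_interval <- function(gstart, B, strand, tx_start, tx_end) {
  if (strand == "+") c(gstart + tx_start, gstart + tx_end)
  else c(gstart + B - tx_end, gstart + B - tx_start)
}

# TRUE when mask[(a-margin)..(b+margin)] is all free (1-based, clamped).
.mask_free <- function(mask, a, b, margin = 6L) {
  lo <- max(1L, a - margin)
  hi <- min(length(mask), b + margin)
  !any(mask[lo:hi])
}
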