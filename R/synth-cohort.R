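#' Simulate per-gene isoform counts
#'
#' Draws per-replicate gene totals from a negative binomial with mean
#' `depth_per_gene / n_replicates` and dispersion `nb_dispersion`
#' (variance = mu + dispersion * mu^2; dispersion 0 degrades to Poisson),
#' then splits each total between the proximal and distal isoforms by a
#' conditional binomial draw. The reference condition uses 1:1 distal:
#' proximal odds; in the comparison condition the odds are multiplied by
#' `2^planted_red_log2`, so shortened genes shift reads toward the proximal
#' site and lengthened genes toward the distal site.
#'
#' @param cohort An `apa_cohort` from [generate_gene_models()].
#' @param seed Seed for this stage (defaults to `config$seed + 2`);
#'   regenerating counts under a different seed leaves models/truth fixed.
#' @return The cohort with a `counts` data.frame
#'   (gene, condition, replicate, p_count, d_count).
#' @export
simulate_isoform_counts <- function(cohort, seed = cohort$config$seed + 2L) {
  cfg <- cohort$config
  if (cfg$depth_per_gene < 0) stop("negative depth")
  n <- nrow(cohort$models)
  R <- cfg$n_replicates
  conds <- unname(.apamir_conditions)

  grid <- expand.grid(gene = cohort$models$gene, condition = conds,
                      replicate = seq_len(R), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (n == 0L) {
    cohort$counts <- data.frame(gene = character(0), condition = character(0),
                                replicate = integer(0), p_count = integer(0),
                                d_count = integer(0))
    return(cohort)
  }
  red <- cohort$truth$genes$planted_red_log2[match(grid$gene,
                                                   cohort$truth$genes$gene)]
  odds <- ifelse(grid$condition == .apamir_conditions[["alt"]], 2^red, 1)
  share_d <- odds / (1 + odds)
  mu <- cfg$depth_per_gene / R

  cohort$counts <- withr::with_seed(as.integer(seed), {
    total <- if (cfg$nb_dispersion > 0)
      rnbinom(nrow(grid), mu = mu, size = 1 / cfg$nb_dispersion)
    else rpois(nrow(grid), mu)
    d <- rbinom(nrow(grid), total, share_d)
    data.frame(gene = grid$gene, condition = grid$condition,
               replicate = grid$replicate,
               p_count = total - d, d_count = d, stringsAsFactors = FALSE)
  })
  cohort
}

#' Simulate 3'-end sequencing reads
#'
#' Emits one record per counted read: the 3'-end position is the assigned
#' cleavage coordinate plus rounded Gaussian jitter (`end_jitter_sd`), and
#' the untemplated-T count is drawn uniformly from 2..6 with probability
#' `1 - internal_priming_rate` (a genuine poly(A) read) and from {0, 1}
#' otherwise (an internal-priming artifact that the >= 2 T filter removes).
#'
#' @param cohort An `apa_cohort` with counts.
#' @param counts Count table to realize as reads (default `cohort$counts`).
#' @param seed Stage seed (defaults to `config$seed + 3`).
#' @return The cohort with a `reads` data.frame
#'   (chrom, pos, strand, n_unaligned_T, gene).
#' @export
simulate_end_reads <- function(cohort, counts = cohort$counts,
                               seed = cohort$config$seed + 3L) {
  cfg <- cohort$config
  m <- cohort$models
  idx <- match(counts$gene, m$gene)
  site <- c(rep(m$pa_proximal[idx], counts$p_count),
            rep(m$pa_distal[idx], counts$d_count))
  ord <- order(c(rep(seq_len(nrow(counts)), counts$p_count),
                 rep(seq_len(nrow(counts)), counts$d_count)))
  gene2 <- c(rep(counts$gene, counts$p_count),
             rep(counts$gene, counts$d_count))[ord]
  site <- site[ord]
  nr <- length(site)
  gidx <- match(gene2, m$gene)

  cohort$reads <- withr::with_seed(as.integer(seed), {
    jitter <- if (cfg$end_jitter_sd > 0)
      as.integer(round(rnorm(nr, 0, cfg$end_jitter_sd))) else 0L
    genuine <- runif(nr) >= cfg$internal_priming_rate
    nT <- ifelse(genuine, sample(2:6, nr, replace = TRUE),
                 sample(0:1, nr, replace = TRUE))
    data.frame(chrom = m$chrom[gidx], pos = site + jitter,
               strand = m$strand[gidx], n_unaligned_T = as.integer(nT),
               gene = gene2, stringsAsFactors = FALSE)
  })
  cohort
}

#' Plant AGO2 peaks, myomiR candidate sites and the conservation track
#'
#' Per gene, an elevated AGO2 binding peak (comparison/reference normalized
#' coverage ratio drawn uniformly in \[2.5, 6\], so FC > 2 detection is
#' unambiguous modulo the pseudocount) is planted inside the aUTR with the
#' class-conditional probability `p_peak_by_class`; conditional on an
#' elevated peak, a myomiR candidate sequence is written into the scaffold
#' inside that peak with probability `p_site_by_class / p_peak_by_class`.
#' A non-elevated background peak (ratio in \[0.4, 1.8\]) is added anywhere
#' in the 3'UTR with probability `p_background_peak`. The conservation
#' track is flat at `background_conservation` except planted candidate
#' footprints (`site_conservation`) and PAS hexamer footprints
#' (`pas_conservation` by class).
#'
#' @param cohort An `apa_cohort` with sequences.
#' @param seed Stage seed (defaults to `config$seed + 4`).
#' @return The cohort augmented with `peaks`, `conservation`, updated
#'   `sequences` and truth tables `truth$sites` / `truth$peaks`.
#' @export
simulate_regulatory_layers <- function(cohort,
                                       seed = cohort$config$seed + 4L) {
  cfg <- cohort$config
  m <- cohort$models
  lay <- .apamir_layout
  if (is.null(cohort$blocks) && nrow(m) > 0L)
    stop("regulatory layers require scaffold sequences")
  kmers <- .reserved_kmers(cfg)
  p_tx <- lay$cds_pad + lay$common_utr
  pw <- cfg$peak_width

  peaks <- list(); tsites <- list(); tpeaks <- list()
  cohort <- withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(m))) {
      cls <- m$class[i]; L <- m$autr_len[i]; B <- m$block_len[i]
      strand <- m$strand[i]; gstart <- m$block_start[i]
      d_tx <- p_tx + L
      wp <- min(pw, L)
      p_peak <- cfg$p_peak_by_class[[cls]]
      p_site <- min(1, cfg$p_site_by_class[[cls]] / max(p_peak, 1e-12))

      if (runif(1) < p_peak) {
        site_tx <- NA_integer_; cand <- NULL
        if (runif(1) < p_site) {
          ci <- sample.int(nrow(cfg$candidates), 1L)
          cand <- cfg$candidates[ci, ]
          k <- nchar(cand$sequence)
          for (try in 1:50) {
            tx0 <- p_tx + sample.int(L - k + 1L, 1L) - 1L
            iv <- if (strand == "+") c(tx0 + 1L, tx0 + k)
                  else c(B - tx0 - k + 1L, B - tx0)
            if (.mask_free(cohort$blocks[[i]]$mask, iv[1], iv[2])) {
              site_tx <- tx0
              break
            }
          }
        }
        if (!is.na(site_tx)) {
          k <- nchar(cand$sequence)
          cohort$blocks[[i]] <- .plant_tx(cohort$blocks[[i]], strand,
                                          site_tx, toupper(cand$sequence))
          cohort$blocks[[i]]$seq <- .scrub_block(cohort$blocks[[i]]$seq,
                                                 cohort$blocks[[i]]$mask,
                                                 kmers)
          lo <- max(p_tx, site_tx + k - wp)
          hi <- min(d_tx - wp, site_tx)
          pk_tx <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          giv <- .tx_interval(gstart, B, strand, site_tx, site_tx + k)
          tsites[[length(tsites) + 1L]] <- data.frame(
            gene = m$gene[i], mirna = cand$mirna,
            sequence = toupper(cand$sequence), chrom = m$chrom[i],
            start = giv[1], end = giv[2], autr_offset = site_tx - p_tx,
            stringsAsFactors = FALSE)
        } else {
          pk_tx <- p_tx + sample.int(L - wp + 1L, 1L) - 1L
        }
        ratio <- runif(1, 2.5, 6)
        cov1 <- runif(1, 1, 5)
        giv <- .tx_interval(gstart, B, strand, pk_tx, pk_tx + wp)
        peaks[[length(peaks) + 1L]] <- data.frame(
          gene = m$gene[i], chrom = m$chrom[i], start = giv[1], end = giv[2],
          strand = strand, cov_ref = cov1,
          cov_alt = ratio * (cov1 + 0.5) - 0.5, stringsAsFactors = FALSE)
        tpeaks[[length(tpeaks) + 1L]] <- data.frame(
          gene = m$gene[i], chrom = m$chrom[i], start = giv[1], end = giv[2],
          ratio = ratio, stringsAsFactors = FALSE)
      }

      if (runif(1) < cfg$p_background_peak) {
        wb <- min(pw, d_tx - lay$cds_pad)
        bg_tx <- lay$cds_pad + sample.int(d_tx - lay$cds_pad - wb + 1L, 1L) - 1L
        ratio <- runif(1, 0.4, 1.8)
        cov1 <- runif(1, 1, 5)
        giv <- .tx_interval(gstart, B, strand, bg_tx, bg_tx + wb)
        peaks[[length(peaks) + 1L]] <- data.frame(
          gene = m$gene[i], chrom = m$chrom[i], start = giv[1], end = giv[2],
          strand = strand, cov_ref = cov1,
          cov_alt = ratio * (cov1 + 0.5) - 0.5, stringsAsFactors = FALSE)
      }
    }
    cohort
  })

  cohort$peaks <- if (length(peaks)) {
    pk <- do.call(rbind, peaks)
    pk <- pk[order(pk$start), , drop = FALSE]
    pk$peak_id <- sprintf("pk%05d", seq_len(nrow(pk)))
    rownames(pk) <- NULL
    pk[, c("peak_id", "gene", "chrom", "start", "end", "strand",
           "cov_ref", "cov_alt")]
  } else data.frame(peak_id = character(0), gene = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    cov_ref = numeric(0), cov_alt = numeric(0),
                    stringsAsFactors = FALSE)
  cohort$truth$sites <- if (length(tsites)) do.call(rbind, tsites)
    else .empty_sites()
  cohort$truth$peaks <- if (length(tpeaks)) do.call(rbind, tpeaks)
    else .empty_peaks()
  cohort$sequences <- assemble_sequences(cohort)
  cohort$conservation <- .build_conservation(cohort)
  cohort
}

# Flat background with planted footprints overlaid; intervals are sorted,
# non-overlapping, 0-based half-open.
.build_conservation <- function(cohort) {
  cfg <- cohort$config
  m <- cohort$models
  fp <- list()
  if (nrow(cohort$truth$sites) > 0L)
    fp[[1]] <- data.frame(start = cohort$truth$sites$start,
                          end = cohort$truth$sites$end,
                          value = cfg$site_conservation)
  if (nrow(m) > 0L) {
    pas_val <- ifelse(m$class == "shorten", cfg$pas_conservation[["shorten"]],
                      cfg$pas_conservation[["other"]])
    hex <- function(cleav, strand) {
      # genomic footprint of the hexamer planted 21..15 nt upstream
      ifelse(strand == "+", cleav - 21L, cleav + 15L)
    }
    fp[[length(fp) + 1L]] <- data.frame(
      start = c(hex(m$pa_proximal, m$strand), hex(m$pa_distal, m$strand)),
      end = c(hex(m$pa_proximal, m$strand), hex(m$pa_distal, m$strand)) + 6L,
      value = rep(pas_val, 2L))
  }
  fp <- if (length(fp)) do.call(rbind, fp) else
    data.frame(start = integer(0), end = integer(0), value = numeric(0))
  fp <- fp[order(fp$start), , drop = FALSE]
  bg <- cfg$background_conservation
  starts <- c(0L, fp$end)
  ends <- c(fp$start, cohort$chrom_len)
  out <- rbind(
    data.frame(start = starts, end = ends, value = bg),
    data.frame(start = fp$start, end = fp$end, value = fp$value)
  )
  out <- out[out$end > out$start, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(chrom = rep("chrS", nrow(out)), out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate expression records for export and translation metrics
#'
#' Emulates the fractionated RNA-seq / polysome-profiling layer: per-gene
#' RPKM values for input, polysome, nucleus and cytoplasm fractions in both
#' conditions. Polysome enrichment is left unchanged across differentiation
#' for shortened-class genes and decreased by 0.5 log2 units (plus noise)
#' for other classes, mirroring the observed escape of shortened mRNAs from
#' global translational repression; the cytoplasm/nucleus ratio carries no
#' class effect.
#'
#' @param cohort An `apa_cohort`.
#' @param seed Stage seed (defaults to `config$seed + 5`).
#' @return The cohort with an `expression` data.frame
#'   (gene, fraction, condition, rpkm).
#' @export
simulate_expression_records <- function(cohort,
                                        seed = cohort$config$seed + 5L) {
  g <- cohort$truth$genes
  n <- nrow(g)
  conds <- .apamir_conditions
  cohort$expression <- withr::with_seed(as.integer(seed), {
    base <- 2^rnorm(n, 5, 1)
    input_ref <- base
    input_alt <- base * 2^rnorm(n, 0, 0.3)
    pe_ref <- rnorm(n, 0.5, 0.3)
    d_pe <- ifelse(g$planted_class == "shorten", 0, -0.5) + rnorm(n, 0, 0.2)
    nuc_ref <- base * 2^rnorm(n, 0, 0.3)
    nuc_alt <- base * 2^rnorm(n, 0, 0.3)
    cn_ref <- rnorm(n, 0.5, 0.3)
    cn_alt <- cn_ref + rnorm(n, 0, 0.2)
    long <- function(fraction, condition, rpkm)
      data.frame(gene = g$gene, fraction = fraction, condition = condition,
                 rpkm = rpkm, stringsAsFactors = FALSE)
    rbind(
      long("input", conds[["ref"]], input_ref),
      long("input", conds[["alt"]], input_alt),
      long("polysome", conds[["ref"]], input_ref * 2^pe_ref),
      long("polysome", conds[["alt"]], input_alt * 2^(pe_ref + d_pe)),
      long("nucleus", conds[["ref"]], nuc_ref),
      long("nucleus", conds[["alt"]], nuc_alt),
      long("cytoplasm", conds[["ref"]], nuc_ref * 2^cn_ref),
      long("cytoplasm", conds[["alt"]], nuc_alt * 2^cn_alt)
    )
  })
  cohort
}

#' Plant a knockdown-recapitulation gene set
#'
#' Draws, for each reference gene, independent membership in the
#' knockdown-shortened query set at the given rate — the generator's model
#' of how CFI subunit depletion recapitulates differentiation-induced
#' shortening (defaults: CFI-68 0.67, CFI-25 0.64; see
#' [cohort_config()]`$cfi_recap`).
#'
#' @param genes Character vector of reference genes.
#' @param rate Per-gene recapitulation probability.
#' @param seed Integer seed.
#' @return Character vector: the planted query subset.
#' @export
simulate_knockdown_overlap <- function(genes, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  withr::with_seed(as.integer(seed),
                   genes[runif(length(genes)) < rate])
}

#' Simulate a complete synthetic cohort
#'
#' Chains [generate_gene_models()], [simulate_isoform_counts()],
#' [simulate_end_reads()], [simulate_regulatory_layers()] and
#' [simulate_expression_records()] under sub-seeds derived from
#' `config$seed`. Identical config + seed gives byte-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param sequences Include sequence-dependent layers (scaffolds, peaks,
#'   candidate sites, conservation). When FALSE only models and counts are
#'   produced, which is much faster for count-level studies.
#' @param reads Simulate read-level 3'-end evidence.
#' @return An `apa_cohort`.
#' @export
simulate_cohort <- function(config, sequences = TRUE, reads = sequences) {
  cohort <- generate_gene_models(config, sequences = sequences)
  cohort <- simulate_isoform_counts(cohort)
  if (reads) cohort <- simulate_end_reads(cohort)
  if (sequences) cohort <- simulate_regulatory_layers(cohort)
  cohort <- simulate_expression_records(cohort)
  cohort
}
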