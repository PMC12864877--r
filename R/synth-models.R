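#' Generate synthetic gene models and scaffold sequences
#'
#' Lays out `n_genes` two-pA-site genes on a single pseudo-chromosome
#' (`chrS`), tiled with 1 kb spacers and alternating strand so downstream
#' strand logic is exercised. Each gene's last exon carries exactly one
#' proximal and one distal cleavage site; the segment between them is the
#' alternative UTR (aUTR). Class labels (shorten/lengthen/nc) are assigned
#' by deterministic rounding of the configured fractions followed by a
#' seeded permutation, so planted class counts are exact.
#'
#' Cleavage coordinates use the BED-end convention: on the plus strand the
#' coordinate is the 0-based position immediately after the last transcribed
#' base, on the minus strand the 0-based start of the last transcribed base;
#' in both cases the aUTR is the half-open genomic interval between the two
#' coordinates and its length is their difference.
#'
#' When `sequences = TRUE`, scaffold sequences are generated, scrubbed of
#' all reserved motifs (UGUA, PAS hexamers, myomiR candidates and their
#' reversals), and then seeded with planted motifs: an AATAAA hexamer 21 nt
#' upstream of each cleavage site, and background UGUA motifs at
#' `ugua_background_rate` per nt (multiplied by `ugua_enrich_factor` in
#' shortened-class aUTRs).
#'
#' @param config A [cohort_config()].
#' @param sequences Generate scaffold sequences (TRUE) or gene models only.
#' @return An `apa_cohort` list with elements `config`, `models`, `truth`,
#'   and (with sequences) `blocks` and `sequences`.
#' @export
generate_gene_models <- function(config, sequences = TRUE) {
  config <- validate_cohort_config(config)
  lay <- .apamir_layout
  n <- config$n_genes

  ns <- floor(config$frac_shorten * n)
  nl <- floor(config$frac_lengthen * n)
  classes <- c(rep("shorten", ns), rep("lengthen", nl), rep("nc", n - ns - nl))

  cohort <- withr::with_seed(config$seed + 1L, {
    classes <- classes[sample.int(max(n, 0L))]
    L <- if (n > 0L)
      sample(seq(config$autr_len_range[1], config$autr_len_range[2]),
             n, replace = TRUE)
    else integer(0)
    strand <- rep_len(c("+", "-"), n)

    p_tx <- lay$cds_pad + lay$common_utr          # proximal cleavage, tx coords
    d_tx <- p_tx + L                              # distal cleavage
    B <- d_tx + lay$tail_pad                      # block length
    gstart <- (lay$spacer +
      cumsum(c(0L, utils::head(B + lay$spacer, -1L))))[seq_len(n)]
    chrom_len <- if (n > 0L) gstart[n] + B[n] + lay$spacer else lay$spacer

    plus <- strand == "+"
    cds_end     <- ifelse(plus, gstart + lay$cds_pad, gstart + B - lay$cds_pad)
    pa_proximal <- ifelse(plus, gstart + p_tx, gstart + B - p_tx)
    pa_distal   <- ifelse(plus, gstart + d_tx, gstart + B - d_tx)
    exon_a <- lay$cds_pad - lay$exon_lead
    exon_b <- d_tx + lay$exon_trail
    last_exon_start <- ifelse(plus, gstart + exon_a, gstart + B - exon_b)
    last_exon_end   <- ifelse(plus, gstart + exon_b, gstart + B - exon_a)
    autr_start <- pmin(pa_proximal, pa_distal)
    autr_end   <- pmax(pa_proximal, pa_distal)

    gene <- if (n > 0L) sprintf("g%05d", seq_len(n)) else character(0)
    models <- data.frame(
      gene = gene, chrom = rep_len("chrS", n), strand = strand,
      block_start = gstart, block_len = B,
      last_exon_start = last_exon_start, last_exon_end = last_exon_end,
      cds_end = cds_end, pa_proximal = pa_proximal, pa_distal = pa_distal,
      autr_start = autr_start, autr_end = autr_end, autr_len = L,
      class = classes, stringsAsFactors = FALSE
    )
    red <- ifelse(classes == "shorten", -config$effect_red_log2,
                  ifelse(classes == "lengthen", config$effect_red_log2, 0))
    truth_genes <- data.frame(
      gene = gene, planted_class = classes, planted_red_log2 = red,
      stringsAsFactors = FALSE
    )

    blocks <- NULL
    if (sequences && n > 0L) {
      kmers <- .reserved_kmers(config)
      blocks <- vector("list", n)
      for (i in seq_len(n)) {
        blk <- list(seq = .rand_dna(B[i]), mask = logical(B[i]))
        blk$seq <- .scrub_block(blk$seq, blk$mask, kmers)
        # PAS hexamers 21 nt upstream of each cleavage site (sense strand)
        blk <- .plant_tx(blk, strand[i], p_tx - 21L, "AATAAA")
        blk <- .plant_tx(blk, strand[i], d_tx[i] - 21L, "AATAAA")
        # background UGUA content of the aUTR
        rate <- config$ugua_background_rate *
          if (classes[i] == "shorten") config$ugua_enrich_factor else 1
        k_ugua <- rpois(1L, L[i] * rate)
        planted <- 0L
        guard <- 0L
        while (planted < k_ugua && guard < 20L * k_ugua + 20L) {
          guard <- guard + 1L
          tx0 <- sample.int(L[i] - 4L, 1L) - 1L + p_tx
          iv <- if (strand[i] == "+") c(tx0 + 1L, tx0 + 4L)
                else c(B[i] - tx0 - 3L, B[i] - tx0)
          if (.mask_free(blk$mask, iv[1], iv[2])) {
            blk <- .plant_tx(blk, strand[i], tx0, "TGTA")
            planted <- planted + 1L
          }
        }
        blk$seq <- .scrub_block(blk$seq, blk$mask, kmers)
        blocks[[i]] <- blk
      }
    }

    truth <- list(genes = truth_genes,
                  sites = .empty_sites(), peaks = .empty_peaks())
    structure(list(config = config, models = models, truth = truth,
                   blocks = blocks, chrom_len = chrom_len),
              class = "apa_cohort")
  })
  if (sequences) cohort$sequences <- assemble_sequences(cohort)
  cohort
}

.empty_sites <- function() {
  data.frame(gene = character(0), mirna = character(0),
             sequence = character(0), chrom = character(0),
             start = integer(0), end = integer(0), autr_offset = integer(0),
             stringsAsFactors = FALSE)
}

.empty_peaks <- function() {
  data.frame(gene = character(0), chrom = character(0),
             start = integer(0), end = integer(0), ratio = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assemble per-gene blocks into chromosome sequences
#'
#' Concatenates gene-block sequences with `N` spacers into the cohort's
#' pseudo-chromosome. Called internally after any stage that edits blocks.
#'
#' @param cohort An `apa_cohort` with `blocks`.
#' @return Named character vector of chromosome sequences.
#' @export
assemble_sequences <- function(cohort) {
  n <- nrow(cohort$models)
  spacer <- strrep("N", .apamir_layout$spacer)
  if (n == 0L || is.null(cohort$blocks)) return(c(chrS = spacer))
  body <- paste(vapply(cohort$blocks, `[[`, character(1), "seq"),
                collapse = spacer)
  c(chrS = paste0(spacer, body, spacer))
}
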