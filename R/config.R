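#' Canonical polyadenylation signal (PAS) hexamers
#'
#' The canonical AAUAAA/AUUAAA signals plus ten common single-base variants
#' reported across the polyadenylation literature, given as DNA 6-mers.
#' The set is configurable wherever it is consumed ([locate_pas_hexamer()]).
#'
#' @return Character vector of twelve 6-mers.
#' @export
pas_hexamers <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Default myomiR candidate target sequences
#'
#' Seed-match style candidate target sequences for the muscle-enriched
#' miR-1/miR-206/miR-133 families (DNA alphabet, sense strand of the mRNA).
#' These defaults are supplied by this package: the miR-1/206 family shares
#' a seed, so its 7mer (ACATTCC) and 8mer (ACATTCCA) matches are both
#' included alongside the miR-133 7mer (GGACCAA). Replace with your own
#' table (columns `mirna`, `sequence`) for other miRNA families.
#'
#' @return A data.frame with columns `mirna` and `sequence`.
#' @export
myomir_candidates <- function() {
  data.frame(
    mirna    = c("miR-1/206-8mer", "miR-1/206-7mer", "miR-133-7mer"),
    sequence = c("ACATTCCA",       "ACATTCC",        "GGACCAA"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Collects and validates every tunable of the synthetic-cohort generator.
#' The class-conditional probabilities default to the proportions observed
#' in differentiating muscle stem cells: 28%/16%/14% of
#' shortened/lengthened/unchanged mRNAs carry a myomiR candidate site inside
#' an increased AGO2 peak, and 68%/55%/53% carry at least one increased
#' AGO2 binding peak in their alternative UTR (aUTR). Planted site
#' conservation is pinned at 0.75 (the moderate 0.7-0.8 range) over a 0.30
#' background.
#'
#' @param n_genes Number of genes in the cohort (0 allowed: empty cohort).
#' @param frac_shorten,frac_lengthen Proportions of genes planted with
#'   3'UTR shortening / lengthening; the remainder is unchanged ("nc").
#'   Class counts are deterministic (`floor(frac * n_genes)`), not Bernoulli.
#' @param effect_red_log2 Planted |delta log2 RED| for affected genes;
#'   shortened genes get `-effect_red_log2`, lengthened `+effect_red_log2`.
#' @param depth_per_gene Expected total reads per gene per condition.
#' @param nb_dispersion Negative-binomial dispersion of per-replicate gene
#'   totals (variance = mu + dispersion * mu^2); 0 degrades to Poisson.
#' @param n_replicates Biological replicates per condition.
#' @param autr_len_range Integer pair: min/max aUTR length (nt), min >= 50.
#' @param ugua_background_rate Expected UGUA motifs per nt in non-shortened
#'   aUTRs (default 1/256, the i.i.d. four-letter expectation).
#' @param ugua_enrich_factor Multiplier on the background UGUA rate for
#'   shortened-class aUTRs.
#' @param p_site_by_class Named probabilities (shorten/lengthen/nc) that a
#'   gene carries a planted myomiR candidate inside an elevated peak.
#' @param p_peak_by_class Named probabilities that a gene carries an
#'   elevated AGO2 peak in its aUTR. Must dominate `p_site_by_class`
#'   class-wise; smaller values trigger a warning and clipping.
#' @param p_background_peak Probability of an additional non-elevated peak
#'   placed anywhere in the 3'UTR (exercises fold-change discrimination).
#' @param site_conservation Conservation value at planted site footprints.
#' @param background_conservation Conservation value elsewhere.
#' @param pas_conservation Named pair `shorten`/`other`: conservation at
#'   PAS hexamer footprints by gene class (shortened genes carry the more
#'   conserved signals).
#' @param cfi_recap Named rates `cfi68`/`cfi25`: probability that a
#'   differentiation-shortened gene is also shortened upon knockdown of the
#'   corresponding cleavage factor I subunit (defaults 0.67 and 0.64).
#' @param internal_priming_rate Probability that a 3'-end read lacks the
#'   >= 2 untemplated-T evidence (internal priming artifact).
#' @param end_jitter_sd Gaussian jitter (nt, sd) on read 3'-end positions.
#' @param peak_width Planted AGO2 peak width (nt).
#' @param candidates Candidate table as from [myomir_candidates()].
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   cohorts.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_genes = 200L,
                          frac_shorten = 0.07,
                          frac_lengthen = 0.06,
                          effect_red_log2 = 1,
                          depth_per_gene = 300,
                          nb_dispersion = 0.1,
                          n_replicates = 2L,
                          autr_len_range = c(200L, 1200L),
                          ugua_background_rate = 1 / 256,
                          ugua_enrich_factor = 3,
                          p_site_by_class = c(shorten = 0.28, lengthen = 0.16, nc = 0.14),
                          p_peak_by_class = c(shorten = 0.68, lengthen = 0.55, nc = 0.53),
                          p_background_peak = 0.9,
                          site_conservation = 0.75,
                          background_conservation = 0.30,
                          pas_conservation = c(shorten = 0.75, other = 0.55),
                          cfi_recap = c(cfi68 = 0.67, cfi25 = 0.64),
                          internal_priming_rate = 0.1,
                          end_jitter_sd = 3,
                          peak_width = 60L,
                          candidates = myomir_candidates(),
                          seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), frac_shorten = frac_shorten,
    frac_lengthen = frac_lengthen, effect_red_log2 = effect_red_log2,
    depth_per_gene = depth_per_gene, nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    autr_len_range = as.integer(autr_len_range),
    ugua_background_rate = ugua_background_rate,
    ugua_enrich_factor = ugua_enrich_factor,
    p_site_by_class = p_site_by_class, p_peak_by_class = p_peak_by_class,
    p_background_peak = p_background_peak,
    site_conservation = site_conservation,
    background_conservation = background_conservation,
    pas_conservation = pas_conservation, cfi_recap = cfi_recap,
    internal_priming_rate = internal_priming_rate,
    end_jitter_sd = end_jitter_sd, peak_width = as.integer(peak_width),
    candidates = candidates, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config A `cohort_config` object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with(config, {
    if (n_genes < 0) stop("n_genes must be >= 0")
    if (frac_shorten < 0 || frac_lengthen < 0 ||
        frac_shorten + frac_lengthen > 1)
      stop("invalid class fractions: need frac_shorten + frac_lengthen <= 1")
    if (depth_per_gene < 0) stop("depth_per_gene must be non-negative")
    if (nb_dispersion < 0) stop("nb_dispersion must be non-negative")
    if (n_replicates < 1) stop("need at least one replicate")
    if (length(autr_len_range) != 2 || autr_len_range[1] > autr_len_range[2])
      stop("autr_len_range must be an ordered integer pair")
    if (autr_len_range[1] < 50) stop("minimum aUTR length must be >= 50 nt")
    probs <- c(p_site_by_class, p_peak_by_class, p_background_peak,
               site_conservation, background_conservation, pas_conservation,
               cfi_recap, internal_priming_rate)
    if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
    if (ugua_enrich_factor <= 0) stop("ugua_enrich_factor must be positive")
    if (end_jitter_sd < 0) stop("end_jitter_sd must be non-negative")
    if (!all(c("shorten", "lengthen", "nc") %in% names(p_site_by_class)) ||
        !all(c("shorten", "lengthen", "nc") %in% names(p_peak_by_class)))
      stop("class probabilities must be named shorten/lengthen/nc")
    if (!all(c("mirna", "sequence") %in% names(candidates)) ||
        nrow(candidates) == 0)
      stop("candidates must be a non-empty table with mirna and sequence")
  })
  bad <- config$p_site_by_class[names(config$p_peak_by_class)] >
    config$p_peak_by_class
  if (any(bad)) {
    warning("p_site_by_class exceeds p_peak_by_class for class(es) ",
            paste(names(config$p_peak_by_class)[bad], collapse = ", "),
            "; clipping to p_peak_by_class")
    hit <- names(config$p_peak_by_class)[bad]
    config$p_site_by_class[hit] <- config$p_peak_by_class[hit]
  }
  config
}
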