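#' Mean conservation over an interval
#'
#' Length-weighted mean of per-base conservation over a 0-based half-open
#' interval; uncovered bases are excluded and a fully uncovered interval
#' yields NA. Zero-length intervals are an error.
#'
#' @param track Conservation data.frame (chrom, start, end, value), sorted
#'   and non-overlapping, values in \[0, 1\].
#' @param chrom,start,end Query interval.
#' @return Mean conservation or NA.
#' @export
mean_conservation <- function(track, chrom, start, end) {
  if (end <= start) stop("zero-length interval")
  .interval_mean(track, chrom, start, end)
}

# Per-base track values at 0-based positions of one chromosome (NA where
# the track has no data). Assumes sorted non-overlapping intervals.
.track_values <- function(track, chrom, positions) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(rep(NA_real_, length(positions)))
  idx <- findInterval(positions, t$start)
  v <- rep(NA_real_, length(positions))
  ok <- idx >= 1L
  ok[ok] <- positions[ok] < t$end[idx[ok]]
  v[ok] <- t$value[idx[ok]]
  v
}

#' Conservation metaprofile around aligned sites
#'
#' Averages per-base conservation across sites at each aligned offset.
#' Sites are oriented 5' to 3' on the mRNA (strand-aware) and anchored at
#' their 5' start, so offset 0 is the first site base, negative offsets
#' are the 5' flank and offsets past the site length run into the 3'
#' flank. Sites of unequal length contribute to every offset their
#' extended window covers.
#'
#' @param track Conservation track.
#' @param sites Data.frame: chrom, start, end, strand.
#' @param flank Flank width (nt, >= 0).
#' @return Data.frame: offset, mean, n (sites with data at that offset).
#' @export
site_metaprofile <- function(track, sites, flank = 50L) {
  if (flank < 0) stop("flank must be non-negative")
  if (nrow(sites) == 0L) stop("no sites supplied")
  max_len <- max(sites$end - sites$start)
  offsets <- seq(-flank, max_len + flank - 1L)
  acc_sum <- numeric(length(offsets))
  acc_n <- integer(length(offsets))
  for (i in seq_len(nrow(sites))) {
    plus <- sites$strand[i] == "+"
    pos <- if (plus) sites$start[i] + offsets else sites$end[i] - 1L - offsets
    v <- .track_values(track, sites$chrom[i], pos)
    ok <- !is.na(v)
    acc_sum[ok] <- acc_sum[ok] + v[ok]
    acc_n[ok] <- acc_n[ok] + 1L
  }
  data.frame(offset = offsets,
             mean = ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), NA_real_),
             n = acc_n)
}

#' Two-sided Wilcoxon rank-sum comparison of score distributions
#'
#' Uses the exact permutation distribution of the Mann-Whitney U statistic
#' (full enumeration of group labelings, ties handled through midranks)
#' when `min(nA, nB) <= 8` and `nA + nB <= 20`, and the normal
#' approximation with tie correction otherwise. The two-sided exact
#' p-value is `P(U <= min(u, nAnB - u)) + P(U >= max(u, nAnB - u))`,
#' capped at 1. Empirical CDF tables of both groups are returned for
#' cumulative-distribution plots.
#'
#' @param a,b Numeric score vectors (each non-empty).
#' @return List: p_value, statistic (U of the first group), method,
#'   cdf (list of two data.frames value/cdf).
#' @export
compare_score_distributions <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (min(na, nb) <= 8L && n <= 20L) {
    combos <- combn(n, na)
    us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    lo <- min(u, na * nb - u); hi <- max(u, na * nb - u)
    eps <- 1e-9
    p <- (sum(us <= lo + eps) + sum(us >= hi - eps)) / ncol(combos)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal_tie_corrected"
  }
  cdf_tab <- function(x) {
    xs <- sort(unique(x))
    data.frame(value = xs, cdf = ecdf(x)(xs))
  }
  list(p_value = min(p, 1), statistic = u, method = method,
       cdf = list(a = cdf_tab(a), b = cdf_tab(b)))
}
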