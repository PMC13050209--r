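#' Probability of detecting an LOH event of a given length
#'
#' With `n` markers uniformly distributed on a genome of length `L`, an
#' event of length `l` converts at least one marker with probability
#' `P_detect(l) = 1 - (1 - l/L)^n`, computed via `log1p` for precision.
#'
#' @param length event length in bp (vectorized)
#' @param n_markers number of markers
#' @param L genome length in bp
#' @return detection probability
#' @export
detection_probability <- function(length, n_markers, L) {
  assert_that(all(length >= 0 & length <= L), "lengths must lie in [0, L]")
  -expm1(n_markers * log1p(-length / L))
}

#' Inter-marker undercount correction of an event-length histogram
#'
#' Detected events are binned by log10 length; each bin's count is divided
#' by the detection probability at the bin's mean detected length. Interior
#' empty bins (flanked by nonempty bins on both sides) receive a pseudocount
#' of 1 before correction, with the bin's geometric midpoint standing in for
#' the mean length.
#'
#' @param lengths detected event lengths (bp, >= 1)
#' @param n_markers marker count
#' @param L genome length (bp)
#' @param bin_width_log10 histogram bin width (default 0.25)
#' @return list with `bins` (data.table: `log10_lo`, `log10_hi`, `k`,
#'   `mean_length`, `p_detect`, `corrected`) and `corrected_total`
#' @export
correct_intermarker <- function(lengths, n_markers, L, bin_width_log10 = 0.25) {
  assert_that(all(lengths >= 1), "event lengths must be >= 1 bp")
  lg <- log10(lengths)
  lo <- floor(min(lg) / bin_width_log10) * bin_width_log10
  hi <- ceiling(max(lg) / bin_width_log10 + 1e-9) * bin_width_log10
  if (hi <= lo) hi <- lo + bin_width_log10
  breaks <- seq(lo, hi, by = bin_width_log10)
  idx <- pmin(findInterval(lg, breaks, rightmost.closed = TRUE),
              length(breaks) - 1L)
  nb <- length(breaks) - 1L
  k <- tabulate(idx, nbins = nb)
  mean_len <- rep(NA_real_, nb)
  agg <- tapply(lengths, idx, mean)
  mean_len[as.integer(names(agg))] <- agg

  nonempty <- which(k > 0L)
  if (length(nonempty) >= 2L) {
    interior_empty <- setdiff(seq(min(nonempty), max(nonempty)), nonempty)
    k[interior_empty] <- 1L
    mean_len[interior_empty] <- 10^((breaks[interior_empty] +
                                       breaks[interior_empty + 1L]) / 2)
  }
  used <- k > 0L
  pd <- rep(NA_real_, nb)
  pd[used] <- detection_probability(pmin(mean_len[used], L), n_markers, L)
  corrected <- ifelse(used, k / pd, 0)
  bins <- data.table::data.table(
    log10_lo = breaks[-length(breaks)], log10_hi = breaks[-1L],
    k = k, mean_length = mean_len, p_detect = pd, corrected = corrected)
  list(bins = bins[], corrected_total = sum(corrected))
}

#' Interstitial LOH event rates
#'
#' Per-arm rate: the mean event count across clones divided by the number
#' of generations. Genome-wide rate: the sum over arms, multiplied by the
#' inter-marker correction factor, and divided by the mean fraction of the
#' genome not masked by terminal events (overlap correction).
#'
#' @param counts data.frame with `clone`, `arm`, `count` for one hybrid
#'   (aneuploid arms excluded upstream)
#' @param generations MA duration T (generations)
#' @param intermarker_factor corrected/detected total ratio from
#'   [correct_intermarker()] (default 1 = no correction)
#' @param tloh_masked_fraction per-clone fraction of the genome converted by
#'   terminal events (default 0)
#' @return list with `per_arm` (data.table `arm`, `rate`) and
#'   `genome_rate` (events genome^-1 generation^-1, corrected)
#' @export
iloh_rates <- function(counts, generations, intermarker_factor = 1,
                       tloh_masked_fraction = 0) {
  assert_that(is.numeric(generations) && generations > 0,
              "generations must be positive")
  dt <- data.table::as.data.table(counts)
  # aggregate first: a `generations` column in the input must not shadow
  # the function argument inside data.table's j
  per_arm <- dt[, list(mean_count = mean(count)), by = list(arm)]
  per_arm$rate <- per_arm$mean_count / generations
  genome <- sum(per_arm$rate) * intermarker_factor /
    mean(1 - tloh_masked_fraction)
  list(per_arm = per_arm[], genome_rate = genome)
}

#' Terminal LOH event rates by the P0 method
#'
#' At most one terminal event is observable per arm per clone, so rates are
#' estimated from the fraction of clones with no detected event:
#' `p0 = (sum(1 - C) + 1) / (n + 1)` (pseudocount 1 keeps the logarithm
#' finite) and `lambda = -ln(p0) / T` under a Poisson event process.
#'
#' @param indicators data.frame with `clone`, `arm`, `count` where `count`
#'   is 0/1 per arm per clone
#' @param generations MA duration T
#' @return list with `per_arm` (data.table `arm`, `p0`, `rate`) and
#'   `genome_rate` (sum over arms)
#' @export
tloh_rates_p0 <- function(indicators, generations) {
  dt <- data.table::as.data.table(indicators)
  assert_that(all(dt$count %in% c(0L, 1L)),
              "terminal-event indicators must be 0/1")
  per_arm <- dt[, list(p0 = (sum(1L - count) + 1) / (.N + 1)),
                by = list(arm)]
  per_arm$rate <- -log(per_arm$p0) / generations
  list(per_arm = per_arm[], genome_rate = sum(per_arm$rate))
}

#' Probability that at least one pair of interstitial events overlap
#'
#' For `k` events of typical length `l` placed uniformly on a genome of
#' length `L`, a given pair overlaps with probability `2l/L`, so
#' `P = 1 - (1 - 2l/L)^(k(k-1)/2)`. `k` may be a non-integer mean.
#'
#' @param k events per clone
#' @param l typical (median) event length (bp)
#' @param L genome length (bp)
#' @return overlap probability
#' @export
overlap_probability_iloh <- function(k, l, L) {
  assert_that(k >= 0, "k must be non-negative")
  if (k <= 1) return(0)
  -expm1(k * (k - 1) / 2 * log1p(-2 * l / L))
}

#' Probability that an interstitial event overlaps a terminal event
#'
#' A given interstitial event of length `l` overlaps a given terminal event
#' of length `s` with probability `(s + l/2)/L`, so with `k` interstitial
#' and `m` terminal events, `P = 1 - (1 - (s + l/2)/L)^(k m)`.
#'
#' @param k interstitial events per clone
#' @param m terminal events per clone
#' @param l typical interstitial length (bp)
#' @param s typical terminal length (bp)
#' @param L genome length (bp)
#' @return overlap probability
#' @export
overlap_probability_tloh <- function(k, m, l, s, L) {
  assert_that(k >= 0 && m >= 0, "k and m must be non-negative")
  if (k == 0 || m == 0) return(0)
  -expm1(k * m * log1p(-(s + l / 2) / L))
}

#' Genome-wide conversion rates
#'
#' The conversion rate is the per-bp, per-generation probability that a
#' site loses heterozygosity: summed event lengths across clones, divided
#' by the number of clones, the effective genome length, and the number of
#' generations. The interstitial denominator additionally subtracts the
#' mean genome length masked by terminal events.
#'
#' @param events classified events table with `start`, `end`, `type`
#' @param n_clones number of end-point clones
#' @param effective_L effective genome length (bp; see
#'   [effective_genome_length()])
#' @param generations MA duration T
#' @param mean_tloh_masked_bp mean per-clone genome length converted by
#'   terminal events (default: computed from `events`)
#' @return named vector: `total`, `terminal`, `interstitial` conversion
#'   rates (bp^-1 generation^-1)
#' @export
conversion_rates <- function(events, n_clones, effective_L, generations,
                             mean_tloh_masked_bp = NULL) {
  ev <- data.table::as.data.table(events)
  len <- if (nrow(ev)) ev$end - ev$start + 1 else numeric(0)
  is_t <- nrow(ev) > 0 & ev$type == "terminal"
  if (is.null(mean_tloh_masked_bp))
    mean_tloh_masked_bp <- sum(len[is_t]) / n_clones
  assert_that(effective_L > mean_tloh_masked_bp,
              "terminal-event mask exceeds the effective genome length")
  denom <- n_clones * effective_L * generations
  c(total = sum(len) / denom,
    terminal = sum(len[is_t]) / denom,
    interstitial = sum(len[!is_t]) /
      (n_clones * (effective_L - mean_tloh_masked_bp) * generations))
}

#' Local LOH event rates per genomic window
#'
#' Breakpoint counts divided by window size, clone count and generations.
#'
#' @param events events table with `chrom`, `breakpoint`
#' @param windows a [tile_windows()] table
#' @param n_clones number of clones
#' @param generations MA duration T
#' @return the windows table with `n_events` and `rate`
#'   (bp^-1 generation^-1)
#' @export
local_rates <- function(events, windows, n_clones, generations) {
  w <- data.table::copy(data.table::as.data.table(windows))
  ev <- data.table::as.data.table(events)
  w$n_events <- 0L
  if (nrow(ev)) {
    for (ch in unique(w$chrom)) {
      wi <- which(w$chrom == ch)
      ei <- ev[ev$chrom == ch & !is.na(ev$breakpoint)]
      if (!nrow(ei)) next
      bin <- findInterval(ei$breakpoint, w$start[wi])
      ok <- bin >= 1L & bin <= length(wi)
      w$n_events[wi] <- tabulate(bin[ok], nbins = length(wi))
    }
  }
  w$rate <- w$n_events / ((w$end - w$start) * n_clones * generations)
  w[]
}
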