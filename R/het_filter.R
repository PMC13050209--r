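#' Beta-binomial density and distribution (symmetric or general)
#'
#' Density of the number of successes out of `n` trials when the success
#' probability is itself Beta(`alpha`, `beta`) distributed. Used with
#' `alpha = beta` to model allele balance at heterozygous sites.
#'
#' @param k successes (vectorized)
#' @param n trials
#' @param alpha,beta beta shape parameters
#' @return probability mass at `k`
#' @export
dbetabinom <- function(k, n, alpha, beta = alpha) {
  out <- exp(lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta))
  out[k < 0 | k > n] <- 0
  out
}

#' High-confidence heterozygous sites across families
#'
#' Sites called heterozygous in at least `founder_min_frac` of founders and
#' at least `endpoint_min_frac` of end-point clones (required counts taken
#' with ceiling). These anchor the allele-balance model fit: they are almost
#' certainly truly heterozygous in every clone.
#'
#' @param founder_gt integer matrix markers x founders (0/1/2/NA)
#' @param endpoint_gt integer matrix markers x end-point clones
#' @param founder_min_frac minimum heterozygous founder fraction
#'   (default 15/16)
#' @param endpoint_min_frac minimum heterozygous end-point fraction
#'   (default 2/3)
#' @return logical vector of retained marker rows
#' @export
high_confidence_het_sites <- function(founder_gt, endpoint_gt,
                                      founder_min_frac = 15 / 16,
                                      endpoint_min_frac = 2 / 3) {
  assert_that(ncol(founder_gt) >= 2L,
              paste("fewer than 2 founders available; use single-family",
                    "fallback thresholds on endpoint_gt alone"))
  need_f <- ceiling(founder_min_frac * ncol(founder_gt))
  need_e <- ceiling(endpoint_min_frac * ncol(endpoint_gt))
  rowSums(founder_gt == 1L, na.rm = TRUE) >= need_f &
    rowSums(endpoint_gt == 1L, na.rm = TRUE) >= need_e
}

#' Fit the beta-binomial overdispersion of allele balance
#'
#' Heterozygous calls are binned by integer read depth `n`; within each bin
#' the variance of the parent-2 allele count is computed and the model
#' `sigma^2(n) = n/4 + rho n (n - 1)` is fitted by least squares over bins
#' with at least `min_bin` calls, weighted by bin call counts. The symmetric
#' beta shape follows as `beta = (1/rho - 4)/8`.
#'
#' @param het_calls data.frame of heterozygous calls with `dp` (total depth)
#'   and `ad2` (reads supporting the parent-2 allele)
#' @param min_bin minimum calls per depth bin (default 100)
#' @return list of class `overdispersion_fit` with `rho`, `beta`, `r2`, and
#'   the per-bin table (`n`, `n_calls`, `mean_ad2`, `var_ad2`)
#' @export
fit_overdispersion <- function(het_calls, min_bin = 100L) {
  dt <- data.table::as.data.table(het_calls)[!is.na(dp) & !is.na(ad2)]
  bins <- dt[, list(n_calls = .N, mean_ad2 = mean(ad2),
                    var_ad2 = stats::var(ad2)), by = list(n = dp)]
  bins <- bins[n_calls >= min_bin & n >= 2L]
  data.table::setorder(bins, n)
  assert_that(nrow(bins) >= 3L,
              "fewer than 3 depth bins retained; lower min_bin or add calls")
  x <- bins$n * (bins$n - 1)
  y <- bins$var_ad2 - bins$n / 4
  w <- bins$n_calls
  rho <- sum(w * x * y) / sum(w * x^2)
  fitted <- bins$n / 4 + rho * x
  ybar <- sum(w * bins$var_ad2) / sum(w)
  r2 <- 1 - sum(w * (bins$var_ad2 - fitted)^2) /
    sum(w * (bins$var_ad2 - ybar)^2)
  structure(list(rho = rho,
                 beta = if (rho > 0) (1 / rho - 4) / 8 else Inf,
                 r2 = r2, bins = bins[], min_bin = min_bin),
            class = "overdispersion_fit")
}

#' Central beta-binomial confidence interval for allele balance
#'
#' Equal-tail interval for the symmetric beta-binomial (alpha = beta) at
#' depth `n`: `lo` is the smallest count whose CDF reaches the lower tail
#' probability, `hi = n - lo` by symmetry, and both endpoints are inside the
#' interval, so each excluded tail holds at most `(1 - level)/2` mass.
#'
#' @param n read depth (vectorized)
#' @param beta symmetric shape parameter; `Inf` gives the binomial limit
#' @param level central coverage (default 0.95)
#' @return matrix with columns `lo`, `hi`
#' @export
beta_binomial_ci <- function(n, beta, level = 0.95) {
  tail <- (1 - level) / 2
  one <- function(ni) {
    if (ni < 1) return(c(lo = 0L, hi = 0L))
    pmf <- if (is.finite(beta)) dbetabinom(0:ni, ni, beta, beta)
           else stats::dbinom(0:ni, ni, 0.5)
    cdf <- cumsum(pmf)
    lo <- which(cdf >= tail - 1e-12)[1L] - 1L
    c(lo = lo, hi = ni - lo)
  }
  res <- t(vapply(n, one, c(lo = 0L, hi = 0L)))
  res
}

#' Remove heterozygous calls with implausible allele balance
#'
#' Heterozygous calls whose parent-2 read support falls outside the central
#' beta-binomial interval at their depth become missing. They are not
#' reassigned to a homozygous state: the allele-frequency evidence
#' contradicts the caller's other evidence, so the site carries no reliable
#' genotype. Homozygous calls are untouched; the filter is idempotent.
#'
#' @param calls an [loh_calls] table
#' @param fit an [fit_overdispersion()] result, or `NULL` to use `beta`
#' @param beta symmetric beta shape used for the interval (default: from
#'   `fit`, rounded as reported when `round_beta`)
#' @param level central coverage (default 0.95)
#' @return list with `calls` (filtered; removed genotypes set to `NA`) and
#'   `n_removed`
#' @export
filter_het_calls <- function(calls, fit = NULL, beta = NULL, level = 0.95) {
  if (is.null(beta)) {
    assert_that(!is.null(fit), "supply an overdispersion fit or beta")
    beta <- fit$beta
  }
  out <- data.table::copy(data.table::as.data.table(calls))
  is_het <- !is.na(out$gt) & out$gt == 1L & !is.na(out$dp) & !is.na(out$ad2)
  if (!any(is_het)) return(list(calls = out, n_removed = 0L))
  depths <- sort(unique(out$dp[is_het]))
  ci <- beta_binomial_ci(depths, beta, level)
  lo <- ci[match(out$dp[is_het], depths), "lo"]
  hi <- ci[match(out$dp[is_het], depths), "hi"]
  bad <- out$ad2[is_het] < lo | out$ad2[is_het] > hi
  idx <- which(is_het)[bad]
  if (length(idx)) data.table::set(out, i = idx, j = "gt", value = NA_integer_)
  list(calls = out, n_removed = length(idx))
}
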