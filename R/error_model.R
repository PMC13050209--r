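#' Founder genotyping-error model parameters
#'
#' Five per-site probabilities drive the posterior odds ratios for a founder
#' call being erroneous, all over the whole duration of the experiment:
#'
#' * `mu` - probability that a flip mutation (het <-> hom between the two
#'   existing alleles) occurs in one line;
#' * `lam` - probability that an LOH event converts the site to homozygosity
#'   in one line;
#' * `f` - probability that a polymorphic site is truly homozygous in the
#'   founder;
#' * `eps_hom` - probability that a true heterozygote is called homozygous;
#' * `eps_het` - probability that a true homozygote is called heterozygous.
#'
#' `f` may be supplied directly or derived from the observed homozygous
#' fraction `f_obs` via [f_from_observed()].
#'
#' @param eps_hom,eps_het call-error probabilities
#' @param mu flip-mutation probability (default 4.45e-8, i.e. one-third of
#'   the diploid point-mutation rate over an 800-generation experiment)
#' @param lam LOH conversion probability (default 0.128; see
#'   [lambda_from_rate()])
#' @param f founder-homozygosity probability, or `NULL` to derive from
#'   `f_obs`
#' @param f_obs observed homozygous fraction at polymorphic sites
#' @return list of class `error_params`
#' @export
error_params <- function(eps_hom, eps_het, mu = 4.45e-8, lam = 0.128,
                         f = NULL, f_obs = NULL) {
  if (is.null(f)) {
    assert_that(!is.null(f_obs), "supply either f or f_obs")
    f <- f_from_observed(f_obs, eps_hom, eps_het)
  }
  p <- list(mu = mu, lam = lam, f = f, eps_hom = eps_hom, eps_het = eps_het)
  ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                 x >= 0 && x <= 1, logical(1))
  assert_that(all(ok), "all parameters must be probabilities in [0, 1]")
  assert_that(mu + lam <= 1, "mu + lam must not exceed 1")
  structure(p, class = "error_params")
}

#' Per-experiment LOH conversion probability from a per-bp-per-generation rate
#'
#' @param rate conversion rate in bp^-1 generation^-1 (default 1.6e-4, the
#'   upper end of published yeast estimates, used as a conservative prior)
#' @param generations experiment duration (default 800)
#' @return `rate * generations`
#' @export
lambda_from_rate <- function(rate = 1.6e-4, generations = 800) {
  rate * generations
}

#' Founder homozygosity probability from its observed counterpart
#'
#' Inverts `f_obs = f (1 - eps_het) + (1 - f) eps_hom`. Feasibility requires
#' `eps_hom <= f_obs` and `eps_het <= 1 - f_obs`; outside those bounds the
#' implied `f` leaves `[0, 1]` and an error names the violated bound.
#'
#' @param f_obs observed homozygous fraction
#' @param eps_hom,eps_het call-error probabilities
#' @return the true homozygosity probability `f`
#' @export
f_from_observed <- function(f_obs, eps_hom, eps_het) {
  assert_that(eps_hom <= f_obs,
              sprintf("infeasible: eps_hom (%g) exceeds f_obs (%g)", eps_hom, f_obs))
  assert_that(eps_het <= 1 - f_obs,
              sprintf("infeasible: eps_het (%g) exceeds 1 - f_obs (%g)", eps_het, 1 - f_obs))
  (f_obs - eps_hom) / (1 - eps_hom - eps_het)
}

#' Descendant-state transition probabilities p_ij
#'
#' `p[i+1, j+1]` is the probability of observing a descendant clone with `j`
#' derived alleles (j = 0, 1, 2) given that the ancestor carried `i` derived
#' alleles (i = 0 homozygous ancestral, i = 1 heterozygous). Two stages:
#'
#' 1. True state after the experiment: a heterozygous site becomes
#'    homozygous on either side with probability `(lam + mu) / 2` each and
#'    stays heterozygous with `1 - lam - mu`; a homozygous site flips to
#'    heterozygous with probability `mu` (LOH does not act on homozygotes;
#'    double events are neglected).
#' 2. Observation: a true heterozygote is called homozygous on each side
#'    with probability `eps_hom` (total `2 eps_hom`) and heterozygous
#'    otherwise; a true homozygote is called heterozygous with probability
#'    `eps_het`, the opposite homozygote never, and correctly otherwise.
#'
#' @param params an [error_params]
#' @return 2 x 3 matrix with rows `anc_hom`, `anc_het`; rows sum to 1
#' @export
transition_probs <- function(params) {
  assert_that(inherits(params, "error_params"), "params must be error_params")
  mu <- params$mu; lam <- params$lam
  eh <- params$eps_hom; et <- params$eps_het
  assert_that(2 * eh <= 1, "eps_hom must not exceed 0.5 (per-side errors total 2*eps_hom)")
  p0 <- c(
    (1 - mu) * (1 - et) + mu * eh,       # observed j = 0
    (1 - mu) * et + mu * (1 - 2 * eh),   # observed j = 1
    mu * eh)                             # observed j = 2
  hw <- (lam + mu) / 2
  p1 <- c(
    hw * (1 - et) + (1 - lam - mu) * eh,
    (lam + mu) * et + (1 - lam - mu) * (1 - 2 * eh),
    hw * (1 - et) + (1 - lam - mu) * eh)
  m <- rbind(anc_hom = p0, anc_het = p1)
  colnames(m) <- c("j0", "j1", "j2")
  m
}

log_config_ratio <- function(p_num, p_den, K) {
  # sum_j K_j * log(p_num[j] / p_den[j]) in log space; +Inf when a
  # numerator term with positive count has zero denominator
  terms <- numeric(3)
  for (j in 1:3) {
    if (K[j] == 0) next
    if (p_den[j] == 0) return(if (p_num[j] > 0) Inf else NaN)
    if (p_num[j] == 0) return(-Inf)
    terms[j] <- K[j] * (log(p_num[j]) - log(p_den[j]))
  }
  sum(terms)
}

#' Posterior odds that a founder homozygous call is a false homozygote
#'
#' `R = [eps_hom / (1 - eps_het)] [(1 - f) / f] prod_j (p_1j / p_0j)^Kj`,
#' where `K0`, `K1`, `K2` count descendants called homozygous-ancestral,
#' heterozygous, and homozygous-derived. `R > 1` favors the hypothesis that
#' the founder site is in fact heterozygous. Computed in log space; a zero
#' denominator with a positive count yields `+Inf`, never `NaN`.
#'
#' @param params an [error_params]
#' @param K0,K1,K2 descendant configuration counts
#' @param log return the log odds ratio instead
#' @return the odds ratio (or its log)
#' @export
odds_false_hom <- function(params, K0, K1, K2, log = FALSE) {
  p <- transition_probs(params)
  lr <- log(params$eps_hom) - log(1 - params$eps_het) +
    log(1 - params$f) - log(params$f) +
    log_config_ratio(p["anc_het", ], p["anc_hom", ], c(K0, K1, K2))
  if (log) lr else exp(lr)
}

#' Posterior odds that a founder heterozygous call is a false heterozygote
#'
#' `R = [eps_het / (1 - 2 eps_hom)] [f / (1 - f)] prod_j (p_0j / p_1j)^Kj`.
#' The ancestral allele defining `K0` is the candidate true-homozygous
#' allele (operationally, the allele carried homozygously by the plurality
#' of descendants, ties toward parent 1).
#'
#' @inheritParams odds_false_hom
#' @return the odds ratio (or its log)
#' @export
odds_false_het <- function(params, K0, K1, K2, log = FALSE) {
  p <- transition_probs(params)
  lr <- log(params$eps_het) - log(1 - 2 * params$eps_hom) +
    log(params$f) - log(1 - params$f) +
    log_config_ratio(p["anc_hom", ], p["anc_het", ], c(K0, K1, K2))
  if (log) lr else exp(lr)
}

#' Homo-FDR and Hetero-FDR from founder/descendant discordance
#'
#' A founder-homozygous site is labelled a false homozygote when at least
#' `min_descendants` descendants are genotyped there and every one of them
#' is called heterozygous; a founder-heterozygous site is labelled a false
#' heterozygote when at least `min_descendants` are genotyped and all are
#' homozygous for the same allele. The FDRs are the labelled fractions of
#' the eligible sites, reported per family and pooled (site totals across
#' families). Families with no eligible sites report `NA`, not 0.
#'
#' @param families list of [family_matrix] objects with founder genotypes
#' @param min_descendants minimum genotyped descendants for eligibility
#' @return list with `per_family` (data.table), `pooled` (named vector
#'   `hetero_fdr`, `homo_fdr`), `mean` (family means), and `labels`
#'   (data.table `family`, `chrom`, `pos`, `label`)
#' @export
estimate_fdrs <- function(families, min_descendants = 6L) {
  per <- list(); labs <- list()
  for (fam in families) {
    assert_that(!is.null(fam$founder_gt),
                "estimate_fdrs requires founder genotypes in every family")
    g <- fam$gt
    n_geno <- rowSums(!is.na(g))
    eligible <- n_geno >= min_descendants
    founder <- fam$founder_gt

    hom_site <- !is.na(founder) & founder %in% c(0L, 2L) & eligible
    all_het <- rowSums(g == 1L, na.rm = TRUE) == n_geno & n_geno > 0L
    false_hom <- hom_site & all_het

    het_site <- !is.na(founder) & founder == 1L & eligible
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    all_same_hom <- (n0 == n_geno | n2 == n_geno) & n_geno > 0L
    false_het <- het_site & all_same_hom

    per[[fam$family]] <- data.table::data.table(
      family = fam$family,
      n_hom_sites = sum(hom_site), n_false_hom = sum(false_hom),
      n_het_sites = sum(het_site), n_false_het = sum(false_het),
      homo_fdr = if (sum(hom_site)) sum(false_hom) / sum(hom_site) else NA_real_,
      hetero_fdr = if (sum(het_site)) sum(false_het) / sum(het_site) else NA_real_)
    if (any(false_hom | false_het)) {
      idx <- which(false_hom | false_het)
      labs[[fam$family]] <- data.table::data.table(
        family = fam$family,
        chrom = fam$markers$chrom[idx], pos = fam$markers$pos[idx],
        label = ifelse(false_hom[idx], "false_homozygous", "false_heterozygous"))
    }
  }
  per <- data.table::rbindlist(per)
  pooled <- c(
    hetero_fdr = if (sum(per$n_het_sites)) sum(per$n_false_het) / sum(per$n_het_sites) else NA_real_,
    homo_fdr = if (sum(per$n_hom_sites)) sum(per$n_false_hom) / sum(per$n_hom_sites) else NA_real_)
  fam_mean <- c(hetero_fdr = mean(per$hetero_fdr, na.rm = TRUE),
                homo_fdr = mean(per$homo_fdr, na.rm = TRUE))
  list(per_family = per, pooled = pooled, mean = fam_mean,
       labels = if (length(labs)) data.table::rbindlist(labs) else
         data.table::data.table(family = character(), chrom = character(),
                                pos = integer(), label = character()))
}

#' Permutation test for an FDR difference between two genotyping procedures
#'
#' Compares family-mean FDRs between two conditions by permuting condition
#' labels within families.
#'
#' @param fdr_a,fdr_b per-family FDR vectors, matched by family
#' @param n_perm permutations (default 10000)
#' @param seed optional RNG seed
#' @return two-sided permutation p-value for the difference of means
#' @export
fdr_permutation_test <- function(fdr_a, fdr_b, n_perm = 10000L, seed = NULL) {
  assert_that(length(fdr_a) == length(fdr_b), "families must be matched")
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(fdr_a) & !is.na(fdr_b)
  a <- fdr_a[keep]; b <- fdr_b[keep]
  obs <- abs(mean(a) - mean(b))
  n <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    flip <- stats::runif(n) < 0.5
    ap <- ifelse(flip, b, a); bp <- ifelse(flip, a, b)
    if (abs(mean(ap) - mean(bp)) >= obs - 1e-15) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Expected number of erroneous sites from an FDR
#'
#' Bookkeeping for error-impact estimates: the expected count of wrongly
#' genotyped sites among `n_sites` given a per-site false discovery rate,
#' optionally multiplied over clones.
#'
#' @param n_sites number of sites of the relevant class
#' @param fdr per-site false discovery rate
#' @param n_clones multiply by a clone count (default 1)
#' @return expected erroneous site count
#' @export
expected_false_sites <- function(n_sites, fdr, n_clones = 1) {
  n_sites * fdr * n_clones
}

#' Excess-conversion estimate of erroneous reference-biased events
#'
#' Under the assumptions of no true conversion bias and of all erroneous
#' events converting toward the reference homolog, the excess of
#' reference-homolog conversions over non-reference ones estimates the
#' erroneous fraction: `(n_ref - n_nonref) / (n_ref + n_nonref)`.
#'
#' @param n_ref events converting toward the reference homolog
#' @param n_nonref events converting toward the other homolog
#' @return list with `n_excess` and `fraction`
#' @export
excess_conversion_error <- function(n_ref, n_nonref) {
  list(n_excess = n_ref - n_nonref,
       fraction = (n_ref - n_nonref) / (n_ref + n_nonref))
}
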