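# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive each quantity by a different route than the
# package implementation.

# two-stage enumeration of descendant-state transition probabilities:
# enumerate {true state after the experiment} x {observed call}
oracle_transition_probs <- function(mu, lam, eps_hom, eps_het) {
  # rows: ancestor 0 or 1 derived alleles; cols: observed 0/1/2
  obs_given_true <- function(true_j) {
    switch(as.character(true_j),
           "0" = c(1 - eps_het, eps_het, 0),
           "1" = c(eps_hom, 1 - 2 * eps_hom, eps_hom),
           "2" = c(0, eps_het, 1 - eps_het))
  }
  true_given_anc <- list(
    "0" = c(`0` = 1 - mu, `1` = mu, `2` = 0),
    "1" = c(`0` = (lam + mu) / 2, `1` = 1 - lam - mu, `2` = (lam + mu) / 2))
  out <- matrix(0, 2, 3)
  for (i in 0:1) for (tj in 0:2) {
    w <- true_given_anc[[as.character(i)]][as.character(tj)]
    out[i + 1, ] <- out[i + 1, ] + w * obs_given_true(tj)
  }
  dimnames(out) <- list(c("anc_hom", "anc_het"), c("j0", "j1", "j2"))
  out
}

# exhaustive-scan LOH event detection over one clone/chromosome genotype
# vector; an interval-based re-derivation independent of rle-based runs
oracle_events <- function(gt, pos, chrom_length, gap_bp = 10000L) {
  keep <- !is.na(gt)
  g <- gt[keep]; p <- pos[keep]
  n <- length(g)
  if (!n) return(NULL)
  # tracts by explicit scanning
  tracts <- list()
  i <- 1L
  while (i <= n) {
    if (g[i] %in% c(0L, 2L)) {
      j <- i
      while (j < n && g[j + 1L] == g[i]) j <- j + 1L
      start <- if (i == 1L) 1L else (p[i - 1L] + p[i]) %/% 2L
      end <- if (j == n) as.integer(chrom_length) else (p[j] + p[j + 1L]) %/% 2L
      tracts[[length(tracts) + 1L]] <-
        list(start = start, end = end, hom = g[i], nm = j - i + 1L,
             tl = i == 1L, tr = j == n)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(tracts)) return(NULL)
  # transitive merging by pairwise distance
  k <- length(tracts)
  grp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (x in seq_len(k)) for (y in seq_len(k)) {
      if (grp[x] != grp[y] &&
          (tracts[[y]]$start - tracts[[x]]$end) < gap_bp &&
          (tracts[[y]]$start - tracts[[x]]$end) >= 0) {
        grp[grp == grp[y]] <- grp[x]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  evs <- lapply(unique(grp), function(gi) {
    tt <- tracts[grp == gi]
    lens <- vapply(tt, function(t) t$end - t$start + 1, numeric(1))
    homs <- vapply(tt, function(t) t$hom, integer(1))
    tot <- tapply(lens, homs, sum)
    best <- as.integer(names(tot)[which.max(tot)])
    if (sum(tot == max(tot)) > 1L) best <- 0L  # tie -> P1
    st <- min(vapply(tt, function(t) t$start, integer(1)))
    en <- max(vapply(tt, function(t) t$end, numeric(1)))
    term <- any(vapply(tt, function(t) t$tl, logical(1))) && st == 1L ||
      any(vapply(tt, function(t) t$tr, logical(1))) && en == chrom_length
    list(start = st, end = en,
         homolog = if (best == 0L) "P1" else "P2",
         n_markers = sum(vapply(tt, function(t) t$nm, integer(1))),
         type = if (term) "terminal" else "interstitial")
  })
  ord <- order(vapply(evs, function(e) e$start, numeric(1)))
  evs[ord]
}

# beta-binomial pmf by direct product formula (not lbeta), for CI oracles
oracle_bb_pmf <- function(k, n, b) {
  num <- prod((b + seq_len(k) - 1) / seq_len(k)) *
    prod((b + seq_len(n - k) - 1) / seq_len(n - k))
  den <- prod((2 * b + seq_len(n) - 1) / seq_len(n))
  # binomial coefficient is absorbed by the factorial denominators
  num / den
}

oracle_bb_ci <- function(n, b, level = 0.95) {
  pmf <- vapply(0:n, oracle_bb_pmf, numeric(1), n = n, b = b)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  lo <- which(cdf >= (1 - level) / 2 - 1e-12)[1] - 1L
  c(lo = lo, hi = n - lo)
}

# base-by-base coordinate map for a single-insertion chain
oracle_lift_insertion <- function(pos, ins_after, ins_len) {
  ifelse(pos <= ins_after, pos, pos + ins_len)
}

# G statistic by the direct 2 sum O log(O/E) formula on a 2 x H matrix
oracle_g <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# small multi-family truth-bookkeeping simulation for FDR estimation tests
sim_fdr_families <- function(n_fam, n_desc, n_sites, f0, lam, eps_hom,
                             eps_het, seed) {
  set.seed(seed)
  mk <- marker_set(data.frame(chrom = "chr1", pos = seq_len(n_sites) * 100L,
                              a1 = "A", a2 = "C"), "final")
  call_gt <- function(true) {
    out <- true
    het <- true == 1L
    flip <- het & stats::runif(length(true)) < 2 * eps_hom
    out[flip] <- ifelse(stats::runif(sum(flip)) < 0.5, 0L, 2L)
    flip2 <- !het & stats::runif(length(true)) < eps_het
    out[flip2] <- 1L
    out
  }
  fams <- list(); truth <- list()
  for (fi in seq_len(n_fam)) {
    founder_true <- ifelse(stats::runif(n_sites) < f0,
                           ifelse(stats::runif(n_sites) < 0.5, 0L, 2L), 1L)
    founder_called <- call_gt(founder_true)
    gts <- matrix(NA_integer_, n_sites, n_desc)
    for (ci in seq_len(n_desc)) {
      desc_true <- founder_true
      conv <- desc_true == 1L & stats::runif(n_sites) < lam
      desc_true[conv] <- ifelse(stats::runif(sum(conv)) < 0.5, 0L, 2L)
      gts[, ci] <- call_gt(desc_true)
    }
    id <- sprintf("F%02d", fi)
    fams[[id]] <- family_matrix(mk, gts, founder_gt = founder_called,
                                family = id)
    truth[[id]] <- list(founder_true = founder_true,
                        founder_called = founder_called)
  }
  list(families = fams, truth = truth, markers = mk)
}
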