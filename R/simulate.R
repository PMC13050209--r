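#' Budding-yeast-like default genome for simulations
#'
#' Sixteen chromosomes totalling ~12.07 Mb with centromere positions,
#' matching the scale of the genome the pipeline targets.
#'
#' @return a [genome_meta] (no masks)
#' @export
yeast_genome_meta <- function() {
  lens <- c(chrI = 230218L, chrII = 813184L, chrIII = 316620L,
            chrIV = 1531933L, chrV = 576874L, chrVI = 270161L,
            chrVII = 1090940L, chrVIII = 562643L, chrIX = 439888L,
            chrX = 745751L, chrXI = 666816L, chrXII = 1078177L,
            chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L,
            chrXVI = 948066L)
  cens <- c(chrI = 151465L, chrII = 238207L, chrIII = 114385L,
            chrIV = 449711L, chrV = 151987L, chrVI = 148510L,
            chrVII = 496920L, chrVIII = 105586L, chrIX = 355629L,
            chrX = 436307L, chrXI = 440129L, chrXII = 150828L,
            chrXIII = 268031L, chrXIV = 628758L, chrXV = 326584L,
            chrXVI = 555957L)
  genome_meta(lens, cens)
}

#' Configuration for a synthetic mutation accumulation experiment
#'
#' Defaults mirror the regime of a large yeast MA panel: a ~12.07-Mb
#' 16-chromosome genome, ~37,000 markers (mean spacing ~326 bp), 16
#' families of 11 end-point clones propagated for 800 generations, read
#' depth around 37x with beta-binomial allele balance (`beta` = 59),
#' interstitial events with a ~399-bp median log-normal length
#' distribution, terminal events with uniformly placed breakpoints, and
#' small genotyping error rates.
#'
#' @param meta a [genome_meta] (default [yeast_genome_meta()])
#' @param n_markers markers placed uniformly, proportional to chromosome
#'   length (default 37000)
#' @param n_families number of founder families (default 16)
#' @param clones_per_family end-point clones per family (default 11)
#' @param generations MA duration (default 800)
#' @param iloh_rate_per_mb per-arm interstitial rate coefficient
#'   (events Mb^-1 generation^-1; per-arm rate = coefficient x arm Mb).
#'   The default 1.1e-3 gives ~10.6 interstitial events per clone over 800
#'   generations on a 12.07-Mb genome, the corrected-count regime of the
#'   targeted experiment
#' @param tloh_rate_per_arm terminal rate per arm per generation; the
#'   default 7.5e-5 gives ~1.9 terminal events per clone over 800
#'   generations across 32 arms
#' @param iloh_median_bp,iloh_sdlog interstitial length distribution
#'   (log-normal; defaults 399 bp and 2.0)
#' @param eps_hom,eps_het genotyping error rates (defaults 1e-3, 1e-4)
#' @param mean_depth mean read depth (default 37)
#' @param beta beta-binomial allele-balance shape (default 59)
#' @param p1_bias_frac fraction of events converting toward parent 1
#'   (default 0.5)
#' @param seed mandatory RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(meta = yeast_genome_meta(), n_markers = 37000L,
                       n_families = 16L, clones_per_family = 11L,
                       generations = 800, iloh_rate_per_mb = 1.1e-3,
                       tloh_rate_per_arm = 7.5e-5,
                       iloh_median_bp = 399, iloh_sdlog = 2.0,
                       eps_hom = 1e-3, eps_het = 1e-4,
                       mean_depth = 37, beta = 59,
                       p1_bias_frac = 0.5, seed) {
  assert_that(!missing(seed) && is.numeric(seed), "seed is mandatory")
  cfg <- list(meta = meta, n_markers = as.integer(n_markers),
              n_families = as.integer(n_families),
              clones_per_family = as.integer(clones_per_family),
              generations = generations,
              iloh_rate_per_mb = iloh_rate_per_mb,
              tloh_rate_per_arm = tloh_rate_per_arm,
              iloh_median_bp = iloh_median_bp, iloh_sdlog = iloh_sdlog,
              eps_hom = eps_hom, eps_het = eps_het,
              mean_depth = mean_depth, beta = beta,
              p1_bias_frac = p1_bias_frac, seed = as.integer(seed))
  ok <- vapply(cfg[c("iloh_rate_per_mb", "tloh_rate_per_arm", "eps_hom",
                     "eps_het")], function(x) x >= 0, logical(1))
  assert_that(all(ok), "rates must be non-negative")
  structure(cfg, class = "sim_config")
}

# chromosome arms of a genome_meta: one row per arm with bounds
genome_arms <- function(meta) {
  ch <- names(meta$chrom_lengths)
  cen <- meta$centromeres[ch]
  data.table::data.table(
    chrom = rep(ch, each = 2L),
    arm = paste0(rep(ch, each = 2L), rep(c("-l", "-r"), length(ch))),
    start = as.vector(rbind(1L, as.integer(cen) + 1L)),
    end = as.vector(rbind(as.integer(cen),
                          as.integer(meta$chrom_lengths[ch]))))
}

rbetabinom <- function(n, size, shape) {
  if (is.finite(shape)) {
    p <- stats::rbeta(n, shape, shape)
    stats::rbinom(n, size, p)
  } else stats::rbinom(n, size, 0.5)
}

#' Simulate a mutation accumulation experiment with truth bookkeeping
#'
#' Generates marker positions, true LOH events per clone (interstitial
#' counts per arm are Poisson in the per-arm rate; at most one terminal
#' event per arm, Bernoulli with the Poisson zero-class probability),
#' applies events and genotyping errors to the genotype matrix, draws read
#' depths and beta-binomial allele counts, and emits one call set per
#' parental reference. Without injected bias the two call sets agree at
#' every site and carry high genotype qualities.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_result`: `truth` (events, error positions,
#'   per-arm rates), `markers` ([marker_set]), `families` (list of
#'   [family_matrix]), `calls_ref1`, `calls_ref2` ([loh_calls] across all
#'   clones, common coordinates), `meta`, `config`
#' @export
simulate_experiment <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  meta <- config$meta
  arms <- genome_arms(meta)
  chlen <- meta$chrom_lengths

  # markers: uniform placement proportional to chromosome length
  n_per <- stats::rmultinom(1L, config$n_markers,
                            chlen / sum(chlen))[, 1L]
  mk <- data.table::rbindlist(lapply(seq_along(chlen), function(i) {
    pos <- sort(sample.int(chlen[i], n_per[i]))
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, n_per[i], replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
    data.table::data.table(chrom = names(chlen)[i], pos = pos,
                           a1 = a1, a2 = unname(a2))
  }))
  markers <- marker_set(mk, "final")
  M <- nrow(markers)
  marker_arm <- integer(M)
  for (i in seq_len(nrow(arms))) {
    sel <- markers$chrom == arms$chrom[i] & markers$pos >= arms$start[i] &
      markers$pos <= arms$end[i]
    marker_arm[sel] <- i
  }

  arm_mb <- (arms$end - arms$start + 1) / 1e6
  lam_i <- config$iloh_rate_per_mb * arm_mb            # per arm per generation
  lam_t <- rep(config$tloh_rate_per_arm, nrow(arms))
  Tg <- config$generations

  truth_events <- list()
  families <- list()
  all_calls1 <- list(); all_calls2 <- list()
  err_positions <- list()

  draw_homolog <- function(n) ifelse(stats::runif(n) < config$p1_bias_frac,
                                     0L, 2L)

  simulate_clone_gt <- function(clone_id) {
    gt <- rep(1L, M)
    evs <- list()
    for (ai in seq_len(nrow(arms))) {
      a0 <- arms$start[ai]; a1e <- arms$end[ai]
      # interstitial events
      ki <- stats::rpois(1L, lam_i[ai] * Tg)
      if (ki > 0L) for (j in seq_len(ki)) {
        len <- round(stats::rlnorm(1L, log(config$iloh_median_bp),
                                   config$iloh_sdlog))
        len <- max(1L, min(len, a1e - a0))
        st <- sample(a0:(a1e - len + 1L), 1L)
        hom <- draw_homolog(1L)
        sel <- marker_arm == ai & markers$pos >= st & markers$pos <= st + len - 1L
        gt[sel] <- hom
        evs[[length(evs) + 1L]] <- data.table::data.table(
          clone = clone_id, chrom = arms$chrom[ai], arm = arms$arm[ai],
          start = st, end = st + len - 1L, type = "interstitial",
          homolog = if (hom == 0L) "P1" else "P2", n_markers_true = sum(sel))
      }
      # terminal event: breakpoint uniform on the arm, extends to the arm's
      # telomeric end
      if (stats::runif(1L) < -expm1(-lam_t[ai] * Tg)) {
        left_arm <- grepl("-l$", arms$arm[ai])
        bkp <- sample(a0:a1e, 1L)
        st <- if (left_arm) a0 else bkp
        en <- if (left_arm) bkp else a1e
        # extend to the chromosome end
        if (left_arm) st <- 1L else en <- chlen[arms$chrom[ai]]
        hom <- draw_homolog(1L)
        sel <- markers$chrom == arms$chrom[ai] & markers$pos >= st &
          markers$pos <= en
        gt[sel] <- hom
        evs[[length(evs) + 1L]] <- data.table::data.table(
          clone = clone_id, chrom = arms$chrom[ai], arm = arms$arm[ai],
          start = as.integer(st), end = as.integer(en), type = "terminal",
          homolog = if (hom == 0L) "P1" else "P2", n_markers_true = sum(sel))
      }
    }
    # genotyping errors
    true_gt <- gt
    is_het <- gt == 1L
    flip_hom <- is_het & stats::runif(M) < 2 * config$eps_hom
    gt[flip_hom] <- ifelse(stats::runif(sum(flip_hom)) < 0.5, 0L, 2L)
    flip_het <- !is_het & stats::runif(M) < config$eps_het
    gt[flip_het] <- 1L
    list(gt = gt, true_gt = true_gt,
         events = if (length(evs)) data.table::rbindlist(evs) else NULL,
         err_idx = which(flip_hom | flip_het))
  }

  reads_for_gt <- function(gt) {
    dp <- pmax(stats::rpois(length(gt), config$mean_depth), 1L)
    ad2 <- integer(length(gt))
    het <- gt == 1L
    ad2[het] <- rbetabinom(sum(het), dp[het], config$beta)
    hom2 <- gt == 2L
    ad2[hom2] <- dp[hom2] - stats::rbinom(sum(hom2), dp[hom2], 0.002)
    hom0 <- gt == 0L
    ad2[hom0] <- stats::rbinom(sum(hom0), dp[hom0], 0.002)
    list(dp = dp, ad1 = dp - ad2, ad2 = ad2)
  }

  calls_for_clone <- function(clone_id, gt) {
    r <- reads_for_gt(gt)
    data.table::data.table(
      sample = clone_id, chrom = markers$chrom, pos = markers$pos,
      a1 = markers$a1, a2 = markers$a2, gt = gt,
      gq = 99, qual = 5000, dp = r$dp, ad1 = r$ad1, ad2 = r$ad2,
      qd = 25, mq = 60, fs = 1, sor = 1)
  }

  true_gts <- list()
  for (fi in seq_len(config$n_families)) {
    fam_id <- sprintf("F%02d", fi)
    # the founder is truly heterozygous at every marker; its *called*
    # genotypes carry the same error process as the end-point clones
    founder_true <- rep(1L, M)
    founder_called <- founder_true
    ffh <- stats::runif(M) < 2 * config$eps_hom
    founder_called[ffh] <- ifelse(stats::runif(sum(ffh)) < 0.5, 0L, 2L)
    clone_ids <- sprintf("%s_c%02d", fam_id, seq_len(config$clones_per_family))
    gts <- matrix(NA_integer_, M, length(clone_ids),
                  dimnames = list(NULL, clone_ids))
    tgts <- matrix(NA_integer_, M, length(clone_ids),
                   dimnames = list(NULL, clone_ids))
    for (ci in seq_along(clone_ids)) {
      res <- simulate_clone_gt(clone_ids[ci])
      gts[, ci] <- res$gt
      tgts[, ci] <- res$true_gt
      if (!is.null(res$events)) {
        res$events$family <- fam_id
        truth_events[[length(truth_events) + 1L]] <- res$events
      }
      if (length(res$err_idx))
        err_positions[[length(err_positions) + 1L]] <- data.table::data.table(
          clone = clone_ids[ci], chrom = markers$chrom[res$err_idx],
          pos = markers$pos[res$err_idx])
      cl <- calls_for_clone(clone_ids[ci], res$gt)
      all_calls1[[length(all_calls1) + 1L]] <- cl
      all_calls2[[length(all_calls2) + 1L]] <- data.table::copy(cl)
    }
    fo <- calls_for_clone(paste0(fam_id, "_founder"), founder_called)
    all_calls1[[length(all_calls1) + 1L]] <- fo
    all_calls2[[length(all_calls2) + 1L]] <- data.table::copy(fo)
    families[[fam_id]] <- family_matrix(markers, gts,
                                        founder_gt = founder_called,
                                        family = fam_id)
    true_gts[[fam_id]] <- tgts
  }

  empty_events <- data.table::data.table(
    clone = character(), chrom = character(), arm = character(),
    start = integer(), end = integer(), type = character(),
    homolog = character(), n_markers_true = integer(), family = character())
  truth <- list(
    events = if (length(truth_events)) data.table::rbindlist(truth_events)
             else empty_events,
    error_positions = if (length(err_positions))
      data.table::rbindlist(err_positions) else data.table::data.table(),
    arm_rates = data.table::data.table(arm = arms$arm, iloh = lam_i,
                                       tloh = lam_t),
    true_gt = true_gts,
    generations = Tg)

  structure(list(truth = truth, markers = markers, families = families,
                 calls_ref1 = loh_calls(data.table::rbindlist(all_calls1)),
                 calls_ref2 = loh_calls(data.table::rbindlist(all_calls2)),
                 meta = meta, arms = arms, config = config),
            class = "sim_result")
}

#' Inject one-sided reference bias into a call set
#'
#' Emulates the genotyping artifact behind high-conversion high-bias
#' windows: at the designated marker sites, the call set produced against
#' one reference shows heterozygous sites skewed toward that reference's
#' allele - at full strength the genotype flips to the reference homolog -
#' while its genotype quality is degraded. The companion call set is left
#' untouched, so dual-reference reconciliation can overrule the biased
#' calls.
#'
#' @param calls an [loh_calls] table (the biased reference's call set)
#' @param bias_sites data.frame with `chrom`, `pos` of affected markers
#' @param strength bias strength in `[0, 1]`: probability that an affected
#'   heterozygous call flips to the reference homolog (0 = identity)
#' @param ref_parent which parent this call set's reference represents
#' @param biased_gq GQ assigned to flipped calls (default 35, below the
#'   reconciliation threshold of 50 but within 30 of it only for weak
#'   opposing calls)
#' @return the modified call table
#' @export
inject_reference_bias <- function(calls, bias_sites, strength,
                                  ref_parent = c("P1", "P2"),
                                  biased_gq = 35) {
  ref_parent <- match.arg(ref_parent)
  assert_that(strength >= 0 && strength <= 1, "strength must be in [0, 1]")
  out <- data.table::copy(data.table::as.data.table(calls))
  if (strength == 0 || nrow(bias_sites) == 0L) return(out)
  key <- paste(out$chrom, out$pos)
  bkey <- paste(bias_sites$chrom, bias_sites$pos)
  hit <- which(key %in% bkey & !is.na(out$gt) & out$gt == 1L)
  hit <- hit[stats::runif(length(hit)) < strength]
  if (!length(hit)) return(out)
  ref_gt <- if (ref_parent == "P1") 0L else 2L
  data.table::set(out, i = hit, j = "gt", value = ref_gt)
  data.table::set(out, i = hit, j = "gq", value = biased_gq)
  # skew the allele depths toward the reference allele
  dp <- out$dp[hit]
  ref_reads <- dp - stats::rbinom(length(hit), dp, 0.05)
  if (ref_parent == "P1") {
    data.table::set(out, i = hit, j = "ad1", value = ref_reads)
    data.table::set(out, i = hit, j = "ad2", value = dp - ref_reads)
  } else {
    data.table::set(out, i = hit, j = "ad2", value = ref_reads)
    data.table::set(out, i = hit, j = "ad1", value = dp - ref_reads)
  }
  out
}

#' Simulate per-arm LOH count tables from the rate model
#'
#' Draws counts directly from the generative model behind [fit_glmm()]:
#' per-arm rates `lambda_ha = mu + alpha_h L_a + beta_a + gamma_ha` with
#' normal arm and hybrid-arm effects, Poisson interstitial counts (or
#' Bernoulli terminal indicators) with mean `f(lambda T)`.
#'
#' @param H,A,n_clones design size: hybrids, arms, clones per hybrid
#' @param generations duration per hybrid (scalar or length-H)
#' @param mu,alpha fixed effects; `alpha` is recycled to length H
#'   (rate per Mb of arm length)
#' @param sigma_fc,sigma_sc random-effect standard deviations
#' @param arm_mb arm lengths in Mb (default: evenly spaced 0.1-1.1)
#' @param family `"poisson_iloh"` or `"bernoulli_tloh"`
#' @param delta link threshold (defaults as in [fit_glmm()])
#' @param seed optional RNG seed
#' @return list with `table` (a [count_table()]) and `truth` (the drawn
#'   effects and per-cell rates)
#' @export
simulate_count_table <- function(H, A, n_clones, generations, mu, alpha,
                                 sigma_fc = 0, sigma_sc = 0, arm_mb = NULL,
                                 family = c("poisson_iloh", "bernoulli_tloh"),
                                 delta = NULL, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(delta)) delta <- if (family == "poisson_iloh") 0.01 else 0.03
  link <- if (family == "poisson_iloh") link_iloh(delta) else link_tloh(delta)
  alpha <- rep(alpha, length.out = H)
  Tg <- rep(generations, length.out = H)
  if (is.null(arm_mb)) arm_mb <- seq(0.1, 1.1, length.out = A)
  beta_a <- stats::rnorm(A, 0, sigma_fc)
  gamma_ha <- matrix(stats::rnorm(H * A, 0, sigma_sc), H, A)
  rows <- list()
  for (h in seq_len(H)) for (a in seq_len(A)) {
    lam <- mu + alpha[h] * arm_mb[a] + beta_a[a] + gamma_ha[h, a]
    m <- link$f(lam * Tg[h])
    cnt <- if (family == "poisson_iloh") stats::rpois(n_clones, m)
           else stats::rbinom(n_clones, 1L, min(m, 1 - 1e-12))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      hybrid = sprintf("H%02d", h), clone = sprintf("H%02d_c%03d", h,
                                                    seq_len(n_clones)),
      arm = sprintf("arm%02d", a), count = cnt,
      arm_bp = arm_mb[a] * 1e6, generations = Tg[h])
  }
  tab <- count_table(data.table::rbindlist(rows),
                     type = if (family == "poisson_iloh") "iloh" else "tloh")
  list(table = tab,
       truth = list(mu = mu, alpha = alpha, beta_a = beta_a,
                    gamma_ha = gamma_ha, arm_mb = arm_mb, T = Tg))
}
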