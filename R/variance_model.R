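#' Stitched link functions for LOH-rate models
#'
#' The linear predictor of the rate models can go negative, so the identity
#' (interstitial counts) and `-log(1 - y)` (terminal indicators) links are
#' smoothly stitched to logarithmic branches below a threshold `delta`,
#' keeping the inverse link positive everywhere and the pair continuously
#' differentiable at the stitch point.
#'
#' * Interstitial: `g(y) = y` for `y >= delta`,
#'   `g(y) = delta + delta * log(y/delta)` for `0 < y < delta`; inverse
#'   `f(x) = x` above `delta` and `delta * exp((x - delta)/delta)` below.
#' * Terminal: with `eps = 1 - exp(-delta)`, `g(y) = -log(1 - y)` for
#'   `eps <= y < 1` and `g(y) = delta + eps * e^delta * log(y/eps)` below;
#'   inverse `f(x) = 1 - exp(-x)` for `x >= delta` and
#'   `eps * exp((x - delta)/(eps * e^delta))` below. Both branches have
#'   slope `e^delta` at the stitch.
#'
#' @param delta stitch threshold (defaults: 0.01 interstitial,
#'   0.03 terminal)
#' @return list with functions `g` (link), `f` (inverse), `fprime`, `fpp`
#'   (first and second derivatives of the inverse), and fields `delta`,
#'   `family`
#' @export
link_iloh <- function(delta = 0.01) {
  g <- function(y) {
    assert_that(all(y > 0), "link requires y > 0")
    ifelse(y >= delta, y, delta + delta * log(y / delta))
  }
  f <- function(x) ifelse(x >= delta, x, delta * exp((x - delta) / delta))
  fprime <- function(x) ifelse(x >= delta, 1, f(x) / delta)
  fpp <- function(x) ifelse(x >= delta, 0, f(x) / delta^2)
  list(g = g, f = f, fprime = fprime, fpp = fpp, delta = delta,
       family = "poisson_iloh")
}

#' @rdname link_iloh
#' @export
link_tloh <- function(delta = 0.03) {
  eps <- -expm1(-delta)
  s <- eps * exp(delta)
  g <- function(y) {
    assert_that(all(y > 0 & y < 1), "link requires y in (0, 1)")
    ifelse(y >= eps, -log1p(-y), delta + s * log(y / eps))
  }
  f <- function(x) ifelse(x >= delta, -expm1(-x), eps * exp((x - delta) / s))
  fprime <- function(x) ifelse(x >= delta, exp(-x), f(x) / s)
  fpp <- function(x) ifelse(x >= delta, -exp(-x), f(x) / s^2)
  list(g = g, f = f, fprime = fprime, fpp = fpp, delta = delta, eps = eps,
       family = "bernoulli_tloh")
}

# per-cell log-likelihood and derivatives w.r.t. the predictor xi, for
# aggregated cells (S = summed counts / successes, n = clones)
cell_loglik <- function(link, family) {
  if (family == "poisson_iloh") {
    # means are clamped away from zero so that underflow of the lower link
    # branch cannot produce log(0) during optimization
    list(
      ll = function(xi, S, n) {
        m <- pmax(link$f(xi), 1e-300)
        S * log(m) - n * m
      },
      d1 = function(xi, S, n) {
        m <- pmax(link$f(xi), 1e-300)
        (S / m - n) * link$fprime(xi)
      },
      d2 = function(xi, S, n) {
        m <- pmax(link$f(xi), 1e-300); mp <- link$fprime(xi)
        -S * (mp / m)^2 + (S / m - n) * link$fpp(xi)
      })
  } else {
    list(
      ll = function(xi, S, n) {
        p <- pmin(pmax(link$f(xi), 1e-300), 1 - 1e-12)
        lp <- ifelse(xi >= link$delta, log1p(-exp(-pmax(xi, 1e-12))),
                     log(p))
        l1mp <- ifelse(xi >= link$delta, -xi, log1p(-p))
        S * lp + (n - S) * l1mp
      },
      d1 = function(xi, S, n) {
        p <- pmin(pmax(link$f(xi), 1e-300), 1 - 1e-12)
        (S / p - (n - S) / (1 - p)) * link$fprime(xi)
      },
      d2 = function(xi, S, n) {
        p <- pmin(pmax(link$f(xi), 1e-300), 1 - 1e-12)
        pp <- link$fprime(xi)
        (-S / p^2 - (n - S) / (1 - p)^2) * pp^2 +
          (S / p - (n - S) / (1 - p)) * link$fpp(xi)
      })
  }
}

#' Per-arm LOH count tables
#'
#' The modeling input: one row per hybrid, clone and chromosome arm with
#' the event count on that arm (interstitial: non-negative integer;
#' terminal: 0/1 indicator), the arm length and the experiment duration.
#'
#' @param df data.frame with `hybrid`, `clone`, `arm`, `count`, `arm_bp`,
#'   `generations`
#' @param type `"iloh"` or `"tloh"`; terminal tables must be 0/1
#' @return data.table of class `count_table`
#' @export
count_table <- function(df, type = c("iloh", "tloh")) {
  type <- match.arg(type)
  dt <- data.table::as.data.table(df)
  need <- c("hybrid", "clone", "arm", "count", "arm_bp", "generations")
  assert_that(all(need %in% names(dt)),
              paste("count table needs columns:", paste(need, collapse = ", ")))
  assert_that(all(dt$count >= 0), "counts must be non-negative")
  if (type == "tloh")
    assert_that(all(dt$count %in% c(0L, 1L)), "terminal counts must be 0/1")
  data.table::setattr(dt, "loh_type", type)
  dt[]
}

# aggregate a count table to (hybrid, arm) cells; sufficient statistics for
# both families are the per-cell sum and the clone count
aggregate_cells <- function(table) {
  dt <- data.table::as.data.table(table)
  cells <- dt[, list(S = sum(count), n = .N,
                     T = generations[1L], L = arm_bp[1L] / 1e6),
              by = list(hybrid, arm)]
  cells$h <- match(cells$hybrid, sort(unique(cells$hybrid)))
  cells$a <- match(cells$arm, sort(unique(cells$arm)))
  cells[]
}

model_structure <- function(model, H) {
  switch(model,
    full = list(fix = c("mu", paste0("alpha", seq_len(H))),
                has_beta = TRUE, has_gamma = TRUE, slope = "per_hybrid"),
    arm = list(fix = c("mu", paste0("alpha", seq_len(H))),
               has_beta = TRUE, has_gamma = FALSE, slope = "per_hybrid"),
    hybrid_slopes = list(fix = c("mu", paste0("alpha", seq_len(H))),
                         has_beta = FALSE, has_gamma = FALSE,
                         slope = "per_hybrid"),
    hybrid_arm = list(fix = "mu", has_beta = FALSE, has_gamma = TRUE,
                      slope = "none"),
    one_slope = list(fix = c("mu", "alpha"), has_beta = FALSE,
                     has_gamma = FALSE, slope = "shared"),
    intercept = list(fix = "mu", has_beta = FALSE, has_gamma = FALSE,
                     slope = "none"),
    stop("unknown model: ", model))
}

fixed_predictor <- function(theta_fix, struct, cells) {
  mu <- theta_fix[1L]
  switch(struct$slope,
         per_hybrid = mu + theta_fix[1L + cells$h] * cells$L,
         shared = mu + theta_fix[2L] * cells$L,
         none = rep(mu, nrow(cells)))
}

# Laplace-approximated marginal log-likelihood contribution of one arm
arm_laplace <- function(eta, Tg, S, n, h_idx, sig_fc, sig_sc, llfun,
                        warm = NULL) {
  H_arm <- length(eta)
  use_b <- !is.na(sig_fc) && sig_fc > 1e-8
  use_g <- !is.na(sig_sc) && sig_sc > 1e-8
  q <- use_b + use_g * H_arm
  lam0 <- function(u) {
    lam <- eta
    if (use_b) lam <- lam + u[1L]
    if (use_g) lam <- lam + u[(1L + use_b):(use_b + H_arm)]
    lam
  }
  sig2 <- c(if (use_b) sig_fc^2, if (use_g) rep(sig_sc^2, H_arm))
  if (q == 0L) {
    return(list(val = sum(llfun$ll(eta * Tg, S, n)), u = numeric(0)))
  }
  negh <- function(u) {
    xi <- lam0(u) * Tg
    -(sum(llfun$ll(xi, S, n)) - sum(u^2 / (2 * sig2)))
  }
  neggrad <- function(u) {
    xi <- lam0(u) * Tg
    d1 <- llfun$d1(xi, S, n) * Tg
    g <- numeric(q)
    if (use_b) g[1L] <- sum(d1)
    if (use_g) g[(1L + use_b):q] <- d1
    -(g - u / sig2)
  }
  start <- if (!is.null(warm) && length(warm) == q) warm else numeric(q)
  opt <- stats::nlminb(start, negh, gradient = neggrad,
                       control = list(iter.max = 200L))
  u <- opt$par
  xi <- lam0(u) * Tg
  w <- -llfun$d2(xi, S, n) * Tg^2   # negative Hessian contributions
  Hmat <- matrix(0, q, q)
  if (use_b) {
    Hmat[1L, 1L] <- sum(w)
    if (use_g) {
      Hmat[1L, 2L:q] <- w
      Hmat[2L:q, 1L] <- w
    }
  }
  if (use_g) {
    gi <- (1L + use_b):q
    diag(Hmat)[gi] <- diag(Hmat)[gi] + w
  }
  # log det(I + Sigma * (-H_ll)) with Sigma = diag(sig2)
  M <- diag(q) + sig2 * Hmat
  ld <- determinant(M, logarithm = TRUE)
  ldet <- as.numeric(ld$modulus)
  if (ld$sign < 0) ldet <- 1e6   # non-PD curvature: heavily penalized
  list(val = -opt$objective - 0.5 * ldet, u = u)
}

#' Fit a generalized linear mixed model for per-arm LOH counts
#'
#' Models the per-generation LOH rate on arm `a` of hybrid `h` as
#' `lambda_ha = mu + alpha_h L_a + beta_a + gamma_ha`, with `beta_a` (fixed
#' cis factors, shared across hybrids) and `gamma_ha` (segregating cis
#' factors) normal with standard deviations `sigma_fc` and `sigma_sc`.
#' Interstitial counts are Poisson with mean `f(lambda T_h)`; terminal
#' indicators are Bernoulli with success probability `f(lambda T_h)`, with
#' `f` the inverse stitched link ([link_iloh()], [link_tloh()]). The
#' marginal likelihood integrates the random effects by the Laplace
#' approximation; random effects factorize by arm, so the integral is
#' computed arm-wise with inner conditional-mode optimization.
#'
#' Nested models: `"full"` (all terms), `"arm"` (no `gamma`),
#' `"hybrid_slopes"` (fixed effects only), `"hybrid_arm"`
#' (`mu + gamma_ha`), `"one_slope"` (`mu + alpha L_a`), `"intercept"`.
#'
#' @param table a [count_table()]
#' @param family `"poisson_iloh"` or `"bernoulli_tloh"`
#' @param model one of the nested model names above
#' @param delta link threshold (default 0.01 Poisson, 0.03 Bernoulli)
#' @param start optional named start values
#' @return object of class `loh_glmm`: fixed effects, variance components,
#'   conditional modes, `logLik`, `npar`, convergence diagnostics
#' @export
fit_glmm <- function(table,
                     family = c("poisson_iloh", "bernoulli_tloh"),
                     model = c("full", "arm", "hybrid_slopes", "hybrid_arm",
                               "one_slope", "intercept"),
                     delta = NULL, start = NULL) {
  family <- match.arg(family)
  model <- match.arg(model)
  if (family == "bernoulli_tloh")
    assert_that(all(table$count %in% c(0L, 1L)),
                "bernoulli_tloh requires 0/1 counts")
  if (is.null(delta)) delta <- if (family == "poisson_iloh") 0.01 else 0.03
  link <- if (family == "poisson_iloh") link_iloh(delta) else link_tloh(delta)
  llfun <- cell_loglik(link, family)

  cells <- aggregate_cells(table)
  H <- max(cells$h); A <- max(cells$a)
  struct <- model_structure(model, H)
  nfix <- length(struct$fix)
  nsig <- struct$has_beta + struct$has_gamma
  arms <- split(seq_len(nrow(cells)), cells$a)

  const <- if (family == "poisson_iloh")
    -sum(lgamma(data.table::as.data.table(table)$count + 1)) else 0

  warm_env <- new.env(parent = emptyenv())

  objective <- function(theta) {
    fix <- theta[seq_len(nfix)]
    sig_fc <- if (struct$has_beta) theta[nfix + 1L] else NA_real_
    sig_sc <- if (struct$has_gamma) theta[nfix + nsig] else NA_real_
    eta_all <- fixed_predictor(fix, struct, cells)
    tot <- 0
    for (ai in seq_along(arms)) {
      idx <- arms[[ai]]
      key <- paste0("a", ai)
      res <- arm_laplace(eta_all[idx], cells$T[idx], cells$S[idx],
                         cells$n[idx], cells$h[idx], sig_fc, sig_sc, llfun,
                         warm = warm_env[[key]])
      warm_env[[key]] <- res$u
      tot <- tot + res$val
      if (!is.finite(tot)) return(1e10)
    }
    -tot
  }

  # moment-based starting values
  if (is.null(start)) {
    rate <- cells$S / (cells$n * cells$T)
    st_fix <- numeric(nfix)
    if (struct$slope == "per_hybrid") {
      ints <- numeric(H); slopes <- numeric(H)
      for (hh in seq_len(H)) {
        sel <- cells$h == hh
        cf <- tryCatch(stats::coef(stats::lm(rate[sel] ~ cells$L[sel])),
                       error = function(e) c(mean(rate[sel]), 0))
        ints[hh] <- cf[1L]; slopes[hh] <- if (is.na(cf[2L])) 0 else cf[2L]
      }
      st_fix[1L] <- max(mean(ints), 1e-4)
      st_fix[-1L] <- pmax(slopes, 0)
      eta0 <- st_fix[1L] + st_fix[1L + cells$h] * cells$L
    } else if (struct$slope == "shared") {
      cf <- stats::coef(stats::lm(rate ~ cells$L))
      st_fix <- c(max(cf[1L], 1e-4), max(cf[2L], 0))
      eta0 <- st_fix[1L] + st_fix[2L] * cells$L
    } else {
      st_fix[1L] <- max(mean(rate), 1e-4)
      eta0 <- rep(st_fix[1L], nrow(cells))
    }
    resid <- rate - eta0
    st_sig <- rep(max(stats::sd(resid) / 2, 1e-3), nsig)
    start <- c(st_fix, st_sig)
  }
  lower <- c(rep(-Inf, nfix), rep(0, nsig))

  opt <- stats::nlminb(start, objective, lower = lower,
                       control = list(iter.max = 500L, rel.tol = 1e-10))
  theta <- opt$par
  fix <- theta[seq_len(nfix)]
  names(fix) <- struct$fix
  sig_fc <- if (struct$has_beta) theta[nfix + 1L] else NA_real_
  sig_sc <- if (struct$has_gamma) theta[nfix + nsig] else NA_real_

  # conditional modes at the optimum
  eta_all <- fixed_predictor(fix, struct, cells)
  beta_a <- rep(0, A); gamma_ha <- matrix(0, H, A)
  for (ai in seq_along(arms)) {
    idx <- arms[[ai]]
    res <- arm_laplace(eta_all[idx], cells$T[idx], cells$S[idx],
                       cells$n[idx], cells$h[idx], sig_fc, sig_sc, llfun,
                       warm = warm_env[[paste0("a", ai)]])
    u <- res$u
    use_b <- !is.na(sig_fc) && sig_fc > 1e-8
    use_g <- !is.na(sig_sc) && sig_sc > 1e-8
    if (use_b) beta_a[ai] <- u[1L]
    if (use_g) gamma_ha[cells$h[idx], ai] <- u[(1L + use_b):length(u)]
  }

  frac_fixed_below <- mean(eta_all < link$delta)
  lam_full <- eta_all + beta_a[cells$a] +
    gamma_ha[cbind(cells$h, cells$a)]
  frac_full_below <- mean(lam_full < link$delta)

  structure(list(
    model = model, family = family, delta = link$delta, link = link,
    fixef = fix, sigma_fc = sig_fc, sigma_sc = sig_sc,
    beta_a = beta_a, gamma_ha = gamma_ha,
    logLik = -opt$objective + const, npar = length(theta),
    convergence = opt$convergence, message = opt$message,
    frac_fixed_below_delta = frac_fixed_below,
    frac_full_below_delta = frac_full_below,
    cells = cells,
    hybrids = sort(unique(cells$hybrid)), arms = sort(unique(cells$arm))),
    class = "loh_glmm")
}

#' @export
print.loh_glmm <- function(x, ...) {
  cat("LOH GLMM (", x$family, ", model = ", x$model, ")\n", sep = "")
  cat("  logLik:", format(x$logLik), "  npar:", x$npar, "\n")
  cat("  fixed effects:\n")
  print(signif(x$fixef, 4))
  cat("  sigma_fc:", format(x$sigma_fc), " sigma_sc:", format(x$sigma_sc), "\n")
  invisible(x)
}

#' Predicted counts from a fitted LOH GLMM
#'
#' @param object a [fit_glmm()] result
#' @param table the count table to predict for (default: the fitted cells)
#' @param level `"full"` (fixed effects plus conditional modes),
#'   `"fixed_arm"` (fixed effects plus arm effects) or `"fixed"` (fixed
#'   effects only)
#' @param ... unused
#' @return numeric vector of predicted counts `f(lambda T)` per row of
#'   `table`
#' @export
predict.loh_glmm <- function(object, table = NULL,
                             level = c("full", "fixed_arm", "fixed"), ...) {
  level <- match.arg(level)
  cells <- object$cells
  if (is.null(table)) {
    h <- cells$h; a <- cells$a; L <- cells$L; Tg <- cells$T
  } else {
    dt <- data.table::as.data.table(table)
    h <- match(dt$hybrid, object$hybrids)
    a <- match(dt$arm, object$arms)
    L <- dt$arm_bp / 1e6; Tg <- dt$generations
  }
  struct <- model_structure(object$model, length(object$hybrids))
  fakecells <- data.table::data.table(h = h, L = L)
  lam <- fixed_predictor(object$fixef, struct, fakecells)
  if (level %in% c("fixed_arm", "full")) lam <- lam + object$beta_a[a]
  if (level == "full") lam <- lam + object$gamma_ha[cbind(h, a)]
  object$link$f(lam * Tg)
}

#' Likelihood ratio test between nested LOH GLMMs
#'
#' @param model_small,model_big nested fits on the same data
#' @param df test degrees of freedom (default: parameter-count difference)
#' @param boundary apply the 50:50 chi-square mixture correction for a
#'   variance parameter tested on its boundary (default `FALSE`)
#' @return list with `statistic`, `df`, `p_value`
#' @export
lrt <- function(model_small, model_big, df = NULL, boundary = FALSE) {
  stat <- 2 * (model_big$logLik - model_small$logLik)
  assert_that(stat > -1e-4,
              "larger model has lower likelihood; check convergence")
  stat <- max(stat, 0)
  if (is.null(df)) df <- model_big$npar - model_small$npar
  assert_that(df >= 1, "models are not nested or have equal dimension")
  p <- if (boundary) {
    0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
      0.5 * (if (df > 1) stats::pchisq(stat, df - 1, lower.tail = FALSE)
             else as.numeric(stat == 0))
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

#' Partition LOH-count variance into trans, cis and noise components
#'
#' Telescoping decomposition of the total variance of the counts:
#' `V_noise` is the mean squared difference between counts and full-model
#' predictions; `V_cis+noise` uses fixed-effects-only predictions and
#' `V_sc+noise` fixed-plus-arm predictions. Then
#' `V_st = V_tot - V_cis+noise` (segregating trans),
#' `V_fc = V_cis+noise - V_sc+noise` (fixed cis) and
#' `V_sc = V_sc+noise - V_noise` (segregating cis). Fractions over `V_tot`
#' sum to 1 exactly by construction. For fits without random effects the
#' cis components are zero and `V_st = V_tot - V_noise`.
#'
#' @param table the count table the model was fitted to
#' @param fit a [fit_glmm()] result
#' @return list with the variance components and `fractions`
#'   (`st`, `fc`, `sc`, `noise`)
#' @export
partition_variance <- function(table, fit) {
  dt <- data.table::as.data.table(table)
  C <- dt$count
  pf <- predict(fit, dt, level = "fixed")
  pa <- predict(fit, dt, level = "fixed_arm")
  pu <- predict(fit, dt, level = "full")
  v_tot <- mean((C - mean(C))^2)
  v_cis_noise <- mean((C - pf)^2)
  v_sc_noise <- mean((C - pa)^2)
  v_noise <- mean((C - pu)^2)
  v_st <- v_tot - v_cis_noise
  v_fc <- v_cis_noise - v_sc_noise
  v_sc <- v_sc_noise - v_noise
  fr <- c(st = v_st, fc = v_fc, sc = v_sc, noise = v_noise) / v_tot
  list(v_tot = v_tot, v_st = v_st, v_fc = v_fc, v_sc = v_sc,
       v_noise = v_noise, fractions = fr)
}

#' G-test of homogeneity for terminal events on long chromosome arms
#'
#' For each focal arm, tests whether the proportion of a hybrid's terminal
#' events falling on that arm is the same across hybrids, using the G
#' statistic (`2 sum O log(O/E)`) on the 2 x H table of on-arm versus
#' elsewhere counts, compared to chi-square with H - 1 degrees of freedom,
#' Bonferroni-adjusted for the number of arms tested. Hybrids with zero
#' total events are excluded with a warning (df reduced).
#'
#' @param counts data.frame with `hybrid`, `arm`, `count` (summed terminal
#'   events per hybrid per arm)
#' @param arms focal arm names (e.g. all arms longer than 0.5 Mb)
#' @return data.table with `arm`, `G`, `df`, `p_value`, `p_adjusted`
#' @export
gtest_long_arms <- function(counts, arms) {
  dt <- data.table::as.data.table(counts)
  totals <- dt[, list(total = sum(count)), by = list(hybrid)]
  zero <- totals$hybrid[totals$total == 0]
  if (length(zero)) {
    warning("excluding hybrids with zero events: ",
            paste(zero, collapse = ", "), call. = FALSE)
    dt <- dt[!(hybrid %in% zero)]
    totals <- totals[!(hybrid %in% zero)]
  }
  hyb <- totals$hybrid
  res <- lapply(arms, function(a) {
    on <- vapply(hyb, function(h) sum(dt$count[dt$hybrid == h & dt$arm == a]),
                 numeric(1))
    tot <- totals$total[match(hyb, totals$hybrid)]
    off <- tot - on
    obs <- rbind(on, off)
    E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    nz <- obs > 0
    G <- 2 * sum(obs[nz] * log(obs[nz] / E[nz]))
    df <- length(hyb) - 1L
    data.table::data.table(arm = a, G = G, df = df,
                           p_value = stats::pchisq(G, df, lower.tail = FALSE))
  })
  out <- data.table::rbindlist(res)
  out$p_adjusted <- pmin(1, out$p_value * length(arms))
  out[]
}
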