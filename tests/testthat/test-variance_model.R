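test_that("stitched links are exact inverses, positive, and C1 at the stitch", {
  li <- link_iloh(0.01)
  expect_equal(li$g(0.01), 0.01)
  expect_equal(li$f(0.01), 0.01)
  y <- exp(seq(log(1e-6), log(10), length.out = 200))
  expect_equal(li$f(li$g(y)), y, tolerance = 1e-12)
  expect_gt(li$f(-5), 0)
  expect_equal(li$f(-5), 0.01 * exp((-5 - 0.01) / 0.01))
  expect_error(li$g(-1), "y > 0")

  lt <- link_tloh(0.03)
  eps <- 1 - exp(-0.03)
  expect_equal(lt$g(eps), 0.03)
  expect_equal(lt$f(0.5), 1 - exp(-0.5))
  y2 <- seq(1e-6, 0.999, length.out = 200)
  expect_equal(lt$f(lt$g(y2)), y2, tolerance = 1e-10)
  expect_error(lt$g(1.5), "0, 1")

  # numeric first-derivative continuity at the stitch points
  h <- 1e-7
  expect_equal((li$f(0.01 + h) - li$f(0.01 - h)) / (2 * h), 1,
               tolerance = 1e-4)
  num <- (lt$g(eps + h) - lt$g(eps - h)) / (2 * h)
  expect_equal(num, exp(0.03), tolerance = 1e-4)
  # inverse stays positive far below the stitch
  expect_gt(lt$f(-3), 0)
})

test_that("fixed-effect models recover simulated parameters", {
  s <- simulate_count_table(1, 12, 60, 800, mu = 2e-3, alpha = 4e-3,
                            sigma_fc = 0, sigma_sc = 0,
                            family = "poisson_iloh", seed = 101)
  # one hybrid: hybrid_slopes is mu + alpha L
  fit <- fit_glmm(s$table, "poisson_iloh", "hybrid_slopes")
  expect_lt(abs(fit$fixef[["mu"]] - 2e-3) / 2e-3, 0.35)
  expect_lt(abs(fit$fixef[["alpha1"]] - 4e-3) / 4e-3, 0.25)

  # one-slope model on multi-hybrid data with a shared slope
  s2 <- simulate_count_table(4, 10, 40, 800, mu = 1e-3, alpha = 3e-3,
                             sigma_fc = 0, sigma_sc = 0, seed = 102)
  fit2 <- fit_glmm(s2$table, "poisson_iloh", "one_slope")
  expect_lt(abs(fit2$fixef[["alpha"]] - 3e-3) / 3e-3, 0.2)

  # bernoulli family at realistic terminal-event scale
  s3 <- simulate_count_table(4, 12, 60, 2000, mu = 2e-5, alpha = 6e-5,
                             sigma_fc = 0, sigma_sc = 0,
                             family = "bernoulli_tloh", seed = 103)
  fit3 <- fit_glmm(s3$table, "bernoulli_tloh", "one_slope")
  expect_lt(abs(fit3$fixef[["alpha"]] - 6e-5) / 6e-5, 0.35)
})

test_that("degenerate variance components collapse the full model onto fixed effects", {
  s <- simulate_count_table(3, 8, 25, 800, mu = 2e-3, alpha = c(2e-3, 4e-3, 6e-3),
                            sigma_fc = 0, sigma_sc = 0, seed = 104)
  f_fix <- fit_glmm(s$table, "poisson_iloh", "hybrid_slopes")
  f_full <- fit_glmm(s$table, "poisson_iloh", "full")
  expect_lt(f_full$sigma_fc, 5e-4)
  expect_lt(f_full$sigma_sc, 5e-4)
  expect_equal(f_full$logLik, f_fix$logLik, tolerance = 1e-4)
  r <- lrt(f_fix, f_full)
  expect_equal(r$df, 2)
  expect_gt(r$p_value, 0.9)
})

test_that("the LRT detects simulated segregating cis variation", {
  s <- simulate_count_table(4, 8, 20, 800, mu = 2e-3, alpha = 3e-3,
                            sigma_fc = 0, sigma_sc = 2e-3, seed = 105)
  f_arm <- fit_glmm(s$table, "poisson_iloh", "arm")
  f_full <- fit_glmm(s$table, "poisson_iloh", "full")
  expect_lt(abs(f_full$sigma_sc - 2e-3) / 2e-3, 0.5)
  r <- lrt(f_arm, f_full, df = 1)
  expect_lt(r$p_value, 1e-4)
  # the boundary-corrected variant halves the tail probability
  rb <- lrt(f_arm, f_full, df = 1, boundary = TRUE)
  expect_equal(rb$p_value, r$p_value / 2, tolerance = 1e-10)
})

test_that("identical models give a unit p-value and fit failures error", {
  s <- simulate_count_table(2, 6, 15, 800, mu = 2e-3, alpha = 3e-3,
                            seed = 106)
  f <- fit_glmm(s$table, "poisson_iloh", "hybrid_slopes")
  r <- lrt(f, f, df = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  f_bad <- f; f_bad$logLik <- f$logLik - 5
  expect_error(lrt(f, f_bad, df = 1), "lower likelihood")
})

test_that("variance partitioning telescopes to exactly one", {
  s <- simulate_count_table(4, 8, 20, 800, mu = 2e-3,
                            alpha = c(1e-3, 3e-3, 6e-3, 1e-2),
                            sigma_fc = 5e-4, sigma_sc = 5e-4, seed = 107)
  fit <- fit_glmm(s$table, "poisson_iloh", "full")
  pv <- partition_variance(s$table, fit)
  expect_equal(sum(pv$fractions), 1, tolerance = 1e-12)
  expect_true(all(is.finite(pv$fractions)))

  # hybrid-slope-only variation: trans dominates, cis components vanish
  s2 <- simulate_count_table(6, 10, 40, 800, mu = 1e-3,
                             alpha = seq(1e-3, 2e-2, length.out = 6),
                             sigma_fc = 0, sigma_sc = 0, seed = 108)
  fit2 <- fit_glmm(s2$table, "poisson_iloh", "full")
  pv2 <- partition_variance(s2$table, fit2)
  expect_lt(abs(pv2$fractions[["fc"]]), 0.05)
  expect_lt(abs(pv2$fractions[["sc"]]), 0.05)
  expect_gt(pv2$fractions[["st"]], pv2$fractions[["fc"]] + pv2$fractions[["sc"]])
})

test_that("the long-arm G test matches the direct formula", {
  # identical proportions: G = 0, p = 1
  cnt <- data.frame(hybrid = rep(c("h1", "h2", "h3"), each = 2),
                    arm = rep(c("a1", "a2"), 3),
                    count = rep(c(10L, 30L), 3))
  g <- gtest_long_arms(cnt, "a1")
  expect_equal(g$G, 0, tolerance = 1e-12)
  expect_equal(g$p_value, 1)

  # hand-built 2 x 3 table against the oracle
  cnt2 <- data.frame(hybrid = rep(c("h1", "h2", "h3"), each = 2),
                     arm = rep(c("a1", "a2"), 3),
                     count = c(12L, 8L, 3L, 17L, 9L, 11L))
  g2 <- gtest_long_arms(cnt2, "a1")
  tab <- rbind(on = c(12, 3, 9), off = c(8, 17, 11))
  expect_equal(g2$G, oracle_g(tab), tolerance = 1e-12)
  expect_equal(g2$df, 2L)
  expect_equal(g2$p_value, pchisq(oracle_g(tab), 2, lower.tail = FALSE))

  # Bonferroni over the arms tested
  g3 <- gtest_long_arms(cnt2, c("a1", "a2"))
  expect_equal(g3$p_adjusted, pmin(1, g3$p_value * 2))

  # hybrids with zero totals are excluded with a warning
  cnt3 <- rbind(cnt2, data.frame(hybrid = "h4", arm = c("a1", "a2"),
                                 count = c(0L, 0L)))
  expect_warning(g4 <- gtest_long_arms(cnt3, "a1"), "zero")
  expect_equal(g4$df, 2L)
})

test_that("null LRT p-values are roughly uniform across replicates", {
  # fixed-effects nested pair keeps each replicate fast; the LRT machinery
  # and fitter are the package's own
  set.seed(109)
  ps <- replicate(120, {
    s <- simulate_count_table(3, 8, 12, 800, mu = 2e-3, alpha = 3e-3,
                              sigma_fc = 0, sigma_sc = 0,
                              seed = sample.int(1e6, 1))
    f0 <- fit_glmm(s$table, "poisson_iloh", "one_slope")
    f1 <- fit_glmm(s$table, "poisson_iloh", "hybrid_slopes")
    lrt(f0, f1, df = 2)$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})
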