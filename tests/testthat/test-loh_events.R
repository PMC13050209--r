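test_that("tract finding applies midpoint and chromosome-end rules", {
  # all-het clone: no tracts
  expect_equal(nrow(find_tracts(rep(1L, 5), (1:5) * 100L, "c", 1000L)), 0L)

  # single converted marker flanked by heterozygous markers
  tr <- find_tracts(c(1L, 0L, 1L), c(100L, 200L, 300L), "c", 500L)
  expect_equal(tr$start, 150L)
  expect_equal(tr$end, 250L)
  expect_equal(tr$n_markers, 1L)
  expect_equal(tr$homolog, "P1")

  # tract containing the last marker extends to the chromosome end
  tr2 <- find_tracts(c(1L, 2L), c(100L, 400000L), "c", 500000L)
  expect_equal(tr2$end, 500000L)
  expect_true(tr2$term_right)

  # missing markers are transparent: the run is not broken
  tr3 <- find_tracts(c(1L, 0L, NA, 0L, 1L), (1:5) * 1000L, "c", 10000L)
  expect_equal(nrow(tr3), 1L)
  expect_equal(tr3$n_markers, 2L)
})

test_that("tract merging respects the 10-kb rule and conversion-length homolog vote", {
  tr <- function(start, end, hom, nm = 2L) {
    data.frame(clone = "c1", chrom = "chr1", start = start, end = end,
               homolog = hom, n_markers = nm, first_marker = start,
               last_marker = end, term_left = FALSE, term_right = FALSE)
  }
  # 5 kb apart: one event
  ev <- merge_into_events(rbind(tr(1000L, 2000L, "P1"),
                                tr(7000L, 9000L, "P1")))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 1000L); expect_equal(ev$end, 9000L)

  # 15 kb apart: two events
  ev2 <- merge_into_events(rbind(tr(1000L, 2000L, "P1"),
                                 tr(17000L, 19000L, "P1")))
  expect_equal(nrow(ev2), 2L)

  # mixed homologs: the larger total conversion length wins
  ev3 <- merge_into_events(rbind(tr(1000L, 9000L, "P1"),
                                 tr(11000L, 12000L, "P2")))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$homolog, "P1")

  # ties resolve to P1 with a warning
  expect_warning(
    ev4 <- merge_into_events(rbind(tr(1000L, 2000L, "P2"),
                                   tr(5000L, 6000L, "P1"))),
    "tie")
  expect_equal(ev4$homolog, "P1")
})

test_that("event classification and breakpoints follow the terminal rules", {
  mkev <- function(start, end, tl = FALSE, tr = FALSE) {
    classify_events(data.frame(clone = "c1", chrom = "chr1", start = start,
                               end = end, homolog = "P1", n_markers = 2L,
                               n_tracts = 1L, term_left = tl, term_right = tr),
                    c(chr1 = 500000L))
  }
  expect_equal(mkev(100000L, 500000L, tr = TRUE)$type, "terminal")
  expect_equal(mkev(100000L, 200000L)$type, "interstitial")
  wc <- mkev(1L, 500000L, tl = TRUE, tr = TRUE)
  expect_equal(wc$type, "terminal")
  expect_true(wc$whole_chrom)

  # interstitial breakpoint: midpoint
  bp <- breakpoint_position(mkev(1000L, 3000L))
  expect_equal(bp$breakpoint, 2000L)
  # short terminal event (< 20 kb): midpoint
  bp2 <- breakpoint_position(mkev(485001L, 500000L, tr = TRUE),
                             centromeres = c(chr1 = 150000L))
  expect_equal(bp2$breakpoint, (485001L + 500000L) %/% 2L)
  # long right-arm terminal event: 10 kb inside from the proximal boundary
  bp3 <- breakpoint_position(mkev(300000L, 500000L, tr = TRUE),
                             centromeres = c(chr1 = 150000L))
  expect_equal(bp3$breakpoint, 310000L)
  # long left-arm terminal event: proximal boundary is the right edge
  bp4 <- breakpoint_position(mkev(1L, 100000L, tl = TRUE),
                             centromeres = c(chr1 = 150000L))
  expect_equal(bp4$breakpoint, 90000L)
  # missing centromere metadata for a long terminal event errors
  expect_error(breakpoint_position(mkev(300000L, 500000L, tr = TRUE)),
               "centromere")
})

test_that("homolog bias uses the exact binomial test", {
  ev <- data.frame(homolog = c(rep("P1", 2479), rep("P2", 3763 - 2479)),
                   type = "interstitial")
  hb <- homolog_bias(ev)
  expect_equal(round(100 * hb$frac_p1[hb$group == "all"], 1), 65.9)

  hb2 <- homolog_bias(data.frame(homolog = rep(c("P1", "P2"), 50),
                                 type = "interstitial"))
  expect_equal(hb2$frac_p1[1], 0.5)
  expect_equal(hb2$p_value[1], 1)

  # 9 of 10 matches brute-force pmf summation
  hb3 <- homolog_bias(data.frame(homolog = c(rep("P1", 9), "P2"),
                                 type = "interstitial"))
  pm <- dbinom(0:10, 10, 0.5)
  expect_equal(hb3$p_value[1], sum(pm[pm <= pm[10] + 1e-12]))
  expect_equal(hb3$p_value[1], binom.test(9, 10)$p.value)
})

test_that("window tiling partitions chromosomes under the end rules", {
  w <- tile_windows(c(c1 = 1000000L))
  expect_equal(nrow(w), 20L)
  expect_true(all(w$end - w$start == 50000L))

  # L = 230 kb: K = 4, r = 15 <= 25 -> merged ends: 65, 50, 50, 65
  w2 <- tile_windows(c(c1 = 230000L))
  expect_equal(w2$end - w2$start, c(65000L, 50000L, 50000L, 65000L))

  # L = 160 kb: K = 3, r = 5 <= 25 -> 55, 50, 55
  w3 <- tile_windows(c(c1 = 160000L))
  expect_equal(w3$end - w3$start, c(55000L, 50000L, 55000L))

  # r > 25 kb: separate end windows
  w4 <- tile_windows(c(c1 = 255000L))  # K = 5, r = 2.5 -> merged
  expect_equal(sum(w4$end - w4$start), 255000L)
  w5 <- tile_windows(c(c1 = 452000L))  # K = 9, r = 1 kb -> merged
  expect_equal(sum(w5$end - w5$start), 452000L)
  w6 <- tile_windows(c(c1 = 160000L), window_bp = 50000L, end_merge_bp = 2000L)
  expect_equal(w6$end - w6$start, c(5000L, 50000L, 50000L, 50000L, 5000L))

  # partition property across random lengths
  set.seed(9)
  for (L in sample(30000:2000000, 25)) {
    w <- tile_windows(c(x = L))
    expect_equal(sum(w$end - w$start), L)
    expect_equal(w$start[-1], w$end[-nrow(w)])  # contiguous, no overlap
  }
})

test_that("HCHB scan flags only strongly biased windows under BH control", {
  set.seed(13)
  wins <- tile_windows(c(c1 = 1000000L, c2 = 1000000L))
  # balanced events everywhere: no flags
  n_ev <- 20L
  ev_bal <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i) {
    data.frame(chrom = wins$chrom[i],
               breakpoint = as.integer(seq(wins$start[i], wins$end[i] - 1L,
                                           length.out = n_ev)),
               homolog = rep(c("P1", "P2"), n_ev / 2))
  }))
  scan <- hchb_scan(ev_bal, wins)
  expect_false(any(scan$hchb))
  expect_equal(sum(scan$n_p1 + scan$n_p2), nrow(ev_bal))  # conservation

  # one 40/0 window among balanced 10/10 windows survives BH
  ev_bias <- rbind(ev_bal,
                   data.frame(chrom = "c1",
                              breakpoint = as.integer(seq(wins$start[1],
                                                          wins$end[1] - 1L,
                                                          length.out = 40)),
                              homolog = "P1"))
  scan2 <- hchb_scan(ev_bias, wins)
  expect_true(scan2$hchb[1])
  expect_equal(sum(scan2$hchb), 1L)
  # BH oracle: adjusted p recomputed independently
  m <- nrow(scan2)
  o <- order(scan2$p_value)
  padj <- numeric(m)
  padj[o] <- rev(cummin(rev(scan2$p_value[o] * m / seq_len(m))))
  expect_equal(scan2$q_value, pmin(1, padj))

  # empty windows take p = 1 and are never flagged
  scan3 <- hchb_scan(ev_bal[0, ], wins)
  expect_true(all(scan3$p_value == 1))
  expect_false(any(scan3$hchb))
})

test_that("event detection agrees with the exhaustive-scan oracle", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(3:25, 1)
    pos <- sort(sample.int(80000L, n))
    gt <- sample(c(0L, 1L, 2L, NA), n, TRUE,
                 prob = c(0.25, 0.4, 0.25, 0.1))
    chrom_len <- 100000L
    tr <- find_tracts(gt, pos, "c1", chrom_len)
    ev <- suppressWarnings(
      classify_events(merge_into_events(tr, gap_bp = 10000L),
                      c(c1 = chrom_len)))
    orc <- suppressWarnings(oracle_events(gt, pos, chrom_len, 10000L))
    if (is.null(orc)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(nrow(ev), length(orc))
      data.table::setorder(ev, start)
      for (k in seq_along(orc)) {
        expect_equal(ev$start[k], orc[[k]]$start)
        expect_equal(ev$end[k], orc[[k]]$end)
        expect_equal(ev$homolog[k], orc[[k]]$homolog)
        expect_equal(ev$n_markers[k], orc[[k]]$n_markers)
        expect_equal(ev$type[k], orc[[k]]$type)
      }
    }
  }
})
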