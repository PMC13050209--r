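#' Find LOH tracts in one clone's genotype vector
#'
#' A tract is a maximal run of adjacent markers homozygous for the same
#' homolog; runs of length 1 count. Adjacency is over non-missing markers
#' only, so missing calls are transparent and do not break a run. Internal
#' tract boundaries are the midpoint (floored) between the outermost
#' converted marker and the adjacent unconverted marker; a tract containing
#' the marker closest to a chromosome end extends to that end.
#'
#' @param gt integer genotype vector over the chromosome's final markers
#'   (0/1/2/NA), in marker order
#' @param pos marker positions (bp), same length
#' @param chrom chromosome name
#' @param chrom_length chromosome length (bp)
#' @param clone clone identifier carried through to the output
#' @return data.table of tracts: `clone`, `chrom`, `start`, `end` (1-based
#'   inclusive), `homolog` ("P1"/"P2"), `n_markers`, `first_marker`,
#'   `last_marker`, `term_left`, `term_right`
#' @export
find_tracts <- function(gt, pos, chrom, chrom_length, clone = "clone1") {
  keep <- !is.na(gt)
  g <- gt[keep]; p <- pos[keep]
  empty <- data.table::data.table(
    clone = character(), chrom = character(), start = integer(),
    end = integer(), homolog = character(), n_markers = integer(),
    first_marker = integer(), last_marker = integer(),
    term_left = logical(), term_right = logical())
  if (!length(g)) return(empty)
  hom <- g %in% c(0L, 2L)
  r <- rle(ifelse(hom, g, -1L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  conv <- which(r$values %in% c(0L, 2L))
  if (!length(conv)) return(empty)
  out <- vector("list", length(conv))
  for (k in seq_along(conv)) {
    i <- conv[k]
    i0 <- starts[i]; i1 <- ends[i]
    term_left <- i0 == 1L
    term_right <- i1 == length(g)
    start <- if (term_left) 1L else (p[i0 - 1L] + p[i0]) %/% 2L
    end <- if (term_right) as.integer(chrom_length) else (p[i1] + p[i1 + 1L]) %/% 2L
    out[[k]] <- data.table::data.table(
      clone = clone, chrom = chrom, start = start, end = end,
      homolog = if (r$values[i] == 0L) "P1" else "P2",
      n_markers = i1 - i0 + 1L,
      first_marker = p[i0], last_marker = p[i1],
      term_left = term_left, term_right = term_right)
  }
  data.table::rbindlist(out)
}

#' Merge LOH tracts into events
#'
#' Tracts whose facing boundaries are separated by less than `gap_bp` are
#' merged transitively into a single event, including tracts converted to
#' different homologs (complex repair outcomes). The event homolog is the
#' one with the greatest total conversion length among member tracts; ties
#' resolve to P1 with a warning.
#'
#' @param tracts a [find_tracts()] table (possibly several clones and
#'   chromosomes)
#' @param gap_bp merge distance (default 10000)
#' @return data.table of events: `clone`, `chrom`, `start`, `end`,
#'   `homolog`, `n_markers`, `n_tracts`, `term_left`, `term_right`
#' @export
merge_into_events <- function(tracts, gap_bp = 10000L) {
  tr <- data.table::as.data.table(tracts)
  if (!nrow(tr)) {
    return(data.table::data.table(
      clone = character(), chrom = character(), start = integer(),
      end = integer(), homolog = character(), n_markers = integer(),
      n_tracts = integer(), term_left = logical(), term_right = logical()))
  }
  data.table::setorder(tr, clone, chrom, start)
  grp <- integer(nrow(tr)); gid <- 0L
  for (i in seq_len(nrow(tr))) {
    if (i == 1L || tr$clone[i] != tr$clone[i - 1L] ||
        tr$chrom[i] != tr$chrom[i - 1L] ||
        tr$start[i] - tr$end[i - 1L] >= gap_bp) {
      gid <- gid + 1L
    }
    grp[i] <- gid
  }
  tr$grp <- grp
  ev <- tr[, {
    len_by_hom <- tapply((end - start + 1), homolog, sum)
    best <- names(len_by_hom)[len_by_hom == max(len_by_hom)]
    if (length(best) > 1L) {
      warning("homolog tie in merged event; resolving to P1", call. = FALSE)
      best <- "P1"
    }
    list(start = min(start), end = max(end), homolog = best,
         n_markers = sum(n_markers), n_tracts = .N,
         term_left = any(term_left), term_right = any(term_right))
  }, by = list(clone, chrom, grp)]
  ev$grp <- NULL
  ev[]
}

#' Classify events as interstitial or terminal
#'
#' An event is terminal when one of its boundaries is a chromosome end;
#' events spanning the centromere with both ends internal stay interstitial.
#' Whole-chromosome events (both ends terminal) are flagged.
#'
#' @param events a [merge_into_events()] table
#' @param chrom_lengths named vector of chromosome lengths
#' @return the events table with `type` ("interstitial"/"terminal") and
#'   `whole_chrom` columns
#' @export
classify_events <- function(events, chrom_lengths) {
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) {
    ev$type <- character(); ev$whole_chrom <- logical()
    return(ev[])
  }
  tl <- ev$term_left | ev$start <= 1L
  tr <- ev$term_right | ev$end >= chrom_lengths[ev$chrom]
  ev$type <- ifelse(tl | tr, "terminal", "interstitial")
  ev$whole_chrom <- tl & tr
  ev[]
}

#' Breakpoint position of each event
#'
#' The inferred DNA-break position: the interval midpoint for interstitial
#' events and for terminal events shorter than `tloh_len_bp`; for longer
#' terminal events, the position 10 kb inside the event from its
#' centromere-proximal boundary. Whole-chromosome events fall back to the
#' midpoint.
#'
#' @param events a classified events table (see [classify_events()])
#' @param centromeres named vector of centromere positions; required when
#'   long terminal events are present
#' @param tloh_len_bp length threshold for the terminal rule (default 20000)
#' @param offset_bp distance from the proximal boundary (default 10000)
#' @return the events table with a `breakpoint` column (bp)
#' @export
breakpoint_position <- function(events, centromeres = NULL,
                                tloh_len_bp = 20000L, offset_bp = 10000L) {
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) { ev$breakpoint <- integer(); return(ev[]) }
  len <- ev$end - ev$start + 1
  mid <- (ev$start + ev$end) %/% 2L
  bp <- mid
  long_t <- ev$type == "terminal" & len > tloh_len_bp & !ev$whole_chrom
  if (any(long_t)) {
    assert_that(!is.null(centromeres),
                "centromere positions required for long terminal events")
    assert_that(all(ev$chrom[long_t] %in% names(centromeres)),
                "missing centromere metadata for a chromosome with long terminal events")
    # right-arm events reach the right end: proximal boundary is the start
    right <- long_t & ev$term_right & !ev$term_left
    left <- long_t & ev$term_left & !ev$term_right
    bp[right] <- ev$start[right] + offset_bp
    bp[left] <- ev$end[left] - offset_bp
  }
  ev$breakpoint <- as.integer(bp)
  ev[]
}

exact_binom_p <- function(k, n, p = 0.5) {
  # two-sided exact binomial p-value; for p = 0.5 this is the symmetric
  # tail sum and matches stats::binom.test
  if (n == 0L) return(1)
  m <- min(k, n - k)
  min(1, stats::pbinom(m, n, p) +
        stats::pbinom(n - m - 1L, n, p, lower.tail = FALSE))
}

#' Homolog bias of LOH events
#'
#' Fraction of events converting toward each parental homolog, with a
#' two-sided exact binomial test against 0.5, overall and within groups.
#'
#' @param events classified events table
#' @param by optional grouping column names (e.g. `"type"`); `NULL` for the
#'   overall summary only
#' @return data.table with `n_p1`, `n_p2`, `frac_p1`, `p_value` per group;
#'   groups with zero events report `NA` fractions and p-values
#' @export
homolog_bias <- function(events, by = "type") {
  ev <- data.table::as.data.table(events)
  summarize <- function(d) {
    n1 <- sum(d$homolog == "P1"); n2 <- sum(d$homolog == "P2")
    n <- n1 + n2
    list(n_p1 = n1, n_p2 = n2,
         frac_p1 = if (n) n1 / n else NA_real_,
         p_value = if (n) exact_binom_p(n1, n) else NA_real_)
  }
  overall <- data.table::as.data.table(c(list(group = "all"), summarize(ev)))
  if (is.null(by) || !nrow(ev)) return(overall)
  per <- ev[, summarize(.SD), by = by]
  data.table::setnames(per, by[1L], "group")
  rbind(overall, per, fill = TRUE)
}

#' Tile chromosomes into windows for local-rate and bias scans
#'
#' Core windows of `window_bp` are centered so a remainder `r = (L - K l)/2`
#' is left at each end. A remainder above `end_merge_bp` becomes its own
#' shorter end window; otherwise it is merged into the terminal core
#' windows. Windows partition each chromosome exactly. Chromosomes shorter
#' than one window form a single window.
#'
#' @param chrom_lengths named vector of chromosome lengths
#' @param window_bp core window size (default 50000)
#' @param end_merge_bp remainder threshold (default 25000)
#' @return data.table of half-open windows: `chrom`, `start`, `end`
#' @export
tile_windows <- function(chrom_lengths, window_bp = 50000L,
                         end_merge_bp = 25000L) {
  out <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    L <- as.numeric(chrom_lengths[i])
    l <- as.numeric(window_bp)
    if (L < l) {
      b <- c(0, L)
    } else {
      K <- floor(L / l)
      r <- (L - K * l) / 2
      if (r == 0) {
        b <- seq(0, L, by = l)
      } else if (r > end_merge_bp) {
        b <- c(0, r + l * (0:K), L)
      } else {
        # merge remainders into the terminal core windows
        if (K == 1L) b <- c(0, L)
        else b <- c(0, r + l * (1:(K - 1)), L)
      }
    }
    b <- round(b)
    out[[i]] <- data.table::data.table(
      chrom = names(chrom_lengths)[i],
      start = as.integer(b[-length(b)]) + 1L,
      end = as.integer(b[-1L]) + 1L)
  }
  data.table::rbindlist(out)
}

#' Scan windows for high-conversion high-bias (HCHB) signatures
#'
#' Event breakpoints are assigned to windows; per window, the homolog split
#' of breakpoints is tested against an unbiased binomial (p = 0.5,
#' two-sided exact test), and Benjamini-Hochberg correction is applied
#' across all genome windows. Windows with adjusted p at or below `fdr` and
#' at least one event are flagged HCHB. Empty windows take p = 1.
#'
#' @param events events table with `chrom`, `breakpoint`, `homolog`
#' @param windows a [tile_windows()] table
#' @param fdr flagging threshold on the BH-adjusted p (default 0.05)
#' @return the windows table with `n_p1`, `n_p2`, `p_value`, `q_value`,
#'   `hchb`
#' @export
hchb_scan <- function(events, windows, fdr = 0.05) {
  w <- data.table::copy(data.table::as.data.table(windows))
  ev <- data.table::as.data.table(events)
  w$n_p1 <- 0L; w$n_p2 <- 0L
  if (nrow(ev)) {
    for (ch in unique(w$chrom)) {
      wi <- which(w$chrom == ch)
      ei <- ev[ev$chrom == ch & !is.na(ev$breakpoint)]
      if (!nrow(ei)) next
      bin <- findInterval(ei$breakpoint, w$start[wi])
      ok <- bin >= 1L & bin <= length(wi)
      t1 <- tabulate(bin[ok & ei$homolog == "P1"], nbins = length(wi))
      t2 <- tabulate(bin[ok & ei$homolog == "P2"], nbins = length(wi))
      w$n_p1[wi] <- t1; w$n_p2[wi] <- t2
    }
  }
  n <- w$n_p1 + w$n_p2
  w$p_value <- mapply(exact_binom_p, w$n_p1, n)
  w$q_value <- stats::p.adjust(w$p_value, method = "BH")
  w$hchb <- w$q_value <= fdr & n > 0L
  w[]
}
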