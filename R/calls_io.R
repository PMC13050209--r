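#' Per-site genotype call tables
#'
#' A call set is a `data.table` with one row per biallelic SNV site and
#' sample, holding the genotype in *parental-allele space* together with the
#' quality annotations used by the site filters. Columns:
#'
#' * `sample` - clone identifier
#' * `chrom`, `pos` - 1-based site coordinate
#' * `a1`, `a2` - the parent-1 and parent-2 alleles (single bases)
#' * `gt` - integer genotype state: 0 = homozygous parent-1, 1 = heterozygous,
#'   2 = homozygous parent-2, `NA` = missing
#' * `gq` - genotype quality, the log10 likelihood ratio between the most and
#'   second most likely genotypes (missing GQ is treated as 0, i.e. it fails
#'   every GQ threshold)
#' * `qual` - site QUAL score
#' * `dp`, `ad1`, `ad2` - total depth and reads supporting each parental allele
#' * `qd`, `mq`, `fs`, `sor` - site annotations used by the hard filters
#'
#' @param df data.frame-like object with the columns above
#' @return a `data.table` of class `loh_calls`
#' @export
loh_calls <- function(df) {
  dt <- data.table::as.data.table(df)
  need <- c("sample", "chrom", "pos", "a1", "a2", "gt", "gq", "qual",
            "dp", "ad1", "ad2", "qd", "mq", "fs", "sor")
  missing_cols <- setdiff(need, names(dt))
  assert_that(length(missing_cols) == 0L,
              paste("call table lacks columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(all(dt$pos >= 1L, na.rm = TRUE), "positions must be >= 1")
  assert_that(all(dt$gt %in% c(0L, 1L, 2L) | is.na(dt$gt)),
              "gt must be 0, 1, 2 or NA")
  data.table::setattr(dt, "class", c("loh_calls", class(dt)))
  dt[]
}

#' Genome metadata: chromosome lengths, centromeres and masked intervals
#'
#' Masks (repeats, telomeric ends) are stored as 1-based half-open
#' `[start, end)` intervals on the common coordinate system.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param centromeres named integer vector of centromere positions (bp);
#'   may be `NULL` if no terminal-event breakpoints will be computed
#' @param masks data.frame with columns `chrom`, `start`, `end` (half-open);
#'   `NULL` for no mask
#' @return list of class `genome_meta`
#' @export
genome_meta <- function(chrom_lengths, centromeres = NULL, masks = NULL) {
  assert_that(!is.null(names(chrom_lengths)) && all(nzchar(names(chrom_lengths))),
              "chrom_lengths must be named")
  if (!is.null(masks)) {
    masks <- data.table::as.data.table(masks)
    assert_that(all(c("chrom", "start", "end") %in% names(masks)),
                "masks need chrom/start/end columns")
    assert_that(all(masks$chrom %in% names(chrom_lengths)),
                "mask chromosome not in chrom_lengths")
    bad <- masks$start < 1 | masks$end > chrom_lengths[masks$chrom] + 1L
    assert_that(!any(bad), "mask intervals outside chromosome bounds")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 centromeres = centromeres,
                 masks = masks),
            class = "genome_meta")
}

#' Telomere mask: fixed flanks at both ends of every chromosome
#'
#' Short-read genotyping near chromosome ends is unreliable, so sites within
#' a fixed distance (default 7.5 kb) of either end are masked.
#'
#' @param chrom_lengths named integer vector
#' @param flank_bp mask width at each end (default 7500)
#' @return data.table of half-open mask intervals
#' @export
telomere_mask <- function(chrom_lengths, flank_bp = 7500L) {
  dt <- data.table::data.table(chrom = rep(names(chrom_lengths), 2L),
                               start = c(rep(1L, length(chrom_lengths)),
                                         pmax(1L, as.integer(chrom_lengths) - as.integer(flank_bp) + 1L)),
                               end = c(pmin(as.integer(chrom_lengths) + 1L, 1L + as.integer(flank_bp)),
                                       as.integer(chrom_lengths) + 1L))
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Read one sample's call set from a VCF file
#'
#' Parses a VCF (v4.x) with per-sample GT, GQ, DP, AD and site-level QD, MQ,
#' FS, SOR INFO annotations. Only biallelic SNVs are kept; indels and
#' multiallelic records are dropped and counted. Records lacking a required
#' annotation are dropped and counted as well.
#'
#' @param path VCF file path (plain text or bgzipped)
#' @param sample sample name to extract (default: first sample)
#' @param ref_parent which parent the reference genome of this VCF
#'   represents, `"P1"` or `"P2"`; genotypes are re-expressed in
#'   parental-allele space accordingly
#' @return list with `calls` (an [loh_calls] table) and `dropped`
#'   (named counts of dropped records)
#' @export
read_call_set <- function(path, sample = NULL, ref_parent = c("P1", "P2")) {
  ref_parent <- match.arg(ref_parent)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(sample)) sample <- colnames(vcf)[1L]
  assert_that(sample %in% colnames(vcf),
              paste0("sample '", sample, "' not present in VCF"))
  vcf <- vcf[, sample]

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- vapply(as.list(altl[n_alt >= 1L]),
                              function(x) as.character(x)[1L], character(1))

  multiallelic <- n_alt > 1L
  is_snv <- !multiallelic & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")

  info <- VariantAnnotation::info(vcf)
  get_info <- function(nm) {
    if (nm %in% names(info)) as.numeric(info[[nm]]) else rep(NA_real_, length(ref))
  }
  qd <- get_info("QD"); mq <- get_info("MQ"); fs <- get_info("FS"); sor <- get_info("SOR")

  g <- VariantAnnotation::geno(vcf)
  assert_that(all(c("GT", "GQ", "DP", "AD") %in% names(g)),
              "VCF lacks one of the required FORMAT fields GT/GQ/DP/AD")
  gt_raw <- as.character(g$GT[, 1L])
  gq <- suppressWarnings(as.numeric(g$GQ[, 1L]))
  dp <- suppressWarnings(as.integer(g$DP[, 1L]))
  ad <- g$AD[, 1L]
  ad_ref <- vapply(ad, function(x) if (length(x) >= 1L) as.integer(x[1L]) else NA_integer_, integer(1))
  ad_alt <- vapply(ad, function(x) if (length(x) >= 2L) as.integer(x[2L]) else NA_integer_, integer(1))

  no_annot <- is.na(dp) | is.na(ad_ref) | is.na(ad_alt)
  keep <- is_snv & !no_annot
  dropped <- c(indel_or_nonSNV = sum(!multiallelic & !is_snv),
               multiallelic = sum(multiallelic),
               missing_annotation = sum(is_snv & no_annot))

  # genotype in REF/ALT space -> parental space
  gt_ra <- rep(NA_integer_, length(gt_raw))
  gt_ra[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt_ra[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt_ra[gt_raw %in% c("1/1", "1|1")] <- 2L

  if (ref_parent == "P1") {
    a1 <- ref; a2 <- alt1; gt <- gt_ra
    adp1 <- ad_ref; adp2 <- ad_alt
  } else {
    a1 <- alt1; a2 <- ref
    gt <- ifelse(is.na(gt_ra), NA_integer_, 2L - gt_ra)
    adp1 <- ad_alt; adp2 <- ad_ref
  }

  calls <- data.table::data.table(
    sample = sample,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    a1 = a1, a2 = a2, gt = gt,
    gq = ifelse(is.na(gq), 0, gq),
    qual = as.numeric(rr$QUAL),
    dp = dp, ad1 = adp1, ad2 = adp2,
    qd = qd, mq = mq, fs = fs, sor = sor)[keep]
  list(calls = loh_calls(calls), dropped = dropped)
}

#' Write a call set to a single-sample VCF file
#'
#' Emits the VCF dialect that [read_call_set()] reads back: biallelic SNVs
#' with GT:GQ:DP:AD genotypes and QD/MQ/FS/SOR INFO annotations. REF is the
#' allele of `ref_parent`.
#'
#' @param calls an [loh_calls] table for one sample
#' @param path output file
#' @param ref_parent `"P1"` or `"P2"`; orientation of the REF column
#' @param chrom_lengths optional named vector for contig header lines
#' @export
write_call_set <- function(calls, path, ref_parent = c("P1", "P2"),
                           chrom_lengths = NULL) {
  ref_parent <- match.arg(ref_parent)
  smp <- unique(calls$sample)
  assert_that(length(smp) == 1L, "write_call_set expects a single sample")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lohsym",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant quality by depth">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="FisherStrand">',
           '##INFO=<ID=SOR,Number=1,Type=Float,Description="StrandOddsRatio">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", smp))

  if (ref_parent == "P1") {
    refa <- calls$a1; alta <- calls$a2; gt_ra <- calls$gt
    adr <- calls$ad1; ada <- calls$ad2
  } else {
    refa <- calls$a2; alta <- calls$a1
    gt_ra <- ifelse(is.na(calls$gt), NA_integer_, 2L - calls$gt)
    adr <- calls$ad2; ada <- calls$ad1
  }
  gt_str <- c("0/0", "0/1", "1/1")[gt_ra + 1L]
  gt_str[is.na(gt_str)] <- "./."
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 8))
  info <- sprintf("QD=%s;MQ=%s;FS=%s;SOR=%s",
                  fmt_num(calls$qd), fmt_num(calls$mq),
                  fmt_num(calls$fs), fmt_num(calls$sor))
  smpf <- sprintf("%s:%d:%d:%d,%d", gt_str, as.integer(round(calls$gq)),
                  calls$dp, adr, ada)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s\tGT:GQ:DP:AD\t%s",
                  calls$chrom, calls$pos, refa, alta, fmt_num(calls$qual),
                  info, smpf)
  ord <- order(calls$chrom, calls$pos)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Hard site-level quality filters
#'
#' Removes calls failing any of the hard filters used for variant curation:
#' QD < 2, MQ < 20, FS > 60, SOR > 10; depth below 6 reads or above 5x the
#' sample median depth; site QUAL < 1000; and position inside a masked
#' interval (repeats and telomeric flanks). Filters are conjunctive
#' predicates, so their order does not affect the surviving set; the report
#' tallies, for each filter, how many input calls fail it.
#'
#' @param calls an [loh_calls] table
#' @param sample_median_depth per-sample median depth over genotyped sites
#' @param meta a [genome_meta] with the masks to apply (may be `NULL`)
#' @param qual_min minimum site QUAL (default 1000)
#' @param depth_min minimum supporting reads (default 6)
#' @param depth_cap_mult maximum depth as a multiple of the median (default 5)
#' @param qd_min,mq_min,fs_max,sor_max annotation thresholds
#' @return list with `calls` (surviving rows) and `report`
#'   (data.table of `filter`, `n_removed`)
#' @export
apply_site_filters <- function(calls, sample_median_depth, meta = NULL,
                               qual_min = 1000, depth_min = 6,
                               depth_cap_mult = 5, qd_min = 2, mq_min = 20,
                               fs_max = 60, sor_max = 10) {
  assert_that(is.numeric(sample_median_depth) && sample_median_depth > 0,
              "sample_median_depth must be positive")
  fail <- list(
    QD = !is.na(calls$qd) & calls$qd < qd_min,
    MQ = !is.na(calls$mq) & calls$mq < mq_min,
    FS = !is.na(calls$fs) & calls$fs > fs_max,
    SOR = !is.na(calls$sor) & calls$sor > sor_max,
    depth_low = is.na(calls$dp) | calls$dp < depth_min,
    depth_high = !is.na(calls$dp) & calls$dp > depth_cap_mult * sample_median_depth,
    QUAL = is.na(calls$qual) | calls$qual < qual_min)

  masked <- rep(FALSE, nrow(calls))
  if (!is.null(meta) && !is.null(meta$masks) && nrow(meta$masks) > 0L) {
    m <- meta$masks
    for (ch in unique(m$chrom)) {
      idx <- which(calls$chrom == ch)
      if (!length(idx)) next
      ir <- mask_to_iranges(m[m$chrom == ch, ])
      hit <- IRanges::overlapsAny(IRanges::IRanges(calls$pos[idx], calls$pos[idx]), ir)
      masked[idx] <- hit
    }
  }
  fail$masked <- masked
  any_fail <- Reduce(`|`, fail)
  report <- data.table::data.table(filter = names(fail),
                                   n_removed = vapply(fail, sum, integer(1)))
  list(calls = calls[!any_fail], report = report)
}

#' Effective genome length after masking
#'
#' Subtracts the merged masked footprint from the genome length. Overlapping
#' mask intervals are merged first and never double-counted.
#'
#' @param genome_length total genome length (bp)
#' @param mask data.frame of half-open intervals (`start`, `end`, optional
#'   `chrom`); `NULL` or empty for no mask
#' @return effective length in bp
#' @export
effective_genome_length <- function(genome_length, mask = NULL) {
  genome_length - merged_mask_bp(mask)
}

#' Read a UCSC chain file
#'
#' @param path chain file path
#' @return an `rtracklayer::Chain` object usable with [lift_positions()]
#' @export
read_chain <- function(path) rtracklayer::import.chain(path)

#' Write a chain file from alignment blocks
#'
#' Blocks map source (the coordinate system of the per-parent call sets) to
#' target (the common coordinate system). Each chromosome's blocks must be
#' non-overlapping and sorted in both systems.
#'
#' @param blocks data.frame with columns `chrom`, `src_start`, `src_end`
#'   (1-based half-open on the source), `tgt_start` (1-based start on the
#'   target; block widths are equal by construction), and `src_len`,
#'   `tgt_len` chromosome lengths
#' @param path output chain file
#' @export
write_chain <- function(blocks, path) {
  blocks <- data.table::as.data.table(blocks)
  out <- character(0)
  id <- 0L
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    data.table::setorder(b, src_start)
    id <- id + 1L
    # chain header: score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
    # rtracklayer lifts from tName space to qName space, so t = source, q = target
    out <- c(out, sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
                          ch, b$src_len[1L], b$src_start[1L] - 1L,
                          b$src_end[nrow(b)] - 1L,
                          ch, b$tgt_len[1L], b$tgt_start[1L] - 1L,
                          b$tgt_start[nrow(b)] - 1L +
                            (b$src_end[nrow(b)] - b$src_start[nrow(b)]),
                          id))
    w <- b$src_end - b$src_start
    n <- nrow(b)
    if (n == 1L) {
      out <- c(out, sprintf("%d", w[1L]), "")
    } else {
      dt_gap <- b$src_start[-1L] - b$src_end[-n]
      dq_gap <- b$tgt_start[-1L] - (b$tgt_start[-n] + w[-n])
      out <- c(out,
               sprintf("%d\t%d\t%d", w[-n], dt_gap, dq_gap),
               sprintf("%d", w[n]), "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Lift positions through a chain map
#'
#' Positions falling inside alignment blocks are translated to the target
#' coordinate system; positions in gaps (deleted or unaligned in the target)
#' are flagged unmapped rather than raising an error.
#'
#' @param chain an `rtracklayer::Chain` object (see [read_chain()]) or a path
#' @param chrom,pos vectors of source coordinates (1-based)
#' @return data.table with `chrom`, `pos`, `new_pos`, `mapped`
#' @export
lift_positions <- function(chain, chrom, pos) {
  if (is.character(chain)) chain <- read_chain(chain)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  res <- rtracklayer::liftOver(gr, chain)
  n_hit <- S4Vectors::elementNROWS(res)
  new_pos <- rep(NA_integer_, length(pos))
  hit <- n_hit == 1L
  if (any(hit)) new_pos[hit] <- GenomicRanges::start(unlist(res[hit]))
  data.table::data.table(chrom = as.character(chrom), pos = as.integer(pos),
                         new_pos = new_pos, mapped = hit)
}
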