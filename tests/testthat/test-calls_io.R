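make_vcf <- function(path, rows) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=1000000>",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=SOR,Number=1,Type=Float,Description="x">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="x">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="x">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  writeLines(c(hdr, rows), path)
  path
}

std_row <- function(pos, ref = "A", alt = "T", qual = 2000,
                    info = "QD=25;MQ=60;FS=2;SOR=1",
                    smp = "0/1:80:40:20,20") {
  sprintf("chr1\t%d\t.\t%s\t%s\t%s\t.\t%s\tGT:GQ:DP:AD\t%s",
          pos, ref, alt, qual, info, smp)
}

test_that("read_call_set keeps biallelic SNVs and drops indels and multiallelics", {
  rows <- c(vapply(1:8, function(i) std_row(i * 100L), character(1)),
            std_row(900L, ref = "AT", alt = "A"),       # indel
            std_row(950L, ref = "A", alt = "AGG"))      # indel
  path <- make_vcf(tempfile(fileext = ".vcf"), rows)
  r <- read_call_set(path)
  expect_equal(nrow(r$calls), 8L)
  expect_equal(unname(r$dropped["indel_or_nonSNV"]), 2L)

  # a record with multiple ALT alleles is dropped
  rows2 <- c(std_row(100L),
             sprintf("chr1\t200\t.\tA\tT,G\t2000\t.\tQD=25;MQ=60;FS=2;SOR=1\tGT:GQ:DP:AD\t1/2:50:30:0,15,15"))
  path2 <- make_vcf(tempfile(fileext = ".vcf"), rows2)
  r2 <- read_call_set(path2)
  expect_equal(nrow(r2$calls), 1L)
  expect_equal(unname(r2$dropped["multiallelic"]), 1L)
})

test_that("VCF round trip preserves genotype, gq and allele depths", {
  calls <- loh_calls(data.frame(
    sample = "s1", chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    a1 = c("A", "C", "G", "T"), a2 = c("T", "G", "A", "C"),
    gt = c(0L, 1L, 2L, NA), gq = c(80, 55, 93, 0), qual = 2000,
    dp = c(30L, 40L, 25L, 10L), ad1 = c(30L, 19L, 0L, 5L),
    ad2 = c(0L, 21L, 25L, 5L), qd = 25, mq = 60, fs = 2, sor = 1))
  path <- tempfile(fileext = ".vcf")
  write_call_set(calls, path, chrom_lengths = c(chr1 = 1000000L))
  back <- read_call_set(path)$calls
  expect_equal(back$gt, calls$gt)
  expect_equal(back$gq, calls$gq)
  expect_equal(back$ad1, calls$ad1)
  expect_equal(back$ad2, calls$ad2)

  # reading against the other reference flips the genotype orientation
  flipped <- read_call_set(path, ref_parent = "P2")$calls
  expect_equal(flipped$gt, c(2L, 1L, 0L, NA))
  expect_equal(flipped$a1, calls$a2)
})

test_that("site filters remove calls per rule and tally reasons", {
  base <- data.frame(
    sample = "s1", chrom = "chr1",
    pos = c(50000L, 50100L, 50200L, 50300L, 3000L),
    a1 = "A", a2 = "T", gt = 1L, gq = 80, qual = 2000,
    dp = c(30L, 30L, 5L, 400L, 30L), ad1 = 15L, ad2 = 15L,
    qd = c(25, 1.5, 25, 25, 25), mq = 60, fs = 2, sor = 1)
  meta <- genome_meta(c(chr1 = 1000000L),
                      masks = telomere_mask(c(chr1 = 1000000L)))
  res <- apply_site_filters(loh_calls(base), sample_median_depth = 30,
                            meta = meta)
  expect_equal(nrow(res$calls), 1L)
  rep <- res$report
  expect_equal(rep$n_removed[rep$filter == "QD"], 1L)
  expect_equal(rep$n_removed[rep$filter == "depth_low"], 1L)
  expect_equal(rep$n_removed[rep$filter == "depth_high"], 1L)
  expect_equal(rep$n_removed[rep$filter == "masked"], 1L)  # pos 3000 < 7.5 kb
  expect_error(apply_site_filters(loh_calls(base), sample_median_depth = 0),
               "positive")
})

test_that("filters are conjunctive: applying them twice changes nothing", {
  set.seed(11)
  n <- 200L
  calls <- loh_calls(data.frame(
    sample = "s1", chrom = "chr1", pos = sort(sample(10000:990000, n)),
    a1 = "A", a2 = "T", gt = 1L, gq = 80,
    qual = sample(c(500, 2000), n, TRUE),
    dp = sample(c(4L, 30L, 200L), n, TRUE), ad1 = 10L, ad2 = 10L,
    qd = sample(c(1, 25), n, TRUE), mq = sample(c(10, 60), n, TRUE),
    fs = sample(c(2, 80), n, TRUE), sor = sample(c(1, 12), n, TRUE)))
  once <- apply_site_filters(calls, 30)$calls
  twice <- apply_site_filters(once, 30)$calls
  expect_equal(once, twice)
})

test_that("effective genome length merges masks and reproduces the published value", {
  expect_equal(effective_genome_length(12071326,
                                       data.frame(chrom = "g", start = 1,
                                                  end = 1774810)),
               10296517)
  expect_equal(effective_genome_length(5000, NULL), 5000)
  expect_equal(effective_genome_length(5000,
                                       data.frame(chrom = "c", start = 1,
                                                  end = 5001)), 0)
  # overlapping intervals are merged, not double-counted
  m <- data.frame(chrom = "c", start = c(100, 150), end = c(200, 250))
  expect_equal(effective_genome_length(1000, m), 1000 - 150)
  # monotonicity: adding mask never increases the effective length
  m2 <- rbind(m, data.frame(chrom = "c", start = 400, end = 500))
  expect_lte(effective_genome_length(1000, m2),
             effective_genome_length(1000, m))
})

test_that("lift_positions maps through chains and flags gaps", {
  # identity chain
  bl <- data.frame(chrom = "chr1", src_start = 1L, src_end = 1001L,
                   tgt_start = 1L, src_len = 1000L, tgt_len = 1000L)
  p <- tempfile(fileext = ".chain"); write_chain(bl, p)
  res <- lift_positions(p, rep("chr1", 3), c(1L, 500L, 1000L))
  expect_equal(res$new_pos, c(1L, 500L, 1000L))
  expect_true(all(res$mapped))

  # 10-bp insertion after source position 500: later positions shift +10
  bl2 <- data.frame(chrom = "chr1", src_start = c(1L, 501L),
                    src_end = c(501L, 1001L), tgt_start = c(1L, 511L),
                    src_len = 1000L, tgt_len = 1010L)
  p2 <- tempfile(fileext = ".chain"); write_chain(bl2, p2)
  pos <- c(10L, 499L, 500L, 501L, 750L, 1000L)
  res2 <- lift_positions(p2, rep("chr1", length(pos)), pos)
  expect_equal(res2$new_pos, oracle_lift_insertion(pos, 500L, 10L))

  # a source gap (deletion in the target) is unmapped, not an error
  bl3 <- data.frame(chrom = "chr1", src_start = c(1L, 601L),
                    src_end = c(501L, 1001L), tgt_start = c(1L, 501L),
                    src_len = 1000L, tgt_len = 900L)
  p3 <- tempfile(fileext = ".chain"); write_chain(bl3, p3)
  res3 <- lift_positions(p3, rep("chr1", 3), c(100L, 550L, 700L))
  expect_equal(res3$mapped, c(TRUE, FALSE, TRUE))
  expect_true(is.na(res3$new_pos[2]))

  # injectivity on mapped positions
  res4 <- lift_positions(p2, rep("chr1", 1000), 1:1000)
  mapped <- res4$new_pos[res4$mapped]
  expect_equal(anyDuplicated(mapped), 0L)
})
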