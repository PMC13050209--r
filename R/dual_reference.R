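#' Ordered ancestral marker sets
#'
#' A marker set holds the positions at which the ancestral diploid can be
#' heterozygous, with the allele carried by each parent, on the common
#' coordinate system. Positions are strictly increasing within chromosomes
#' and the two parental alleles differ at every marker.
#'
#' @param df data.frame with `chrom`, `pos`, `a1`, `a2`
#' @param provenance `"potential"` or `"final"`
#' @return a `data.table` of class `marker_set`
#' @export
marker_set <- function(df, provenance = c("potential", "final")) {
  provenance <- match.arg(provenance)
  dt <- data.table::as.data.table(df)[, c("chrom", "pos", "a1", "a2")]
  data.table::setorder(dt, chrom, pos)
  assert_that(!any(duplicated(dt[, c("chrom", "pos")])),
              "duplicate marker positions")
  assert_that(all(dt$a1 != dt$a2), "parental alleles must differ at markers")
  data.table::setattr(dt, "provenance", provenance)
  data.table::setattr(dt, "class", c("marker_set", class(dt)))
  dt[]
}

#' Potential markers: symmetric difference of the parental variant sets
#'
#' Takes the two sets of sites at which each parent differs from the common
#' reference, on common coordinates, and keeps the union minus the
#' intersection: positions where both parents differ from the reference are
#' not heterozygous in the hybrid and are removed. Positions present in both
#' sets with conflicting allele pairs are likewise excluded (and counted).
#'
#' @param variants_p1,variants_p2 data.frames with `chrom`, `pos`, `ref`,
#'   `alt` - each parent's differences from the common reference
#' @return list with `markers` (a [marker_set], provenance `"potential"`) and
#'   `n_shared` (positions removed as the intersection)
#' @export
potential_markers <- function(variants_p1, variants_p2) {
  v1 <- data.table::as.data.table(variants_p1)
  v2 <- data.table::as.data.table(variants_p2)
  k1 <- paste(v1$chrom, v1$pos)
  k2 <- paste(v2$chrom, v2$pos)
  shared <- intersect(k1, k2)
  only1 <- v1[!(k1 %in% shared)]
  only2 <- v2[!(k2 %in% shared)]
  mk <- rbind(
    # parent 1 carries the alt allele, parent 2 matches the reference
    data.table::data.table(chrom = only1$chrom, pos = only1$pos,
                           a1 = only1$alt, a2 = only1$ref),
    data.table::data.table(chrom = only2$chrom, pos = only2$pos,
                           a1 = only2$ref, a2 = only2$alt))
  list(markers = marker_set(mk, "potential"), n_shared = length(shared))
}

#' Reconcile the two per-reference call sets at shared markers
#'
#' The reconciliation rule is symmetric in the two references:
#' * both calls with GQ below `gq_min`, or either call missing: discard;
#' * calls agree (and at least one has GQ >= `gq_min`): that genotype;
#' * calls disagree and the GQ difference is >= `gq_delta`: the higher-GQ
#'   genotype (a tie at exactly `gq_delta` resolves to the higher-GQ call);
#' * calls disagree and the GQ difference is < `gq_delta`: discard.
#'
#' Both inputs must already be expressed in parental-allele space (see
#' [read_call_set()]), so "agree" compares homolog states rather than
#' REF/ALT encodings. A missing genotype (`NA`) counts as a missing call.
#'
#' @param calls_ref1,calls_ref2 [loh_calls] tables for the same sample on
#'   common coordinates
#' @param gq_min GQ threshold below which a call is low-quality (default 50)
#' @param gq_delta GQ difference needed for one call to override (default 30)
#' @return list with `calls` (reconciled [loh_calls]; discarded sites absent)
#'   and `report` (counts per rule branch)
#' @export
reconcile_calls <- function(calls_ref1, calls_ref2, gq_min = 50, gq_delta = 30) {
  c1 <- data.table::as.data.table(calls_ref1)
  c2 <- data.table::as.data.table(calls_ref2)
  key <- c("sample", "chrom", "pos")
  m <- merge(c1, c2, by = key, suffixes = c(".1", ".2"))
  ok_alleles <- is.na(m$a1.1) | is.na(m$a1.2) |
    (m$a1.1 == m$a1.2 & m$a2.1 == m$a2.2)
  assert_that(all(ok_alleles),
              "inconsistent parental allele assignment between the two call sets")

  gq1 <- ifelse(is.na(m$gq.1), 0, m$gq.1)
  gq2 <- ifelse(is.na(m$gq.2), 0, m$gq.2)
  miss <- is.na(m$gt.1) | is.na(m$gt.2)
  lowq <- !miss & gq1 < gq_min & gq2 < gq_min
  agree <- !miss & !lowq & m$gt.1 == m$gt.2
  disagree <- !miss & !lowq & m$gt.1 != m$gt.2
  dwin <- disagree & abs(gq1 - gq2) >= gq_delta
  ddisc <- disagree & abs(gq1 - gq2) < gq_delta

  # annotations follow the higher-GQ side (reference 1 on exact GQ ties)
  take1 <- (agree & gq1 >= gq2) | (dwin & gq1 > gq2)
  take2 <- (agree & gq2 > gq1) | (dwin & gq2 > gq1)
  keep <- take1 | take2

  pick <- function(col) {
    v <- m[[paste0(col, ".1")]]
    v[take2] <- m[[paste0(col, ".2")]][take2]
    v
  }
  out <- data.table::data.table(
    sample = m$sample, chrom = m$chrom, pos = m$pos,
    a1 = pick("a1"), a2 = pick("a2"), gt = pick("gt"),
    gq = pmax(gq1, gq2),
    qual = pick("qual"), dp = pick("dp"),
    ad1 = pick("ad1"), ad2 = pick("ad2"),
    qd = pick("qd"), mq = pick("mq"), fs = pick("fs"), sor = pick("sor"))[keep]

  # sites present in only one call set are missing calls: discarded
  n_one_sided <- nrow(c1) + nrow(c2) - 2L * nrow(m)
  report <- data.table::data.table(
    branch = c("missing_one_side", "both_low_gq", "agree",
               "disagree_gq_win", "disagree_discarded"),
    n = c(sum(miss) + n_one_sided, sum(lowq), sum(agree), sum(dwin), sum(ddisc)))
  list(calls = loh_calls(out), report = report)
}

#' Family genotype matrices
#'
#' A family matrix holds the genotype states of all end-point clones of one
#' family (and the founder, when sequenced) over a marker set.
#'
#' @param markers a [marker_set]
#' @param gt integer matrix markers x clones with values 0/1/2/NA
#' @param gq optional numeric matrix of genotype qualities, same shape
#' @param founder_gt optional integer vector of founder genotypes
#' @param founder_gq optional numeric vector
#' @param family family identifier
#' @return list of class `family_matrix`
#' @export
family_matrix <- function(markers, gt, gq = NULL, founder_gt = NULL,
                          founder_gq = NULL, family = "family1") {
  assert_that(nrow(gt) == nrow(markers),
              "gt matrix rows must match the marker set")
  if (!is.null(founder_gt))
    assert_that(length(founder_gt) == nrow(markers),
                "founder_gt length must match the marker set")
  structure(list(markers = markers, gt = gt, gq = gq,
                 founder_gt = founder_gt, founder_gq = founder_gq,
                 family = family),
            class = "family_matrix")
}

#' Final ancestral markers: founder-conditional descendant support
#'
#' With a sequenced founder, a potential marker is retained when the founder
#' is called heterozygous and at least `min_desc_with_founder` descendants
#' are too; without a founder, at least `min_desc_without` heterozygous
#' descendants are required.
#'
#' @param potential a [marker_set]
#' @param family a [family_matrix] built on `potential`
#' @param min_desc_with_founder minimum heterozygous descendants when the
#'   founder is sequenced (default 3)
#' @param min_desc_without minimum when it is not (default 4)
#' @return a [marker_set] with provenance `"final"`
#' @export
final_markers <- function(potential, family, min_desc_with_founder = 3L,
                          min_desc_without = 4L) {
  n_het <- rowSums(family$gt == 1L, na.rm = TRUE)
  if (!is.null(family$founder_gt)) {
    keep <- !is.na(family$founder_gt) & family$founder_gt == 1L &
      n_het >= min_desc_with_founder
  } else {
    keep <- n_het >= min_desc_without
  }
  marker_set(potential[keep], "final")
}

#' Flag aneuploid chromosomes and whole-genome duplications
#'
#' Per-chromosome mean allele depths are normalized so a euploid diploid has
#' relative coverage 1 for each parental allele (i.e. divided by half the
#' clone's genome-wide mean depth). A chromosome is flagged when either
#' allele's relative coverage is below `lo` (near-zero, homolog loss) or
#' above `hi` (gain). A whole-genome duplication of one parental set is
#' flagged when the allele coverage ratio sits near 0.5 (or, symmetrically,
#' 2) on every chromosome, with tolerance `wgd_tol`.
#'
#' @param per_chrom_allele_depth data.frame with `chrom`, `depth_p1`,
#'   `depth_p2` (mean reads supporting each parental allele)
#' @param genome_mean_depth the clone's genome-wide mean depth
#' @param lo,hi relative-coverage thresholds (defaults 0.05 and 1.5)
#' @param wgd_tol tolerance around 0.5 for the whole-genome ratio test
#' @return list with `chrom_flags` (data.table `chrom`, `rel_p1`, `rel_p2`,
#'   `aneuploid`) and `whole_genome_duplication` (logical)
#' @export
detect_aneuploidy <- function(per_chrom_allele_depth, genome_mean_depth,
                              lo = 0.05, hi = 1.5, wgd_tol = 0.1) {
  assert_that(is.numeric(genome_mean_depth) && genome_mean_depth > 0,
              "genome_mean_depth must be positive")
  d <- data.table::as.data.table(per_chrom_allele_depth)
  rel1 <- d$depth_p1 / (genome_mean_depth / 2)
  rel2 <- d$depth_p2 / (genome_mean_depth / 2)
  flags <- data.table::data.table(
    chrom = d$chrom, rel_p1 = rel1, rel_p2 = rel2,
    aneuploid = rel1 < lo | rel1 > hi | rel2 < lo | rel2 > hi)
  ratio <- ifelse(rel2 > 0, rel1 / rel2, Inf)
  folded <- pmin(ratio, 1 / ratio)
  wgd <- all(is.finite(folded)) && all(abs(folded - 0.5) <= wgd_tol)
  list(chrom_flags = flags, whole_genome_duplication = wgd)
}
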