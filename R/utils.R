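# Internal helpers shared across modules.

# required so data.table's non-standard evaluation works inside this package
.datatable.aware <- TRUE

# genotype state codes used throughout the package:
#   0 = HOM_P1, 1 = HET, 2 = HOM_P2, NA = missing
GT_LEVELS <- c(HOM_P1 = 0L, HET = 1L, HOM_P2 = 2L)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# masks and windows are stored 1-based half-open [start, end)
mask_to_iranges <- function(mask) {
  IRanges::IRanges(start = as.integer(mask$start),
                   end   = as.integer(mask$end) - 1L)
}

# merge possibly overlapping half-open intervals within one chromosome,
# returning total covered bp
merged_mask_bp <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(0)
  split_by <- if ("chrom" %in% names(mask)) mask$chrom else rep("*", nrow(mask))
  tot <- 0
  for (ch in unique(split_by)) {
    m <- mask[split_by == ch, , drop = FALSE]
    tot <- tot + sum(IRanges::width(IRanges::reduce(mask_to_iranges(m))))
  }
  tot
}
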