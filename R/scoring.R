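## scoring: agreement between predicted occupancy and a reference map via
## normalized mutual information (the quality score rho) and rank-based AUC.
## A region with median predicted occupancy strictly greater than the
## critical level c is classified "nucleosome", otherwise "linker"; rho is
## the threshold-maximized mutual information divided by the label entropy,
## so it is invariant to any strictly monotone transform of the occupancy.

#' Median predicted occupancy per region
#'
#' @param occupancy Per-base numeric occupancy track (or
#'   [coverage_track()]).
#' @param regions A [genomic_regions()] table (0-based half-open, within
#'   the track).
#' @return Numeric vector of exact per-region medians (even-length regions
#'   average the central pair).
#' @export
region_medians <- function(occupancy, regions) {
  v <- if (inherits(occupancy, "coverage_track")) occupancy$values else
    occupancy
  if (nrow(regions) == 0) return(numeric(0))
  if (any(regions$end > length(v)))
    stop("region extends beyond the occupancy track")
  region_medians_cpp(v, regions$start, regions$end)
}

#' Mutual information of a 2x2 contingency of fractions
#'
#' `I = sum_xy f_xy ln(f_xy / (f_x. f_.y))` in nats; empty cells contribute
#' zero.
#'
#' @param fractions Numeric vector `c(f_nn, f_nl, f_ln, f_ll)` (prediction
#'   x annotation), summing to 1.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(fractions) {
  if (length(fractions) != 4 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 4 non-negative values summing to 1")
  f <- matrix(fractions, 2, 2, byrow = TRUE) # rows: prediction, cols: annot
  rs <- rowSums(f); cs <- colSums(f)
  s <- 0
  for (i in 1:2) for (j in 1:2)
    if (f[i, j] > 0) s <- s + f[i, j] * log(f[i, j] / (rs[i] * cs[j]))
  s
}

label_to_int <- function(labels) {
  if (is.character(labels)) {
    if (!all(labels %in% c("nucleosome", "linker")))
      stop("labels must be 'nucleosome' or 'linker'")
    as.integer(labels == "nucleosome")
  } else as.integer(labels)
}

#' Threshold-maximized mutual information
#'
#' Scans every midpoint between consecutive distinct sorted medians (plus
#' the two extremes); ties in MI resolve to the smallest threshold.
#'
#' @param medians Per-region median occupancies.
#' @param labels Annotation labels (`nucleosome`/`linker`, or 1/0).
#' @return List with `mi_star` (nats), `c_star`, `entropy` (nats), `rho`.
#' @export
max_mi_threshold <- function(medians, labels) {
  lab <- label_to_int(labels)
  if (length(medians) != length(lab)) stop("length mismatch")
  mi_scan_cpp(medians, lab)
}

#' Quality score of a prediction against annotated regions
#'
#' `rho = I* / H`: the fraction of the nucleosome/linker label information
#' captured by the thresholded prediction, in `[0, 1]` and independent of
#' the logarithm base.
#'
#' @inheritParams max_mi_threshold
#' @param auc Also compute the rank-based AUC (default `TRUE`).
#' @return An object of class `quality_result`: `mi`, `mi_star`, `c_star`,
#'   `entropy`, `rho`, `auc`, `n_regions`.
#' @export
quality_score <- function(medians, labels, auc = TRUE) {
  sc <- max_mi_threshold(medians, labels)
  structure(list(mi_star = sc$mi_star, c_star = sc$c_star,
                 entropy = sc$entropy, rho = sc$rho,
                 auc = if (auc) roc_auc(medians, labels) else NA_real_,
                 n_regions = length(medians)),
            class = "quality_result")
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf(paste0("<quality_result> rho = %.4f (I* = %.4f nats, ",
                     "H = %.4f nats, c* = %.4g, AUC = %.4f, n = %d)\n"),
              x$rho, x$mi_star, x$entropy, x$c_star, x$auc, x$n_regions))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' The probability that a random annotated-nucleosome region has a higher
#' median than a random linker region, ties counting one half.
#'
#' @inheritParams max_mi_threshold
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(medians, labels) {
  lab <- label_to_int(labels)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) stop("both labels must be present")
  r <- rank(medians)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Restrict regions to promoter windows and/or classes
#'
#' Keeps regions whose midpoint falls within any gene's strand-aware
#' promoter window (`upstream` bp before to `downstream` bp after the
#' TSS), and optionally filters by class.
#'
#' @param regions A [genomic_regions()] table.
#' @param genes A [gene_annotation()] table, or `NULL` to skip the
#'   promoter filter.
#' @param upstream,downstream Promoter window in bp around the TSS
#'   (defaults 500/100).
#' @param classes Optional class filter: any of `nucleosome`,
#'   `short_linker`, `NFR`, `linker`.
#' @return The filtered [genomic_regions()] table.
#' @export
subset_regions <- function(regions, genes = NULL, upstream = 500,
                           downstream = 100, classes = NULL) {
  keep <- rep(TRUE, nrow(regions))
  if (!is.null(genes) && nrow(regions) > 0) {
    mid <- (regions$start + regions$end) %/% 2L
    lo <- ifelse(genes$strand == "+", genes$tss - upstream,
                 genes$tss - downstream)
    hi <- ifelse(genes$strand == "+", genes$tss + downstream,
                 genes$tss + upstream)
    inprom <- rep(FALSE, nrow(regions))
    for (g in seq_len(nrow(genes)))
      inprom <- inprom | (regions$chrom == genes$chrom[g] &
                            mid >= lo[g] & mid <= hi[g])
    keep <- keep & inprom
  }
  if (!is.null(classes) && nrow(regions) > 0) {
    cls <- ifelse(regions$label == "nucleosome", "nucleosome",
                  ifelse(regions$subclass == "none", "linker",
                         regions$subclass))
    keep <- keep & (cls %in% classes |
                      (regions$label == "linker" & "linker" %in% classes))
  }
  validate_regions(regions[keep, , drop = FALSE])
}
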