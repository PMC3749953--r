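## reference_maps: raw coverage / read-midpoint data -> normalized
## probability tracks and consensus nucleosome/linker maps, with
## reproducibility diagnostics.

#' Normalize a signal track to coverage probabilities
#'
#' Assumes the signal is proportional to the log of the binding
#' probability, `p_i = exp((s_i - b)/a)`: `b` is pinned so the largest
#' retained signal maps to `p = 1`, and `a > 0` is solved by a monotone
#' root find so the mean retained probability matches `target_mean`.
#' Extreme positions (a fraction `trim_frac` per tail) are excluded from
#' the fit and clamped into `[0,1]` afterwards.
#'
#' @param signal A [coverage_track()] (basis `signal` or `reads`).
#' @param target_mean Desired mean coverage probability, in (0,1)
#'   (default 0.81, a typical bulk nucleosome coverage).
#' @param trim_frac Fraction of positions per tail excluded from fitting.
#' @return An object of class `normalized_coverage`: list with `track`
#'   (probability basis), `a`, `b`, `trim_frac`.
#' @export
normalize_coverage <- function(signal, target_mean = 0.81,
                               trim_frac = 0.001) {
  if (target_mean <= 0 || target_mean >= 1)
    stop("target_mean must be in (0,1)")
  s <- signal$values
  if (any(!is.finite(s))) stop("signal contains non-finite values")
  qs <- stats::quantile(s, c(trim_frac, 1 - trim_frac), names = FALSE)
  retained <- s[s >= qs[1] & s <= qs[2]]
  if (length(retained) < 2) stop("too few positions after trimming")
  b <- max(retained)
  if (max(retained) - min(retained) < 1e-12) {
    # constant signal: any a works, probabilities are flat at the target
    p <- rep(target_mean, length(s))
    return(structure(list(track = coverage_track(signal$chrom, p,
                                                 "probability"),
                          a = 1, b = b, trim_frac = trim_frac),
                     class = "normalized_coverage"))
  }
  fmean <- function(loga) mean(exp((retained - b) / exp(loga))) - target_mean
  lo <- -20; hi <- 20
  flo <- fmean(lo); fhi <- fmean(hi)
  if (flo * fhi > 0)
    stop("no root for the normalization slope in (0, Inf); ",
         "mean range [", format(flo + target_mean), ", ",
         format(fhi + target_mean), "] does not bracket ", target_mean)
  a <- exp(stats::uniroot(fmean, c(lo, hi), tol = 1e-12)$root)
  p <- pmin(pmax(exp((s - b) / a), 0), 1)
  achieved <- mean(exp((retained - b) / a))
  if (abs(achieved - target_mean) > 1e-6)
    stop("root find failed to reach the target mean")
  structure(list(track = coverage_track(signal$chrom, p, "probability"),
                 a = a, b = b, trim_frac = trim_frac),
            class = "normalized_coverage")
}

#' Call nucleosome dyads from read midpoints or coverage
#'
#' GeneTrack-style calling: a Gaussian kernel (peak value 1, so heights are
#' in reads-equivalents) smooths the midpoint counts; local maxima are
#' taken greedily in decreasing height, suppressing candidates within the
#' exclusion zone of an accepted call, and peaks below the height cutoff
#' are dropped.
#'
#' @param midpoints Integer vector of 0-based read midpoints (or `NULL`).
#' @param coverage A [coverage_track()] used directly as the density (when
#'   `midpoints` is `NULL`).
#' @param chrom_length Chromosome length (required with `midpoints`).
#' @param sigma Smoothing kernel SD in bp.
#' @param exclusion_w Width of the exclusion zone in bp (non-overlapping
#'   nucleosomes: 147).
#' @param peak_halfwidth Half-width assigned to each called peak (73).
#' @param height_cutoff Minimum smoothed height (reads-equivalent).
#' @param dataset Dataset identifier recorded with each call.
#' @param chrom Chromosome name recorded with midpoint-based calls.
#' @return A `data.frame` of class `nucleosome_calls` with columns
#'   `chrom`, `dyad`, `height`, `dataset`.
#' @export
call_nucleosomes <- function(midpoints = NULL, coverage = NULL,
                             chrom_length = NULL, sigma = 20,
                             exclusion_w = 147, peak_halfwidth = 73,
                             height_cutoff = 3.0, dataset = "ds1",
                             chrom = "chr") {
  if (sigma <= 0) stop("sigma must be > 0")
  if (exclusion_w < 1) stop("exclusion_w must be >= 1")
  if (!is.null(midpoints)) {
    if (is.null(chrom_length)) stop("chrom_length required with midpoints")
    if (length(midpoints) == 0) {
      warning("no read midpoints; empty call set")
      return(nucleosome_calls(character(), integer(), numeric(),
                              character()))
    }
    counts <- tabulate(midpoints + 1L, nbins = chrom_length)
    dens <- gaussian_smooth(counts, sigma)
  } else {
    if (is.null(coverage)) stop("need midpoints or coverage")
    chrom <- coverage$chrom
    dens <- coverage$values
  }
  L <- length(dens)
  # local maxima (plateau-left convention)
  left <- c(-Inf, dens[-L])
  right <- c(dens[-1], -Inf)
  cand <- which(dens > left & dens >= right & dens >= height_cutoff)
  if (length(cand) == 0)
    return(nucleosome_calls(character(), integer(), numeric(), character()))
  cand <- cand[order(dens[cand], decreasing = TRUE)]
  accepted <- integer(0)
  taken <- logical(L)
  half <- as.integer(ceiling(exclusion_w - 1))
  for (p in cand) {
    if (!taken[p]) {
      accepted <- c(accepted, p)
      lo <- max(1L, p - half); hi <- min(L, p + half)
      taken[lo:hi] <- TRUE
    }
  }
  accepted <- sort(accepted)
  nucleosome_calls(chrom, accepted - 1L, dens[accepted], dataset)
}

nucleosome_calls <- function(chrom, dyad, height, dataset) {
  df <- data.frame(chrom = as.character(chrom), dyad = as.integer(dyad),
                   height = as.numeric(height),
                   dataset = as.character(dataset), stringsAsFactors = FALSE)
  class(df) <- c("nucleosome_calls", "data.frame")
  df
}

# Gaussian smoothing with a kernel whose peak value is 1 (heights stay in
# reads-equivalents); kernel truncated at 4 sigma.
gaussian_smooth <- function(x, sigma) {
  half <- ceiling(4 * sigma)
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  out <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Build a consensus nucleosome/linker reference map
#'
#' Per-dataset call dyads are re-clustered with the same peak-calling
#' machinery (each call counted as one read); consensus nucleosomes are
#' retained only when supported by at least `min_support` datasets (a call
#' within half the exclusion zone). Linkers are the maximal interior gaps
#' covered by no dataset's calls, subclassified as `short_linker`
#' (< `length_threshold`) or `NFR`.
#'
#' @param calls_list List of per-dataset [call_nucleosomes()] results
#'   (>= 2 datasets).
#' @param genome_length Chromosome length in bp.
#' @param min_support Minimum number of supporting datasets (default: all).
#' @param length_threshold Linker subclass threshold in bp (default 50).
#' @param sigma,exclusion_w,height_cutoff Second-pass calling parameters;
#'   the height cutoff defaults to `min_support - 0.5` call-equivalents.
#' @return An object of class `reference_map`: list with `nucleosomes`
#'   (score = supporting-dataset count), `linkers`, `regions` (both,
#'   concatenated), and the call sets used.
#' @export
build_reference_map <- function(calls_list, genome_length,
                                min_support = length(calls_list),
                                length_threshold = 50, sigma = 20,
                                exclusion_w = 147,
                                height_cutoff = NULL) {
  if (length(calls_list) < 2) stop("need at least two datasets")
  if (min_support > length(calls_list))
    stop("min_support exceeds the number of datasets")
  if (is.null(height_cutoff)) height_cutoff <- min_support - 0.5
  chrom <- calls_list[[1]]$chrom[1]
  if (is.na(chrom)) chrom <- "chr"
  all_dyads <- unlist(lapply(calls_list, `[[`, "dyad"))
  consensus <- call_nucleosomes(midpoints = all_dyads,
                                chrom_length = genome_length, sigma = sigma,
                                exclusion_w = exclusion_w,
                                height_cutoff = height_cutoff,
                                dataset = "consensus")
  half <- floor(exclusion_w / 2)
  support <- vapply(consensus$dyad, function(d) {
    sum(vapply(calls_list, function(cl)
      any(abs(cl$dyad - d) <= half), FALSE))
  }, 0L)
  keep <- support >= min_support
  dyads <- consensus$dyad[keep]
  support <- support[keep]
  nuc_start <- pmax(0L, dyads - 73L)
  nuc_end <- pmin(genome_length, dyads + 74L)
  nucs <- genomic_regions(chrom, nuc_start, nuc_end, "nucleosome", "none",
                          score = support)
  # linkers: interior gaps covered by NO dataset's calls
  cov <- logical(genome_length)
  for (cl in calls_list) {
    for (d in cl$dyad) {
      lo <- max(1L, d - 73L + 1L); hi <- min(genome_length, d + 74L)
      cov[lo:hi] <- TRUE
    }
  }
  covered_idx <- which(cov)
  linkers <- genomic_regions(character(), integer(), integer(), "linker")
  if (length(covered_idx) > 1) {
    r <- rle(cov[covered_idx[1]:covered_idx[length(covered_idx)]])
    offs <- covered_idx[1] - 1L
    ends <- offs + cumsum(r$lengths)
    starts <- ends - r$lengths
    gap <- !r$values
    if (any(gap)) {
      ls <- starts[gap]; le <- ends[gap]
      len <- le - ls
      sub <- ifelse(len < length_threshold, "short_linker", "NFR")
      linkers <- genomic_regions(chrom, ls, le, "linker", sub,
                                 score = NA_real_)
    }
  }
  structure(list(nucleosomes = nucs, linkers = linkers,
                 regions = validate_regions(rbind(as.data.frame(nucs),
                                                  as.data.frame(linkers))),
                 support = support, genome_length = genome_length,
                 exclusion_w = exclusion_w),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf(paste0("<reference_map> %d nucleosomes, %d linkers ",
                     "(%d short, %d NFR) on %d bp\n"),
              nrow(x$nucleosomes), nrow(x$linkers),
              sum(x$linkers$subclass == "short_linker"),
              sum(x$linkers$subclass == "NFR"), x$genome_length))
  invisible(x)
}

#' Per-nucleosome positional reproducibility
#'
#' For each reference nucleosome, the population standard deviation of the
#' matched per-dataset dyads (nearest dyad within half the exclusion zone;
#' ties resolved toward the smaller coordinate). Reference nucleosomes
#' matched in fewer than two datasets are excluded and counted.
#'
#' @param reference A [build_reference_map()] result.
#' @param calls_list The per-dataset call sets the map was built from.
#' @return Numeric vector of SDs (one per matched reference nucleosome),
#'   with attribute `n_unmatched`.
#' @export
position_reproducibility <- function(reference, calls_list) {
  half <- floor(reference$exclusion_w / 2)
  dyads <- reference$nucleosomes$start + 73L
  sds <- rep(NA_real_, length(dyads))
  for (i in seq_along(dyads)) {
    d <- dyads[i]
    matched <- vapply(calls_list, function(cl) {
      dist <- abs(cl$dyad - d)
      j <- which(dist <= half)
      if (length(j) == 0) return(NA_real_)
      j <- j[order(dist[j], cl$dyad[j])][1]
      as.numeric(cl$dyad[j])
    }, 0)
    matched <- matched[!is.na(matched)]
    if (length(matched) >= 2)
      sds[i] <- sqrt(mean((matched - mean(matched))^2))  # population SD
  }
  out <- sds[!is.na(sds)]
  attr(out, "n_unmatched") <- sum(is.na(sds))
  out
}

#' Randomized-read reproducibility control
#'
#' Repositions every read uniformly at random, re-runs the calling and map
#' construction, and recomputes the per-nucleosome SDs — the chance
#' expectation of the annotation procedure.
#'
#' @param midpoints_list Per-dataset read midpoint vectors.
#' @param genome_length Chromosome length.
#' @param min_support Support filter for the control map; randomized reads
#'   rarely reproduce across all datasets, so the control defaults to 2.
#' @param ... Passed to [call_nucleosomes()].
#' @return As [position_reproducibility()].
#' @export
randomized_reproducibility <- function(midpoints_list, genome_length,
                                       min_support = 2, ...) {
  rand <- lapply(midpoints_list, function(m)
    sample.int(genome_length, length(m), replace = TRUE) - 1L)
  calls <- lapply(seq_along(rand), function(i)
    call_nucleosomes(midpoints = rand[[i]], chrom_length = genome_length,
                     dataset = paste0("rand", i), ...))
  ref <- build_reference_map(calls, genome_length,
                             min_support = min_support)
  position_reproducibility(ref, calls)
}

#' Trimmed Pearson correlation between two tracks
#'
#' Positions falling in the top or bottom `trim_frac` of either track are
#' excluded before computing Pearson's r (guards against aberrant signal
#' spikes dominating a per-base correlation).
#'
#' @param track_a,track_b Numeric vectors or [coverage_track()]s of equal
#'   length.
#' @param trim_frac Fraction per tail per track (default 5e-4).
#' @return Pearson correlation on the retained positions.
#' @export
trimmed_pearson <- function(track_a, track_b, trim_frac = 5e-4) {
  a <- if (inherits(track_a, "coverage_track")) track_a$values else track_a
  b <- if (inherits(track_b, "coverage_track")) track_b$values else track_b
  if (length(a) != length(b)) stop("tracks must have equal length")
  qa <- stats::quantile(a, c(trim_frac, 1 - trim_frac), names = FALSE)
  qb <- stats::quantile(b, c(trim_frac, 1 - trim_frac), names = FALSE)
  keep <- a >= qa[1] & a <= qa[2] & b >= qb[1] & b <= qb[2]
  if (sum(keep) < 10) stop("fewer than 10 positions remain after trimming")
  stats::cor(a[keep], b[keep])
}

#' Empirical CDF of a coverage track
#'
#' @param track A probability-basis [coverage_track()] (or numeric vector).
#' @return A `data.frame` with sorted `value` and `cum_frac` columns.
#' @export
coverage_cdf <- function(track) {
  v <- if (inherits(track, "coverage_track")) track$values else track
  v <- sort(v)
  data.frame(value = v, cum_frac = seq_along(v) / length(v))
}
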