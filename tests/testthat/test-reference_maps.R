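test_that("coverage normalization hits the target mean and stays in [0,1]", {
  # constant signal: flat probabilities at the target
  ct <- coverage_track("c", rep(3.3, 500))
  nc <- normalize_coverage(ct, target_mean = 0.8, trim_frac = 0)
  expect_true(all(nc$track$values == 0.8))

  # two-level closed form: {0 on half, 1 on half}, target 0.6
  # b = 1 (max), exp(-1/a) = 0.2 -> a = 1/ln 5
  tv <- coverage_track("c", rep(c(0, 1), each = 250))
  nc2 <- normalize_coverage(tv, target_mean = 0.6, trim_frac = 0)
  expect_equal(nc2$b, 1)
  expect_equal(nc2$a, 1 / log(5), tolerance = 1e-8)
  expect_equal(sort(unique(nc2$track$values)), c(0.2, 1), tolerance = 1e-8)

  # random lognormal signals: mean within 1e-6, order preserved
  set.seed(61)
  for (i in 1:5) {
    s <- coverage_track("c", exp(stats::rnorm(4000)))
    nc3 <- normalize_coverage(s, target_mean = 0.81, trim_frac = 0.001)
    p <- nc3$track$values
    expect_true(all(p >= 0 & p <= 1))
    keep <- s$values >= stats::quantile(s$values, 0.001) &
      s$values <= stats::quantile(s$values, 0.999)
    expect_equal(mean(exp((s$values[keep] - nc3$b) / nc3$a)), 0.81,
                 tolerance = 1e-6)
    o <- order(s$values[keep])
    expect_true(all(diff(p[keep][o]) >= -1e-12))  # monotone transform
  }
})

test_that("peak calling finds planted dyads and respects the exclusion zone", {
  # all midpoints at one position -> one call at that dyad
  calls <- call_nucleosomes(midpoints = rep(500L, 100), chrom_length = 1000L)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$dyad, 500L)

  # two equal clusters 200 bp apart -> two calls
  calls2 <- call_nucleosomes(midpoints = c(rep(300L, 50), rep(500L, 50)),
                             chrom_length = 1000L)
  expect_equal(sort(calls2$dyad), c(300L, 500L))

  # planted array of 8 nucleosomes spaced 165 bp, noisy reads
  set.seed(67)
  truth <- 300 + 165 * (0:7)
  mids <- unlist(lapply(truth, function(d)
    round(d + stats::rnorm(50, 0, 20))))
  calls3 <- call_nucleosomes(midpoints = as.integer(mids),
                             chrom_length = 2000L)
  expect_equal(nrow(calls3), 8)
  expect_true(all(abs(sort(calls3$dyad) - truth) <= 10))
  # exclusion-zone invariant
  expect_true(min(diff(sort(calls3$dyad))) >= 147)

  expect_warning(empty <- call_nucleosomes(midpoints = integer(),
                                           chrom_length = 100L), "no read")
  expect_equal(nrow(empty), 0)
})

test_that("reference maps intersect datasets and tile the chromosome", {
  set.seed(71)
  truth <- 300 + 165 * (0:7)
  mklist <- function(n) lapply(seq_len(n), function(d)
    call_nucleosomes(midpoints = as.integer(unlist(lapply(truth, function(x)
      round(x + stats::rnorm(60, 0, 15))))), chrom_length = 2000L,
      dataset = paste0("ds", d)))
  calls <- mklist(4)
  ref <- build_reference_map(calls, 2000L)
  expect_equal(nrow(ref$nucleosomes), 8)
  expect_true(all(abs(sort(ref$nucleosomes$start + 73) - truth) <= 20))
  # non-overlap of reference nucleosomes
  ns <- ref$nucleosomes[order(ref$nucleosomes$start), ]
  expect_true(all(ns$start[-1] >= ns$end[-nrow(ns)]))
  # regions never overlap each other
  all_r <- ref$regions[order(ref$regions$start), ]
  expect_true(all(all_r$start[-1] >= all_r$end[-nrow(all_r)]))

  # a nucleosome absent from one dataset is dropped from the reference
  # nucleosomes AND its span stays out of the linkers
  calls_miss <- calls
  drop_dyad <- truth[4]
  keep <- abs(calls_miss[[1]]$dyad - drop_dyad) > 73
  calls_miss[[1]] <- calls_miss[[1]][keep, ]
  ref2 <- build_reference_map(calls_miss, 2000L)
  expect_equal(nrow(ref2$nucleosomes), 7)
  expect_false(any(abs(ref2$nucleosomes$start + 73 - drop_dyad) <= 40))
  if (nrow(ref2$linkers) > 0) {
    inside <- ref2$linkers$start <= drop_dyad & ref2$linkers$end > drop_dyad
    expect_false(any(inside))
  }

  expect_error(build_reference_map(calls, 2000L, min_support = 9),
               "min_support")
  expect_error(build_reference_map(calls[1], 2000L), "two datasets")
})

test_that("linkers are subclassified by the length threshold", {
  mk <- function(dyads) call_nucleosomes(
    midpoints = as.integer(unlist(lapply(dyads, rep, 50))),
    chrom_length = 1500L)
  # gap of 33 bp (short) and one of 153 bp (NFR) between three nucleosomes
  dyads <- c(300L, 480L, 780L)
  calls <- list(mk(dyads), mk(dyads))
  ref <- build_reference_map(calls, 1500L)
  expect_equal(nrow(ref$linkers), 2)
  expect_equal(ref$linkers$end - ref$linkers$start, c(33L, 153L))
  expect_equal(ref$linkers$subclass, c("short_linker", "NFR"))
})

test_that("positional reproducibility uses the population SD", {
  mk1 <- function(dyad) nucfree:::nucleosome_calls("c", dyad, 10, "d")
  calls <- list(mk1(98L), mk1(100L), mk1(102L))
  ref <- build_reference_map(calls, 1000L, min_support = 3)
  expect_equal(nrow(ref$nucleosomes), 1)
  sds <- position_reproducibility(ref, calls)
  expect_equal(as.numeric(sds), sqrt(mean((c(98, 100, 102) - 100)^2)))
  # identical datasets -> zero SD
  calls0 <- list(mk1(400L), mk1(400L))
  ref0 <- build_reference_map(calls0, 1000L)
  expect_equal(as.numeric(position_reproducibility(ref0, calls0)), 0)
})

test_that("randomized reads reproduce worse than structured reads", {
  set.seed(73)
  truth <- 300 + 170 * (0:8)
  mids <- lapply(1:4, function(d) as.integer(unlist(
    lapply(truth, function(x) round(x + stats::rnorm(60, 0, 12))))))
  calls <- lapply(seq_along(mids), function(i)
    call_nucleosomes(midpoints = mids[[i]], chrom_length = 2200L,
                     dataset = paste0("d", i)))
  ref <- build_reference_map(calls, 2200L)
  real_sd <- stats::median(position_reproducibility(ref, calls))
  rand_sd <- stats::median(randomized_reproducibility(mids, 2200L,
                                                      height_cutoff = 1))
  expect_true(is.na(rand_sd) || rand_sd > real_sd)
  # the structured map reproduces tightly in absolute terms
  expect_lt(real_sd, 10)
})

test_that("trimmed correlation excludes extreme positions", {
  v <- stats::rnorm(2000)
  expect_equal(trimmed_pearson(v, v), 1)
  expect_equal(trimmed_pearson(v, -v), -1)
  # shared latent signal with known mixing: r = 1/(1+s^2) analytically
  set.seed(79)
  lat <- stats::rnorm(20000)
  s <- 0.5
  a <- lat + s * stats::rnorm(20000)
  b <- lat + s * stats::rnorm(20000)
  r_true <- 1 / (1 + s^2)
  r_obs <- trimmed_pearson(a, b, trim_frac = 5e-4)
  expect_lt(abs(r_obs - r_true), 3 / sqrt(20000) * (1 - r_true^2) * 3)
  expect_error(trimmed_pearson(1:5, 1:5), "10 positions")
})

test_that("coverage CDFs are deterministic and distribution-faithful", {
  cdf <- coverage_cdf(rep(0.8, 10))
  expect_true(all(cdf$value == 0.8))
  expect_equal(cdf$cum_frac[10], 1)
  grid <- coverage_cdf(seq(0, 1, length.out = 1001))
  expect_lt(max(abs(grid$value - grid$cum_frac)), 0.002)
})
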