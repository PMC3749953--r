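test_that("partition sums reproduce small closed-form cases", {
  # empty weights: only the empty configuration
  w <- raw_weights(list(rep(0, 8)), 3L, 10L)
  s <- forward_backward(w)
  expect_equal(s$logZ, 0)
  expect_equal(s$logF, rep(0, 11))

  # L = l, one site of weight q: Z = 1 + q
  q <- 2.3
  w <- raw_weights(list(q), 4L, 4L)
  expect_equal(forward_backward(w)$logZ, log(1 + q), tolerance = 1e-12)

  # L = 2l, uniform weight at l+1 starts: Z = 1 + (l+1) q + q^2
  l <- 3; q <- 0.7
  w <- raw_weights(list(rep(q, l + 1)), l, 2L * l)
  expect_equal(forward_backward(w)$logZ, log(1 + (l + 1) * q + q^2),
               tolerance = 1e-12)

  expect_error(forward_backward(raw_weights(list(c(1, -1, 1)), 2L, 4L)),
               "negative")
})

test_that("forward and backward sums agree on logZ", {
  set.seed(31)
  for (i in 1:10) {
    w <- random_instance()
    s <- forward_backward(w)
    expect_equal(s$logF[w$L + 1], s$logR[1], tolerance = 1e-9)
    expect_equal(s$logF[1], 0)
    expect_equal(s$logR[w$L + 1], 0)
  }
})

test_that("DP posteriors match brute-force enumeration on random instances", {
  set.seed(37)
  worst <- 0
  for (i in 1:50) {
    w <- random_instance()
    bf <- brute_force(w)
    s <- forward_backward(w)
    occ <- site_posteriors(s, w)
    worst <- max(worst,
                 abs(s$logZ - bf$logZ) / max(1, abs(bf$logZ)),
                 max(abs(unlist(occ$posteriors) -
                           unlist(bf$posteriors))))
  }
  expect_lt(worst, 1e-9)
})

test_that("occupancies and the free fraction always sum to one", {
  set.seed(41)
  for (i in 1:10) {
    w <- random_instance()
    occ <- site_posteriors(forward_backward(w), w)
    total <- Reduce(`+`, occ$occupancy) + occ$free
    expect_lt(max(abs(total - 1)), 1e-9)
    expect_true(all(unlist(occ$posteriors) >= 0))
    expect_true(all(unlist(occ$posteriors) <= 1 + 1e-12))
  }
})

test_that("a single two-state site has posterior q/(1+q)", {
  q <- 3
  w <- raw_weights(list(q), 5L, 5L)
  occ <- site_posteriors(forward_backward(w), w)
  expect_equal(occ$posteriors[[1]], q / (1 + q), tolerance = 1e-12)
  expect_equal(occ$occupancy[[1]], rep(q / (1 + q), 5), tolerance = 1e-12)
})

test_that("raising a concentration never lowers that factor's coverage", {
  set.seed(43)
  for (i in 1:8) {
    w <- random_instance(L = 16, max_factors = 2)
    bf1 <- brute_force(w)
    w2 <- w
    w2$q[[1]] <- w$q[[1]] * exp(0.8)  # scale factor 1's concentration up
    bf2 <- brute_force(w2)
    cov1 <- sum(bf1$posteriors[[1]]) * w$footprints[1]
    cov2 <- sum(bf2$posteriors[[1]]) * w$footprints[1]
    expect_gte(cov2, cov1 - 1e-12)
  }
})

test_that("zero specificity gives an end-symmetric occupancy profile", {
  L <- 400L
  w <- raw_weights(list(rep(1.5, L - 10 + 1)), 10L, L)
  occ <- site_posteriors(forward_backward(w), w)
  prof <- occ$occupancy[[1]]
  expect_lt(max(abs(prof - rev(prof))), 1e-9)
  # bulk translation invariance away from the ends
  mid <- prof[150:250]
  expect_lt(diff(range(mid)), 1e-6)
})

test_that("configuration log-weights normalize over the enumeration", {
  set.seed(47)
  w <- random_instance(L = 14, max_factors = 2)
  s <- forward_backward(w)
  # enumerate configurations recursively and accumulate exp(logw - logZ)
  nf <- length(w$q)
  total <- 0
  rec <- function(i, cfg) {
    if (i > w$L) {
      lw <- configuration_log_weight(cfg, w)
      total <<- total + exp(lw - s$logZ)
      return(invisible())
    }
    rec(i + 1, cfg)
    for (f in seq_len(nf)) {
      l <- w$footprints[f]
      if (i + l - 1 <= w$L && w$q[[f]][i] > 0)
        rec(i + l, rbind(cfg, data.frame(factor = f, start = i - 1)))
    }
  }
  rec(1, data.frame(factor = integer(), start = integer()))
  expect_equal(total, 1, tolerance = 1e-9)
  expect_equal(configuration_log_weight(
    data.frame(factor = integer(), start = integer()), w), 0)
  # overlap detection
  bad <- data.frame(factor = c(1, 1), start = c(0, 1))
  expect_error(validate_configuration(bad, w), "overlap")
})

test_that("stochastic traceback reproduces exact posteriors", {
  # single site, q = 1: present in ~50% of draws
  w <- raw_weights(list(1), 4L, 4L)
  s <- forward_backward(w)
  set.seed(53)
  hits <- sum(vapply(1:4000, function(i)
    nrow(sample_configuration(s, w)) > 0, FALSE))
  expect_lt(abs(hits / 4000 - 0.5), 3 * sqrt(0.25 / 4000))

  # all weights zero: always the empty configuration
  w0 <- raw_weights(list(rep(0, 5)), 3L, 7L)
  s0 <- forward_backward(w0)
  expect_equal(nrow(sample_configuration(s0, w0)), 0)

  # empirical site frequencies on a 25-bp instance within 3 MC sigma
  set.seed(59)
  w <- random_instance(L = 25, max_factors = 3)
  s <- forward_backward(w)
  occ <- site_posteriors(s, w)
  n <- 4000
  counts <- lapply(w$q, function(q) numeric(length(q)))
  for (i in seq_len(n)) {
    cfg <- sample_configuration(s, w)
    if (nrow(cfg))
      for (k in seq_len(nrow(cfg)))
        counts[[cfg$factor[k]]][cfg$start[k] + 1] <-
          counts[[cfg$factor[k]]][cfg$start[k] + 1] + 1
  }
  for (f in seq_along(counts)) {
    p <- occ$posteriors[[f]]
    emp <- counts[[f]] / n
    sig <- sqrt(pmax(p * (1 - p), 1e-12) / n)
    expect_true(all(abs(emp - p) <= 3.5 * sig + 1e-9))
  }
})

test_that("sampling is reproducible under a fixed seed", {
  w <- random_instance(L = 20)
  s <- forward_backward(w)
  set.seed(7); a <- sample_configuration(s, w, n = 5)
  set.seed(7); b <- sample_configuration(s, w, n = 5)
  expect_identical(a, b)
})

test_that("the enumeration guard refuses oversized instances", {
  w <- raw_weights(list(rep(1, 30)), 1L, 30L)
  expect_error(brute_force(w), "too large")
  expect_error(brute_force(raw_weights(list(rep(1, 30)), 2L, 31L)),
               "L <= 30")
})
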