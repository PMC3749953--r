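test_that("k-fold splits partition and stratify", {
  regs <- genomic_regions("c", (0:9) * 100, (0:9) * 100 + 50,
                          label = rep(c("nucleosome", "linker"), 5))
  folds <- kfold_split(regs, 5, seed = 2)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), 1:10)

  set.seed(113)
  n <- 83
  regs <- genomic_regions("c", (0:(n - 1)) * 100, (0:(n - 1)) * 100 + 50,
                          label = sample(c("nucleosome", "linker"), n, TRUE,
                                         prob = c(0.6, 0.4)))
  folds <- kfold_split(regs, 5, seed = 3)
  expect_setequal(unlist(folds), seq_len(n))
  expect_true(max(lengths(folds)) - min(lengths(folds)) <= 1)
  global <- mean(regs$label == "nucleosome")
  for (f in folds) {
    cnt <- sum(regs$label[f] == "nucleosome")
    expect_lte(abs(cnt - global * length(f)), 1 + 1e-9)
  }
  # a label rarer than k falls back with a warning
  regs2 <- genomic_regions("c", (0:9) * 100, (0:9) * 100 + 50,
                           label = c(rep("nucleosome", 8), "linker",
                                     "linker"))
  expect_warning(kfold_split(regs2, 5, seed = 1), "unstratified")
})

test_that("column shuffling conserves information and row multiset", {
  wm <- generate_wm(6, 7, seed = 21)
  sh <- shuffle_wm_columns(wm, seed = 5)
  expect_equal(information_content(sh), information_content(wm),
               tolerance = 1e-12)
  expect_equal(unclass(sh)[order(sh[, 1]), ], unclass(wm)[order(wm[, 1]), ],
               tolerance = 1e-15, ignore_attr = TRUE)
  # length-1 identity
  one <- weight_matrix(matrix(c(0.7, 0.1, 0.1, 0.1), 1))
  expect_equal(unclass(shuffle_wm_columns(one, 1)), unclass(one),
               ignore_attr = TRUE)
  # permutations are uniform over 1000 shuffles of a length-3 matrix
  wm3 <- generate_wm(3, 3, seed = 9)
  set.seed(11)
  perms <- replicate(1000, paste(order(shuffle_wm_columns(wm3)[, 1]),
                                 collapse = ""))
  tab <- table(perms)
  expect_length(tab, 6)
  expect_true(all(abs(tab - 1000 / 6) < 3 * sqrt(1000 * (1 / 6) * (5 / 6))))
})

test_that("zero free parameters returns the input unchanged", {
  g <- random_genome(3000, seed = 17)
  nm <- nucleosome_model("dinucleotide")
  nf <- factor_spec("nucleosome", "nucleosome", gamma = 0.4, log_conc = 1)
  ctx <- model_context(list(nf), g, nm)
  regs <- genomic_regions("c", seq(0, 2500, by = 250),
                          seq(0, 2500, by = 250) + 147,
                          label = rep(c("nucleosome", "linker"),
                                      length.out = 11))
  fit <- fit_model(ctx, regs, free_params(character(), character()))
  expect_equal(fit$log_conc, 1)
  expect_equal(fit$gamma, 0.4)
  expect_true(is.finite(fit$rho))
})

test_that("fitting is deterministic under a fixed seed", {
  sc <- make_scenario("null", overrides = list(length = 20000L, n_genes = 4,
                                               cells_per_dataset = 300),
                      seed = 3)
  ref <- scenario_reference_map(sc, min_support = 2)
  ctx <- model_context(sc$factors[1], sc$genome, sc$nuc_model)
  free <- free_params("nucleosome", "log_conc")
  cfg <- fit_config(t0 = 0.3, cooling = 0.7, steps_per_t = 4, t_min = 0.05,
                    seed = 42)
  f1 <- fit_model(ctx, ref$regions, free, cfg)
  f2 <- fit_model(ctx, ref$regions, free, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$log_conc, f2$log_conc)
})

test_that("characterization matches brute-force posterior averages", {
  # single-site system: P = 0.5, l = 10, L = 100 -> phi = 0.05
  w <- raw_weights(list(c(1, rep(0, 90))), 10L, 100L)
  occ <- site_posteriors(forward_backward(w), w)
  f <- factor_spec("t", "nucleosome", footprint = 10L, gamma = 0)
  wts <- w
  wts$energies <- list(list(e_sym = rep(0, 91)))
  ch <- characterize(occ, wts, list(f))
  expect_equal(ch$phi, 0.05, tolerance = 1e-12)
  expect_equal(ch$entropy, 0, tolerance = 1e-12)  # single dominant site

  # m equal sites -> S = ln m (up to edge effects use far-apart sites)
  q <- rep(0, 181)
  q[c(1, 61, 121, 181)] <- 0.2
  w2 <- raw_weights(list(q), 10L, 190L)
  occ2 <- site_posteriors(forward_backward(w2), w2)
  pi <- occ2$posteriors[[1]]
  pi <- pi[pi > 0] / sum(pi[pi > 0])
  expect_equal(-sum(pi * log(pi)), log(4), tolerance = 1e-6)

  # posterior-weighted energies agree with brute force on a small instance
  set.seed(127)
  g <- random_genome(1000, seed = 31)
  nm <- nucleosome_model("dinucleotide", footprint = 10L)
  nf <- factor_spec("nuc", "nucleosome", footprint = 10L, gamma = 0.8,
                    log_conc = -1)
  wts <- binding_weights(list(nf), g, nuc_model = nm)
  occ <- site_posteriors(forward_backward(wts), wts)
  ch <- characterize(occ, wts, list(nf))
  e_eff <- nf$gamma * (wts$energies[[1]]$e_sym -
                         mean(wts$energies[[1]]$e_sym))
  P <- occ$posteriors[[1]]
  expect_equal(ch$mean_energy, sum(P * e_eff) / sum(P), tolerance = 1e-9)
  expect_equal(ch$phi, 10 / 1000 * sum(P), tolerance = 1e-12)
})

test_that("positional profiles align strand-aware around anchors", {
  v <- 1:100
  prof <- positional_profile(v, data.frame(position = 49, strand = "+"),
                             window = c(-3, 3))
  expect_equal(prof$mean, 47:53)
  prof_m <- positional_profile(v, data.frame(position = 49, strand = "-"),
                               window = c(-3, 3))
  expect_equal(prof_m$mean, 53:47)  # minus strand flips the offset axis
  # constant track -> flat profile
  profc <- positional_profile(rep(2.5, 100),
                              data.frame(position = c(10, 50, 90),
                                         strand = c("+", "-", "+")),
                              window = c(-5, 5))
  expect_true(all(profc$mean == 2.5))
  expect_true(all(profc$n == 3))
  expect_error(positional_profile(v, data.frame(position = integer(),
                                                strand = character())),
               "empty")
})

test_that("model parameter files round-trip", {
  wm <- generate_wm(6, 8, seed = 13)
  fs <- list(factor_spec("nucleosome", "nucleosome", gamma = 0.5,
                         log_conc = 1.2),
             factor_spec("TF01", "tf", wm = wm, gamma = 0.8,
                         log_conc = -2))
  f <- withr::local_tempfile(fileext = ".yml")
  write_model_params(fs, f)
  back <- read_model_params(f, wms = list(TF01 = wm))
  expect_equal(back[[1]]$log_conc, 1.2)
  expect_equal(back[[2]]$gamma, 0.8)
  expect_equal(back[[2]]$footprint, 6L)
})
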