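test_that("mismatch energies anchor the consensus at zero", {
  wm <- toy_wm()
  expect_equal(wm_energy(wm, "ACA"), 0)
  expect_equal(wm_energy(weight_matrix(matrix(0.25, 2, 4)), "GT"), 0)
  # 2-position worked case: (ln 0.5 - ln 0.25) + 0 = ln 2
  wm2 <- weight_matrix(rbind(c(0.5, 0.25, 0.125, 0.125),
                             c(0.7, 0.1, 0.1, 0.1)))
  expect_equal(wm_energy(wm2, "CA"), log(2), tolerance = 1e-12)
  expect_true(is.na(wm_energy(wm2, "NA")))
  expect_error(wm_energy(wm2, "ACG"), "length")
})

test_that("genome scanning matches direct window evaluation on both strands", {
  set.seed(21)
  g <- random_genome(1000, seed = 8)
  wm <- generate_wm(5, 6, seed = 4)
  f <- factor_spec("t", "tf", wm = wm)
  tr <- scan_genome(f, g)
  ref <- direct_scan(wm, g)
  expect_equal(tr$e_fwd, ref$e_fwd, tolerance = 1e-9)
  expect_equal(tr$e_rev, ref$e_rev, tolerance = 1e-9)
})

test_that("palindromic matrices give identical strand energies", {
  pal <- weight_matrix(rbind(c(0.6, 0.2, 0.1, 0.1),
                             c(0.1, 0.1, 0.2, 0.6)))  # AT-palindrome
  g <- random_genome(1000, seed = 3)
  tr <- scan_genome(factor_spec("p", "tf", wm = pal), g)
  expect_equal(tr$e_fwd, tr$e_rev, tolerance = 1e-12)
})

test_that("N windows are flagged unbindable", {
  g <- genome_sequence("c", paste0(strrep("A", 1000), "N",
                                   strrep("A", 1000)))
  wm <- weight_matrix(matrix(c(0.97, 0.01, 0.01, 0.01), 3, 4, byrow = TRUE))
  tr <- scan_genome(factor_spec("t", "tf", wm = wm), g)
  expect_true(all(is.na(tr$e_fwd[999:1001])))
  expect_equal(tr$e_fwd[1], 0)
})

test_that("E0 calibration makes the mean Boltzmann factor exactly one", {
  # hand example: energies {0, ln 4} at gamma 1 -> E0 = ln 0.625
  e0 <- calibrate_e0(list(e_fwd = c(0, log(4)), e_rev = NULL), 1)
  expect_equal(e0, log(0.625), tolerance = 1e-12)
  expect_equal(calibrate_e0(list(e_fwd = c(0, 1, 2), e_rev = NULL), 0), 0)
  expect_equal(calibrate_e0(list(e_fwd = c(0, 0), e_rev = c(0, 0)), 2), 0)

  set.seed(5)
  g <- random_genome(2000, seed = 9)
  f <- factor_spec("t", "tf", wm = generate_wm(6, 7, seed = 2), gamma = 0.7)
  sc <- scan_genome(f, g)
  e0g <- calibrate_e0(sc, f$gamma)
  e <- c(sc$e_fwd, sc$e_rev)
  expect_equal(mean(exp(-f$gamma * e[is.finite(e)] - e0g)), 1,
               tolerance = 1e-12)
})

test_that("shifting all energies and recalibrating leaves weights unchanged", {
  set.seed(6)
  g <- random_genome(1500, seed = 12)
  f <- factor_spec("t", "tf", wm = generate_wm(5, 5, seed = 3), gamma = 1,
                   log_conc = 0.3)
  tr <- scan_genome(f, g)
  delta <- 2.7
  tr2 <- tr
  tr2$e_fwd <- tr$e_fwd + delta
  tr2$e_rev <- tr$e_rev + delta
  w1 <- binding_weights(list(f), g, energies = list(tr))
  w2 <- binding_weights(list(f), g, energies = list(tr2))
  expect_equal(w1$q[[1]], w2$q[[1]], tolerance = 1e-9)
})

test_that("gamma scales the nucleosome energy SD linearly", {
  g <- random_genome(3000, seed = 7)
  m <- nucleosome_model("dinucleotide")
  tr <- nucleosome_energy(m, g)
  s0 <- stats::sd(tr$e_sym)
  expect_equal(stats::sd(scale_nucleosome_energy(tr, 1)), s0,
               tolerance = 1e-12)
  expect_equal(stats::sd(scale_nucleosome_energy(tr, 0.5)), 0.5 * s0,
               tolerance = 1e-12)
  expect_true(all(scale_nucleosome_energy(tr, 0) == 0))
  # synthetic per-start track with SD 2 kT
  vals <- stats::rnorm(3000 - 146, sd = 2)
  trk <- nucleosome_energy(nucleosome_model("track", values = vals), g)
  expect_equal(stats::sd(scale_nucleosome_energy(trk, 0.5)),
               0.5 * stats::sd(vals), tolerance = 1e-12)
})

test_that("nucleosome energies are strand-symmetric", {
  g <- random_genome(2000, seed = 15)
  grc <- genome_sequence("rc", revcomp_str(g$residues))
  m <- nucleosome_model("dinucleotide")
  e1 <- nucleosome_energy(m, g)$e_sym
  e2 <- nucleosome_energy(m, grc)$e_sym
  expect_equal(e1, rev(e2), tolerance = 1e-9)
})

test_that("WM rescaling follows the exponent semigroup", {
  wm <- toy_wm()
  expect_equal(unclass(rescale_wm(wm, 1)), unclass(wm), tolerance = 1e-12)
  expect_true(all(abs(unclass(rescale_wm(wm, 0)) - 0.25) < 1e-12))
  # two-letter worked case (0.25, 0.75), gamma 2 -> (0.1, 0.9)
  w2 <- weight_matrix(matrix(c(0.25, 0.75, 1e-12, 1e-12), 1) /
                        (1 + 2e-12))
  r <- rescale_wm(w2, 2)
  expect_equal(unname(r[1, 1] / (r[1, 1] + r[1, 2])), 0.1,
               tolerance = 1e-6)
  set.seed(2)
  for (i in 1:10) {
    a <- stats::runif(1, 0.2, 3); b <- stats::runif(1, 0.2, 3)
    lhs <- unclass(rescale_wm(rescale_wm(wm, a), b))
    rhs <- unclass(rescale_wm(wm, a * b))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("information content matches hand arithmetic and limits", {
  uni <- weight_matrix(matrix(0.25, 4, 4))
  expect_equal(information_content(uni), 0, tolerance = 1e-9)
  expect_equal(information_content(uni, gamma = 3), 0, tolerance = 1e-9)
  one <- weight_matrix(matrix(c(0.7, 0.1, 0.1, 0.1), 1))
  expect_equal(information_content(one),
               0.7 * log2(2.8) + 3 * 0.1 * log2(0.4), tolerance = 1e-12)
  # near-delta rows approach 2 bits per position
  d <- weight_matrix(matrix(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 5, 4,
                            byrow = TRUE))
  expect_equal(information_content(d), 10, tolerance = 1e-6)
  expect_error(information_content(one, background = c(0.5, 0.5, 0, 0)),
               "zero background")
})
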