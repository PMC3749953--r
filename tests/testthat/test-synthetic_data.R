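test_that("genome generation respects composition and determinism", {
  g <- generate_genome(10000, gc = 0.5, seed = 5)
  gcfrac <- mean(strsplit(g$residues, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcfrac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(generate_genome(2000, 0.4, seed = 9)$residues,
                   generate_genome(2000, 0.4, seed = 9)$residues)
  expect_error(generate_genome(2000, gc = 1), "strictly inside")
  expect_error(generate_genome(500, 0.5), ">= 1000")
})

test_that("weight-matrix generation reaches the information target", {
  w0 <- generate_wm(6, 0, seed = 2)
  expect_lt(information_content(w0), 1e-6)
  wmax <- generate_wm(4, 8, seed = 3)
  expect_lt(abs(information_content(wmax) - 8), 0.1)
  w8 <- generate_wm(8, 8, seed = 4)
  expect_lt(abs(information_content(w8) - 8), 0.1)
  expect_error(generate_wm(4, 9, seed = 1), "target_bits")
})

test_that("scenarios are reproducible and internally consistent", {
  ov <- list(length = 30000L, n_genes = 6, cells_per_dataset = 200,
             n_tfs = 5, causal_tf_count = 2)
  s1 <- make_scenario("nfr_carving", ov, seed = 4)
  s2 <- make_scenario("nfr_carving", ov, seed = 4)
  expect_identical(s1$genome$residues, s2$genome$residues)
  expect_identical(s1$datasets, s2$datasets)
  expect_identical(s1$truth, s2$truth)
  s3 <- make_scenario("nfr_carving", ov, seed = 5)
  expect_false(identical(s1$datasets, s3$datasets))
  expect_error(make_scenario("bogus"), "phasing_only")

  # every causal TF has a planted site in every promoter
  expect_equal(nrow(s1$planted_sites), 6 * 2)
  # planted sites match the consensus up to the mutation rate
  cons <- nucfree:::consensus_string(s1$wms[[s1$truth$causal[1]]])
  rows <- s1$planted_sites[s1$planted_sites$factor == s1$truth$causal[1], ]
  mism <- vapply(seq_len(nrow(rows)), function(i) {
    seg <- substr(s1$genome$residues, rows$position[i] + 1,
                  rows$position[i] + nchar(cons))
    if (rows$strand[i] == "-") seg <- revcomp_str(seg)
    sum(strsplit(seg, "")[[1]] != strsplit(cons, "")[[1]])
  }, 0)
  expect_lt(mean(mism) / nchar(cons), 0.2)

  # most decoy TFs have no perfect consensus hit in the genome
  decoys <- setdiff(names(s1$wms), s1$truth$causal)
  best <- vapply(decoys, function(nm) {
    tr <- scan_genome(factor_spec(nm, "tf", wm = s1$wms[[nm]]), s1$genome)
    min(c(tr$e_fwd, tr$e_rev), na.rm = TRUE)
  }, 0)
  expect_gt(mean(best > 1e-6), 0.6)
})

test_that("gene bodies carry a ~10 bp A/T periodicity when seeded", {
  sc <- make_scenario("phasing_only",
                      overrides = list(length = 50000L, n_genes = 10,
                                       cells_per_dataset = 100),
                      seed = 6)
  ch <- strsplit(sc$genome$residues, "")[[1]] %in% c("A", "T")
  g <- sc$genes[sc$genes$strand == "+", ][1, ]
  body <- ch[(g$tss + 100):(g$tss + 1800)]
  ac <- stats::acf(as.numeric(body), lag.max = 15, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[8:12]) + 7, 10, tolerance = 1)
})

test_that("sampled read coverage matches the exact occupancy", {
  sc <- make_scenario("phasing_only",
                      overrides = list(length = 20000L, n_genes = 4,
                                       cells_per_dataset = 100), seed = 2)
  w <- binding_weights(sc$factors, sc$genome, nuc_model = sc$nuc_model)
  occ <- site_posteriors(forward_backward(w), w)
  exact <- occ$occupancy[[1]]
  mids <- sample_datasets(sc$factors, sc$genome, sc$nuc_model,
                          n_datasets = 1, cells_per_dataset = 4000,
                          reads_per_nucleosome = 1, pos_noise_sd = 0,
                          seed = 11)[[1]]
  # per-base nucleosome coverage from reads (each midpoint covers +/-73)
  L <- sc$genome$length
  cov <- numeric(L)
  for (m in mids) {
    lo <- max(1L, m - 73 + 1L); hi <- min(L, m + 73 + 1L)
    cov[lo:hi] <- cov[lo:hi] + 1
  }
  cov <- cov / 4000
  # compare region-averaged coverage away from the ends
  idx <- 2000:18000
  expect_lt(abs(mean(cov[idx]) - mean(exact[idx])), 0.02)
  expect_gt(stats::cor(cov[idx], exact[idx]), 0.8)

  # same seed -> identical datasets
  a <- sample_datasets(sc$factors, sc$genome, sc$nuc_model, 2, 100, 0.5,
                       5, seed = 3)
  b <- sample_datasets(sc$factors, sc$genome, sc$nuc_model, 2, 100, 0.5,
                       5, seed = 3)
  expect_identical(a, b)
  # zero positional noise, deterministic read count: midpoints sit at dyads
  one <- sample_datasets(sc$factors, sc$genome, sc$nuc_model, 1, 50, 2,
                         0, seed = 8)[[1]]
  expect_true(all(one >= 0 & one < sc$genome$length))
})

test_that("scenario directories round-trip through standard formats", {
  sc <- make_scenario("nfr_carving",
                      overrides = list(length = 30000L, n_genes = 6,
                                       n_tfs = 4, causal_tf_count = 1,
                                       cells_per_dataset = 100),
                      seed = 7)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  g <- read_fasta(file.path(dir, "genome.fa"))[[1]]
  expect_identical(g$residues, sc$genome$residues)
  genes <- read_genes(file.path(dir, "genes.gff"))
  expect_equal(genes$tss, sc$genes$tss)
  expect_equal(genes$strand, sc$genes$strand)
  wm <- read_wm(file.path(dir, "wms", "TF01.pfm"))[[1]]
  expect_equal(unclass(wm), unclass(sc$wms$TF01), tolerance = 1e-4,
               ignore_attr = TRUE)
  links <- read_links(file.path(dir, "links.tsv"))
  expect_equal(nrow(links), nrow(sc$links))
  truth <- yaml::read_yaml(file.path(dir, "truth.yml"))
  expect_equal(truth$gamma_nuc, sc$truth$gamma_nuc)
})
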