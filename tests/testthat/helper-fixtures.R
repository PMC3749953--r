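# Small in-code fixtures shared across the suite.

# random small binding-weight instance for oracle comparisons
random_instance <- function(L = NULL, max_factors = 3) {
  repeat {
    Li <- if (is.null(L)) sample(10:26, 1) else L
    nf <- sample(seq_len(max_factors), 1)
    fps <- pmin(sample(3:7, nf, replace = TRUE), Li)
    q <- lapply(seq_len(nf), function(f) {
      v <- stats::rexp(Li - fps[f] + 1)
      v[stats::runif(length(v)) < 0.2] <- 0
      v
    })
    w <- raw_weights(q, fps, Li)
    # keep the instance enumerable by the brute-force oracle
    cnt <- numeric(Li + 1)
    cnt[1] <- 1
    for (i in seq_len(Li)) {
      v <- cnt[i]
      for (f in seq_len(nf))
        if (i >= fps[f] && q[[f]][i - fps[f] + 1] > 0)
          v <- v + cnt[i - fps[f] + 1]
      cnt[i + 1] <- v
    }
    if (cnt[Li + 1] <= 5e4) return(w)
  }
}

# deterministic toy weight matrix
toy_wm <- function() {
  weight_matrix(rbind(c(0.7, 0.1, 0.1, 0.1),
                      c(0.1, 0.7, 0.1, 0.1),
                      c(0.25, 0.25, 0.25, 0.25)), name = "toy")
}

random_genome <- function(L = 1000, seed = 1, gc = 0.5) {
  generate_genome(max(L, 1000), gc = gc, seed = seed)
}

# direct per-window energy evaluation (independent of the C++ scanner)
direct_scan <- function(wm, genome) {
  l <- nrow(wm)
  n <- genome$length - l + 1
  ef <- er <- numeric(n)
  for (j in seq_len(n)) {
    seg <- substr(genome$residues, j, j + l - 1)
    ef[j] <- wm_energy(wm, seg)
    er[j] <- wm_energy(wm, revcomp_str(seg))
  }
  list(e_fwd = ef, e_rev = er)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
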