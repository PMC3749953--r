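## thermo_core: exact equilibrium statistics of non-overlapping binding
## configurations. Each configuration C has probability
## P(C) = prod_{sites} q_f(j) / Z with q the calibrated Boltzmann weight;
## Z and all site posteriors come from a forward/backward recursion over
## the chromosome, with a brute-force enumerator as independent oracle.

#' Build per-site Boltzmann weights for a factor set
#'
#' For a TF, `q_f(j) = exp(ln c - gamma*E_fwd(j) - E0) +
#' exp(ln c - gamma*E_rev(j) - E0)` (both orientations share one
#' concentration and are summed). For the nucleosome,
#' `q(j) = exp(ln c - gamma*(E(j) - mean E))` with strand-symmetrized
#' energies. Invalid starts get weight 0.
#'
#' @param factors List of [factor_spec()].
#' @param genome A [genome_sequence()], or `NULL` if `energies` given.
#' @param nuc_model A [nucleosome_model()] for nucleosome-kind factors.
#' @param energies Optional precomputed list of energy tracks (one per
#'   factor, same order), as from [scan_genome()]/[nucleosome_energy()].
#' @return An object of class `binding_weights`: list with `q` (per-factor
#'   weight vectors), `footprints`, `names`, `L`, `e0` and the energy
#'   tracks used.
#' @export
binding_weights <- function(factors, genome = NULL, nuc_model = NULL,
                            energies = NULL) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (is.null(energies)) {
    energies <- lapply(factors, function(f) {
      if (f$kind == "tf") scan_genome(f, genome)
      else {
        if (is.null(nuc_model)) stop("nucleosome factor needs a nuc_model")
        nucleosome_energy(nuc_model, genome)
      }
    })
  }
  L <- if (!is.null(genome)) genome$length else
    max(vapply(seq_along(factors), function(i)
      length(energies[[i]]$e_fwd) + factors[[i]]$footprint - 1L, 0L))
  q <- vector("list", length(factors))
  e0 <- numeric(length(factors))
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    tr <- energies[[i]]
    if (f$kind == "tf") {
      e0[i] <- calibrate_e0(tr, f$gamma)
      qa <- exp(f$log_conc - f$gamma * tr$e_fwd - e0[i])
      qb <- exp(f$log_conc - f$gamma * tr$e_rev - e0[i])
      qa[is.na(qa)] <- 0; qb[is.na(qb)] <- 0
      q[[i]] <- qa + qb
    } else {
      es <- scale_nucleosome_energy(tr, f$gamma)
      qi <- exp(f$log_conc - es)
      qi[is.na(qi)] <- 0
      q[[i]] <- qi
      e0[i] <- 0
    }
    if (length(q[[i]]) != L - f$footprint + 1L)
      stop("energy track length mismatch for factor ", f$name)
  }
  structure(list(q = q, footprints = vapply(factors, `[[`, 0L, "footprint"),
                 names = vapply(factors, `[[`, "", "name"),
                 kinds = vapply(factors, `[[`, "", "kind"),
                 L = as.integer(L), e0 = e0, energies = energies),
            class = "binding_weights")
}

#' Raw binding weights from explicit vectors
#'
#' Low-level constructor used by the oracle tests and small examples.
#'
#' @param q List of per-start weight vectors (0-based start `j` at index
#'   `j+1`; length `L - l + 1` per factor).
#' @param footprints Integer site lengths.
#' @param L Chromosome length.
#' @param names Factor names.
#' @param kinds Factor kinds (`tf`/`nucleosome`).
#' @return A `binding_weights` object.
#' @export
raw_weights <- function(q, footprints, L,
                        names = paste0("f", seq_along(q)),
                        kinds = rep("tf", length(q))) {
  if (!is.list(q)) q <- list(q)
  for (i in seq_along(q)) {
    if (any(q[[i]] < 0)) stop("negative site weight")
    if (length(q[[i]]) != L - footprints[i] + 1L)
      stop("weight vector ", i, " must have length L - footprint + 1")
  }
  structure(list(q = q, footprints = as.integer(footprints), names = names,
                 kinds = kinds, L = as.integer(L),
                 e0 = rep(0, length(q)), energies = NULL),
            class = "binding_weights")
}

#' Forward/backward partition sums
#'
#' `F(i)` sums all configurations on the first `i` bases
#' (`F(i) = F(i-1) + sum_f q_f(i-l_f) F(i-l_f)`, with 0-based starts);
#' `R(i)` mirrors from the right. The recursion runs in the linear domain
#' with block rescaling, so overflow cannot occur; results are returned in
#' log space.
#'
#' @param weights A `binding_weights` object.
#' @return An object of class `partition_sums`: list with `logF` (length
#'   `L+1`, `logF[i+1] = log F(i)`), `logR` (`logR[i+1] = log R(i)`,
#'   `R(L) = 1`) and `logZ`.
#' @export
forward_backward <- function(weights) {
  r <- forward_backward_cpp(weights$q, weights$footprints, weights$L)
  structure(list(logF = r$logF, logR = r$logR, logZ = r$logZ,
                 L = weights$L), class = "partition_sums")
}

#' Site posteriors and occupancy tracks
#'
#' `P_f(j) = F(j) q_f(j) R(j + l_f) / Z` is the probability that a site of
#' factor `f` starts at `j`; per-base occupancy accumulates posteriors over
#' covering sites, and the free fraction completes them to one at every
#' base.
#'
#' @param sums A `partition_sums` from [forward_backward()].
#' @param weights The same `binding_weights` the sums were computed from.
#' @return An object of class `occupancy_result`: `posteriors` (per-factor
#'   vectors over starts), `occupancy` (per-factor per-base vectors),
#'   `free` (per-base), plus factor names.
#' @export
site_posteriors <- function(sums, weights) {
  if (sums$L != weights$L) stop("sums and weights disagree on length")
  r <- posteriors_cpp(sums$logF, sums$logR, sums$logZ, weights$q,
                      weights$footprints, weights$L)
  names(r$posteriors) <- weights$names
  names(r$occupancy) <- weights$names
  structure(list(posteriors = r$posteriors, occupancy = r$occupancy,
                 free = r$free, names = weights$names,
                 kinds = weights$kinds, L = weights$L),
            class = "occupancy_result")
}

#' Total nucleosome occupancy track
#' @param occ An `occupancy_result`.
#' @return Per-base occupancy summed over nucleosome-kind factors.
#' @export
nucleosome_occupancy <- function(occ) {
  idx <- which(occ$kinds == "nucleosome")
  if (length(idx) == 0) stop("no nucleosome-kind factor present")
  Reduce(`+`, occ$occupancy[idx])
}

#' Equilibrium occupancy for a factor set on a genome
#'
#' Convenience wrapper: weights, forward/backward and posteriors in one
#' call.
#'
#' @inheritParams binding_weights
#' @return An `occupancy_result`.
#' @export
compute_occupancy <- function(factors, genome, nuc_model = NULL,
                              energies = NULL) {
  w <- binding_weights(factors, genome, nuc_model, energies)
  site_posteriors(forward_backward(w), w)
}

#' Log weight of one explicit configuration
#'
#' @param config Data frame with columns `factor` (index into the weight
#'   set) and `start` (0-based).
#' @param weights A `binding_weights` object.
#' @return `sum log q` over placed sites; the configuration probability is
#'   `exp(value - logZ)`.
#' @export
configuration_log_weight <- function(config, weights) {
  if (nrow(config) == 0) return(0)
  validate_configuration(config, weights)
  s <- 0
  for (k in seq_len(nrow(config))) {
    f <- config$factor[k]
    q <- weights$q[[f]][config$start[k] + 1L]
    if (q <= 0) return(-Inf)
    s <- s + log(q)
  }
  s
}

#' Validate that a configuration is non-overlapping and in bounds
#' @inheritParams configuration_log_weight
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_configuration <- function(config, weights) {
  if (nrow(config) == 0) return(invisible(TRUE))
  l <- weights$footprints[config$factor]
  if (any(config$start < 0 | config$start + l > weights$L))
    stop("site out of bounds")
  o <- order(config$start)
  s <- config$start[o]; e <- s + l[o]
  if (any(s[-1] < e[-length(e)])) stop("overlapping sites in configuration")
  invisible(TRUE)
}

#' Draw configurations by stochastic traceback
#'
#' Walks from the right end of the chromosome choosing "free base" versus
#' "site ends here" with probabilities proportional to their forward-sum
#' contributions; each draw is an exact sample from the equilibrium
#' configuration distribution. Uses R's RNG (`set.seed()` for
#' reproducibility).
#'
#' @param sums `partition_sums` for `weights`.
#' @param weights A `binding_weights` object.
#' @param n Number of configurations to draw.
#' @return A list of data frames with columns `factor` (index) and `start`
#'   (0-based), or a single data frame if `n = 1`.
#' @export
sample_configuration <- function(sums, weights, n = 1) {
  draws <- lapply(seq_len(n), function(i) {
    m <- sample_config_cpp(sums$logF, weights$q, weights$footprints,
                           weights$L)
    data.frame(factor = m[, 1], start = m[, 2])
  })
  if (n == 1) draws[[1]] else draws
}

#' Brute-force enumeration oracle
#'
#' Exhaustively enumerates all non-overlapping configurations (guarded by a
#' configuration-count estimate), accumulating the partition function and
#' every site posterior by direct summation. Independent of the
#' dynamic-programming implementation; intended for small instances.
#'
#' @param weights A `binding_weights` object with `L <= 30`.
#' @param max_configs Refusal threshold on the enumeration size.
#' @return List with `logZ` and `posteriors` (same shapes as
#'   [site_posteriors()]).
#' @export
brute_force <- function(weights, max_configs = 2e6) {
  L <- weights$L
  if (L > 30) stop("brute force is limited to L <= 30 (got ", L, ")")
  nf <- length(weights$q)
  # count configurations first (counting recursion, weights ignored)
  cnt <- numeric(L + 1)
  cnt[1] <- 1
  for (i in seq_len(L)) {
    v <- cnt[i]
    for (f in seq_len(nf)) {
      l <- weights$footprints[f]
      if (i >= l && weights$q[[f]][i - l + 1] > 0) v <- v + cnt[i - l + 1]
    }
    cnt[i + 1] <- v
  }
  if (cnt[L + 1] > max_configs)
    stop("instance too large: ~", format(cnt[L + 1], big.mark = ","),
         " configurations exceed the enumeration guard")
  Z <- 0
  post <- lapply(seq_len(nf), function(f) numeric(length(weights$q[[f]])))
  sites <- list()  # stack of c(f, j)
  recurse <- function(i, w) {
    if (i > L) {
      Z <<- Z + w
      for (s in sites) post[[s[1]]][s[2]] <<- post[[s[1]]][s[2]] + w
      return(invisible())
    }
    recurse(i + 1, w)  # position i free
    for (f in seq_len(nf)) {
      l <- weights$footprints[f]
      if (i + l - 1 <= L) {
        qf <- weights$q[[f]][i]
        if (qf > 0) {
          sites[[length(sites) + 1]] <<- c(f, i)
          recurse(i + l, w * qf)
          sites[[length(sites)]] <<- NULL
        }
      }
    }
  }
  recurse(1, 1)
  list(logZ = log(Z), posteriors = lapply(post, function(p) p / Z))
}

#' Write occupancy tracks as bedGraph files
#'
#' One file per factor plus `free` and the all-TF total (the browser
#' surface of the model).
#'
#' @param occ An `occupancy_result`.
#' @param chrom Chromosome name for the tracks.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_occupancy_tracks <- function(occ, chrom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(occ$occupancy)) {
    p <- file.path(dir, paste0(occ$names[i], ".bedgraph"))
    write_track(coverage_track(chrom, occ$occupancy[[i]], "probability"), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "free.bedgraph")
  write_track(coverage_track(chrom, pmin(pmax(occ$free, 0), 1),
                             "probability"), p)
  paths <- c(paths, p)
  tf <- which(occ$kinds == "tf")
  if (length(tf)) {
    tot <- Reduce(`+`, occ$occupancy[tf])
    p <- file.path(dir, "all_tf_total.bedgraph")
    write_track(coverage_track(chrom, tot, "probability"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
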