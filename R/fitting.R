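## fitting: maximize the quality score rho over concentrations and
## specificity scales. rho depends on the parameters only through the
## ranking of region medians, so it is piecewise constant; optimization
## therefore combines simulated annealing (exploration) with a
## Nelder-Mead polish, as is standard for non-smooth objectives.

#' Fitting configuration
#'
#' @param t0 Initial annealing temperature on the rho scale.
#' @param cooling Geometric cooling factor per temperature step.
#' @param steps_per_t Metropolis proposals per temperature.
#' @param t_min Final temperature.
#' @param proposal_sd_logc,proposal_sd_gamma Proposal SDs for log
#'   concentrations and specificity scales.
#' @param simplex_reltol,simplex_maxit Nelder-Mead polish controls.
#' @param bounds_logc,bounds_gamma Box bounds (parameters are clamped).
#' @param k_folds Number of cross-validation folds.
#' @param seed RNG seed for proposals and fold assignment.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(t0 = 1.0, cooling = 0.88, steps_per_t = 14,
                       t_min = 1e-3, proposal_sd_logc = 0.3,
                       proposal_sd_gamma = 0.1, simplex_reltol = 1e-4,
                       simplex_maxit = 200, bounds_logc = c(-30, 10),
                       bounds_gamma = c(0, 5), k_folds = 5, seed = 1) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  structure(list(t0 = t0, cooling = cooling, steps_per_t = steps_per_t,
                 t_min = t_min, proposal_sd_logc = proposal_sd_logc,
                 proposal_sd_gamma = proposal_sd_gamma,
                 simplex_reltol = simplex_reltol,
                 simplex_maxit = simplex_maxit, bounds_logc = bounds_logc,
                 bounds_gamma = bounds_gamma, k_folds = k_folds,
                 seed = seed), class = "fit_config")
}

# lighter schedule used for the many 2-parameter single-TF fits in ranking
rank_fit_config <- function(seed = 1, k_folds = 5) {
  fit_config(t0 = 0.5, cooling = 0.8, steps_per_t = 6, t_min = 0.1,
             simplex_maxit = 100, seed = seed, k_folds = k_folds)
}

#' Precompute the model context for fitting
#'
#' Scans the genome once per factor; the context is reused across all
#' objective evaluations (only the parameters change).
#'
#' @param factors List of [factor_spec()].
#' @param genome A [genome_sequence()].
#' @param nuc_model A [nucleosome_model()] for nucleosome-kind factors.
#' @return A `model_context` list.
#' @export
model_context <- function(factors, genome, nuc_model = NULL) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  energies <- vector("list", length(factors))
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    if (f$kind == "tf") {
      tr <- scan_genome(f, genome)
      energies[[i]] <- list(e_fwd = tr$e_fwd, e_rev = tr$e_rev)
    } else {
      if (is.null(nuc_model)) stop("nucleosome factor needs a nuc_model")
      tr <- nucleosome_energy(nuc_model, genome)
      energies[[i]] <- list(e_cen = tr$e_sym - mean(tr$e_sym, na.rm = TRUE))
    }
  }
  structure(list(energies = energies, factors = factors,
                 footprints = vapply(factors, `[[`, 0L, "footprint"),
                 is_nuc = vapply(factors, `[[`, "", "kind") == "nucleosome",
                 names = vapply(factors, `[[`, "", "name"),
                 L = genome$length,
                 e0_cache = new.env(parent = emptyenv())),
            class = "model_context")
}

#' Evaluate the quality score at given parameters
#'
#' The E0 calibration is recomputed internally whenever a TF gamma
#' changes, so it is never a free parameter.
#'
#' @param ctx A [model_context()].
#' @param log_conc,gamma Per-factor parameter vectors (context order).
#' @param regions Scoring regions ([genomic_regions()] with labels).
#' @return List with `rho`, `mi_star`, `c_star`, `entropy`, `logZ`.
#' @export
evaluate_quality <- function(ctx, log_conc, gamma, regions) {
  gamma <- as.numeric(gamma)
  # E0 depends only on a TF's gamma; memoize across objective evaluations
  e0 <- rep(NA_real_, length(ctx$factors))
  if (!is.null(ctx$e0_cache)) {
    for (f in which(!ctx$is_nuc)) {
      key <- sprintf("%d_%.17g", f, gamma[f])
      v <- get0(key, ctx$e0_cache)
      if (is.null(v)) {
        v <- tf_e0_cpp(ctx$energies[[f]]$e_fwd, ctx$energies[[f]]$e_rev,
                       gamma[f])
        assign(key, v, ctx$e0_cache)
      }
      e0[f] <- v
    }
  }
  rho_objective_cpp(ctx$energies, ctx$footprints, ctx$is_nuc,
                    as.numeric(log_conc), gamma, e0, ctx$L,
                    regions$start, regions$end,
                    label_to_int(regions$label))
}

#' Specify free parameters for fitting
#' @param factor Factor names (recycled against `param`).
#' @param param `log_conc` or `gamma`.
#' @return A data.frame understood by [fit_model()].
#' @export
free_params <- function(factor, param) {
  data.frame(factor = factor, param = param, stringsAsFactors = FALSE)
}

clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

# Coarse deterministic grid over one TF's (log_conc, gamma), used to pick
# the starting basin for single-TF fits: the landscape between "absent"
# and "binding" is flat, so local search alone cannot cross it. Ties
# resolve toward the lowest concentration (the nested, TF-absent model).
tf_grid_start <- function(ctx, regions, tf_index,
                          lnc_grid = seq(-12, 4, by = 2),
                          gamma_grid = c(0.5, 1, 1.5)) {
  lnc <- vapply(ctx$factors, `[[`, 0, "log_conc")
  gam <- vapply(ctx$factors, `[[`, 0, "gamma")
  best <- c(lnc_grid[1], gamma_grid[1])
  bestr <- -Inf
  for (lc in lnc_grid) for (g in gamma_grid) {
    lnc[tf_index] <- lc
    gam[tf_index] <- g
    r <- evaluate_quality(ctx, lnc, gam, regions)$rho
    if (r > bestr + 1e-12) { bestr <- r; best <- c(lc, g) }
  }
  best
}

#' Fit concentrations and specificity scales to a reference map
#'
#' Maximizes rho on the supplied regions by simulated annealing
#' (Metropolis on -rho) followed by a Nelder-Mead polish; deterministic
#' given `config$seed`.
#'
#' @param ctx A [model_context()] (holds the factors and their energies).
#' @param regions Training regions with labels.
#' @param free A [free_params()] table (subset of
#'   `{log_conc, gamma} x factors`); empty means evaluate-only.
#' @param config A [fit_config()].
#' @return List of class `fit_result`: fitted `factors`, `log_conc`,
#'   `gamma`, `rho`, and the annealing `trace` (objective per accepted
#'   move).
#' @export
fit_model <- function(ctx, regions, free, config = fit_config()) {
  lnc0 <- vapply(ctx$factors, `[[`, 0, "log_conc")
  gam0 <- vapply(ctx$factors, `[[`, 0, "gamma")
  if (nrow(free) == 0) {
    ev <- evaluate_quality(ctx, lnc0, gam0, regions)
    return(structure(list(factors = ctx$factors, log_conc = lnc0,
                          gamma = gam0, rho = ev$rho, trace = numeric(0)),
                     class = "fit_result"))
  }
  fidx <- match(free$factor, ctx$names)
  if (anyNA(fidx)) stop("unknown factor in free parameter table")
  is_gamma <- free$param == "gamma"
  par0 <- ifelse(is_gamma, gam0[fidx], lnc0[fidx])
  unpack <- function(par) {
    par <- ifelse(is_gamma, clamp(par, config$bounds_gamma),
                  clamp(par, config$bounds_logc))
    lnc <- lnc0; gam <- gam0
    lnc[fidx[!is_gamma]] <- par[!is_gamma]
    gam[fidx[is_gamma]] <- par[is_gamma]
    list(lnc = lnc, gam = gam)
  }
  objective <- function(par) {
    p <- unpack(par)
    -evaluate_quality(ctx, p$lnc, p$gam, regions)$rho
  }
  oldseed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(config$seed)
  f0 <- objective(par0)
  if (!is.finite(f0))
    stop("objective non-finite at the starting point; parameters: ",
         paste(sprintf("%.3g", par0), collapse = ", "))
  cur <- par0; fcur <- f0
  best <- par0; fbest <- f0
  trace <- f0
  sd_vec <- ifelse(is_gamma, config$proposal_sd_gamma,
                   config$proposal_sd_logc)
  temp <- config$t0
  np <- length(par0)
  while (temp > config$t_min) {
    for (s in seq_len(config$steps_per_t)) {
      j <- if (np == 1) 1L else sample.int(np, 1)
      prop <- cur
      prop[j] <- prop[j] + stats::rnorm(1, 0, sd_vec[j])
      prop[j] <- if (is_gamma[j]) clamp(prop[j], config$bounds_gamma) else
        clamp(prop[j], config$bounds_logc)
      fprop <- objective(prop)
      if (fprop <= fcur || stats::runif(1) < exp((fcur - fprop) / temp)) {
        cur <- prop; fcur <- fprop
        trace <- c(trace, fcur)
        if (fcur < fbest) { best <- cur; fbest <- fcur }
      }
    }
    temp <- temp * config$cooling
  }
  # Nelder-Mead polish from the annealing optimum
  if (np == 1) {
    opt <- stats::optim(best, objective, method = "Brent",
                        lower = if (is_gamma[1]) config$bounds_gamma[1] else
                          config$bounds_logc[1],
                        upper = if (is_gamma[1]) config$bounds_gamma[2] else
                          config$bounds_logc[2])
  } else {
    opt <- stats::optim(best, objective, method = "Nelder-Mead",
                        control = list(reltol = config$simplex_reltol,
                                       maxit = config$simplex_maxit))
  }
  if (opt$value < fbest) { best <- opt$par; fbest <- opt$value }
  p <- unpack(best)
  factors <- ctx$factors
  for (i in seq_along(factors)) {
    factors[[i]]$log_conc <- p$lnc[i]
    factors[[i]]$gamma <- p$gam[i]
  }
  structure(list(factors = factors, log_conc = p$lnc, gamma = p$gam,
                 rho = -fbest, trace = -trace), class = "fit_result")
}

#' Stratified k-fold split of scoring regions
#'
#' Random partition with fold sizes differing by at most one, stratified
#' by label so each fold carries both nucleosomes and linkers (falls back
#' to unstratified with a warning if a label has fewer members than
#' folds).
#'
#' @param regions A [genomic_regions()] table.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of `k` integer index vectors (disjoint, union = all rows).
#' @export
kfold_split <- function(regions, k, seed = 1) {
  n <- nrow(regions)
  if (n < k) stop("fewer regions than folds")
  oldseed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  lab <- regions$label
  if (min(table(lab)) < k) {
    warning("a label has fewer than k members; unstratified split")
    ord <- sample.int(n)
  } else {
    ord <- c(sample(which(lab == "nucleosome")),
             sample(which(lab == "linker")))
  }
  fold <- rep_len(seq_len(k), n)
  split(ord, fold)
}

#' Cross-validated fitting
#'
#' Fits on each training set and evaluates rho on the held-out fold;
#' reports the per-fold and mean test quality with its standard error.
#'
#' @inheritParams fit_model
#' @param folds Optional precomputed [kfold_split()] folds (index
#'   vectors); defaults to a fresh split from `config`.
#' @return List of class `cv_result`: `folds`, `fold_fits`, `train_rho`,
#'   `test_rho`, `mean_test_rho`, `se_test_rho`, `log_conc` / `gamma`
#'   matrices (fold x factor) and their means.
#' @export
cross_validate <- function(ctx, regions, free, config = fit_config(),
                           folds = NULL) {
  if (is.null(folds)) folds <- kfold_split(regions, config$k_folds,
                                           config$seed)
  k <- length(folds)
  fold_fits <- vector("list", k)
  train_rho <- test_rho <- numeric(k)
  lncm <- gamm <- matrix(0, k, length(ctx$factors),
                         dimnames = list(NULL, ctx$names))
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train <- validate_regions(regions[-test_idx, , drop = FALSE])
    test <- validate_regions(regions[test_idx, , drop = FALSE])
    cfg <- config
    cfg$seed <- config$seed + i * 1000L
    fit <- fit_model(ctx, train, free, cfg)
    fold_fits[[i]] <- fit
    train_rho[i] <- fit$rho
    test_rho[i] <- evaluate_quality(ctx, fit$log_conc, fit$gamma, test)$rho
    lncm[i, ] <- fit$log_conc
    gamm[i, ] <- fit$gamma
  }
  structure(list(folds = folds, fold_fits = fold_fits,
                 train_rho = train_rho, test_rho = test_rho,
                 mean_test_rho = mean(test_rho),
                 se_test_rho = stats::sd(test_rho) / sqrt(k),
                 log_conc = lncm, gamma = gamm,
                 log_conc_mean = colMeans(lncm), gamma_mean = colMeans(gamm)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean test rho = %.4f +/- %.4f (%d folds)\n",
              x$mean_test_rho, x$se_test_rho, length(x$folds)))
  invisible(x)
}

#' Rank TFs by their paired cross-validated quality gain
#'
#' For each TF, the model "nucleosome + this TF" is fitted per fold with
#' the nucleosome parameters fixed at the nucleosome-only per-fold optimum
#' and the folds shared with the baseline, so the per-fold quality
#' difference is paired. TFs are ranked by `z = mean(delta) / SE(delta)`.
#'
#' @param tf_factors List of TF [factor_spec()]s to rank.
#' @param baseline_cv A [cross_validate()] result for the nucleosome-only
#'   model (provides folds and per-fold nucleosome parameters).
#' @param nuc_factor The nucleosome [factor_spec()] used in the baseline.
#' @param genome A [genome_sequence()].
#' @param regions The same scoring regions used for the baseline.
#' @param nuc_model A [nucleosome_model()].
#' @param config A [fit_config()] for the per-TF fits (defaults to a
#'   light annealing schedule suited to 2-parameter fits).
#' @param control Flag recorded per TF (`real` or `shuffled`).
#' @param tf_start_log_conc Concentration anchoring the low end of the
#'   per-fold starting grid (the nested, TF-absent model). Each per-TF
#'   fit first scans a coarse deterministic grid over the TF's two
#'   parameters and then refines from the best cell, so a TF enters the
#'   model only when some grid cell improves the training objective.
#' @return A `data.frame` of class `tf_ranking`, ordered by decreasing z:
#'   columns `tf`, `mean_delta`, `se_delta`, `z`, `control`.
#' @export
rank_tfs <- function(tf_factors, baseline_cv, nuc_factor, genome, regions,
                     nuc_model, config = NULL, control = "real",
                     tf_start_log_conc = -12) {
  k <- length(baseline_cv$folds)
  if (is.null(config)) config <- rank_fit_config(k_folds = k)
  nuc_tr <- nucleosome_energy(nuc_model, genome)
  nuc_energy <- list(e_cen = nuc_tr$e_sym - mean(nuc_tr$e_sym, na.rm = TRUE))
  rows <- vector("list", length(tf_factors))
  for (t in seq_along(tf_factors)) {
    tf <- tf_factors[[t]]
    tf$log_conc <- tf_start_log_conc
    tr <- scan_genome(tf, genome)
    ctx <- structure(list(
      energies = list(nuc_energy, list(e_fwd = tr$e_fwd, e_rev = tr$e_rev)),
      factors = list(nuc_factor, tf),
      footprints = c(nuc_factor$footprint, tf$footprint),
      is_nuc = c(TRUE, FALSE), names = c(nuc_factor$name, tf$name),
      L = genome$length), class = "model_context")
    free <- free_params(tf$name, c("log_conc", "gamma"))
    delta <- numeric(k)
    for (i in seq_len(k)) {
      test_idx <- baseline_cv$folds[[i]]
      train <- validate_regions(regions[-test_idx, , drop = FALSE])
      test <- validate_regions(regions[test_idx, , drop = FALSE])
      # nucleosome fixed at the per-fold baseline optimum
      ctx$factors[[1]]$log_conc <- baseline_cv$log_conc[i, nuc_factor$name]
      ctx$factors[[1]]$gamma <- baseline_cv$gamma[i, nuc_factor$name]
      cfg <- config
      cfg$seed <- config$seed + i * 1000L + t
      gs <- tf_grid_start(ctx, train, 2L,
                          lnc_grid = seq(tf_start_log_conc, 4, by = 2))
      ctx$factors[[2]]$log_conc <- gs[1]
      ctx$factors[[2]]$gamma <- gs[2]
      fit <- fit_model(ctx, train, free, cfg)
      rho_tf <- evaluate_quality(ctx, fit$log_conc, fit$gamma, test)$rho
      delta[i] <- rho_tf - baseline_cv$test_rho[i]
    }
    m <- mean(delta)
    se <- stats::sd(delta) / sqrt(k)
    z <- if (se > 0) m / se else if (m == 0) 0 else {
      warning("zero SE with nonzero mean for TF ", tf$name,
              "; z set to +/-Inf")
      sign(m) * Inf
    }
    rows[[t]] <- data.frame(tf = tf$name, mean_delta = m, se_delta = se,
                            z = z, control = control,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$z), ]
  rownames(out) <- NULL
  class(out) <- c("tf_ranking", "data.frame")
  out
}

#' Shuffle the columns (positions) of a weight matrix
#'
#' A uniformly random permutation of the position rows: base composition
#' and information content are conserved, positional structure is
#' destroyed — the null model for TF ranking.
#'
#' @param wm A [weight_matrix()].
#' @param seed Optional RNG seed.
#' @return A shuffled [weight_matrix()].
#' @export
shuffle_wm_columns <- function(wm, seed = NULL) {
  if (!is.null(seed)) {
    oldseed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(oldseed))
      assign(".Random.seed", oldseed, globalenv()))
    set.seed(seed)
  }
  n <- wm_length(wm)
  if (n < 2) return(wm)
  perm <- sample.int(n)
  weight_matrix(unclass(wm)[perm, , drop = FALSE],
                name = paste0(attr(wm, "name"), "_shuf"),
                pseudocount = attr(wm, "pseudocount"))
}

#' Biophysical characterization of fitted factors
#'
#' Per factor: genome coverage fraction `phi = (l/L) sum_j P(j)`, the
#' posterior-weighted mean and SD of the (scaled) site energies, and the
#' site-distribution entropy `S = -sum pi log pi` with
#' `pi = P(j)/sum P` — high when coverage comes from many weak sites.
#' `entropy_mode = "binary"` instead averages the per-site binary entropy
#' of occupancy over bound sites.
#'
#' @param occ An `occupancy_result` from [site_posteriors()].
#' @param weights The `binding_weights` used (for energies and scales).
#' @param factors The factor list (for gamma and footprints).
#' @param entropy_mode `site_distribution` (default) or `binary`.
#' @return A `data.frame`: `factor`, `phi`, `mean_energy`, `sd_energy`,
#'   `entropy`.
#' @export
characterize <- function(occ, weights, factors,
                         entropy_mode = c("site_distribution", "binary")) {
  entropy_mode <- match.arg(entropy_mode)
  L <- occ$L
  rows <- lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    P <- occ$posteriors[[i]]
    tot <- sum(P)
    if (tot <= 0)
      return(data.frame(factor = f$name, phi = 0, mean_energy = NA_real_,
                        sd_energy = NA_real_, entropy = NA_real_))
    tr <- weights$energies[[i]]
    if (f$kind == "tf") {
      wgt <- (exp(-f$gamma * tr$e_fwd) + exp(-f$gamma * tr$e_rev)) / 2
      e_eff <- -log(wgt)
      e_eff[is.na(e_eff)] <- 0
    } else {
      e_eff <- f$gamma * (tr$e_sym - mean(tr$e_sym, na.rm = TRUE))
      e_eff[is.na(e_eff)] <- 0
    }
    me <- sum(P * e_eff) / tot
    se <- sqrt(pmax(sum(P * e_eff^2) / tot - me^2, 0))
    ent <- if (entropy_mode == "site_distribution") {
      pi <- P[P > 0] / tot
      -sum(pi * log(pi))
    } else {
      p <- P[P > 0 & P < 1]
      sum(-(p * log(p) + (1 - p) * log(1 - p))) / tot
    }
    data.frame(factor = f$name, phi = f$footprint / L * tot,
               mean_energy = me, sd_energy = se, entropy = ent)
  })
  do.call(rbind, rows)
}

#' Average a track around anchor positions
#'
#' Strand-aware alignment (minus-strand anchors are flipped) and per-offset
#' means with bookkeeping of how many anchors contribute at each offset.
#'
#' @param track Per-base numeric vector or [coverage_track()].
#' @param anchors `data.frame` with columns `position` (0-based) and
#'   `strand` (`+`/`-`).
#' @param window Offsets relative to the anchor, `c(lo, hi)`.
#' @return A `data.frame`: `offset`, `mean`, `n`.
#' @export
positional_profile <- function(track, anchors, window = c(-500, 500)) {
  v <- if (inherits(track, "coverage_track")) track$values else track
  if (nrow(anchors) == 0) stop("empty anchor list")
  offs <- window[1]:window[2]
  s <- numeric(length(offs))
  n <- integer(length(offs))
  L <- length(v)
  for (a in seq_len(nrow(anchors))) {
    pos <- anchors$position[a]
    dir <- if (anchors$strand[a] == "-") -1L else 1L
    idx <- pos + dir * offs + 1L
    ok <- idx >= 1L & idx <= L
    s[ok] <- s[ok] + v[idx[ok]]
    n[ok] <- n[ok] + 1L
  }
  data.frame(offset = offs, mean = ifelse(n > 0, s / n, NA_real_), n = n)
}

#' Write / read fitted model parameters (YAML)
#'
#' @param factors List of [factor_spec()].
#' @param path Output path.
#' @export
write_model_params <- function(factors, path) {
  recs <- lapply(factors, function(f)
    list(factor = f$name, kind = f$kind, footprint = f$footprint,
         ln_conc = f$log_conc, gamma = f$gamma, e0 = f$e0))
  yaml::write_yaml(list(factors = recs), path)
  invisible(path)
}

#' @rdname write_model_params
#' @param wms Named list of weight matrices to attach to TF entries.
#' @export
read_model_params <- function(path, wms = NULL) {
  y <- yaml::read_yaml(path)
  lapply(y$factors, function(r)
    factor_spec(r$factor, r$kind,
                wm = if (r$kind == "tf") wms[[r$factor]] else NULL,
                gamma = r$gamma, log_conc = r$ln_conc,
                footprint = r$footprint, e0 = r$e0))
}
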