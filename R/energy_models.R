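## energy_models: sequence specificities -> binding energies and Boltzmann
## weights. Energies use the mismatch convention (consensus = 0, in kT with
## beta = 1); the additive freedom of the sequence-independent offset is
## absorbed by the E0 calibration, and the specificity scale gamma acts as an
## exponent on the Boltzmann weight so that gamma = 0 means no specificity
## and gamma = 1 the base model.

#' Construct a binding-species specification
#'
#' One binding species: a transcription factor (with a weight matrix) or the
#' nucleosome (147-bp footprint, sequence model supplied separately).
#'
#' @param name Factor identifier.
#' @param kind `tf` or `nucleosome`.
#' @param wm A [weight_matrix()] (TFs only; fixes the footprint).
#' @param gamma Specificity scale, >= 0 (0 = no sequence preference,
#'   1 = base model).
#' @param log_conc Natural log of the factor concentration.
#' @param footprint Site length in bp (defaults to the WM length for TFs,
#'   147 for nucleosomes).
#' @param e0 Calibration offset; normally set by [calibrate_e0()].
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, kind = c("tf", "nucleosome"), wm = NULL,
                        gamma = 1, log_conc = 0, footprint = NULL, e0 = 0) {
  kind <- match.arg(kind)
  if (gamma < 0) stop("gamma must be >= 0")
  if (kind == "tf") {
    if (is.null(wm)) stop("a TF needs a weight matrix")
    footprint <- wm_length(wm)
  } else if (is.null(footprint)) footprint <- 147L
  if (footprint < 1) stop("footprint must be >= 1")
  structure(list(name = as.character(name), kind = kind,
                 footprint = as.integer(footprint), wm = wm,
                 gamma = gamma, log_conc = log_conc, e0 = e0),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s (%s): footprint %d, gamma %.3g, ln c %.3g\n",
              x$name, x$kind, x$footprint, x$gamma, x$log_conc))
  invisible(x)
}

#' Mismatch binding energy of one segment under a weight matrix
#'
#' `E(s) = sum_i [log w(i, a_max) - log w(i, s_i)]` in kT; the consensus
#' sequence scores exactly 0 and all energies are >= 0.
#'
#' @param wm A [weight_matrix()].
#' @param segment Character scalar of the same length as the matrix.
#' @return Energy in kT, or `NA` (unbindable) if the segment contains `N`.
#' @export
wm_energy <- function(wm, segment) {
  segment <- toupper(segment)
  if (nchar(segment) != wm_length(wm))
    stop("segment length ", nchar(segment), " != WM length ", wm_length(wm))
  idx <- match(strsplit(segment, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  lw <- log(wm)
  sum(apply(lw, 1, max) - lw[cbind(seq_len(nrow(wm)), idx)])
}

#' Scan a genome with a factor's energy model
#'
#' For TFs, both strands are scanned (the reverse-strand energy at start `j`
#' is the energy of the reverse complement of the window). Positions whose
#' window contains `N` or runs off the end are invalid and carry Boltzmann
#' weight 0 downstream.
#'
#' @param factor A [factor_spec()] of kind `tf`.
#' @param genome A [genome_sequence()].
#' @return An `energy_track`: list with `factor`, `chrom`, `e_fwd`, `e_rev`
#'   (energies per 0-based start, `NA` where invalid) and `footprint`.
#' @export
scan_genome <- function(factor, genome) {
  stopifnot(inherits(factor, "factor_spec"))
  if (factor$kind != "tf")
    stop("use nucleosome_energy() for nucleosome-kind factors")
  l <- factor$footprint
  if (genome$length < l) {
    warning("genome shorter than footprint; empty track")
    return(energy_track(factor$name, genome$name, numeric(0), numeric(0), l))
  }
  sc <- scan_wm_cpp(encode_sequence(genome), log(unclass(factor$wm)))
  energy_track(factor$name, genome$name, sc$e_fwd, sc$e_rev, l)
}

energy_track <- function(factor, chrom, e_fwd, e_rev, footprint,
                         kind = "tf") {
  structure(list(factor = factor, chrom = chrom, e_fwd = e_fwd,
                 e_rev = e_rev, footprint = as.integer(footprint),
                 kind = kind),
            class = "energy_track")
}

#' Calibrate the sequence-independent energy offset
#'
#' Sets `E0 = log mean exp(-gamma * E)` over all valid windows on both
#' strands, so that after calibration the genome-wide mean Boltzmann factor
#' `exp(-gamma*E - E0)` is exactly 1 ("equal binding to the genome" across
#' factors in the low-concentration limit).
#'
#' @param track An `energy_track` from [scan_genome()].
#' @param gamma Specificity scale.
#' @return The offset `E0` (natural log units).
#' @export
calibrate_e0 <- function(track, gamma) {
  e <- c(track$e_fwd, track$e_rev)
  e <- e[is.finite(e)]
  if (length(e) == 0) stop("no valid windows to calibrate on")
  x <- -gamma * e
  m <- max(x)
  m + log(mean(exp(x - m)))
}

## ------------------------------------------------------- nucleosome model

#' Define a nucleosome sequence-specificity model
#'
#' Either a precomputed per-start energy track (one value per 147-bp window
#' start) or a built-in dinucleotide model: 16 log-propensities combined
#' with a cosine positional weighting of period 10.2 bp across the window,
#' mimicking the helical-phase preference of bendable dinucleotides.
#'
#' @param kind `dinucleotide` or `track`.
#' @param log_propensities Named numeric vector of 16 dinucleotide
#'   log-propensities (names `AA`..`TT`); defaults favour AA/TT/TA steps.
#' @param period Positional weighting period in bp (default 10.2).
#' @param amplitude Cosine amplitude of the positional weighting.
#' @param footprint Window size in bp (147).
#' @param values For `kind = "track"`: numeric per-start energies.
#' @return An object of class `nucleosome_model`.
#' @export
nucleosome_model <- function(kind = c("dinucleotide", "track"),
                             log_propensities = NULL, period = 10.2,
                             amplitude = 0.5, footprint = 147L,
                             values = NULL) {
  kind <- match.arg(kind)
  if (kind == "dinucleotide") {
    if (is.null(log_propensities)) log_propensities <- default_dinuc_lp()
    nm <- dinuc_names()
    if (!all(nm %in% names(log_propensities)))
      stop("log_propensities must be named with all 16 dinucleotides")
    log_propensities <- log_propensities[nm]
  } else {
    if (is.null(values)) stop("track model needs per-start energy values")
    if (anyNA(values))
      stop("track model missing positions (NA) at starts: ",
           paste(utils::head(which(is.na(values)), 5), collapse = ", "))
  }
  structure(list(kind = kind, log_propensities = log_propensities,
                 period = period, amplitude = amplitude,
                 footprint = as.integer(footprint), values = values),
            class = "nucleosome_model")
}

dinuc_names <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}

# Built-in stand-in propensities: AA/TT/TA steps are favoured (flexible,
# minor-groove-in), G/C-rich steps disfavoured; zero-centred.
default_dinuc_lp <- function() {
  lp <- stats::setNames(rep(0, 16), dinuc_names())
  lp[c("AA", "TT")] <- 0.30
  lp["TA"] <- 0.20
  lp["AT"] <- 0.10
  lp[c("GC", "CG")] <- -0.25
  lp[c("GG", "CC")] <- -0.20
  lp - mean(lp)
}

#' Nucleosome binding energies across a genome
#'
#' Computes the raw model energy of every 147-bp window. Strand handling:
#' the Boltzmann weights of each window and its reverse complement are
#' averaged before conversion back to an energy, so occupancy is
#' strand-symmetric. The returned track carries raw (unscaled) energies;
#' apply [scale_nucleosome_energy()] or let [binding_weights()] apply the
#' centred `gamma` scaling.
#'
#' @param model A [nucleosome_model()].
#' @param genome A [genome_sequence()].
#' @return An `energy_track` with field `e_sym` (symmetrized energies per
#'   0-based start) and `kind = "nucleosome"`.
#' @export
nucleosome_energy <- function(model, genome) {
  l <- model$footprint
  if (genome$length < l) {
    warning("genome shorter than nucleosome footprint; empty track")
    tr <- energy_track("nucleosome", genome$name, numeric(0), numeric(0), l,
                       kind = "nucleosome")
    tr$e_sym <- numeric(0)
    return(tr)
  }
  if (model$kind == "track") {
    n <- genome$length - l + 1
    if (length(model$values) != n)
      stop("track model has ", length(model$values),
           " positions, expected ", n)
    e_sym <- as.numeric(model$values)
  } else {
    k <- seq_len(l - 1)
    posw <- 1 + model$amplitude * cos(2 * pi * (k - 1) / model$period)
    sc <- scan_dinuc_cpp(encode_sequence(genome),
                         as.numeric(model$log_propensities), posw, l)
    # strand-symmetrize on the Boltzmann scale
    e_sym <- ifelse(is.na(sc$e_fwd), NA_real_,
                    -log((exp(-sc$e_fwd) + exp(-sc$e_rc)) / 2))
  }
  tr <- energy_track("nucleosome", genome$name, e_sym, e_sym, l,
                     kind = "nucleosome")
  tr$e_sym <- e_sym
  tr
}

#' Centre and scale nucleosome energies
#'
#' `E_scaled(s) = gamma * (E(s) - mean_s E)`: the genome-wide standard
#' deviation of the scaled energies is exactly `gamma` times that of the
#' base model, so `gamma = 0` removes sequence preference entirely and
#' `gamma = 1` reproduces the base model's specificity. The mean shift is
#' absorbed by the nucleosome concentration.
#'
#' @param track An `energy_track` from [nucleosome_energy()].
#' @param gamma Nucleosome specificity scale, >= 0.
#' @return Numeric vector of scaled energies (NA at invalid starts).
#' @export
scale_nucleosome_energy <- function(track, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  e <- track$e_sym
  gamma * (e - mean(e, na.rm = TRUE))
}

## ------------------------------------------------------------- WM algebra

#' Rescale a weight matrix by a specificity exponent
#'
#' `w'(i,a) = w(i,a)^gamma / sum_b w(i,b)^gamma`. `gamma = 0` gives uniform
#' rows, `gamma = 1` the identity; composition multiplies exponents.
#'
#' @param wm A [weight_matrix()].
#' @param gamma Exponent, >= 0.
#' @return A rescaled [weight_matrix()].
#' @export
rescale_wm <- function(wm, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  lw <- gamma * log(unclass(wm))
  lw <- lw - apply(lw, 1, max)        # log-space, guards large exponents
  m <- pmax(exp(lw), 1e-300)
  m <- m / rowSums(m)
  weight_matrix(m, name = attr(wm, "name"),
                pseudocount = attr(wm, "pseudocount"))
}

#' Information content of a (rescaled) weight matrix
#'
#' `I = sum_i sum_a w'(i,a) log2(w'(i,a) / b_a)` with `w'` the
#' gamma-rescaled matrix and `b` the background distribution.
#'
#' @param wm A [weight_matrix()].
#' @param gamma Specificity exponent applied before scoring (default 1).
#' @param background Background base probabilities (default uniform).
#' @return Information content in bits.
#' @export
information_content <- function(wm, gamma = 1, background = rep(0.25, 4)) {
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  w <- unclass(if (gamma == 1) wm else rescale_wm(wm, gamma))
  if (any(background == 0 & colSums(w) > 0))
    stop("zero background entry with nonzero matrix weight")
  sum(w * log2(sweep(w, 2, background, "/")))
}
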