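## synthetic_data: fully specified synthetic study systems — genome, factor
## specificities, ground-truth thermodynamic model, exact configuration
## samples converted to noisy multi-dataset reads, gene annotation and a toy
## protein-link table — so every pipeline stage is testable with recorded
## truth. Every generator is a pure function of (parameters, seed).

with_seed <- function(seed, expr) {
  oldseed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random genome sequence
#'
#' i.i.d. bases at the requested G+C composition.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc G+C fraction, strictly inside (0,1).
#' @param seed RNG seed.
#' @param name Sequence name.
#' @return A [genome_sequence()].
#' @export
generate_genome <- function(length, gc = 0.4, seed = 1, name = "chrS") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0,1)")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome_sequence(name, paste(sample(names(p), length, replace = TRUE,
                                       prob = p), collapse = ""))
  })
}

#' Generate a weight matrix with a target information content
#'
#' Rows are drawn from a Dirichlet distribution and the whole matrix is
#' then exponent-rescaled ([rescale_wm()]) until the information content
#' is within 0.1 bits of the target (the rescaling sweeps IC continuously
#' from 0 to 2 bits per position).
#'
#' @param length Number of positions.
#' @param target_bits Target information content in `[0, 2*length]`.
#' @param seed RNG seed.
#' @param name Matrix name.
#' @return A [weight_matrix()].
#' @export
generate_wm <- function(length, target_bits, seed = 1,
                        name = paste0("wm", seed)) {
  if (target_bits < 0 || target_bits > 2 * length)
    stop("target_bits must lie in [0, 2*length]")
  with_seed(seed, {
    g <- matrix(stats::rgamma(4 * length, shape = 1), length, 4)
    w <- weight_matrix((g + 1e-6) / rowSums(g + 1e-6), name = name)
    if (target_bits == 0) return(rescale_wm(w, 0))
    f <- function(logt) information_content(rescale_wm(w, exp(logt))) -
      target_bits
    if (f(10) < 0)
      stop("target information content unreachable for this draw")
    logt <- stats::uniroot(f, c(-8, 10), tol = 1e-10)$root
    out <- rescale_wm(w, exp(logt))
    if (abs(information_content(out) - target_bits) > 0.1)
      stop("failed to reach target information content")
    attr(out, "name") <- name
    out
  })
}

consensus_string <- function(wm) {
  paste(c("A", "C", "G", "T")[apply(unclass(wm), 1, which.max)],
        collapse = "")
}

scenario_defaults <- function(name) {
  common <- list(
    gc = 0.4, wm_length = 12, wm_bits = 13, n_tfs = 20,
    gene_length = 2000, promoter_len = 500, mutation_rate = 0.05,
    n_datasets = 4, cells_per_dataset = 2000,
    reads_per_nucleosome = 0.05, pos_noise_sd = 20,
    target_coverage = 0.81, tf_gamma = 1, causal_log_conc = 0,
    array_spacing = 165, period = 10.2, seed_bias = 0.35,
    barrier_gc = 0.8)
  per <- switch(name,
    phasing_only = list(length = 200000L, n_genes = 40, causal_tf_count = 0,
                        gamma_nuc = 0.5, periodic = TRUE),
    nfr_carving = list(length = 100000L, n_genes = 25, causal_tf_count = 3,
                       gamma_nuc = 0.2, periodic = FALSE),
    mixed = list(length = 100000L, n_genes = 25, causal_tf_count = 3,
                 gamma_nuc = 0.5, periodic = TRUE, barrier_gc = 0),
    null = list(length = 100000L, n_genes = 25, causal_tf_count = 0,
                gamma_nuc = 0, periodic = FALSE),
    stop("unknown scenario '", name,
         "'; options: phasing_only, nfr_carving, mixed, null"))
  utils::modifyList(common, per)
}

# Lay genes on the forward strand at regular slots; alternate strands so
# minus-strand handling is exercised. Promoter = promoter_len bp 5' of TSS.
layout_genes <- function(L, n_genes, gene_length, promoter_len) {
  slot <- promoter_len + gene_length + 500
  spacing <- max(slot, floor((L - 2000) / n_genes))
  starts <- 1000 + (seq_len(n_genes) - 1L) * spacing
  if (any(starts + slot > L - 1000))
    stop("promoter windows do not fit; reduce n_genes or gene_length")
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss <- ifelse(strand == "+", starts + promoter_len,
                starts + promoter_len + gene_length - 1L)
  tes <- ifelse(strand == "+", starts + promoter_len + gene_length - 1L,
                starts + promoter_len)
  gene_annotation(sprintf("gene%02d", seq_len(n_genes)), "chrS", strand,
                  as.integer(tss), as.integer(tes))
}

replace_segment <- function(residues, start0, segment) {
  # start0 is 0-based
  paste0(substr(residues, 1, start0),
         segment,
         substr(residues, start0 + nchar(segment) + 1, nchar(residues)))
}

mutate_segment <- function(segment, rate) {
  if (rate <= 0) return(segment)
  ch <- strsplit(segment, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# Sequence-driven nucleosome structure: a nucleosome-excluding barrier
# element upstream of each TSS (G/C-rich, disfavoured by the dinucleotide
# model, emulating promoter exclusion elements) and a 10.2-bp periodic A/T
# bias through gene bodies. Arrays then emerge from statistical positioning
# against the barriers, with the periodic bias rotationally phasing them.
seed_periodicity <- function(residues, genes, params) {
  ch <- strsplit(residues, "")[[1]]
  for (g in seq_len(nrow(genes))) {
    tss <- genes$tss[g]
    dir <- if (genes$strand[g] == "+") 1L else -1L
    # barrier element ~50-200 bp upstream of the TSS
    bar <- tss - dir * (50:200)
    bar <- bar[bar >= 0 & bar < length(ch)]
    hit <- stats::runif(length(bar)) < params$barrier_gc
    ch[bar[hit] + 1L] <- sample(c("G", "C"), sum(hit), replace = TRUE)
    # rotational phasing signal through the gene body
    body <- 50:(params$gene_length - 50)
    pos <- tss + dir * body
    phase <- cos(2 * pi * body / params$period)
    hit <- phase > 0.55 & stats::runif(length(body)) < params$seed_bias
    if (any(hit)) {
      p <- pos[hit] + 1L
      p <- p[p >= 1 & p <= length(ch)]
      ch[p] <- sample(c("A", "T"), length(p), replace = TRUE)
    }
  }
  paste(ch, collapse = "")
}

# Choose ln c_nuc so the nucleosome-only equilibrium coverage matches the
# target mean (root find on the exact occupancy).
calibrate_nuc_conc <- function(genome, nuc_model, gamma_nuc,
                               target = 0.81) {
  tr <- nucleosome_energy(nuc_model, genome)
  en <- list(list(e_cen = tr$e_sym - mean(tr$e_sym, na.rm = TRUE)))
  f <- function(lnc) {
    nf <- factor_spec("nucleosome", "nucleosome", gamma = gamma_nuc,
                      log_conc = lnc)
    w <- binding_weights(list(nf), genome = NULL, energies = list(tr))
    w$L <- genome$length
    occ <- site_posteriors(forward_backward(w), w)
    mean(occ$occupancy[[1]]) - target
  }
  stats::uniroot(f, c(-4, 8), tol = 1e-4)$root
}

#' Build a synthetic study system with recorded ground truth
#'
#' `phasing_only`: sequence-driven nucleosome arrays, no causal TFs (for
#' specificity/concentration recovery and genome-wide scoring).
#' `nfr_carving`: causal TFs with consensus sites planted in every
#' promoter carve nucleosome-free regions; weak nucleosome specificity.
#' `mixed`: both mechanisms. `null`: no structure at all.
#'
#' @param name One of `phasing_only`, `nfr_carving`, `mixed`, `null`.
#' @param overrides Named list of parameter overrides (see
#'   `nucfree:::scenario_defaults`).
#' @param seed Master seed; the scenario is a pure function of
#'   `(name, overrides, seed)`.
#' @return An object of class `scenario`: `genome`, `genes`, `wms` (all
#'   TFs), `factors` (true binding model: nucleosome + causal TFs),
#'   `nuc_model`, `planted_sites`, `datasets` (per-dataset 0-based read
#'   midpoints), `links`, `categories`, `truth` (all parameters + seed).
#' @export
make_scenario <- function(name, overrides = list(), seed = 1) {
  params <- utils::modifyList(scenario_defaults(name), overrides)
  genome <- generate_genome(params$length, params$gc, seed = seed * 13 + 1)
  genes <- layout_genes(params$length, params$n_genes, params$gene_length,
                        params$promoter_len)
  wms <- lapply(seq_len(params$n_tfs), function(i)
    generate_wm(params$wm_length, params$wm_bits, seed = seed * 1009 + i,
                name = sprintf("TF%02d", i)))
  names(wms) <- vapply(wms, attr, "", "name")
  causal <- if (params$causal_tf_count > 0)
    names(wms)[seq_len(params$causal_tf_count)] else character(0)

  planted <- data.frame(factor = character(), position = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  residues <- genome$residues
  with_seed(seed * 271 + 5, {
    # plant one consensus site per causal TF in every promoter, clustered
    # 150-260 bp upstream of the TSS
    if (length(causal) > 0) {
      for (g in seq_len(nrow(genes))) {
        dir <- if (genes$strand[g] == "+") 1L else -1L
        for (ci in seq_along(causal)) {
          offset <- 150 + 35 * (ci - 1)
          pos <- genes$tss[g] - dir * offset
          start0 <- if (dir == 1L) pos else pos - params$wm_length + 1L
          site <- mutate_segment(consensus_string(wms[[causal[ci]]]),
                                 params$mutation_rate)
          if (dir == -1L) site <- revcomp(site)
          residues <- replace_segment(residues, start0, site)
          planted[nrow(planted) + 1L, ] <-
            list(causal[ci], as.integer(start0),
                 if (dir == 1L) "+" else "-")
        }
      }
    }
    if (isTRUE(params$periodic))
      residues <- seed_periodicity(residues, genes, params)
  })
  genome <- genome_sequence(genome$name, residues)

  nuc_model <- nucleosome_model("dinucleotide", period = params$period)
  lnc_nuc <- calibrate_nuc_conc(genome, nuc_model, params$gamma_nuc,
                                params$target_coverage)
  factors <- list(factor_spec("nucleosome", "nucleosome",
                              gamma = params$gamma_nuc,
                              log_conc = lnc_nuc))
  for (tf in causal)
    factors[[length(factors) + 1L]] <-
      factor_spec(tf, "tf", wm = wms[[tf]], gamma = params$tf_gamma,
                  log_conc = params$causal_log_conc)

  weights <- binding_weights(factors, genome, nuc_model = nuc_model)
  sums <- forward_backward(weights)
  datasets <- lapply(seq_len(params$n_datasets), function(d)
    with_seed(seed * 7919 + d,
              sample_midpoints_cpp(sums$logF, weights$q,
                                   weights$footprints, weights$L,
                                   1L, params$cells_per_dataset,
                                   params$reads_per_nucleosome,
                                   params$pos_noise_sd)))
  names(datasets) <- sprintf("ds%d", seq_len(params$n_datasets))

  lk <- with_seed(seed * 104729 + 7,
                  toy_links(names(wms), causal))

  structure(list(name = name, genome = genome, genes = genes, wms = wms,
                 factors = factors, nuc_model = nuc_model,
                 planted_sites = planted, datasets = datasets,
                 links = lk$links, categories = lk$categories,
                 truth = c(params, list(seed = seed, causal = causal,
                                        log_conc_nuc = lnc_nuc))),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("<scenario> %s: %d bp, %d genes, %d TFs (%d causal), ",
                     "%d datasets\n"), x$name, x$genome$length,
              nrow(x$genes), length(x$wms), length(x$truth$causal),
              length(x$datasets)))
  invisible(x)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Toy STRING-like link table: causal TFs link strongly to chromatin-class
# proteins; decoys link rarely and weakly.
toy_links <- function(tf_names, causal) {
  categories <- list(
    remodelers = sprintf("RMD%d", 1:6),
    modifiers = sprintf("MOD%d", 1:8),
    histones = sprintf("HIS%d", 1:4))
  a <- character(0); b <- character(0); sc <- integer(0)
  for (tf in tf_names) {
    if (tf %in% causal) {
      partners <- c(sample(categories$remodelers, 2),
                    sample(categories$modifiers, 2),
                    sample(categories$histones, 1))
      score <- sample(500:950, length(partners), replace = TRUE)
    } else {
      npart <- stats::rbinom(1, 2, 0.25)
      partners <- if (npart > 0)
        sample(unlist(categories), npart) else character(0)
      score <- sample(150:550, length(partners), replace = TRUE)
    }
    a <- c(a, rep(tf, length(partners)))
    b <- c(b, partners)
    sc <- c(sc, score)
  }
  list(links = link_table(a, b, sc), categories = categories)
}

#' Sample noisy read-midpoint datasets from a true binding model
#'
#' For each dataset, `cells_per_dataset` configurations are drawn exactly
#' from the equilibrium distribution; every placed nucleosome emits
#' `Poisson(reads_per_nucleosome)` midpoints at its dyad plus Gaussian
#' positional noise. Datasets differ only by their RNG substream.
#'
#' @param factors True [factor_spec()] list (first nucleosome-kind factor
#'   is the one sequenced).
#' @param genome A [genome_sequence()].
#' @param nuc_model A [nucleosome_model()].
#' @param n_datasets,cells_per_dataset,reads_per_nucleosome,pos_noise_sd
#'   Read-model parameters.
#' @param seed Master seed.
#' @return List of 0-based integer midpoint vectors, one per dataset.
#' @export
sample_datasets <- function(factors, genome, nuc_model, n_datasets = 4,
                            cells_per_dataset = 2000,
                            reads_per_nucleosome = 0.05, pos_noise_sd = 20,
                            seed = 1) {
  weights <- binding_weights(factors, genome, nuc_model = nuc_model)
  sums <- forward_backward(weights)
  nuc_idx <- which(weights$kinds == "nucleosome")[1]
  out <- lapply(seq_len(n_datasets), function(d)
    with_seed(seed * 7919 + d,
              sample_midpoints_cpp(sums$logF, weights$q,
                                   weights$footprints, weights$L, nuc_idx,
                                   cells_per_dataset, reads_per_nucleosome,
                                   pos_noise_sd)))
  names(out) <- sprintf("ds%d", seq_len(n_datasets))
  out
}

#' Build the consensus reference map of a scenario's datasets
#'
#' Runs per-dataset peak calling on the sampled read midpoints and
#' intersects the calls into a consensus map.
#'
#' @param scenario A [make_scenario()] result.
#' @param min_support Minimum supporting datasets (default: all).
#' @param ... Passed to [call_nucleosomes()]/[build_reference_map()].
#' @return A `reference_map`.
#' @export
scenario_reference_map <- function(scenario,
                                   min_support =
                                     length(scenario$datasets), ...) {
  calls <- lapply(names(scenario$datasets), function(d)
    call_nucleosomes(midpoints = scenario$datasets[[d]],
                     chrom_length = scenario$genome$length, dataset = d,
                     chrom = scenario$genome$name, ...))
  build_reference_map(calls, scenario$genome$length,
                      min_support = min_support)
}

#' Write a scenario to a directory of standard files
#'
#' `genome.fa`, `wms/` (one pfm per TF), `genes.gff`, `datasets/*.tsv`
#' (0-based midpoints), `links.tsv`, `truth.yml`.
#'
#' @param scenario A [make_scenario()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(file.path(dir, "wms"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "datasets"), showWarnings = FALSE)
  write_fasta(scenario$genome, file.path(dir, "genome.fa"))
  for (wm in scenario$wms)
    write_wm(wm, file.path(dir, "wms", paste0(attr(wm, "name"), ".pfm")))
  write_genes(scenario$genes, file.path(dir, "genes.gff"))
  for (d in names(scenario$datasets))
    utils::write.table(data.frame(chrom = scenario$genome$name,
                                  midpoint = scenario$datasets[[d]]),
                       file.path(dir, "datasets", paste0(d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_links(scenario$links, file.path(dir, "links.tsv"))
  truth <- scenario$truth
  truth$causal <- as.list(truth$causal)
  yaml::write_yaml(truth, file.path(dir, "truth.yml"))
  invisible(dir)
}
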