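# nucfree

Exact equilibrium modeling of sequence-specific transcription factors
(TFs) competing with nucleosomes for non-overlapping binding on DNA, and
evaluation of the resulting occupancy predictions against consensus
nucleosome/linker maps.

## Who this is for

Chromatin and regulatory-genomics researchers who want to ask, on a
genome or a synthetic system, how much of nucleosome positioning is
explained by nucleosome sequence preference versus competitive TF
binding: which factors carve nucleosome-free regions (NFRs) in promoters,
how well a thermodynamic model explains an MNase-style reference
annotation, and whether a factor's contribution survives
cross-validation.

## The model

A configuration $C$ of non-overlapping bound sites has probability

$$P(C) = \frac{1}{Z} \prod_{s \in C} e^{\ln c_f - \gamma_f E_f(s) - E^0_f}$$

with per-factor concentration $c_f$, binding energy $E_f$ (from a
position weight matrix for TFs, in the Berg–von-Hippel mismatch
convention with the consensus at $0\,kT$; from a tunable dinucleotide
model for nucleosomes), specificity scale $\gamma_f$ ($0$ = no sequence
preference, $1$ = base model) and a calibrated offset $E^0_f$ that gives
every factor equal genome-wide binding at low concentration. The
partition function $Z$ and all site posteriors
$P_f(j) = F(j) q_f(j) R(j + l_f)/Z$ are computed exactly by a
forward/backward recursion; a stochastic traceback draws exact
configuration samples.

Predictions are scored against a reference map by the quality score
$\rho = I^*/H$: the mutual information between thresholded per-region
median occupancy and the nucleosome/linker annotation, maximized exactly
over the threshold and normalized by the label entropy. Concentrations
and specificity scales are fitted by simulated annealing plus
Nelder–Mead under stratified k-fold cross-validation; TFs are ranked by
the paired z-statistic of their held-out quality gain, with
column-shuffled matrices as the null. Hypergeometric tests quantify the
enrichment of chromatin-associated annotations and protein links among
top-ranked TFs.

A fully synthetic data generator (genomes with planted binding sites and
sequence-encoded nucleosome barriers, exact-model configuration samples
turned into noisy multi-dataset read midpoints, gene annotations, toy
protein-link tables) makes every stage testable with recorded ground
truth — no external data are required.

## Worked example

```r
library(nucfree)
sc  <- make_scenario("nfr_carving", seed = 1)   # 100 kb, 20 TFs, 3 causal
ref <- scenario_reference_map(sc)               # peak calling + consensus
ref
#> <reference_map> 329 nucleosomes, 398 linkers (259 short, 139 NFR) on 100000 bp

ctx <- model_context(sc$factors[1], sc$genome, sc$nuc_model)
cv  <- cross_validate(ctx, ref$regions,
                      free_params("nucleosome", c("log_conc", "gamma")),
                      fit_config(seed = 5))
cv
#> <cv_result> mean test rho = 0.1366 +/- 0.0245 (5 folds)

tfs <- lapply(names(sc$wms), function(n) factor_spec(n, "tf", wm = sc$wms[[n]]))
rk  <- rank_tfs(tfs, cv, sc$factors[[1]], sc$genome, ref$regions, sc$nuc_model)
head(rk, 4)
#>     tf mean_delta    se_delta        z control
#> 1 TF01 0.22499885 0.028601042 7.866806    real
#> 2 TF02 0.14930071 0.019887748 7.507170    real
#> 3 TF03 0.12892814 0.031911246 4.040210    real
#> 4 TF18 0.01558218 0.006372289 2.445304    real
```

The nucleosome-only model explains ~14% of the label information on this
map. The three planted causal TFs take the top three ranks with strongly
positive z-statistics (every decoy sits near or below chance), and with the
true model the promoter-region quality score rises to ~0.87 versus ~0.14
for the nucleosome-only model — the NFRs here are carved by TF
competition, not nucleosome sequence preference.

A thin command-line wrapper over the same functions lives in
`inst/cli/nucfree.R` (`simulate`, `occupancy`, `score`, `enrich`).

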