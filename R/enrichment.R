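## enrichment: over-representation of functional categories and
## protein-interaction links among top-ranked TFs (hypergeometric tests).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: `k` successes in a
#' selection of `n` draws from a background of `N` with `K` successes.
#'
#' @param k Observed successes in the selection.
#' @param n Selection size (draws).
#' @param K Background successes.
#' @param N Background size.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (k < 0 || k > n || n > N || K > N || K < 0)
    stop("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k == 0) return(1)
  # log-space tail via the regularized sum of the pmf
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Fold enrichment
#'
#' `(k/n) / (K/N)`: the rate of successes in the selection relative to the
#' background rate.
#'
#' @inheritParams hypergeom_tail
#' @return The fold-enrichment ratio.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n <= 0 || K <= 0 || N <= 0) stop("n, K and N must be positive")
  (k / n) / (K / N)
}

enrichment_result <- function(k, n, K, N, fold, p) {
  structure(list(k = k, n = n, K = K, N = N, fold = fold, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> k=%d of n=%d (background %d/%d): fold %.3g, p %.3g\n",
              x$k, x$n, x$K, x$N, x$fold, x$p))
  invisible(x)
}

#' Link enrichment among top-ranked TFs
#'
#' Counts protein-interaction links (score >= `score_cutoff`) between any
#' TF and any category protein; `k` of the `n` links touch a top-set TF.
#' The fold enrichment compares `k/n` with the top-set fraction
#' `|top|/|TFs|`; the p-value treats links as exchangeable draws (an
#' approximation, since links are not independent) and is labelled as
#' such.
#'
#' @param links A [link_table()].
#' @param tf_set Character vector of all TF identifiers.
#' @param top_set The selected (top-ranked) TFs.
#' @param category_set Identifiers of the category proteins (e.g.
#'   histones).
#' @param score_cutoff Minimum evidence score (default 400).
#' @return An `enrichment_result` (fields `k`, `n`, `K = |top|`,
#'   `N = |tf_set|`, `fold`, `p`).
#' @export
link_enrichment <- function(links, tf_set, top_set, category_set,
                            score_cutoff = 400) {
  if (length(category_set) == 0) stop("empty category set")
  if (!all(top_set %in% tf_set)) stop("top_set must be a subset of tf_set")
  lk <- links[links$score >= score_cutoff, , drop = FALSE]
  a_tf <- lk$protein_a %in% tf_set & lk$protein_b %in% category_set
  b_tf <- lk$protein_b %in% tf_set & lk$protein_a %in% category_set
  tf_of_link <- c(lk$protein_a[a_tf], lk$protein_b[b_tf])
  n <- length(tf_of_link)
  if (n == 0)
    stop("no TF-category links at score cutoff ", score_cutoff)
  k <- sum(tf_of_link %in% top_set)
  fold <- fold_enrichment(k, n, length(top_set), length(tf_set))
  # exchangeable-links approximation: each link's TF endpoint treated as an
  # independent draw hitting the top set with probability |top|/|TFs|; the
  # fold statistic is exact, this tail probability is approximate
  p <- stats::pbinom(k - 1, n, length(top_set) / length(tf_set),
                     lower.tail = FALSE)
  enrichment_result(k, n, length(top_set), length(tf_set), fold, p)
}

#' Category (gene-set) enrichment of the top TFs
#'
#' Classic hypergeometric over TFs: background `N = |tf_set|` with
#' `K = |annotated|` successes; `k` of the `n` top TFs are annotated.
#'
#' @param top_set Selected TFs.
#' @param tf_set All TFs (background).
#' @param annotated_set Annotated TFs (must be a subset of `tf_set`).
#' @return An `enrichment_result`.
#' @export
category_enrichment <- function(top_set, tf_set, annotated_set) {
  if (!all(annotated_set %in% tf_set))
    stop("annotated_set must be a subset of tf_set")
  if (!all(top_set %in% tf_set))
    stop("top_set must be a subset of tf_set")
  N <- length(tf_set); K <- length(annotated_set); n <- length(top_set)
  k <- length(intersect(top_set, annotated_set))
  enrichment_result(k, n, K, N,
                    fold_enrichment(k, n, K, N),
                    hypergeom_tail(k, n, K, N))
}

#' Chromatin-related GO categories
#'
#' The built-in list of GO identifiers used to flag chromatin-related
#' TFs; extendable via configuration.
#'
#' @return Named character vector of GO ids.
#' @export
chromatin_go_categories <- function() {
  c("GO:0016568" = "chromatin modification",
    "GO:0006338" = "chromatin remodeling",
    "GO:0008301" = "DNA bending activity",
    "GO:0031491" = "nucleosome binding",
    "GO:0003682" = "chromatin binding",
    "GO:0033698" = "Rpd3C(L) histone deacetylase complex")
}
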