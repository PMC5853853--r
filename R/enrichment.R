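# Singular enrichment analysis: per-term over-representation of a study
# gene set against a background via the one-sided Fisher's exact
# (hypergeometric upper-tail) test, BH-adjusted across tested terms.
# Term maps are flat - no ontology DAG propagation.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric with `K` annotated genes in a background
#' of `N`, drawing the study set of size `n`: the one-sided Fisher's exact
#' p-value for over-representation.
#'
#' @param k Study hits (can be a vector).
#' @param K Background hits.
#' @param n Study size.
#' @param N Background size.
#' @return Upper-tail probabilities.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    abort_input("inconsistent 2x2 table: need k <= min(n, K), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Singular enrichment of a study set against a background
#'
#' For each term annotating at least one study gene, tests
#' over-representation of the term among the study genes relative to the
#' background universe with the one-sided Fisher's exact test, then adjusts
#' across terms with Benjamini-Hochberg. Both background modes of the
#' emulated workflow are expressed through the `background` argument: pass
#' the responsive up-/down-regulated set, or the whole expressed universe.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Data frame `gene_id`, `term_id` (flat annotation).
#' @param q_cutoff Significance threshold on q (default 0.05).
#' @return Data frame `term_id`, `k`, `n`, `K`, `N`, `odds_ratio`,
#'   `p_value`, `q_value`, `significant`, sorted by q then p. Zero rows when
#'   no term annotates a study gene.
#' @export
fisher_enrich <- function(study, background, term_map, q_cutoff = 0.05) {
  study <- unique(study)
  background <- unique(background)
  outside <- setdiff(study, background)
  if (length(outside)) {
    abort_input("study set is not a subset of the background (%d offending gene(s))",
                length(outside))
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(study)
  empty <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(tm) == 0) return(empty)
  K_all <- table(tm$term_id)
  k_all <- table(tm$term_id[tm$gene_id %in% study])
  terms <- names(k_all)[k_all > 0]            # k = 0 terms are not tested
  if (!length(terms)) return(empty)
  k <- as.integer(k_all[terms])
  K <- as.integer(K_all[terms])
  p <- hypergeom_upper(k, K, n, N)
  # sample odds ratio of the 2x2 table (study/term margins)
  or_num <- k * (N - K - n + k)
  or_den <- (n - k) * (K - k)
  odds_ratio <- ifelse(or_den == 0, Inf, or_num / or_den)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    odds_ratio = odds_ratio, p_value = p,
                    q_value = bh_adjust(p), stringsAsFactors = FALSE)
  out$significant <- out$q_value <= q_cutoff
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
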