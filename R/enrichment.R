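# Over-representation statistics for GO biological processes: one-sided
# hypergeometric (Fisher) tail or its conservative EASE variant (overlap
# decremented by one), with Benjamini-Hochberg or Bonferroni control.
# Stands in for web-service enrichment tools at desk scale; annotation
# terms are taken as given (no ontology propagation).

#' Hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for drawing `k` annotated genes in a study of
#' size `n` from a population of `N` genes of which `K` carry the
#' annotation. `mode = "ease"` substitutes `max(k - 1, 0)` for `k`, the
#' conservative variant used by classical enrichment services.
#'
#' @param k,n,K,N overlap, study size, term size, population size
#'   (vectorized over `k` and `K`).
#' @param mode `"ease"` or `"fisher"`.
#' @return numeric vector of raw p-values.
#' @export
hypergeom_test <- function(k, n, K, N, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    stop("inconsistent hypergeometric counts (need k <= min(n, K), n <= N, K <= N)",
         call. = FALSE)
  }
  kk <- if (mode == "ease") pmax(k - 1, 0) else k
  stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

check_pvalues <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' Multiple-testing adjustments
#'
#' Thin validated wrappers around [stats::p.adjust()]: `adjust_bh()` is the
#' Benjamini-Hochberg step-up false discovery rate adjustment, and
#' `adjust_bonferroni()` is `min(1, p * m)`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, in input order.
#' @export
adjust_bh <- function(p) stats::p.adjust(check_pvalues(p), method = "BH")

#' @rdname adjust_bh
#' @export
adjust_bonferroni <- function(p) {
  stats::p.adjust(check_pvalues(p), method = "bonferroni")
}

#' Enriched biological processes in a study gene set
#'
#' Tests every annotation term with nonzero study overlap for
#' over-representation, adjusts by Benjamini-Hochberg, and flags terms with
#' adjusted p below `alpha` as enriched. The default population is every
#' gene appearing in any annotation term; study genes outside the
#' population are dropped with a warning.
#'
#' @param study character vector of study gene symbols.
#' @param annotations named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param population character vector of population symbols, or `NULL`.
#' @param alpha adjusted-p threshold for the `enriched` flag.
#' @param mode statistic variant, see [hypergeom_test()].
#' @return data frame with columns `process_id`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adjusted`, `enriched`, sorted by adjusted then raw p then
#'   term id.
#' @export
enriched_processes <- function(study, annotations, population = NULL,
                               alpha = 0.01, mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  if (is.null(population)) population <- unique(unlist(annotations,
                                                       use.names = FALSE))
  population <- unique(as.character(population))
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  study <- unique(as.character(study))
  outside <- setdiff(study, population)
  if (length(outside) > 0L) {
    warning(length(outside),
            " study gene(s) absent from the population were dropped")
    study <- setdiff(study, outside)
  }
  N <- length(population)
  n <- length(study)
  terms <- lapply(annotations, function(s) intersect(unique(s), population))
  K <- lengths(terms)
  k <- vapply(terms, function(s) length(intersect(s, study)), integer(1L))
  keep <- k > 0L
  out <- data.frame(process_id = names(annotations)[keep],
                    k = unname(k[keep]), K = unname(K[keep]),
                    n = n, N = N, stringsAsFactors = FALSE)
  out$p_raw <- if (nrow(out) > 0L) {
    hypergeom_test(out$k, out$n, out$K, out$N, mode = mode)
  } else numeric(0)
  out$p_adjusted <- adjust_bh(out$p_raw)
  out$enriched <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$p_raw, out$process_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
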