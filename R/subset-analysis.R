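# Statistical comparison of gene subsets (e.g. apoptosis, CNS) against the
# remaining network genes, and literature co-mention analysis of the
# top-ranked genes.

#' Compare centralities of a gene subset against the rest of the network
#'
#' Welch's t-test per centrality measure (DC, CC, BC), comparing the
#' aggregated per-symbol values of subset members against all other
#' network symbols.
#'
#' @param profile a [gene_centrality_profile()].
#' @param subset character vector of gene symbols.
#' @return data frame with columns `measure`, `n_in`, `n_out`, `mean_in`,
#'   `mean_out`, `t`, `df`, `p`.
#' @export
subset_centrality_test <- function(profile, subset) {
  stopifnot(inherits(profile, "centrality_profile"))
  in_set <- profile$symbol %in% subset
  if (!any(in_set)) stop("subset does not intersect the network symbols",
                         call. = FALSE)
  if (all(in_set)) stop("subset covers every network symbol: no complement",
                        call. = FALSE)
  rows <- lapply(c(dc = "dc", cc = "cc", bc = "bc"), function(m) {
    w <- welch_test(profile[[m]][in_set], profile[[m]][!in_set])
    data.frame(measure = toupper(m), n_in = sum(in_set),
               n_out = sum(!in_set), mean_in = w$mean_x,
               mean_out = w$mean_y, t = w$t, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Literature co-mention frequency
#'
#' `F = n_comorbid / n_total`, the fraction of abstracts mentioning the
#' gene that also mention "comorbid"/"comorbidity". Genes never mentioned
#' (`n_total = 0`) get `F = NA` and are excluded from downstream tests.
#'
#' @param counts data frame with columns `symbol`, `n_comorbid`, `n_total`.
#' @return the input with an added numeric column `F`.
#' @export
comention_frequency <- function(counts) {
  stopifnot(all(c("symbol", "n_comorbid", "n_total") %in% names(counts)))
  if (any(counts$n_comorbid < 0) || any(counts$n_total < 0)) {
    stop("co-mention counts must be non-negative", call. = FALSE)
  }
  if (any(counts$n_comorbid > counts$n_total)) {
    stop("n_comorbid cannot exceed n_total", call. = FALSE)
  }
  counts$F <- ifelse(counts$n_total > 0,
                     counts$n_comorbid / counts$n_total, NA_real_)
  counts
}

#' Co-mention enrichment of a top gene list
#'
#' Mann-Whitney U test comparing the co-mention frequencies `F` of the top
#' genes against those of the complete candidate list.
#'
#' @param table result of [comention_frequency()].
#' @param top character vector of top gene symbols (subset of
#'   `all_candidates`).
#' @param all_candidates character vector of all candidate symbols.
#' @return list with `F_top_mean`, `F_all_mean`, `U`, `p`.
#' @export
toplist_comention_test <- function(table, top, all_candidates) {
  stopifnot(all(top %in% all_candidates))
  tab <- table[!is.na(table$F), , drop = FALSE]
  f_top <- tab$F[tab$symbol %in% top]
  f_all <- tab$F[tab$symbol %in% all_candidates]
  if (length(f_top) < 2L || length(f_all) < 2L) {
    stop("need at least 2 defined co-mention frequencies per group",
         call. = FALSE)
  }
  mw <- mann_whitney_u(f_top, f_all)
  list(F_top_mean = mean(f_top), F_all_mean = mean(f_all),
       U = mw$U, p = mw$p)
}

#' Average-rank enrichment of a gene subset
#'
#' Compares the final priority scores of subset members against the
#' remaining candidates (Welch's t-test, consistent with the other subset
#' comparisons here). A subset whose members rank systematically better
#' has a lower mean final score.
#'
#' @param priority a `gene_priority` from [aggregate_ranks()].
#' @param subset character vector of gene symbols.
#' @return list with `n_in`, `n_out`, `mean_rank_in`, `mean_rank_out`,
#'   `t`, `df`, `p`.
#' @export
toplist_rank_enrichment <- function(priority, subset) {
  stopifnot(inherits(priority, "gene_priority"))
  tabl <- priority$table
  in_set <- tabl$symbol %in% subset
  if (!any(in_set)) stop("subset does not intersect the candidates",
                         call. = FALSE)
  if (all(in_set)) stop("subset covers every candidate: no complement",
                        call. = FALSE)
  w <- welch_test(tabl$average[in_set], tabl$average[!in_set])
  list(n_in = sum(in_set), n_out = sum(!in_set),
       mean_rank_in = w$mean_x, mean_rank_out = w$mean_y,
       t = w$t, df = w$df, p = w$p)
}
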