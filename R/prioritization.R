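# The ten ranking criteria and their aggregation. Criteria 1-2 ingest
# external prioritizer scores; 3 counts membership in enriched GO processes
# of the complete and regulatory networks; 4-5 rank by mean centrality;
# 6 by specificity of gene-process association (Welch t, Bonferroni);
# 7-10 are binary SNP criteria over "list Y" (whole-blood eQTL SNPs with
# mean European minor allele frequency >= 5%): rank 1 when a qualifying
# SNP (with the criterion's disease condition) exists, otherwise the
# maximal rank N. The final score is the arithmetic mean of the ten ranks.

criterion_ranking <- function(criterion_id, ranks, n) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)))
  structure(list(criterion_id = as.integer(criterion_id),
                 ranks = setNames(as.integer(ranks), names(ranks)),
                 n = as.integer(n)),
            class = "criterion_ranking")
}

#' @export
print.criterion_ranking <- function(x, ...) {
  cat("Criterion", x$criterion_id, "ranking over", x$n, "candidates\n")
  top <- sort(x$ranks)[seq_len(min(5L, length(x$ranks)))]
  cat("  best:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ordinal rank transform
#'
#' Sorts candidates by score in the given direction and assigns ordinal
#' ranks `1..N`; ties are broken by lexicographic symbol order, and
#' candidates missing a score all receive the maximal rank `N`.
#'
#' @param scores named numeric vector (names are symbols; symbols outside
#'   `candidates` are ignored).
#' @param candidates character vector of candidate symbols (no duplicates).
#' @param direction `"ascending"` (smaller score ranks first) or
#'   `"descending"`.
#' @param criterion_id integer id recorded on the result.
#' @return a `criterion_ranking` object with one rank per candidate.
#' @export
rank_transform <- function(scores, candidates,
                           direction = c("ascending", "descending"),
                           criterion_id = NA_integer_) {
  direction <- match.arg(direction)
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  if (anyDuplicated(candidates)) stop("duplicate candidate symbols",
                                      call. = FALSE)
  n <- length(candidates)
  scores <- scores[names(scores) %in% candidates]
  scores <- scores[!is.na(scores)]
  ranks <- setNames(rep(n, n), candidates)
  if (length(scores) > 0L) {
    s <- if (direction == "descending") -scores else scores
    ord <- order(s, names(s))
    ranks[names(s)[ord]] <- seq_along(s)
  }
  criterion_ranking(criterion_id, ranks, n)
}

#' Ingest an external prioritizer ranking (criteria 1-2)
#'
#' Applies [rank_transform()] with the table's sort order; candidates the
#' external tool did not score are reported in the `"missing"` attribute
#' and ranked `N`.
#'
#' @param table an [external_ranks()] object.
#' @param candidates character vector of candidate symbols.
#' @return a `criterion_ranking`.
#' @export
ingest_external_ranking <- function(table, candidates) {
  stopifnot(inherits(table, "external_ranks"))
  r <- rank_transform(table$scores, candidates,
                      direction = table$sort_order,
                      criterion_id = table$criterion_id)
  attr(r, "missing") <- setdiff(candidates, names(table$scores))
  r
}

#' Criterion 3: involvement in enriched biological processes
#'
#' Scores each candidate by `N1 + N2`, the number of enriched terms of the
#' complete-network and regulatory-network enrichment analyses whose
#' annotation set contains the gene, and ranks descending (more enriched
#' processes rank first).
#'
#' @param enriched_complete,enriched_regulatory results of
#'   [enriched_processes()] for the two networks.
#' @param annotations named list of term gene sets.
#' @param candidates character vector of candidate symbols.
#' @return a `criterion_ranking` (id 3); the `N1 + N2` counts are kept in
#'   the `"counts"` attribute.
#' @export
criterion_enrichment <- function(enriched_complete, enriched_regulatory,
                                 annotations, candidates) {
  count_membership <- function(enr) {
    terms <- enr$process_id[enr$enriched]
    sets <- annotations[terms]
    vapply(candidates,
           function(g) sum(vapply(sets, function(s) g %in% s, logical(1L))),
           integer(1L))
  }
  n_total <- count_membership(enriched_complete) +
    count_membership(enriched_regulatory)
  r <- rank_transform(setNames(as.numeric(n_total), candidates), candidates,
                      direction = "descending", criterion_id = 3L)
  attr(r, "counts") <- n_total
  r
}

#' Criteria 4-5: centrality ranking
#'
#' Ranks candidates descending by `mean3` (the mean of aggregated degree,
#' closeness and betweenness centrality) from a [gene_centrality_profile()]
#' of the complete (criterion 4) or genetic regulatory (criterion 5)
#' network. Symbols absent from the network receive rank `N`.
#'
#' @param profile a `centrality_profile`, or `NULL` (all candidates absent,
#'   e.g. an empty regulatory subnetwork).
#' @param candidates character vector of candidate symbols.
#' @param criterion_id 4 or 5.
#' @return a `criterion_ranking`.
#' @export
criterion_centrality <- function(profile, candidates, criterion_id) {
  stopifnot(criterion_id %in% 4:5)
  scores <- if (is.null(profile)) {
    setNames(numeric(0), character(0))
  } else {
    setNames(profile$mean3, profile$symbol)
  }
  rank_transform(scores, candidates, direction = "descending",
                 criterion_id = criterion_id)
}

#' Criterion 6: specificity of gene-process association
#'
#' For each gene, compares its 0/1 connection indicators over the test
#' processes (associated with both diseases) against the control processes
#' by Welch's unequal-variance t-test, Bonferroni-adjusts over the
#' candidates, and ranks ascending by adjusted p among genes whose test-set
#' connection rate exceeds their control rate; all remaining genes follow
#' (same ordering rule). Genes absent from the table are treated as having
#' no links.
#'
#' @param tab a [process_table()].
#' @param candidates character vector of candidate symbols.
#' @param alpha significance threshold used for the `specific` flag.
#' @return a `criterion_ranking` (id 6) with a per-gene data frame of test
#'   statistics in the `"stats"` attribute (columns `symbol`, `k_test`,
#'   `k_control`, `mean_test`, `mean_control`, `t`, `df`, `p`,
#'   `p_bonferroni`, `specific`).
#' @export
criterion_process_specificity <- function(tab, candidates, alpha = 0.01) {
  stopifnot(inherits(tab, "process_table"))
  is_test <- tab$partition == "test"
  n_t <- sum(is_test); n_c <- sum(!is_test)
  if (n_t < 2L || n_c < 2L) {
    stop("need at least 2 test and 2 control processes", call. = FALSE)
  }
  k_t <- setNames(rep(0, length(candidates)), candidates)
  k_c <- k_t
  present <- intersect(candidates, tab$genes)
  if (length(present) > 0L) {
    lk <- tab$links[match(present, tab$genes), , drop = FALSE]
    k_t[present] <- Matrix::rowSums(lk[, is_test, drop = FALSE])
    k_c[present] <- Matrix::rowSums(lk[, !is_test, drop = FALSE])
  }
  m1 <- k_t / n_t; m2 <- k_c / n_c
  v1 <- k_t * (1 - m1) / (n_t - 1)      # sample variance of a 0/1 vector
  v2 <- k_c * (1 - m2) / (n_c - 1)
  w <- welch_from_moments(m1, v1, n_t, m2, v2, n_c)
  p_adj <- pmin(1, w$p * length(candidates))
  specific <- m1 > m2
  stats_df <- data.frame(symbol = candidates, k_test = unname(k_t),
                         k_control = unname(k_c), mean_test = unname(m1),
                         mean_control = unname(m2), t = unname(w$t),
                         df = unname(w$df), p = unname(w$p),
                         p_bonferroni = unname(p_adj),
                         specific = unname(specific & p_adj < alpha),
                         stringsAsFactors = FALSE)
  ord <- order(!specific, p_adj, w$p, candidates)
  ranks <- setNames(integer(length(candidates)), candidates)
  ranks[candidates[ord]] <- seq_along(candidates)
  r <- criterion_ranking(6L, ranks, length(candidates))
  attr(r, "stats") <- stats_df
  r
}

#' Build list Y: qualifying eQTL SNPs per gene
#'
#' A SNP qualifies when it is an eQTL for the gene in the given tissue and
#' its minor allele frequency, averaged over the available listed
#' populations, is at least `maf_min` (inclusive). SNPs with no MAF data
#' are excluded with a warning.
#'
#' @param snps an [snp_annotation()].
#' @param tissue eQTL tissue required (default whole blood).
#' @param populations European population codes whose MAF columns enter the
#'   average (missing values are ignored).
#' @param maf_min inclusive minor allele frequency threshold.
#' @return named list: gene symbol -> character vector of SNP ids (only
#'   genes with at least one qualifying SNP appear).
#' @export
build_list_y <- function(snps, tissue = "whole blood",
                         populations = c("CEU", "GBR", "IBS", "TSI"),
                         maf_min = 0.05) {
  stopifnot(inherits(snps, "snp_annotation"))
  rec <- snps$records
  if (nrow(rec) == 0L) return(setNames(list(), character()))
  maf_cols <- paste0("maf_", tolower(populations))
  maf_cols <- intersect(maf_cols, names(rec))
  maf_mat <- as.matrix(rec[, maf_cols, drop = FALSE])
  n_avail <- rowSums(!is.na(maf_mat))
  no_maf <- n_avail == 0L
  if (any(no_maf)) {
    warning(sum(no_maf), " SNP(s) without MAF data excluded from list Y")
  }
  mean_maf <- rowSums(maf_mat, na.rm = TRUE) / pmax(n_avail, 1L)
  in_tissue <- vapply(strsplit(rec$tissues, ";", fixed = TRUE),
                      function(tt) tissue %in% trimws(tt), logical(1L))
  ok <- !no_maf & in_tissue & mean_maf >= maf_min
  split(rec$snp_id[ok], rec$symbol[ok])
}

#' SNP density per gene
#'
#' Qualifying SNPs per 1000 nucleotides of gene length, binned into the
#' reporting categories small (0.01-0.099), moderate (0.1-0.9),
#' high (1.0-4.9) and very-high (>= 5.0). Genes without qualifying SNPs
#' stay uncategorized.
#'
#' @param list_y result of [build_list_y()].
#' @param gene_lengths named numeric vector of gene lengths (nucleotides);
#'   a gene in `list_y` without a length is an error.
#' @return data frame with columns `symbol`, `n_snps`, `length`, `density`,
#'   `category`.
#' @export
snp_density <- function(list_y, gene_lengths) {
  symbols <- names(list_y)
  missing_len <- setdiff(symbols, names(gene_lengths))
  if (length(missing_len) > 0L) {
    stop("no gene length for: ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  }
  len <- gene_lengths[symbols]
  dens <- 1000 * lengths(list_y) / len
  category <- rep(NA_character_, length(dens))
  category[dens >= 0.01 & dens < 0.1] <- "small"
  category[dens >= 0.1 & dens < 1.0] <- "moderate"
  category[dens >= 1.0 & dens < 5.0] <- "high"
  category[dens >= 5.0] <- "very-high"
  category[lengths(list_y) == 0L] <- NA_character_
  data.frame(symbol = symbols, n_snps = unname(lengths(list_y)),
             length = unname(len), density = unname(dens),
             category = category, stringsAsFactors = FALSE, row.names = NULL)
}

#' Criteria 7-10: binary SNP criteria
#'
#' A candidate ranks 1 when it carries at least one list-Y SNP satisfying
#' the criterion's disease condition, otherwise it receives the maximal
#' rank `N`:
#' * 7 - any list-Y SNP;
#' * 8 - a list-Y SNP associated with one of the two primary diseases;
#' * 9 - a list-Y SNP associated with a disease comorbid to either primary
#'   disease;
#' * 10 - a list-Y SNP associated with any other disease (primary and
#'   comorbid diseases excluded; a SNP may satisfy several criteria through
#'   different disease links).
#'
#' @param list_y result of [build_list_y()].
#' @param snps the [snp_annotation()] the list was built from (provides the
#'   SNP-disease links).
#' @param comorbid character vector of comorbid disease names (required
#'   non-empty for criterion 9).
#' @param candidates character vector of candidate symbols.
#' @param criterion_id 7, 8, 9 or 10.
#' @param primary_diseases names of the two diseases under study.
#' @return a `criterion_ranking` taking only the values 1 and `N`.
#' @export
criterion_snp <- function(list_y, snps, comorbid, candidates, criterion_id,
                          primary_diseases = c("asthma", "hypertension")) {
  stopifnot(criterion_id %in% 7:10, inherits(snps, "snp_annotation"))
  if (criterion_id == 9L && length(comorbid) == 0L) {
    stop("criterion 9 requires a non-empty comorbid disease list",
         call. = FALSE)
  }
  rec <- snps$records
  disease_of <- setNames(strsplit(rec$diseases, ";", fixed = TRUE),
                         rec$snp_id)
  disease_of <- lapply(disease_of, function(d) trimws(d[nzchar(trimws(d))]))
  qualifies <- function(snp_ids) {
    if (length(snp_ids) == 0L) return(FALSE)
    if (criterion_id == 7L) return(TRUE)
    links <- disease_of[snp_ids]
    any(vapply(links, function(d) {
      switch(as.character(criterion_id),
             "8" = length(intersect(d, primary_diseases)) > 0L,
             "9" = length(intersect(d, comorbid)) > 0L,
             "10" = length(setdiff(d, c(primary_diseases, comorbid))) > 0L)
    }, logical(1L)))
  }
  n <- length(candidates)
  hit <- vapply(candidates, function(g) qualifies(list_y[[g]]), logical(1L))
  criterion_ranking(criterion_id, setNames(ifelse(hit, 1L, n), candidates),
                    n)
}

#' Aggregate the ten criterion rankings into the final priority
#'
#' The final score of each candidate is the arithmetic mean of its ten
#' criterion ranks; candidates are ordered ascending by final score (lower
#' = higher priority), ties broken by symbol.
#'
#' @param rankings list of ten `criterion_ranking` objects with ids 1-10
#'   over the same candidate set.
#' @param candidates character vector of candidate symbols.
#' @return object of class `gene_priority`; see [print.gene_priority()].
#' @export
aggregate_ranks <- function(rankings, candidates) {
  ids <- vapply(rankings, function(r) r$criterion_id, integer(1L))
  missing_ids <- setdiff(1:10, ids)
  if (length(missing_ids) > 0L) {
    stop("missing criterion ranking(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  rankings <- rankings[match(1:10, ids)]
  n <- length(candidates)
  mat <- vapply(rankings, function(r) {
    if (!setequal(names(r$ranks), candidates)) {
      stop("criterion ", r$criterion_id,
           " ranking does not cover the candidate set", call. = FALSE)
    }
    as.numeric(r$ranks[candidates])
  }, numeric(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  colnames(mat) <- paste0("rank", 1:10)
  final <- rowMeans(mat)
  tabl <- data.frame(symbol = candidates, mat, average = final,
                     stringsAsFactors = FALSE, row.names = NULL,
                     check.names = FALSE)
  tabl <- tabl[order(tabl$average, tabl$symbol), , drop = FALSE]
  rownames(tabl) <- NULL
  structure(list(table = tabl, n = n), class = "gene_priority")
}

#' Pearson correlation between two criterion rankings
#'
#' @param r1,r2 `criterion_ranking` objects over the same candidates
#'   (at least 3).
#' @return list with `r` (Pearson coefficient over the paired rank
#'   vectors) and `p` (two-sided, via the t transform).
#' @export
rank_correlation <- function(r1, r2) {
  stopifnot(inherits(r1, "criterion_ranking"),
            inherits(r2, "criterion_ranking"))
  if (!setequal(names(r1$ranks), names(r2$ranks))) {
    stop("rankings cover different candidate sets", call. = FALSE)
  }
  x <- as.numeric(r1$ranks)
  y <- as.numeric(r2$ranks[names(r1$ranks)])
  if (length(x) < 3L) stop("need at least 3 shared candidates",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a ranking has zero variance",
         call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}
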