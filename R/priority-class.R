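# Methods for the aggregated priority object.

#' @describeIn aggregate_ranks print the top of the priority table.
#' @param x,object a `gene_priority`.
#' @param k number of top genes to display.
#' @param ... ignored.
#' @export
print.gene_priority <- function(x, k = 10L, ...) {
  cat("Gene priority over", x$n, "candidates (average of 10 criterion",
      "ranks; lower = higher priority)\n\n")
  print(head(x$table, k), row.names = TRUE)
  if (nrow(x$table) > k) cat("... and", nrow(x$table) - k, "more genes\n")
  invisible(x)
}

#' @describeIn aggregate_ranks summary statistics of the final scores.
#' @export
summary.gene_priority <- function(object, k = 10L, ...) {
  structure(list(n = object$n,
                 top = head(object$table$symbol, k),
                 average = summary(object$table$average),
                 binary_hits = vapply(paste0("rank", 7:10), function(cc) {
                   sum(object$table[[cc]] == 1L)
                 }, integer(1L))),
            class = "summary.gene_priority")
}

#' @export
print.summary.gene_priority <- function(x, ...) {
  cat("Priority over", x$n, "candidates\n")
  cat("  top genes:", paste(x$top, collapse = ", "), "\n")
  cat("  final score distribution:\n")
  print(x$average)
  cat("  genes with qualifying SNPs (criteria 7-10):",
      paste(x$binary_hits, collapse = "/"), "\n")
  invisible(x)
}

#' @describeIn aggregate_ranks the full ranked table as a data frame
#'   (columns `symbol`, `rank1`..`rank10`, `average`).
#' @export
as.data.frame.gene_priority <- function(x, ...) x$table

#' @describeIn aggregate_ranks dot chart of the best average ranks.
#' @export
plot.gene_priority <- function(x, k = 10L, ...) {
  top <- head(x$table, k)
  graphics::dotchart(rev(top$average), labels = rev(top$symbol),
                     xlab = "average rank (lower = higher priority)",
                     main = "Top comorbidity candidate genes", ...)
  invisible(x)
}

#' Top-ranked gene symbols
#'
#' @param priority a `gene_priority` from [aggregate_ranks()].
#' @param k number of genes.
#' @return character vector of the `k` highest-priority symbols.
#' @export
top_genes <- function(priority, k = 10L) {
  stopifnot(inherits(priority, "gene_priority"))
  head(priority$table$symbol, k)
}
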