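# Readers and writers for the on-disk formats consumed by the pipeline:
# network TSV/SIF, GMT gene sets, gene-process association tables, external
# prioritizer rank tables, SNP annotation tables, co-mention counts and
# disease lists. All files are UTF-8, tab-separated with a header unless
# stated otherwise.

read_tsv_chr <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = NULL)
}

#' Read an associative network from disk
#'
#' The TSV dialect has columns `src_symbol`, `src_kind`, `tgt_symbol`,
#' `tgt_kind`, `itype`, `directed` (TRUE/FALSE). Rows with empty target
#' fields declare isolated nodes, so networks that retain isolated shared
#' vertices round-trip exactly. SIF (`source itype target...`) is accepted
#' read-only; SIF node kinds default to `gene` and edge direction follows
#' the vocabulary default for the interaction type.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param label network label; defaults to the file name.
#' @return an [assoc_network()]. A missing or empty file body yields an
#'   empty network (0 nodes, 0 edges); malformed rows and unknown
#'   interaction types raise errors naming the offending line.
#' @export
read_network <- function(path, format = c("tsv", "sif"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path,
                               call. = FALSE)
  if (is.null(label)) label <- basename(path)
  if (format == "sif") return(read_network_sif(path, label))

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {          # empty or header-only file
    return(assoc_network(label = label))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, edge_columns)) {
    stop("network TSV header must be: ", paste(edge_columns, collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  # node-only rows end in empty fields; strsplit drops the trailing one
  parts <- lapply(parts, function(p) c(p, character(6L - min(length(p), 6L))))
  is_node_like <- vapply(parts, function(p) {
    nzchar(p[1L]) && nzchar(p[2L]) && !any(nzchar(p[3:6]))
  }, logical(1L))
  bad <- which(n_fields != length(edge_columns) &
                 !(is_node_like & n_fields >= 2L))
  if (length(bad) > 0L) {
    stop("malformed network row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", length(edge_columns), " fields, got ",
         n_fields[bad[1L]], ")", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  df <- data.frame(src_symbol = m[, 1L], src_kind = m[, 2L],
                   tgt_symbol = m[, 3L], tgt_kind = m[, 4L],
                   itype = m[, 5L], directed = m[, 6L],
                   stringsAsFactors = FALSE)

  is_node_row <- !nzchar(df$tgt_symbol) & !nzchar(df$itype)
  node_rows <- df[is_node_row, , drop = FALSE]
  df <- df[!is_node_row, , drop = FALSE]

  bad_itype <- setdiff(unique(df$itype), interaction_types())
  if (length(bad_itype) > 0L) {
    stop("unknown interaction type(s) in ", path, ": ",
         paste(bad_itype, collapse = ", "), call. = FALSE)
  }
  directed <- rep(NA, nrow(df))
  directed[tolower(df$directed) %in% c("true", "1")] <- TRUE
  directed[tolower(df$directed) %in% c("false", "0")] <- FALSE
  if (anyNA(directed) && nrow(df) > 0L) {
    stop("malformed 'directed' flag at line ",
         which(is.na(directed))[1L] + 1L, " of ", path, call. = FALSE)
  }
  df$directed <- directed

  nodes <- NULL
  if (nrow(node_rows) > 0L) {
    nodes <- data.frame(symbol = node_rows$src_symbol,
                        kind = node_rows$src_kind, stringsAsFactors = FALSE)
  }
  assoc_network(nodes = nodes, edges = df, label = label)
}

read_network_sif <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(assoc_network(label = label))
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) == 1L) {            # lone node
      rows[[length(rows) + 1L]] <- data.frame(
        src_symbol = f[1L], src_kind = "gene", tgt_symbol = "",
        tgt_kind = "", itype = "", directed = "", stringsAsFactors = FALSE)
      next
    }
    if (length(f) < 3L) {
      stop("malformed SIF record at line ", i, " of ", path, call. = FALSE)
    }
    check_itypes(f[2L])
    for (tgt in f[-(1:2)]) {
      rows[[length(rows) + 1L]] <- data.frame(
        src_symbol = f[1L], src_kind = "gene", tgt_symbol = tgt,
        tgt_kind = "gene", itype = f[2L],
        directed = itype_directed_default(f[2L]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  is_node <- !nzchar(df$tgt_symbol)
  nodes <- if (any(is_node)) {
    data.frame(symbol = df$src_symbol[is_node], kind = df$src_kind[is_node],
               stringsAsFactors = FALSE)
  }
  edges <- df[!is_node, , drop = FALSE]
  edges$directed <- as.logical(edges$directed)
  assoc_network(nodes = nodes, edges = edges, label = label)
}

#' Write an associative network to disk
#'
#' Inverse of [read_network()] for the TSV dialect: one row per edge plus a
#' node-only row (empty target fields) for every isolated vertex, so that
#' `read_network(write_network(net, path))` reproduces `net` exactly.
#'
#' @param net an [assoc_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "assoc_network"))
  edges <- net$edges[, edge_columns, drop = FALSE]
  touched <- unique(node_id(c(edges$src_symbol, edges$tgt_symbol),
                            c(edges$src_kind, edges$tgt_kind)))
  iso <- net$nodes[!node_id(net$nodes$symbol, net$nodes$kind) %in% touched, ,
                   drop = FALSE]
  if (nrow(iso) > 0L) {
    edges <- rbind(edges, data.frame(
      src_symbol = iso$symbol, src_kind = iso$kind, tgt_symbol = "",
      tgt_kind = "", itype = "", directed = "", stringsAsFactors = FALSE))
  }
  edges$directed <- as.character(edges$directed)
  edges$directed[is.na(edges$directed)] <- ""
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: per line a set name, a description, then member
#' symbols, all tab-separated. Duplicate symbols within a line are collapsed;
#' line order is preserved.
#'
#' @param path GMT file path.
#' @return named list of character vectors (one per set); empty file gives
#'   an empty list. Lines with fewer than 2 fields raise a parse error.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short) > 0L) {
    stop("malformed GMT record at line ", short[1L], " of ", path,
         " (fewer than 2 fields)", call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1L), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)) || length(sets) == 0L)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-process association table
#'
#' Binary indicators linking genes to biological processes, with each
#' process assigned to the `test` partition (processes associated with both
#' diseases) or the `control` partition (all other processes). Consumed by
#' the process-specificity ranking criterion.
#'
#' @param genes character vector of gene symbols (row order).
#' @param processes character vector of process identifiers (column order).
#' @param links binary matrix or Matrix, genes x processes.
#' @param partition named character vector over `processes` with values
#'   `"test"` or `"control"`.
#' @return object of class `process_table`.
#' @export
process_table <- function(genes, processes, links, partition) {
  stopifnot(length(genes) == nrow(links), length(processes) == ncol(links))
  if (anyDuplicated(genes)) stop("duplicate gene symbols", call. = FALSE)
  if (anyDuplicated(processes)) stop("duplicate process ids", call. = FALSE)
  links <- Matrix::drop0(methods::as(
    methods::as(Matrix::Matrix(links, sparse = TRUE), "generalMatrix"),
    "CsparseMatrix"))
  if (any(links@x != 1)) stop("link indicators must be 0/1", call. = FALSE)
  if (!all(processes %in% names(partition))) {
    stop("partition must cover every process", call. = FALSE)
  }
  partition <- partition[processes]
  if (!all(partition %in% c("test", "control"))) {
    stop("partition values must be 'test' or 'control'", call. = FALSE)
  }
  dimnames(links) <- list(genes, processes)
  structure(list(genes = genes, processes = processes, links = links,
                 partition = partition),
            class = "process_table")
}

#' @export
print.process_table <- function(x, ...) {
  cat("Gene-process association table:", length(x$genes), "genes x",
      length(x$processes), "processes (",
      sum(x$partition == "test"), "test /",
      sum(x$partition == "control"), "control );",
      length(x$links@x), "links\n")
  invisible(x)
}

#' Read / write a gene-process association table
#'
#' The links TSV has columns `gene`, `process_id`, `link` (0/1); zero links
#' may be omitted. The partition TSV has columns `process_id`, `partition`
#' (`test`/`control`) and defines the process universe.
#'
#' @param links_path,partition_path file paths.
#' @param genes optional character vector fixing the gene universe (genes
#'   with no links would otherwise be dropped).
#' @return a [process_table()].
#' @export
read_process_table <- function(links_path, partition_path, genes = NULL) {
  links_df <- read_tsv_chr(links_path)
  part_df <- read_tsv_chr(partition_path)
  stopifnot(all(c("gene", "process_id", "link") %in% names(links_df)),
            all(c("process_id", "partition") %in% names(part_df)))
  lk <- as.integer(links_df$link)
  if (anyNA(lk) || !all(lk %in% c(0L, 1L))) {
    stop("link column must be 0/1", call. = FALSE)
  }
  links_df <- links_df[lk == 1L, , drop = FALSE]
  processes <- part_df$process_id
  partition <- setNames(part_df$partition, processes)
  if (is.null(genes)) genes <- sort(unique(links_df$gene))
  unknown <- setdiff(unique(links_df$gene), genes)
  if (length(unknown) > 0L) {
    stop("link rows for genes outside the gene universe: ",
         paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  i <- match(links_df$gene, genes)
  j <- match(links_df$process_id, processes)
  if (anyNA(j)) stop("link rows reference processes missing from partition",
                     call. = FALSE)
  links <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(length(genes), length(processes)))
  process_table(genes, processes, links, partition)
}

#' @rdname read_process_table
#' @param tab a [process_table()].
#' @export
write_process_table <- function(tab, links_path, partition_path) {
  stopifnot(inherits(tab, "process_table"))
  tr <- Matrix::summary(tab$links)
  links_df <- data.frame(gene = tab$genes[tr$i],
                         process_id = tab$processes[tr$j], link = 1L)
  links_df <- links_df[order(links_df$gene, links_df$process_id), ]
  utils::write.table(links_df, links_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(process_id = tab$processes,
               partition = unname(tab$partition)),
    partition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(links_path)
}

#' External prioritizer rank table
#'
#' Raw scores from an external gene prioritizer (ranking criteria 1 and 2),
#' one score per symbol, together with the direction in which better scores
#' sort.
#'
#' @param criterion_id integer, 1 or 2.
#' @param scores named numeric vector (names are gene symbols).
#' @param sort_order `"ascending"` (smaller score is better) or
#'   `"descending"`.
#' @return object of class `external_ranks`.
#' @export
external_ranks <- function(criterion_id, scores,
                           sort_order = c("ascending", "descending")) {
  sort_order <- match.arg(sort_order)
  criterion_id <- as.integer(criterion_id)
  stopifnot(criterion_id %in% 1:2)
  if (length(scores) == 0L) stop("empty external rank table", call. = FALSE)
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by symbol", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  structure(list(criterion_id = criterion_id, scores = scores,
                 sort_order = sort_order),
            class = "external_ranks")
}

#' Read an external prioritizer rank table (TSV: symbol, score)
#'
#' @param path file path.
#' @inheritParams external_ranks
#' @return an [external_ranks()] object.
#' @export
read_external_ranks <- function(path, criterion_id,
                                sort_order = c("ascending", "descending")) {
  df <- read_tsv_chr(path)
  stopifnot(all(c("symbol", "score") %in% names(df)))
  if (anyDuplicated(df$symbol)) {
    stop("duplicate symbol in external rank table: ", path, call. = FALSE)
  }
  external_ranks(criterion_id, setNames(as.numeric(df$score), df$symbol),
                 sort_order = match.arg(sort_order))
}

#' SNP annotation set
#'
#' Per-SNP records carrying the host gene, eQTL tissues, per-population
#' minor allele frequencies (CEU/GBR/IBS/TSI) and disease associations,
#' plus gene lengths for SNP-density computation.
#'
#' @param records data frame with columns `snp_id`, `symbol`, `tissues`
#'   (`;`-separated), `maf_ceu`, `maf_gbr`, `maf_ibs`, `maf_tsi` (numeric,
#'   `NA` allowed), `diseases` (`;`-separated, may be empty).
#' @param gene_lengths named numeric vector of gene lengths in nucleotides.
#' @return object of class `snp_annotation`.
#' @export
snp_annotation <- function(records, gene_lengths = numeric()) {
  need <- c("snp_id", "symbol", "tissues", "maf_ceu", "maf_gbr", "maf_ibs",
            "maf_tsi", "diseases")
  stopifnot(all(need %in% names(records)))
  records <- as.data.frame(records, stringsAsFactors = FALSE)[, need]
  for (cc in c("maf_ceu", "maf_gbr", "maf_ibs", "maf_tsi")) {
    records[[cc]] <- as.numeric(records[[cc]])
    bad <- !is.na(records[[cc]]) &
      (records[[cc]] < 0 | records[[cc]] > 0.5)
    if (any(bad)) stop("minor allele frequencies must lie in [0, 0.5]",
                       call. = FALSE)
  }
  if (length(gene_lengths) > 0L && any(gene_lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  structure(list(records = records, gene_lengths = gene_lengths),
            class = "snp_annotation")
}

#' Read SNP annotations from disk
#'
#' @param records_path TSV with the columns of [snp_annotation()] records
#'   (empty MAF fields read as `NA`).
#' @param lengths_path optional TSV with columns `symbol`, `length`.
#' @return an [snp_annotation()].
#' @export
read_snp_table <- function(records_path, lengths_path = NULL) {
  df <- read_tsv_chr(records_path)
  for (cc in c("maf_ceu", "maf_gbr", "maf_ibs", "maf_tsi")) {
    df[[cc]][!nzchar(df[[cc]])] <- NA_character_
  }
  lens <- numeric()
  if (!is.null(lengths_path)) {
    ldf <- read_tsv_chr(lengths_path)
    stopifnot(all(c("symbol", "length") %in% names(ldf)))
    lens <- setNames(as.numeric(ldf$length), ldf$symbol)
  }
  snp_annotation(df, lens)
}

#' @rdname read_snp_table
#' @param snps an [snp_annotation()].
#' @export
write_snp_table <- function(snps, records_path, lengths_path = NULL) {
  stopifnot(inherits(snps, "snp_annotation"))
  utils::write.table(snps$records, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(
      data.frame(symbol = names(snps$gene_lengths),
                 length = unname(snps$gene_lengths)),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(records_path)
}

#' Read literature co-mention counts (TSV: symbol, n_comorbid, n_total)
#'
#' @param path file path.
#' @return data frame with integer columns `n_comorbid`, `n_total`.
#' @export
read_comention <- function(path) {
  df <- read_tsv_chr(path)
  stopifnot(all(c("symbol", "n_comorbid", "n_total") %in% names(df)))
  df$n_comorbid <- as.integer(df$n_comorbid)
  df$n_total <- as.integer(df$n_total)
  df
}

#' Read a disease list (one disease name per line; `#` comments allowed)
#'
#' @param path file path.
#' @return character vector of disease names.
#' @export
read_disease_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
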