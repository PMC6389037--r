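# Seeded generator of a complete synthetic knowledgebase with planted
# true-comorbidity genes, so that every pipeline stage can be exercised
# end-to-end without external downloads. The full profile mirrors the scale
# of a two-disease knowledgebase analysis (hundreds of disease genes, ~200
# shared, ~10^4 shared typed interactions dominated by associative edges, a
# 118 / 13,538 test/control process split, ~30 SNP-bearing genes); the tiny
# profile keeps unit tests fast. Planted genes receive elevated network
# degree, membership in shared-gene-biased annotation terms, excess
# test-process links, qualifying whole-blood eQTL SNPs with primary-,
# comorbid- and other-disease associations, favorable external scores
# (perturbed by Gaussian noise on the rank scale) and elevated literature
# co-mention frequency.

.comorbid_disease_pool <- c("diabetes mellitus", "rheumatoid arthritis",
                            "myocardial infarction",
                            "chronic kidney disease",
                            "diabetic nephropathy")
.other_disease_pool <- c("psoriasis", "migraine", "osteoporosis",
                         "major depressive disorder", "ulcerative colitis")

#' Synthetic knowledgebase configuration
#'
#' Returns the generator configuration. The `"full"` profile is the default
#' study condition (knowledgebase scale); the `"tiny"` profile is a fast
#' small-world variant for unit testing. Any field can be overridden via
#' `...`.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param seed integer seed; every artifact stream is derived from it.
#' @param ... named overrides of config fields.
#' @return object of class `synthetic_config` (a named list).
#' @export
synthetic_config <- function(profile = c("full", "tiny"), seed = 1L, ...) {
  profile <- match.arg(profile)
  full_mix <- c("association" = 7973, "protein-protein" = 554,
                "activity-regulation" = 347, "transport-regulation" = 262,
                "genetic-regulation" = 200, "expression" = 84,
                "expression-upregulation" = 80,
                "expression-downregulation" = 65,
                "chemical-transformation" = 45,
                "degradation-regulation" = 25, "co-expression" = 3)
  cfg <- if (profile == "full") {
    list(
      n_genes_a = 755L, n_genes_b = 713L, n_shared = 205L, n_planted = 10L,
      edge_type_mix = full_mix / sum(full_mix),
      n_core_edges = 9638L, n_specific_edges_a = 12000L,
      n_specific_edges_b = 12000L, planted_degree_boost = 6,
      n_terms = 300L, term_size_range = c(10L, 80L), n_biased_terms = 40L,
      biased_shared_fraction = 0.7, planted_term_prob = 0.7,
      n_test_processes = 118L, n_control_processes = 13538L,
      test_link_prob_planted = 0.35, test_link_prob_background = 0.03,
      control_link_prob = 0.03,
      n_snp_genes = 30L, snp_per_gene_range = c(10L, 80L),
      eqtl_fraction = 0.8, common_maf_fraction = 0.8,
      n_background_primary = 0L, n_background_comorbid = 0L,
      n_background_other = 5L,
      gene_length_range = c(2000, 100000),
      rank_noise = 15,
      comention_rate_planted = 0.023, comention_rate_background = 0.006,
      comention_total_range = c(50L, 400L),
      apoptosis_size = 60L, apoptosis_planted = 7L,
      cns_size = 40L, cns_planted = 5L,
      seed = as.integer(seed))
  } else {
    list(
      n_genes_a = 30L, n_genes_b = 28L, n_shared = 20L, n_planted = 4L,
      edge_type_mix = full_mix / sum(full_mix),
      n_core_edges = 130L, n_specific_edges_a = 90L,
      n_specific_edges_b = 90L, planted_degree_boost = 5,
      n_terms = 20L, term_size_range = c(8L, 14L), n_biased_terms = 6L,
      biased_shared_fraction = 1, planted_term_prob = 0.8,
      n_test_processes = 10L, n_control_processes = 60L,
      test_link_prob_planted = 0.5, test_link_prob_background = 0.05,
      control_link_prob = 0.05,
      n_snp_genes = 7L, snp_per_gene_range = c(2L, 8L),
      eqtl_fraction = 0.8, common_maf_fraction = 0.8,
      n_background_primary = 0L, n_background_comorbid = 0L,
      n_background_other = 2L,
      gene_length_range = c(1000, 20000),
      rank_noise = 2,
      comention_rate_planted = 0.15, comention_rate_background = 0.01,
      comention_total_range = c(30L, 120L),
      apoptosis_size = 8L, apoptosis_planted = 3L,
      cns_size = 6L, cns_planted = 2L,
      seed = as.integer(seed))
  }
  cfg$profile <- profile
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, over)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_planted > n_shared || n_shared > min(n_genes_a, n_genes_b)) {
      stop("infeasible config: need n_planted <= n_shared <= min(n_genes_a, n_genes_b)",
           call. = FALSE)
    }
    if (abs(sum(edge_type_mix) - 1) > 1e-8 || any(edge_type_mix < 0)) {
      stop("infeasible config: edge_type_mix must be a probability vector",
           call. = FALSE)
    }
    check_itypes(names(edge_type_mix))
    if (max(term_size_range) > n_genes_a + n_genes_b - n_shared) {
      stop("infeasible config: term sizes exceed the gene pool",
           call. = FALSE)
    }
    if (n_snp_genes > n_shared || n_snp_genes < n_planted) {
      stop("infeasible config: need n_planted <= n_snp_genes <= n_shared",
           call. = FALSE)
    }
    if (apoptosis_size > n_shared || cns_size > n_shared ||
        apoptosis_planted > min(apoptosis_size, max(n_planted, 1L)) &&
        n_planted > 0L) {
      stop("infeasible config: subset sizes exceed the shared gene pool",
           call. = FALSE)
    }
    if (any(c(n_genes_a, n_genes_b, n_shared, n_planted, n_core_edges,
              n_terms, n_test_processes, n_control_processes) < 0)) {
      stop("infeasible config: counts must be non-negative", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic knowledgebase config (profile '", x$profile, "', seed ",
      x$seed, ")\n", sep = "")
  cat("  genes: ", x$n_genes_a, " + ", x$n_genes_b, " (", x$n_shared,
      " shared, ", x$n_planted, " planted)\n", sep = "")
  cat("  shared typed edges: ", x$n_core_edges, "; processes: ",
      x$n_test_processes, " test / ", x$n_control_processes,
      " control\n", sep = "")
  invisible(x)
}

# independent reproducible RNG stream per artifact
.set_stream <- function(cfg, offset) {
  set.seed((as.integer(cfg$seed) %% 100000L) * 20000L + offset)
}

both_forms <- function(symbols) {
  data.frame(symbol = rep(symbols, each = 2L),
             kind = rep(c("gene", "protein"), length(symbols)),
             stringsAsFactors = FALSE)
}

# draw unique typed edges between node pools until n reached
draw_typed_edges <- function(src_nodes, tgt_nodes, w_src, w_tgt, n, mix,
                             max_iter = 40L) {
  acc <- empty_edges()
  seen <- character(0)
  for (iter in seq_len(max_iter)) {
    need <- n - nrow(acc)
    if (need <= 0L) break
    m <- ceiling(need * 1.5) + 10L
    si <- sample.int(nrow(src_nodes), m, replace = TRUE, prob = w_src)
    ti <- sample.int(nrow(tgt_nodes), m, replace = TRUE, prob = w_tgt)
    itype <- sample(names(mix), m, replace = TRUE, prob = mix)
    df <- data.frame(src_symbol = src_nodes$symbol[si],
                     src_kind = src_nodes$kind[si],
                     tgt_symbol = tgt_nodes$symbol[ti],
                     tgt_kind = tgt_nodes$kind[ti],
                     itype = itype,
                     directed = itype_directed_default(itype),
                     stringsAsFactors = FALSE)
    self <- df$src_symbol == df$tgt_symbol & df$src_kind == df$tgt_kind
    df <- df[!self, , drop = FALSE]
    df <- canonicalize_edges(df)
    key <- edge_key(df)
    fresh <- !duplicated(key) & !key %in% seen
    df <- df[fresh, , drop = FALSE]
    if (nrow(df) > need) df <- df[seq_len(need), , drop = FALSE]
    seen <- c(seen, edge_key(df))
    acc <- rbind(acc, df)
  }
  if (nrow(acc) < n) {
    stop("could not draw ", n, " unique edges; node pool too small",
         call. = FALSE)
  }
  rownames(acc) <- NULL
  acc
}

#' Generate a synthetic knowledgebase dataset
#'
#' Produces two overlapping disease networks (gene and protein vertex forms
#' per symbol), GO-style annotations with terms biased toward the shared
#' genes, a gene-process association table with a test/control partition,
#' SNP annotations with whole-blood eQTL flags, per-population European
#' minor allele frequencies and disease links, two external prioritizer
#' score tables, literature co-mention counts, apoptosis-like and CNS-like
#' gene subsets, and the planted true-comorbidity gene set. Identical
#' configurations (including the seed) give identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`; see Details.
#' @details The returned list carries `config`, `candidates` (shared gene
#'   symbols), `planted`, `network_a`, `network_b`, `annotations`,
#'   `process_tab`, `snps`, `external_rank_1`, `external_rank_2`,
#'   `comention`, `comorbid_diseases`, `subsets`
#'   (`$apoptosis_like`, `$cns_like`).
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config

  shared <- sprintf("CG%03d", seq_len(cfg$n_shared))
  spec_a <- if (cfg$n_genes_a > cfg$n_shared) {
    sprintf("AG%03d", seq_len(cfg$n_genes_a - cfg$n_shared))
  } else character(0)
  spec_b <- if (cfg$n_genes_b > cfg$n_shared) {
    sprintf("BG%03d", seq_len(cfg$n_genes_b - cfg$n_shared))
  } else character(0)

  .set_stream(cfg, 1L)
  planted <- if (cfg$n_planted > 0L) sort(sample(shared, cfg$n_planted))
             else character(0)

  shared_nodes <- both_forms(shared)
  nodes_a <- rbind(shared_nodes, both_forms(spec_a))
  nodes_b <- rbind(shared_nodes, both_forms(spec_b))

  # shared core: identical typed edges in both disease networks; planted
  # symbols get boosted endpoint weight, hence elevated centrality
  .set_stream(cfg, 2L)
  w_core <- ifelse(shared_nodes$symbol %in% planted,
                   cfg$planted_degree_boost, 1)
  core <- draw_typed_edges(shared_nodes, shared_nodes, w_core, w_core,
                           cfg$n_core_edges, cfg$edge_type_mix)

  # disease-specific edges always touch a disease-specific symbol, so the
  # network intersection is exactly the shared core
  .set_stream(cfg, 3L)
  edges_a <- core
  if (cfg$n_specific_edges_a > 0L && length(spec_a) > 0L) {
    spec_a_nodes <- both_forms(spec_a)
    ea <- draw_typed_edges(spec_a_nodes, nodes_a,
                           rep(1, nrow(spec_a_nodes)), rep(1, nrow(nodes_a)),
                           cfg$n_specific_edges_a, cfg$edge_type_mix)
    edges_a <- rbind(core, ea)
  }
  .set_stream(cfg, 4L)
  edges_b <- core
  if (cfg$n_specific_edges_b > 0L && length(spec_b) > 0L) {
    spec_b_nodes <- both_forms(spec_b)
    eb <- draw_typed_edges(spec_b_nodes, nodes_b,
                           rep(1, nrow(spec_b_nodes)), rep(1, nrow(nodes_b)),
                           cfg$n_specific_edges_b, cfg$edge_type_mix)
    edges_b <- rbind(core, eb)
  }
  network_a <- assoc_network(nodes_a, edges_a, label = "disease_A")
  network_b <- assoc_network(nodes_b, edges_b, label = "disease_B")

  # annotations: background terms uniform over the pool, biased terms
  # drawn mostly from the shared genes and seeded with planted genes
  .set_stream(cfg, 5L)
  population <- c(shared, spec_a, spec_b)
  n_background <- cfg$n_terms - cfg$n_biased_terms
  annotations <- list()
  sizes <- sample(seq(cfg$term_size_range[1L], cfg$term_size_range[2L]),
                  cfg$n_terms, replace = TRUE)
  for (i in seq_len(cfg$n_biased_terms)) {
    sz <- sizes[i]
    n_sh <- min(length(shared), round(cfg$biased_shared_fraction * sz))
    members <- c(sample(shared, n_sh),
                 sample(population, sz - n_sh))
    extra <- planted[runif(length(planted)) < cfg$planted_term_prob]
    annotations[[sprintf("GO:%07d", i)]] <- unique(c(extra, members))
  }
  for (i in seq_len(n_background)) {
    sz <- sizes[cfg$n_biased_terms + i]
    annotations[[sprintf("GO:%07d", cfg$n_biased_terms + i)]] <-
      unique(sample(population, sz))
  }

  # gene-process association table with test/control partition
  .set_stream(cfg, 6L)
  processes <- c(sprintf("TP%04d", seq_len(cfg$n_test_processes)),
                 sprintf("CP%05d", seq_len(cfg$n_control_processes)))
  partition <- setNames(rep(c("test", "control"),
                            c(cfg$n_test_processes,
                              cfg$n_control_processes)), processes)
  ii <- integer(0); jj <- integer(0)
  for (gi in seq_along(shared)) {
    p_t <- if (shared[gi] %in% planted) cfg$test_link_prob_planted
           else cfg$test_link_prob_background
    kt <- rbinom(1L, cfg$n_test_processes, p_t)
    kc <- rbinom(1L, cfg$n_control_processes, cfg$control_link_prob)
    jt <- if (kt > 0L) sample.int(cfg$n_test_processes, kt) else integer(0)
    jc <- if (kc > 0L) cfg$n_test_processes +
      sample.int(cfg$n_control_processes, kc) else integer(0)
    jj <- c(jj, jt, jc)
    ii <- c(ii, rep(gi, kt + kc))
  }
  links <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                dims = c(length(shared), length(processes)))
  process_tab <- process_table(shared, processes, links, partition)

  # SNP annotations: a minority of shared genes carry eQTL SNPs; planted
  # genes always carry qualifying SNPs linked to the primary diseases, a
  # comorbid disease and an unrelated disease
  .set_stream(cfg, 7L)
  gene_lengths <- setNames(round(runif(length(shared),
                                       cfg$gene_length_range[1L],
                                       cfg$gene_length_range[2L])), shared)
  non_planted <- setdiff(shared, planted)
  snp_genes <- c(planted,
                 sample(non_planted, cfg$n_snp_genes - cfg$n_planted))
  other_tissues <- c("lung", "liver", "brain")
  primary_diseases <- c("asthma", "hypertension")
  rows <- vector("list", length(snp_genes))
  for (gi in seq_along(snp_genes)) {
    g <- snp_genes[gi]
    n_snp <- sample(seq(cfg$snp_per_gene_range[1L],
                        cfg$snp_per_gene_range[2L]), 1L)
    n_snp <- max(n_snp, if (g %in% planted) 3L else 1L)
    wb <- runif(n_snp) < cfg$eqtl_fraction
    common <- runif(n_snp) < cfg$common_maf_fraction
    base_maf <- ifelse(common, runif(n_snp, 0.05, 0.5),
                       runif(n_snp, 0.001, 0.045))
    jitter <- function() pmin(0.5, pmax(0.001,
                                        base_maf + runif(n_snp, -0.01, 0.01)))
    diseases <- rep("", n_snp)
    if (g %in% planted) {
      wb[1:3] <- TRUE
      base_maf[1:3] <- runif(3L, 0.1, 0.4)
      diseases[1L] <- sample(primary_diseases, 1L)
      diseases[2L] <- sample(.comorbid_disease_pool, 1L)
      diseases[3L] <- sample(.other_disease_pool, 1L)
    }
    rows[[gi]] <- data.frame(
      snp_id = sprintf("rs%03d%04d", gi, seq_len(n_snp)),
      symbol = g,
      tissues = ifelse(wb, "whole blood",
                       sample(other_tissues, n_snp, replace = TRUE)),
      maf_ceu = jitter(), maf_gbr = jitter(), maf_ibs = jitter(),
      maf_tsi = jitter(), diseases = diseases, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  # unrelated-disease links on background SNP genes
  bg <- setdiff(snp_genes, planted)
  give_link <- function(records, genes, pool) {
    for (g in genes) {
      idx <- which(records$symbol == g)[1L]
      records$tissues[idx] <- "whole blood"
      records$maf_ceu[idx] <- records$maf_gbr[idx] <-
        records$maf_ibs[idx] <- records$maf_tsi[idx] <- 0.25
      records$diseases[idx] <- paste(
        unique(c(strsplit(records$diseases[idx], ";")[[1L]],
                 sample(pool, 1L))), collapse = ";")
    }
    records
  }
  if (cfg$n_background_primary > 0L && length(bg) > 0L) {
    records <- give_link(records, sample(bg, min(cfg$n_background_primary,
                                                 length(bg))),
                         primary_diseases)
  }
  if (cfg$n_background_comorbid > 0L && length(bg) > 0L) {
    records <- give_link(records, sample(bg, min(cfg$n_background_comorbid,
                                                 length(bg))),
                         .comorbid_disease_pool)
  }
  if (cfg$n_background_other > 0L && length(bg) > 0L) {
    records <- give_link(records, sample(bg, min(cfg$n_background_other,
                                                 length(bg))),
                         .other_disease_pool)
  }
  records$diseases <- sub("^;", "", records$diseases)
  snps <- snp_annotation(records, gene_lengths)

  # external prioritizer scores: planted-first signal + Gaussian noise on
  # the rank scale; the first score table sorts ascending (p-value-like),
  # the second descending
  .set_stream(cfg, 8L)
  n <- length(shared)
  pos <- setNames(integer(n), shared)
  pos[planted] <- sample.int(cfg$n_planted)
  pos[setdiff(shared, planted)] <- cfg$n_planted +
    sample.int(n - cfg$n_planted)
  er1 <- external_ranks(1L, pos + rnorm(n, 0, cfg$rank_noise),
                        sort_order = "ascending")
  .set_stream(cfg, 9L)
  er2 <- external_ranks(2L, -(pos + rnorm(n, 0, cfg$rank_noise)),
                        sort_order = "descending")

  # literature co-mention counts
  .set_stream(cfg, 10L)
  n_total <- sample(seq(cfg$comention_total_range[1L],
                        cfg$comention_total_range[2L]), n, replace = TRUE)
  rate <- ifelse(shared %in% planted, cfg$comention_rate_planted,
                 cfg$comention_rate_background)
  comention <- data.frame(symbol = shared,
                          n_comorbid = rbinom(n, n_total, rate),
                          n_total = n_total, stringsAsFactors = FALSE)

  # apoptosis-like and CNS-like subsets overlapping the planted genes
  .set_stream(cfg, 11L)
  pick_subset <- function(size, n_from_planted) {
    n_pl <- min(n_from_planted, length(planted))
    sort(c(sample(planted, n_pl),
           sample(non_planted, size - n_pl)))
  }
  subsets <- list(apoptosis_like = pick_subset(cfg$apoptosis_size,
                                               cfg$apoptosis_planted),
                  cns_like = pick_subset(cfg$cns_size, cfg$cns_planted))

  structure(list(config = cfg, candidates = shared, planted = planted,
                 network_a = network_a, network_b = network_b,
                 annotations = annotations, process_tab = process_tab,
                 snps = snps, external_rank_1 = er1, external_rank_2 = er2,
                 comention = comention,
                 comorbid_diseases = .comorbid_disease_pool,
                 subsets = subsets),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic comorbidity dataset (profile '", x$config$profile,
      "', seed ", x$config$seed, ")\n", sep = "")
  cat("  candidates:", length(x$candidates), "shared genes;",
      length(x$planted), "planted\n")
  cat("  disease networks:", nrow(x$network_a$edges), "and",
      nrow(x$network_b$edges), "edges\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes every artifact in the formats the package readers consume, plus a
#' pipeline config (`config.yaml`) referencing them and a `planted.txt`
#' manifest of the true comorbidity genes.
#'
#' @param ds a [generate_synthetic_dataset()] result.
#' @param dir output directory (created if needed).
#' @return path to the written `config.yaml`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_network(ds$network_a, p("network_a.tsv"))
  write_network(ds$network_b, p("network_b.tsv"))
  write_gene_sets(ds$annotations, p("annotations.gmt"))
  write_gene_sets(ds$subsets, p("subsets.gmt"))
  write_process_table(ds$process_tab, p("process_links.tsv"),
                      p("process_partition.tsv"))
  write_snp_table(ds$snps, p("snp_table.tsv"), p("gene_lengths.tsv"))
  for (cid in 1:2) {
    er <- ds[[paste0("external_rank_", cid)]]
    utils::write.table(
      data.frame(symbol = names(er$scores), score = unname(er$scores)),
      p(paste0("external_rank_", cid, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(ds$comention, p("comention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ds$comorbid_diseases, p("comorbid_diseases.txt"))
  writeLines(ds$planted, p("planted.txt"))
  writeLines(ds$candidates, p("candidates.txt"))
  config <- list(
    inputs = list(
      network_a = "network_a.tsv", network_b = "network_b.tsv",
      annotations = "annotations.gmt", subsets = "subsets.gmt",
      process_links = "process_links.tsv",
      process_partition = "process_partition.tsv",
      snp_table = "snp_table.tsv", gene_lengths = "gene_lengths.tsv",
      external_rank_1 = "external_rank_1.tsv",
      external_rank_2 = "external_rank_2.tsv",
      comention = "comention.tsv",
      comorbid_diseases = "comorbid_diseases.txt"),
    params = list(alpha = 0.01, maf_min = 0.05, tissue = "whole blood",
                  populations = c("CEU", "GBR", "IBS", "TSI"),
                  primary_diseases = c("asthma", "hypertension"),
                  external_sort_order = c("ascending", "descending")))
  yaml::write_yaml(config, p("config.yaml"))
  invisible(p("config.yaml"))
}

#' Planted-gene recovery report
#'
#' Measures how many planted true-comorbidity genes the pipeline returned
#' among its top `k` candidates.
#'
#' @param ds the [generate_synthetic_dataset()] the pipeline ran on.
#' @param priority the resulting `gene_priority` (see [aggregate_ranks()]).
#' @param k top-list size; defaults to the number of planted genes.
#' @return list with `k`, `top_k_overlap`, `precision_at_k`.
#' @export
recovery_report <- function(ds, priority, k = NULL) {
  stopifnot(inherits(ds, "synthetic_dataset"),
            inherits(priority, "gene_priority"))
  if (!setequal(priority$table$symbol, ds$candidates)) {
    stop("priority candidates do not match the dataset candidates",
         call. = FALSE)
  }
  if (is.null(k)) k <- length(ds$planted)
  k <- as.integer(k)
  overlap <- length(intersect(top_genes(priority, k), ds$planted))
  list(k = k, top_k_overlap = overlap,
       precision_at_k = if (k > 0L) overlap / k else 0)
}

#' Chance baseline for precision at k
#'
#' Monte-Carlo estimate of the expected precision at `k` when the ten
#' criterion rankings carry no signal: each replicate aggregates ten
#' independent random permutations of the candidates and scores the top
#' `k` against a fixed `k`-gene target set. The expectation is `k / n`.
#'
#' @param n number of candidates.
#' @param k target-set and top-list size.
#' @param n_rep Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list with `mean_precision` and `expected` (`k / n`).
#' @export
chance_precision <- function(n, k, n_rep = 200L, seed = 1L) {
  set.seed(as.integer(seed))
  symbols <- sprintf("G%04d", seq_len(n))
  target <- symbols[seq_len(k)]
  prec <- vapply(seq_len(n_rep), function(i) {
    final <- rowMeans(vapply(1:10, function(j) sample.int(n),
                             integer(n)))
    top <- symbols[order(final, symbols)][seq_len(k)]
    length(intersect(top, target)) / k
  }, numeric(1L))
  list(mean_precision = mean(prec), expected = k / n)
}
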