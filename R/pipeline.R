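# End-to-end orchestration: build the comorbidity networks, run enrichment,
# compute the ten criteria, aggregate, and (file-driven variant) write the
# ranked table, reports and a reproducibility manifest.

#' Prioritize comorbidity candidate genes
#'
#' Runs the full analysis on in-memory inputs: intersects the two disease
#' networks into the complete comorbidity network, extracts the genetic
#' regulatory subnetwork, computes GO-process enrichment for both, derives
#' criteria 1-10 and aggregates them into the final average-rank priority.
#'
#' @param network_a,network_b single-disease [assoc_network()] objects.
#' @param annotations named list of GO-term gene sets
#'   (see [read_gene_sets()]).
#' @param process_tab a [process_table()] with test/control partition.
#' @param external_rank_1,external_rank_2 [external_ranks()] objects
#'   (criteria 1 and 2).
#' @param snps an [snp_annotation()].
#' @param comorbid_diseases character vector of diseases comorbid to either
#'   primary disease (criterion 9).
#' @param candidates candidate gene symbols; defaults to the shared genes
#'   of the complete network.
#' @param alpha significance threshold for enrichment and specificity.
#' @param maf_min inclusive minor-allele-frequency threshold for list Y.
#' @param tissue eQTL tissue for list Y.
#' @param populations population codes averaged for the MAF filter.
#' @param primary_diseases the two diseases under study (criterion 8).
#' @return object of class `comorbidity_run`: list with `priority`
#'   (a `gene_priority`), `bundle` (a `comorbidity_bundle`), `candidates`,
#'   `profiles` (centrality profiles of both networks), `enrichment`
#'   (both enrichment tables), `rankings` (the ten `criterion_ranking`s),
#'   `list_y`, `snp_density`, `external_correlation`, `params`.
#' @seealso [run_pipeline()] for the file-driven variant.
#' @export
prioritize_comorbidity <- function(network_a, network_b, annotations,
                                   process_tab, external_rank_1,
                                   external_rank_2, snps,
                                   comorbid_diseases,
                                   candidates = NULL, alpha = 0.01,
                                   maf_min = 0.05, tissue = "whole blood",
                                   populations = c("CEU", "GBR", "IBS",
                                                   "TSI"),
                                   primary_diseases = c("asthma",
                                                        "hypertension")) {
  bundle <- build_comorbidity(network_a, network_b)
  if (is.null(candidates)) candidates <- bundle$shared_genes
  if (length(candidates) == 0L) {
    stop("no candidate genes: the disease networks share no gene vertices",
         call. = FALSE)
  }

  profile_complete <- gene_centrality_profile(bundle$complete)
  profile_regulatory <- if (nrow(bundle$regulatory$nodes) >= 2L) {
    gene_centrality_profile(bundle$regulatory)
  } else NULL

  population <- unique(unlist(annotations, use.names = FALSE))
  enr_complete <- enriched_processes(
    intersect(network_symbols(bundle$complete), population), annotations,
    population = population, alpha = alpha)
  enr_regulatory <- enriched_processes(
    intersect(network_symbols(bundle$regulatory), population), annotations,
    population = population, alpha = alpha)

  list_y <- build_list_y(snps, tissue = tissue, populations = populations,
                         maf_min = maf_min)
  dens <- if (length(list_y) > 0L &&
              all(names(list_y) %in% names(snps$gene_lengths))) {
    snp_density(list_y, snps$gene_lengths)
  } else NULL

  rankings <- list(
    ingest_external_ranking(external_rank_1, candidates),
    ingest_external_ranking(external_rank_2, candidates),
    criterion_enrichment(enr_complete, enr_regulatory, annotations,
                         candidates),
    criterion_centrality(profile_complete, candidates, 4L),
    criterion_centrality(profile_regulatory, candidates, 5L),
    criterion_process_specificity(process_tab, candidates, alpha = alpha))
  for (cid in 7:10) {
    rankings[[length(rankings) + 1L]] <-
      criterion_snp(list_y, snps, comorbid_diseases, candidates, cid,
                    primary_diseases = primary_diseases)
  }

  priority <- aggregate_ranks(rankings, candidates)
  ext_cor <- tryCatch(rank_correlation(rankings[[1L]], rankings[[2L]]),
                      error = function(e) NULL)

  structure(list(priority = priority, bundle = bundle,
                 candidates = candidates,
                 profiles = list(complete = profile_complete,
                                 regulatory = profile_regulatory),
                 enrichment = list(complete = enr_complete,
                                   regulatory = enr_regulatory),
                 rankings = rankings, list_y = list_y, snp_density = dens,
                 external_correlation = ext_cor,
                 params = list(alpha = alpha, maf_min = maf_min,
                               tissue = tissue, populations = populations,
                               primary_diseases = primary_diseases)),
            class = "comorbidity_run")
}

#' @export
print.comorbidity_run <- function(x, ...) {
  cat("Comorbidity prioritization run\n")
  cat("  shared genes:", length(x$candidates), "| complete network:",
      nrow(x$bundle$complete$edges), "interactions | regulatory:",
      nrow(x$bundle$regulatory$edges), "\n")
  cat("  enriched processes (complete/regulatory):",
      sum(x$enrichment$complete$enriched), "/",
      sum(x$enrichment$regulatory$enriched), "\n")
  if (!is.null(x$external_correlation)) {
    cat(sprintf("  criteria 1-2 rank correlation: r = %.3f (p = %.3g)\n",
                x$external_correlation$r, x$external_correlation$p))
  }
  cat("\n")
  print(x$priority)
  invisible(x)
}

#' @export
summary.comorbidity_run <- function(object, ...) summary(object$priority)

#' Run the comorbidity pipeline from a configuration file
#'
#' Reads every input named in the config, runs
#' [prioritize_comorbidity()], runs the subset analyses when a subsets GMT
#' and co-mention table are supplied, and writes the ranked gene table
#' (columns `gene`, `rank1`..`rank10`, `average`), the complete and
#' regulatory networks, enrichment tables, a subset/co-mention report and
#' a manifest with input/output digests. The run is a pure function of the
#' config and input files; reruns produce identical outputs.
#'
#' @param config path to a YAML config, or an equivalent list, with
#'   entries `inputs` (paths for `network_a`, `network_b`, `annotations`,
#'   `process_links`, `process_partition`, `external_rank_1`,
#'   `external_rank_2`, `snp_table`, `gene_lengths`, `comorbid_diseases`;
#'   optional `subsets`, `comention`, `candidates`) and `params`
#'   (`alpha`, `maf_min`, `tissue`, `populations`, `primary_diseases`,
#'   `external_sort_order`).
#' @param out_dir output directory; default `"run"` next to the config.
#' @param quiet suppress per-stage progress messages.
#' @return the `comorbidity_run`, invisibly, with the output paths in the
#'   `"outputs"` attribute.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  inputs <- config$inputs
  params <- config$params
  if (is.null(params)) params <- list()
  defaults <- list(alpha = 0.01, maf_min = 0.05, tissue = "whole blood",
                   populations = c("CEU", "GBR", "IBS", "TSI"),
                   primary_diseases = c("asthma", "hypertension"),
                   external_sort_order = c("ascending", "descending"))
  params <- utils::modifyList(defaults, params)
  if (is.null(out_dir)) out_dir <- file.path(base_dir, "run")

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  required <- c(network_a = "disease network A",
                network_b = "disease network B",
                annotations = "GO annotations",
                process_links = "gene-process links",
                process_partition = "process partition",
                external_rank_1 = "criterion 1 external ranking",
                external_rank_2 = "criterion 2 external ranking",
                snp_table = "SNP table",
                comorbid_diseases = "comorbid disease list")
  paths <- lapply(inputs, resolve)
  for (key in names(required)) {
    if (is.null(paths[[key]]) || !file.exists(paths[[key]])) {
      stop("missing input for ", required[[key]], " ('", key, "')",
           call. = FALSE)
    }
  }

  stage <- function(msg) if (!quiet) message("[comorbinet] ", msg)
  timings <- list()
  timed <- function(name, expr) {
    t1 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t1,
                                            units = "secs"))
    res
  }

  stage("reading inputs")
  net_a <- timed("read", {
    read_network(paths$network_a)
  })
  net_b <- read_network(paths$network_b)
  annotations <- read_gene_sets(paths$annotations)
  candidates <- if (!is.null(paths$candidates)) {
    readLines(paths$candidates, warn = FALSE)
  } else NULL
  process_tab <- read_process_table(paths$process_links,
                                    paths$process_partition,
                                    genes = candidates)
  er1 <- read_external_ranks(paths$external_rank_1, 1L,
                             params$external_sort_order[1L])
  er2 <- read_external_ranks(paths$external_rank_2, 2L,
                             params$external_sort_order[2L])
  snps <- read_snp_table(paths$snp_table, paths$gene_lengths)
  comorbid <- read_disease_list(paths$comorbid_diseases)
  subsets <- if (!is.null(paths$subsets)) read_gene_sets(paths$subsets)
  comention <- if (!is.null(paths$comention)) {
    comention_frequency(read_comention(paths$comention))
  }

  stage("prioritizing")
  run <- timed("prioritize", prioritize_comorbidity(
    net_a, net_b, annotations, process_tab, er1, er2, snps, comorbid,
    candidates = candidates, alpha = params$alpha,
    maf_min = params$maf_min, tissue = params$tissue,
    populations = params$populations,
    primary_diseases = params$primary_diseases))

  stage("subset analyses")
  subset_report <- list()
  if (!is.null(subsets)) {
    for (nm in names(subsets)) {
      subset_report[[nm]] <- list(
        centrality_complete =
          subset_centrality_test(run$profiles$complete, subsets[[nm]]),
        rank_enrichment =
          tryCatch(toplist_rank_enrichment(run$priority, subsets[[nm]]),
                   error = function(e) list(error = conditionMessage(e))))
    }
  }
  if (!is.null(comention)) {
    subset_report$comention_top10 <- tryCatch(
      toplist_comention_test(comention, top_genes(run$priority, 10L),
                             run$candidates),
      error = function(e) list(error = conditionMessage(e)))
  }

  stage("writing outputs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out_dir, f)
  ranked <- run$priority$table
  names(ranked)[names(ranked) == "symbol"] <- "gene"
  utils::write.table(ranked, o("ranked_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(run$bundle$complete, o("complete_network.tsv"))
  write_network(run$bundle$regulatory, o("regulatory_network.tsv"))
  utils::write.table(run$enrichment$complete, o("enrichment_complete.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$enrichment$regulatory,
                     o("enrichment_regulatory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(subset_report, o("subset_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  summaries <- list(
    complete = unclass(network_summary(run$bundle$complete)),
    regulatory = unclass(network_summary(run$bundle$regulatory)),
    n_candidates = length(run$candidates),
    external_correlation = run$external_correlation)
  jsonlite::write_json(summaries, o("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  out_files <- c("ranked_genes.tsv", "complete_network.tsv",
                 "regulatory_network.tsv", "enrichment_complete.tsv",
                 "enrichment_regulatory.tsv", "subset_report.json",
                 "summary.json")
  manifest <- list(
    params = params,
    inputs = lapply(paths[!vapply(paths, is.null, logical(1L))],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = lapply(setNames(nm = out_files),
                     function(f) list(path = o(f),
                                      md5 = unname(tools::md5sum(o(f))))),
    timings_sec = timings,
    warnings = list(
      candidates_missing_from_external_1 =
        attr(run$rankings[[1L]], "missing"),
      candidates_missing_from_external_2 =
        attr(run$rankings[[2L]], "missing")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  attr(run, "outputs") <- vapply(out_files, o, character(1L))
  attr(run, "subset_report") <- subset_report
  invisible(run)
}
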