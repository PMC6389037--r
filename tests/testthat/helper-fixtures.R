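# Shared fixtures: hand-built toy networks and cached tiny synthetic
# datasets (generation is seeded, so caching is safe).

ed <- function(src, skind, tgt, tkind, itype, directed = NULL) {
  if (is.null(directed)) {
    directed <- unname(comorbinet:::itype_directed_default(itype))
    if (is.na(directed)) directed <- FALSE
  }
  data.frame(src_symbol = src, src_kind = skind, tgt_symbol = tgt,
             tgt_kind = tkind, itype = itype, directed = directed,
             stringsAsFactors = FALSE)
}

# small mixed-type network: gene/protein forms, directed + undirected edges
toy_network <- function() {
  assoc_network(edges = rbind(
    ed("TNF", "protein", "NFKB1", "gene", "expression-upregulation"),
    ed("NFKB1", "protein", "APOA1", "gene", "expression-downregulation"),
    ed("TNF", "gene", "IL10", "gene", "association"),
    ed("IL10", "protein", "APOA1", "protein", "protein-protein"),
    ed("TNF", "gene", "TNF", "gene", "association")
  ), label = "toy")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_dataset <- function(seed = 1L) {
  cached(paste0("tiny", seed), {
    generate_synthetic_dataset(synthetic_config("tiny", seed = seed))
  })
}

tiny_run <- function(seed = 1L) {
  cached(paste0("tinyrun", seed), {
    ds <- tiny_dataset(seed)
    prioritize_comorbidity(ds$network_a, ds$network_b, ds$annotations,
                           ds$process_tab, ds$external_rank_1,
                           ds$external_rank_2, ds$snps,
                           ds$comorbid_diseases)
  })
}

full_dataset <- function(seed = 1L) {
  cached(paste0("full", seed), {
    generate_synthetic_dataset(synthetic_config("full", seed = seed))
  })
}

run_dataset <- function(ds) {
  prioritize_comorbidity(ds$network_a, ds$network_b, ds$annotations,
                         ds$process_tab, ds$external_rank_1,
                         ds$external_rank_2, ds$snps, ds$comorbid_diseases)
}

published_ranks_path <- function() {
  system.file("extdata", "top10_criterion_ranks.tsv",
              package = "comorbinet")
}
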