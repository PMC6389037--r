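# Synthetic knowledgebase generator: determinism, structure, planted
# signal, round-tripping.

test_that("identical seeds give byte-identical datasets; different seeds
           differ", {
  cfg <- synthetic_config("tiny", seed = 5)
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(synthetic_config("tiny", seed = 5))
  dir1 <- tempfile(); dir2 <- tempfile()
  write_synthetic_dataset(d1, dir1)
  write_synthetic_dataset(d2, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- file.path(dir2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  d3 <- generate_synthetic_dataset(synthetic_config("tiny", seed = 6))
  expect_false(identical(d1$planted, d3$planted) &&
               identical(d1$network_a$edges, d3$network_a$edges))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config("tiny", n_planted = 25),
               "infeasible")
  expect_error(synthetic_config("tiny", n_snp_genes = 2),
               "infeasible")
  expect_error(synthetic_config("tiny", bogus_field = 1), "unknown")
  cfg <- synthetic_config("tiny")
  expect_equal(sum(cfg$edge_type_mix), 1)
})

test_that("the intersection of the generated networks is the shared core", {
  ds <- tiny_dataset(1)
  cfg <- ds$config
  xs <- intersect_networks(ds$network_a, ds$network_b)
  # gene + protein forms for every shared symbol
  expect_equal(nrow(xs$nodes), 2L * cfg$n_shared)
  expect_equal(nrow(xs$edges), cfg$n_core_edges)
  expect_setequal(unique(xs$nodes$symbol), ds$candidates)
  expect_true(all(ds$planted %in% ds$candidates))
})

test_that("generated edge-type frequencies follow the configured mix", {
  cfg <- synthetic_config("tiny", seed = 2, n_shared = 60L,
                          n_genes_a = 70L, n_genes_b = 65L,
                          n_core_edges = 1000L,
                          n_specific_edges_a = 0L,
                          n_specific_edges_b = 0L)
  ds <- generate_synthetic_dataset(cfg)
  observed <- table(factor(ds$network_a$edges$itype,
                           levels = names(cfg$edge_type_mix)))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(observed), p = cfg$edge_type_mix))
  expect_gt(gof$p.value, 0.001)
})

test_that("all artifacts round-trip through the package readers", {
  ds <- tiny_dataset(1)
  dir <- tempfile()
  write_synthetic_dataset(ds, dir)
  p <- function(f) file.path(dir, f)

  na <- read_network(p("network_a.tsv"), label = "disease_A")
  expect_identical(na$edges, ds$network_a$edges)
  expect_identical(na$nodes, ds$network_a$nodes)
  expect_equal(read_gene_sets(p("annotations.gmt")), ds$annotations)
  pt <- read_process_table(p("process_links.tsv"),
                           p("process_partition.tsv"),
                           genes = ds$candidates)
  expect_equal(as.matrix(pt$links), as.matrix(ds$process_tab$links),
               ignore_attr = TRUE)
  snps <- read_snp_table(p("snp_table.tsv"), p("gene_lengths.tsv"))
  expect_equal(snps$records$snp_id, ds$snps$records$snp_id)
  expect_equal(snps$gene_lengths, ds$snps$gene_lengths)
  er1 <- read_external_ranks(p("external_rank_1.tsv"), 1)
  expect_equal(er1$scores, ds$external_rank_1$scores, tolerance = 1e-9)
  expect_equal(read_disease_list(p("comorbid_diseases.txt")),
               ds$comorbid_diseases)
})

test_that("without planted genes no candidate passes criteria 8-9", {
  cfg <- synthetic_config("tiny", seed = 3, n_planted = 0L)
  ds <- generate_synthetic_dataset(cfg)
  y <- suppressWarnings(build_list_y(ds$snps))
  n <- length(ds$candidates)
  r8 <- criterion_snp(y, ds$snps, ds$comorbid_diseases, ds$candidates, 8L)
  r9 <- criterion_snp(y, ds$snps, ds$comorbid_diseases, ds$candidates, 9L)
  expect_true(all(r8$ranks == n))
  expect_true(all(r9$ranks == n))
  # background genes with unrelated disease links still satisfy 10
  r10 <- criterion_snp(y, ds$snps, ds$comorbid_diseases, ds$candidates,
                       10L)
  expect_gte(sum(r10$ranks == 1L), 1L)
})

test_that("recovery report scores planted genes in the top list", {
  ds <- tiny_dataset(1)
  run <- tiny_run(1)
  rep <- recovery_report(ds, run$priority)
  expect_equal(rep$k, length(ds$planted))
  expect_equal(rep$precision_at_k, rep$top_k_overlap / rep$k)
  expect_equal(recovery_report(ds, run$priority, k = 0)$top_k_overlap, 0L)

  other <- generate_synthetic_dataset(synthetic_config("tiny", seed = 9,
                                                       n_shared = 21L))
  expect_error(recovery_report(other, run$priority), "do not match")
})

test_that("chance precision baseline approaches k / n", {
  cb <- chance_precision(50, 5, n_rep = 400, seed = 2)
  expect_equal(cb$expected, 0.1)
  expect_lt(abs(cb$mean_precision - cb$expected), 0.03)
})
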