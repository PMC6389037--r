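# Core data types and on-disk formats.

test_that("assoc_network validates inputs and deduplicates edges", {
  net <- toy_network()
  expect_equal(nrow(net$nodes), 8L)
  expect_equal(nrow(net$edges), 5L)
  expect_true(any(net$edges$self_loop))

  # duplicate edge (same endpoints, type, direction) collapses, including
  # the flipped form of an undirected edge
  dup <- rbind(ed("A", "gene", "B", "gene", "association"),
               ed("B", "gene", "A", "gene", "association"),
               ed("A", "gene", "B", "gene", "association"))
  expect_equal(nrow(assoc_network(edges = dup)$edges), 1L)

  # directed edges in opposite directions are distinct
  two <- rbind(ed("A", "gene", "B", "gene", "genetic-regulation"),
               ed("B", "gene", "A", "gene", "genetic-regulation"))
  expect_equal(nrow(assoc_network(edges = two)$edges), 2L)

  expect_error(assoc_network(edges = ed("A", "gene", "B", "gene",
                                        "frobnication")),
               "unknown interaction type")
  expect_error(assoc_network(edges = ed("A", "widget", "B", "gene",
                                        "association")),
               "unknown node kind")
})

test_that("the interaction vocabulary is extensible via the registry", {
  on.exit(reset_interaction_types())
  expect_error(assoc_network(edges = ed("A", "gene", "B", "gene",
                                        "methylation", TRUE)),
               "unknown interaction type")
  register_interaction_type("methylation", directed = TRUE)
  expect_silent(net <- assoc_network(edges = ed("A", "gene", "B", "gene",
                                                "methylation", TRUE)))
  expect_equal(nrow(net$edges), 1L)
})

test_that("network TSV round-trips exactly, including isolated nodes", {
  net <- assoc_network(
    nodes = data.frame(symbol = c("LONE", "X", "Y", "Z"),
                       kind = c("protein", "gene", "gene", "protein")),
    edges = rbind(ed("X", "gene", "Y", "gene", "association"),
                  ed("X", "gene", "Z", "protein", "genetic-regulation"),
                  ed("Y", "gene", "Z", "protein", "protein-protein")),
    label = "rt")
  tmp <- tempfile(fileext = ".tsv")
  write_network(net, tmp)
  back <- read_network(tmp, label = "rt")
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges, net$edges)

  # second round trip is byte-identical (canonical form)
  tmp2 <- tempfile(fileext = ".tsv")
  write_network(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("network reader handles empty files and rejects bad rows", {
  empty <- tempfile(); file.create(empty)
  net <- read_network(empty)
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)

  hdr <- paste(c("src_symbol", "src_kind", "tgt_symbol", "tgt_kind",
                 "itype", "directed"), collapse = "\t")
  bad_fields <- tempfile()
  writeLines(c(hdr, "A\tgene\tB"), bad_fields)
  expect_error(read_network(bad_fields), "line 2")

  bad_itype <- tempfile()
  writeLines(c(hdr, "A\tgene\tB\tgene\tfrobnication\tFALSE"), bad_itype)
  expect_error(read_network(bad_itype), "unknown interaction type")

  two_rows <- tempfile()
  writeLines(c(hdr, "A\tgene\tB\tgene\tassociation\tFALSE",
               "B\tgene\tC\tprotein\texpression\tTRUE"), two_rows)
  net2 <- read_network(two_rows)
  expect_equal(nrow(net2$nodes), 3L)
  expect_equal(nrow(net2$edges), 2L)
})

test_that("SIF input is accepted read-only with vocabulary defaults", {
  sif <- tempfile(fileext = ".sif")
  writeLines(c("TNF association NFKB1 IL10", "NFKB1 genetic-regulation APOA1",
               "LONELY"), sif)
  net <- read_network(sif, format = "sif")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$nodes$kind == "gene"))
  expect_true("LONELY" %in% net$nodes$symbol)
  expect_equal(sort(net$edges$directed), c(FALSE, FALSE, TRUE))
})

test_that("network_summary counts are conserved", {
  net <- toy_network()
  s <- network_summary(net)
  expect_equal(sum(s$edges_by_type), s$n_edges)
  expect_equal(s$n_genes + s$n_proteins, s$n_nodes)
  expect_equal(unname(s$edges_by_type["association"]), 2L)
  expect_equal(unname(s$edges_by_type["protein-protein"]), 1L)
  expect_equal(s$n_self_loops, 1L)

  s0 <- network_summary(assoc_network(label = "void"))
  expect_equal(s0$n_nodes, 0L)
  expect_equal(sum(s0$edges_by_type), 0L)

  # counts invariant under symbol relabeling
  relabeled <- net
  relabeled$nodes$symbol <- paste0("x", relabeled$nodes$symbol)
  relabeled$edges$src_symbol <- paste0("x", relabeled$edges$src_symbol)
  relabeled$edges$tgt_symbol <- paste0("x", relabeled$edges$tgt_symbol)
  relabeled <- assoc_network(relabeled$nodes, relabeled$edges, "toy2")
  s2 <- network_summary(relabeled)
  expect_equal(s2$edges_by_type, s$edges_by_type)
  expect_equal(s2$n_nodes, s$n_nodes)
})

test_that("GMT reader collapses duplicates and preserves order", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("apoptosis\tdesc\tA\tB\tA", "cns\tdesc\tC"), gmt)
  sets <- read_gene_sets(gmt)
  expect_equal(names(sets), c("apoptosis", "cns"))
  expect_equal(sets$apoptosis, c("A", "B"))

  empty <- tempfile(); file.create(empty)
  expect_length(read_gene_sets(empty), 0L)

  bad <- tempfile()
  writeLines(c("ok\tdesc\tA", "loneField"), bad)
  expect_error(read_gene_sets(bad), "line 2")

  # round trip through the writer
  out <- tempfile(fileext = ".gmt")
  write_gene_sets(sets, out)
  expect_equal(read_gene_sets(out), sets)
})

test_that("process table round-trips and validates its partition", {
  genes <- c("g1", "g2", "g3")
  procs <- c("t1", "t2", "c1", "c2", "c3")
  links <- matrix(0, 3, 5)
  links[1, c(1, 2)] <- 1
  links[2, 4] <- 1
  part <- setNames(c("test", "test", "control", "control", "control"),
                   procs)
  tab <- process_table(genes, procs, links, part)
  lp <- tempfile(); pp <- tempfile()
  write_process_table(tab, lp, pp)
  back <- read_process_table(lp, pp, genes = genes)
  expect_equal(back$genes, genes)
  expect_equal(back$processes, procs)
  expect_equal(as.matrix(back$links), as.matrix(tab$links),
               ignore_attr = TRUE)
  expect_equal(back$partition, tab$partition)

  expect_error(process_table(genes, procs, links,
                             setNames(rep("weird", 5), procs)),
               "test.*control")
  expect_error(process_table(genes, procs, links, part[1:3]),
               "cover every process")
})

test_that("external rank tables validate and round-trip", {
  tmp <- tempfile()
  writeLines(c("symbol\tscore", "A\t0.1", "B\t0.5"), tmp)
  er <- read_external_ranks(tmp, 1, "ascending")
  expect_equal(er$scores, c(A = 0.1, B = 0.5))

  dup <- tempfile()
  writeLines(c("symbol\tscore", "A\t0.1", "A\t0.2"), dup)
  expect_error(read_external_ranks(dup, 1), "duplicate symbol")

  expect_error(external_ranks(1, setNames(numeric(0), character(0))),
               "empty")
  expect_error(external_ranks(1, c(A = Inf)), "finite")
  expect_error(external_ranks(3, c(A = 1)))
})

test_that("SNP annotations validate MAF ranges and lengths", {
  rec <- data.frame(snp_id = "rs1", symbol = "G1", tissues = "whole blood",
                    maf_ceu = 0.1, maf_gbr = 0.1, maf_ibs = 0.1,
                    maf_tsi = 0.1, diseases = "")
  expect_silent(snp_annotation(rec, c(G1 = 1000)))
  rec$maf_ceu <- 0.7
  expect_error(snp_annotation(rec), "0, 0.5")
  rec$maf_ceu <- 0.1
  expect_error(snp_annotation(rec, c(G1 = -5)), "positive")
})
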