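# The ten ranking criteria and their aggregation.

test_that("rank_transform assigns ordinal ranks with lexicographic ties
           and the missing-score rule", {
  r <- rank_transform(c(A = 3, B = 1, C = 2), c("A", "B", "C"))
  expect_equal(r$ranks, c(A = 3L, B = 1L, C = 2L))

  # all equal scores: symbol order
  tie <- rank_transform(c(B = 1, A = 1, C = 1), c("A", "B", "C"))
  expect_equal(tie$ranks, c(A = 1L, B = 2L, C = 3L))

  # missing scores drop to rank N
  miss <- rank_transform(c(A = 1, B = 2), c("A", "B", "C", "D", "E"))
  expect_equal(unname(miss$ranks[c("C", "D", "E")]), c(5L, 5L, 5L))

  # permutation property under total scores
  set.seed(13)
  for (i in 1:5) {
    n <- sample(3:40, 1)
    cands <- sample(sprintf("g%02d", 1:n))
    sc <- stats::setNames(stats::rnorm(n), cands)
    rr <- rank_transform(sc, cands)
    expect_setequal(unname(rr$ranks), seq_len(n))
    # descending order reverses an untied ranking
    rd <- rank_transform(sc, cands, direction = "descending")
    expect_equal(unname(rd$ranks[names(sort(sc))]), seq_len(n)[n:1])
  }

  expect_error(rank_transform(c(A = 1), c("A", "A")), "duplicate")
  expect_error(rank_transform(c(A = 1), character(0)), "empty")
})

test_that("external rankings ingest with coverage reporting", {
  er <- external_ranks(1, c(A = 0.2, B = 0.1, C = 0.9))
  r <- ingest_external_ranking(er, c("A", "B", "C", "D"))
  expect_equal(r$ranks, c(A = 2L, B = 1L, C = 3L, D = 4L))
  expect_equal(attr(r, "missing"), "D")

  # reversed sort order flips the ranking of scored genes
  er2 <- external_ranks(2, c(A = 0.2, B = 0.1, C = 0.9),
                        sort_order = "descending")
  r2 <- ingest_external_ranking(er2, c("A", "B", "C"))
  expect_equal(r2$ranks, c(A = 2L, B = 3L, C = 1L))
})

test_that("criterion 3 adds membership counts over both enrichment runs", {
  annotations <- list(t1 = c("A", "B"), t2 = c("A"), t3 = c("B", "C"),
                      t4 = c("A", "C"))
  enr_c <- data.frame(process_id = c("t1", "t2", "t3"),
                      enriched = c(TRUE, TRUE, FALSE))
  enr_r <- data.frame(process_id = c("t4"), enriched = TRUE)
  r <- criterion_enrichment(enr_c, enr_r, annotations, c("A", "B", "C"))
  counts <- attr(r, "counts")
  expect_equal(unname(counts), c(3L, 1L, 1L))      # A: t1+t2+t4
  expect_equal(unname(r$ranks["A"]), 1L)
  # B and C tie at 1 -> lexicographic
  expect_equal(unname(r$ranks[c("B", "C")]), c(2L, 3L))
})

test_that("centrality criteria rank by mean3 with absent symbols last", {
  net <- assoc_network(edges = rbind(
    ed("HUB", "gene", "A", "gene", "association"),
    ed("HUB", "gene", "B", "gene", "association"),
    ed("HUB", "gene", "C", "gene", "association")))
  prof <- gene_centrality_profile(net)
  r4 <- criterion_centrality(prof, c("A", "B", "HUB", "GHOST"), 4L)
  expect_equal(unname(r4$ranks["HUB"]), 1L)
  expect_equal(unname(r4$ranks["GHOST"]), 4L)

  # NULL profile (empty regulatory network): everyone at rank N
  r5 <- criterion_centrality(NULL, c("A", "B"), 5L)
  expect_equal(unname(r5$ranks), c(2L, 2L))
  expect_error(criterion_centrality(prof, c("A"), 6L))
})

test_that("criterion 6 Welch statistics match stats::t.test on dense
           indicators", {
  genes <- c("sep", "flat", "inv", "off")
  procs <- c(paste0("t", 1:20), paste0("c", 1:100))
  part <- stats::setNames(rep(c("test", "control"), c(20, 100)), procs)
  links <- matrix(0, 4, 120, dimnames = list(genes, procs))
  links["sep", 1:20] <- 1                    # all test, no control
  links["flat", c(1:4, 21:40)] <- 1          # same 20% rate in both
  links["inv", 21:80] <- 1                   # control-heavy
  links["off", c(1:10, 21:25)] <- 1          # 10/20 test vs 5/100 control
  tab <- process_table(genes, procs, links, part)
  r <- criterion_process_specificity(tab, genes, alpha = 0.01)
  st <- attr(r, "stats")

  for (g in c("flat", "off", "inv")) {
    ht <- stats::t.test(links[g, 1:20], links[g, 21:120],
                        var.equal = FALSE)
    row <- st[st$symbol == g, ]
    expect_equal(row$t, unname(ht$statistic), tolerance = 1e-12)
    expect_equal(row$df, unname(ht$parameter), tolerance = 1e-12)
    expect_equal(row$p, ht$p.value, tolerance = 1e-12)
  }
  # and against the from-scratch Welch formula oracle
  ow <- oracle_welch(links["off", 1:20], links["off", 21:120])
  expect_equal(st$p[st$symbol == "off"], ow$p, tolerance = 1e-12)

  # perfect separation ranks first; equal-rate gene has t = 0, p = 1
  expect_equal(unname(r$ranks["sep"]), 1L)
  expect_equal(st$t[st$symbol == "flat"], 0)
  expect_equal(st$p[st$symbol == "flat"], 1)
  # the control-heavy gene cannot out-rank any specific gene
  expect_gt(r$ranks[["inv"]], r$ranks[["off"]])

  # genes absent from the table are linkless, not errors
  r2 <- criterion_process_specificity(tab, c(genes, "ghost"))
  expect_equal(unname(r2$ranks["ghost"]),
               max(unname(r2$ranks)))
})

test_that("list Y applies the whole-blood eQTL and inclusive MAF-mean
           filters", {
  rec <- data.frame(
    snp_id = paste0("rs", 1:5),
    symbol = c("G1", "G1", "G2", "G3", "G4"),
    tissues = c("whole blood", "whole blood;lung", "lung",
                "whole blood", "whole blood"),
    maf_ceu = c(0.04, 0.10, 0.30, 0.04, NA),
    maf_gbr = c(0.06, 0.20, 0.30, 0.04, NA),
    maf_ibs = c(0.05, 0.15, 0.30, 0.04, NA),
    maf_tsi = c(0.05, 0.25, 0.30, 0.05, NA),
    diseases = "", stringsAsFactors = FALSE)
  snps <- snp_annotation(rec)
  expect_warning(y <- build_list_y(snps), "without MAF")
  # rs1: mean exactly 0.05 -> included ("at least 5%")
  expect_setequal(y$G1, c("rs1", "rs2"))
  # rs3: right MAF, wrong tissue; rs4: whole blood but mean 0.0425
  expect_false("G2" %in% names(y))
  expect_false("G3" %in% names(y))
  # rs5: no MAF data at all -> excluded with the warning above
  expect_false("G4" %in% names(y))

  # missing populations are ignored in the mean
  rec2 <- rec[2, ]
  rec2$maf_ceu <- NA
  y2 <- build_list_y(snp_annotation(rec2))
  expect_equal(y2$G1, "rs2")   # mean of (0.20, 0.15, 0.25) = 0.2
})

test_that("snp_density bins follow the reporting categories", {
  y <- list(vh = paste0("s", 1:14), mod = "s15", none = character(0),
            sm = "s16", hi = paste0("h", 1:3))
  lens <- c(vh = 2000, mod = 10000, none = 5000, sm = 50000, hi = 1500)
  d <- snp_density(y, lens)
  expect_equal(d$density[d$symbol == "vh"], 7.0)
  expect_equal(d$category[d$symbol == "vh"], "very-high")
  expect_equal(d$density[d$symbol == "mod"], 0.1)
  expect_equal(d$category[d$symbol == "mod"], "moderate")
  expect_equal(d$category[d$symbol == "sm"], "small")
  expect_equal(d$category[d$symbol == "hi"], "high")
  expect_true(is.na(d$category[d$symbol == "none"]))
  expect_equal(d$density[d$symbol == "none"], 0)

  expect_error(snp_density(y, lens[-1]), "no gene length")
})

test_that("SNP criteria 7-10 are binary with the documented disease
           conditions", {
  rec <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    symbol = c("GA", "GB", "GC", "GD"),
    tissues = "whole blood",
    maf_ceu = 0.2, maf_gbr = 0.2, maf_ibs = 0.2, maf_tsi = 0.2,
    diseases = c("asthma", "diabetes mellitus", "psoriasis", ""),
    stringsAsFactors = FALSE)
  snps <- snp_annotation(rec)
  y <- build_list_y(snps)
  cands <- c("GA", "GB", "GC", "GD", "GE")
  comorbid <- "diabetes mellitus"
  n <- length(cands)

  r7 <- criterion_snp(y, snps, comorbid, cands, 7L)
  r8 <- criterion_snp(y, snps, comorbid, cands, 8L)
  r9 <- criterion_snp(y, snps, comorbid, cands, 9L)
  r10 <- criterion_snp(y, snps, comorbid, cands, 10L)

  # binary {1, N} everywhere
  for (r in list(r7, r8, r9, r10)) {
    expect_true(all(r$ranks %in% c(1L, n)))
  }
  expect_equal(unname(r7$ranks), c(1L, 1L, 1L, 1L, n))
  expect_equal(unname(r8$ranks), c(1L, n, n, n, n))
  expect_equal(unname(r9$ranks), c(n, 1L, n, n, n))
  # GA's only link is a primary disease: excluded from criterion 10
  expect_equal(unname(r10$ranks), c(n, n, 1L, n, n))

  # criterion 9 hits are a subset of criterion 7 hits
  expect_true(all(names(r9$ranks)[r9$ranks == 1L] %in%
                  names(r7$ranks)[r7$ranks == 1L]))

  expect_error(criterion_snp(y, snps, character(0), cands, 9L),
               "comorbid")
})

test_that("aggregation reproduces the published worked example and is
           symmetric and monotone", {
  tabl <- utils::read.delim(published_ranks_path())
  cands <- tabl$gene
  rankings <- lapply(1:10, function(cid) {
    comorbinet:::criterion_ranking(
      cid, stats::setNames(tabl[[paste0("rank", cid)]], cands), 205L)
  })
  agg <- aggregate_ranks(rankings, cands)
  out <- agg$table
  expect_equal(out$average[out$symbol == "IL10"], 24.3)
  expect_equal(out$average[out$symbol == "TLR4"], 28.8)
  expect_equal(out$average[out$symbol == "CAT"], 29.1)
  # the published ordering is recovered from the ranks alone
  expect_equal(out$symbol[1:3], c("IL10", "TLR4", "CAT"))

  # permuting criterion order leaves the result unchanged
  agg2 <- aggregate_ranks(rankings[c(7, 2, 10, 4, 5, 1, 6, 3, 9, 8)],
                          cands)
  expect_identical(agg2$table, agg$table)

  # improving one criterion rank strictly lowers the final score
  better <- rankings
  b <- better[[4L]]$ranks
  b["CAT"] <- 1L
  better[[4L]] <- comorbinet:::criterion_ranking(4L, b, 205L)
  agg3 <- aggregate_ranks(better, cands)
  expect_lt(agg3$table$average[agg3$table$symbol == "CAT"],
            out$average[out$symbol == "CAT"])

  # all ranks 1 -> final 1
  ones <- lapply(1:10, function(cid) {
    comorbinet:::criterion_ranking(cid, c(X = 1L), 1L)
  })
  expect_equal(aggregate_ranks(ones, "X")$table$average, 1)

  expect_error(aggregate_ranks(rankings[1:9], cands),
               "missing criterion")
})

test_that("rank correlation matches closed forms", {
  mk <- function(v, id = 1) {
    comorbinet:::criterion_ranking(id, stats::setNames(v, letters[1:4]),
                                   4L)
  }
  expect_equal(rank_correlation(mk(1:4), mk(1:4, 2))$r, 1)
  expect_equal(rank_correlation(mk(1:4), mk(4:1, 2))$r, -1)
  rc <- rank_correlation(mk(1:4), mk(c(2, 1, 4, 3), 2))
  expect_equal(rc$r, 0.6)
  expect_error(rank_correlation(mk(c(2, 2, 2, 2)), mk(1:4, 2)),
               "zero variance")
})
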