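test_that("shared subgraph partitions targets per pathway as in the toy", {
  net <- toy_network(list(q = c("A", "B"), r = c("B", "C")),
                     list(P1 = c("A", "B", "C")))
  sg <- shared_pathway_subgraph(net, "q", "r")
  expect_identical(sg$pathways$pathway_id, "P1")
  expect_identical(sg$targets$P1$common, "B")
  expect_identical(sg$targets$P1$query_only, "A")
  expect_identical(sg$targets$P1$reference_only, "C")
  expect_identical(sg$pathways$contribution, 4L)  # F_q = 2, F_r = 2
  expect_identical(sg$pathways$contribution,
                   as.integer(count_path_instances(net, "q", "r")))
})

test_that("disjoint incidence yields an empty subgraph with a warning", {
  net <- toy_network(list(q = "A", r = "B"),
                     list(P1 = c("A", "X"), P2 = c("B", "Y")))
  expect_warning(sg <- shared_pathway_subgraph(net, "q", "r"), "no shared")
  expect_identical(nrow(sg$pathways), 0L)
})

test_that("self comparison marks every mediating target common", {
  net <- toy_network(list(q = c("A", "B")), list(P1 = c("A", "B")))
  sg <- shared_pathway_subgraph(net, "q", "q")
  expect_setequal(sg$targets$P1$common, c("A", "B"))
  expect_identical(sg$targets$P1$query_only, character(0))
})

test_that("per-pathway contributions always sum to the pair's path count", {
  set.seed(707)
  for (i in 1:15) {
    net <- random_network(p_dt = 0.4, p_tp = 0.4)
    pair <- sample(net$drugs, 2)
    sg <- suppressWarnings(shared_pathway_subgraph(net, pair[1], pair[2]))
    expect_identical(sum(sg$pathways$contribution),
                     as.integer(naive_path_count(net, pair[1], pair[2])))
  }
})

test_that("pathway prediction ranks by contribution with id tie-break", {
  net <- toy_network(list(q = c("A", "B"), r = c("B", "C")),
                     list(P_big = c("A", "B", "C"),   # 2 * 2
                          P_small = c("B"),           # 1 * 1
                          P_tie2 = c("B"), P_tie1 = c("B")))
  pred <- predict_pathways(net, "q", "r")
  expect_identical(pred$pathway_id, c("P_big", "P_small", "P_tie1", "P_tie2"))
  expect_identical(pred$contribution, c(4L, 1L, 1L, 1L))
  expect_identical(nrow(predict_pathways(net, "q", "r", top_n = 2)), 2L)
})

test_that("DE classification applies inclusive boundaries", {
  rec <- data.frame(gene = c("G1", "G2", "G3", "G4", "G5", "G6"),
                    fc = c(2.0, 1.5, 1.2, 1 / 1.5, 0.4, 2.0),
                    fdr = c(0.05, 0.1, 0.01, 0.1, 0.02, 0.2))
  calls <- classify_de(rec)
  expect_identical(calls$call, c("up", "up", "ns", "down", "down", "ns"))
  # exhaustive partition
  expect_true(all(calls$call %in% c("up", "down", "ns")))
  expect_error(classify_de(rbind(rec, rec[1, ])), "duplicate")
})

test_that("log2 fold changes are accepted by declared column name", {
  rec <- data.frame(gene = c("G1", "G2"), log2fc = c(1, -1), fdr = c(0.01, 0.01))
  calls <- classify_de(rec)
  expect_identical(calls$call, c("up", "down"))
  expect_equal(calls$fc, c(2, 0.5))
})

test_that("regulation ratio counts DE genes in the set under both policies", {
  calls <- classify_de(data.frame(
    gene = c("A", "B", "C", "D", "E"),
    fc = c(2, 3, 0.5, 1.0, 2),
    fdr = c(0.01, 0.01, 0.01, 0.01, 0.01)))
  r <- regulation_ratio(calls, c("A", "B", "C", "D"), pathway_id = "P")
  expect_identical(r$n_up, 2L); expect_identical(r$n_down, 1L)
  expect_identical(r$n_de, 3L)
  expect_equal(r$ratio_up, 2 / 3)
  rm <- regulation_ratio(calls, c("A", "B", "C", "D"),
                         denominator = "measured", pathway_id = "P")
  expect_equal(rm$ratio_up, 2 / 4)
  # all ns -> missing ratio, zero counts
  rz <- regulation_ratio(calls, "D", pathway_id = "P")
  expect_identical(rz$n_de, 0L)
  expect_true(is.na(rz$ratio_up))
  # all up -> 1
  expect_equal(regulation_ratio(calls, c("A", "B"))$ratio_up, 1)
  expect_error(regulation_ratio(calls, character(0)), "non-empty")
})

test_that("ratio_up and ratio_down complement when any gene is DE", {
  set.seed(808)
  genes <- sprintf("G%02d", 1:30)
  for (i in 1:20) {
    calls <- data.frame(gene = genes,
                        fc = exp(rnorm(30, 0, 1)),
                        fdr = runif(30), stringsAsFactors = FALSE)
    calls <- classify_de(calls)
    r <- regulation_ratio(calls, sample(genes, 10))
    if (r$n_de > 0) {
      expect_equal(r$ratio_up + r$n_down / r$n_de, 1)
    } else {
      expect_true(is.na(r$ratio_up))
    }
  }
})

test_that("regulation comparison respects the neutral band", {
  rep_at <- function(x) {
    structure(data.frame(contrast = "c", pathway_id = "P", ratio_up = x),
              class = c("regulation_report", "data.frame"))
  }
  expect_identical(as.character(compare_regulation(rep_at(0.9), rep_at(0.8))),
                   "concordant")
  expect_identical(attr(compare_regulation(rep_at(0.9), rep_at(0.8)),
                        "direction"), "up")
  expect_identical(attr(compare_regulation(rep_at(0.1), rep_at(0.3)),
                        "direction"), "down")
  expect_identical(compare_regulation(rep_at(0.9), rep_at(0.1)), "discordant")
  expect_identical(compare_regulation(rep_at(0.5), rep_at(0.9)),
                   "indeterminate")
  expect_identical(compare_regulation(rep_at(NA_real_), rep_at(0.9)),
                   "indeterminate")
  # band edges are inside the band
  expect_identical(compare_regulation(rep_at(0.6), rep_at(0.9)),
                   "indeterminate")
  b <- rep_at(0.9); b$pathway_id <- "Q"
  expect_error(compare_regulation(rep_at(0.9), b), "different pathways")
})

test_that("subgraph export writes viewer-ready edge and node tables", {
  net <- toy_network(list(q = c("A", "B"), r = c("B", "C")),
                     list(P1 = c("A", "B", "C")))
  sg <- shared_pathway_subgraph(net, "q", "r")
  stem <- file.path(withr::local_tempdir(), "sg")
  files <- write_subgraph(sg, stem)
  edges <- read.delim(files[1])
  nodes <- read.delim(files[2])
  expect_setequal(nodes$partition[nodes$node_type == "target"],
                  c("common", "query_only", "reference_only"))
  expect_identical(sum(edges$edge_type == "target-pathway"), 3L)
  # common target B connects to both drugs
  expect_identical(sum(edges$from %in% c("q", "r") & edges$to == "B"), 2L)
})
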