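test_that("bioassay outcomes map to probabilities, aliases included", {
  expect_identical(map_bioassay_outcome("active"), 1)
  expect_identical(map_bioassay_outcome("inactive"), 0)
  expect_identical(map_bioassay_outcome("inconclusive"), 0.5)
  expect_identical(map_bioassay_outcome(c("Active", "UNSPECIFIC", "unspecified")),
                   c(1, 0.5, 0.5))
  expect_error(map_bioassay_outcome("maybe"), "maybe")
})

test_that("noisy-OR confidence combination matches hand values and bounds", {
  expect_equal(combine_confidence(c(stitch = 0.3, pubchem = 0.5, batman = 0.2)),
               1 - 0.7 * 0.5 * 0.8, tolerance = 1e-15)
  expect_identical(combine_confidence(c(stitch = 1)), 1)
  expect_identical(combine_confidence(numeric(0)), 0)
  expect_identical(combine_confidence(c(0, 0, 0)), 0)
  expect_error(combine_confidence(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(combine_confidence(c(-0.1)), "\\[0, 1\\]")
})

test_that("noisy-OR is monotone, permutation-invariant, and absorbing at 1", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:5, 1))
    base <- combine_confidence(p)
    expect_gte(base, 0); expect_lte(base, 1)
    expect_equal(combine_confidence(sample(p)), base, tolerance = 1e-15)
    # adding any positive source never decreases the score
    extra <- runif(1, 0.01, 1)
    expect_gte(combine_confidence(c(p, extra)), base - 1e-15)
    # raising one probability never decreases the score
    j <- sample(seq_along(p), 1)
    p2 <- p; p2[j] <- min(1, p2[j] + runif(1, 0, 1 - p2[j]))
    expect_gte(combine_confidence(p2), base - 1e-15)
    expect_identical(combine_confidence(c(p, 1)), 1)
  }
})

test_that("score_interactions deduplicates within source by max, then combines", {
  ev <- data.frame(
    drug_id = "d1", target_id = "A",
    source = c("stitch", "stitch", "pubchem"),
    probability = c(0.3, 0.6, 0.5))
  out <- score_interactions(ev)
  # duplicate stitch rows collapse to 0.6 before the noisy-OR
  expect_equal(out$combined_score, 1 - 0.4 * 0.5, tolerance = 1e-15)
  expect_identical(out$sources, "pubchem,stitch")
  expect_identical(out$n_sources, 2L)
})

test_that("gene symbols are upper-cased at scoring time", {
  ev <- data.frame(drug_id = "d1", target_id = c("abc", "ABC"),
                   source = c("stitch", "batman"),
                   probability = c(0.3, 0.5))
  out <- score_interactions(ev)
  expect_identical(nrow(out), 1L)
  expect_identical(out$target_id, "ABC")
  expect_equal(out$combined_score, 1 - 0.7 * 0.5, tolerance = 1e-15)
})

test_that("composition merge takes the max score per target, unions sources", {
  m <- merge_composition_targets(list(
    data.frame(target_id = "T1", combined_score = 0.5, sources = "stitch"),
    data.frame(target_id = "T1", combined_score = 0.8, sources = "batman")),
    drug_id = "xyp")
  expect_equal(m$combined_score, 0.8)
  expect_identical(m$sources, "batman,stitch")

  single <- merge_composition_targets(
    list(data.frame(target_id = "T1", combined_score = 0.5)))
  expect_equal(single$combined_score, 0.5)

  multi <- merge_composition_targets(list(
    data.frame(target_id = c("T1", "T2"), combined_score = c(0.5, 0.9)),
    data.frame(target_id = c("T2", "T3"), combined_score = c(0.3, 0.6))))
  expect_identical(multi$target_id, c("T1", "T2", "T3"))
  expect_equal(multi$combined_score, c(0.5, 0.9, 0.6))

  expect_error(merge_composition_targets(list()), "non-empty")
})

test_that("the threshold applies after the composition max-merge", {
  # per-composition all scores are <= 0.4, but the merged profile mixes
  # a passing composition in: ordering matters for T2
  ev <- data.frame(
    drug_id = c("compA", "compA", "compB"),
    target_id = c("T1", "T2", "T2"),
    source = "stitch",
    probability = c(0.35, 0.30, 0.45))
  comp <- data.frame(composition_id = c("compA", "compB"),
                     drug_id = c("xyp", "xyp"))
  merged <- score_interactions(ev, comp)
  kept <- filter_interactions(merged, 0.4)
  expect_identical(kept$target_id, "T2")
  expect_equal(kept$combined_score, 0.45)
})

test_that("filtering is strictly greater-than, boundary excluded", {
  inter <- make_interactions(d = c(T1 = 0.72, T2 = 0.40, T3 = 0.41))
  kept <- filter_interactions(inter, 0.4)
  expect_setequal(kept$target_id, c("T1", "T3"))
  expect_identical(nrow(filter_interactions(inter[0, ], 0.4)), 0L)
  all_pos <- make_interactions(d = c(T1 = 0.1, T2 = 0.9))
  expect_identical(nrow(filter_interactions(all_pos, 0)), 2L)
  expect_error(filter_interactions(inter, 1.5), "\\[0, 1\\]")
})

test_that("class consensus keeps targets supported by >= min_support drugs", {
  sets <- list(d1 = c("A", "B"), d2 = c("B", "C"), d3 = "C")
  expect_identical(class_consensus_targets(sets, 2), c("B", "C"))
  expect_identical(class_consensus_targets(sets, 1), c("A", "B", "C"))
  expect_identical(class_consensus_targets(list(d1 = "A"), 2), character(0))
  expect_error(class_consensus_targets(sets, 0), ">= 1")
})

test_that("build_network edge counts match hand enumeration", {
  inter <- make_interactions(d1 = c(A = 0.9, B = 0.5), d2 = c(B = 0.8, C = 0.3))
  gs <- gene_sets(c("P1", "P2"), genes = list(c("A", "B", "Z"), c("C", "B")))
  net <- build_network(inter, gs, cs_threshold = 0.4)
  # C (score 0.3) drops; dt: d1-A, d1-B, d2-B
  expect_identical(nrow(net$dt_edges), 3L)
  expect_setequal(net$targets, c("A", "B"))
  # restricted tp incidence: P1 x {A,B}, P2 x {B}; Z and C never targeted
  expect_identical(nrow(net$tp_edges), 3L)
  expect_error(build_network(inter, gs, cs_threshold = 1),
               "no interactions")
})

test_that("brute-force incidence agrees with build_network on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    net <- random_network()
    dt_pairs <- unique(paste(net$dt_edges$drug_id, net$dt_edges$target_id))
    expect_identical(nrow(net$dt_edges), length(dt_pairs))
    manual_tp <- 0L
    for (p in net$pathways$ids) {
      manual_tp <- manual_tp +
        length(intersect(net$pathways$genes[[p]], net$targets))
    }
    expect_identical(nrow(net$tp_edges), manual_tp)
  }
})

test_that("pathways with no drug targets stay present but inert", {
  net <- toy_network(list(d1 = "A", d2 = "B"),
                     list(P1 = c("A", "B"), P_empty = c("X", "Y")))
  expect_true("P_EMPTY" %in% toupper(net$pathways$ids) ||
              "P_empty" %in% net$pathways$ids)
  F <- pathway_fingerprints(net)
  expect_identical(unname(F[, "P_empty"]), c(0L, 0L))
})

test_that("restrict_pathways selects by keyword or ids and rejects misses", {
  net <- toy_network(list(d1 = c("A", "B")),
                     list(P_inflamA = c("A"), P_immuneB = c("B")))
  r <- restrict_pathways(net, keyword = "inflam")
  expect_identical(r$pathways$ids, "P_inflamA")
  expect_identical(r$dt_edges, net$dt_edges)
  full <- restrict_pathways(net, pathways = net$pathways$ids)
  expect_identical(full$pathways$ids, net$pathways$ids)
  expect_identical(nrow(full$tp_edges), nrow(net$tp_edges))
  expect_error(restrict_pathways(net, pathways = character(0)), "empty")
  expect_error(restrict_pathways(net, keyword = "zzz"), "matches no")
  expect_error(restrict_pathways(net), "exactly one")
})
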