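# Shared fixtures and independent oracles.

# interaction table shorthand: named score vectors per drug
make_interactions <- function(...) {
  sets <- list(...)
  do.call(rbind, lapply(names(sets), function(d) {
    data.frame(drug_id = d, target_id = names(sets[[d]]),
               combined_score = unname(sets[[d]]),
               stringsAsFactors = FALSE)
  }))
}

# toy tripartite network from target sets + gene sets
toy_network <- function(targets_by_drug, genes_by_pathway,
                        cs_threshold = 0) {
  inter <- do.call(rbind, lapply(names(targets_by_drug), function(d) {
    data.frame(drug_id = d, target_id = targets_by_drug[[d]],
               combined_score = 1, stringsAsFactors = FALSE)
  }))
  gs <- gene_sets(names(genes_by_pathway), genes = genes_by_pathway)
  build_network(inter, gs, cs_threshold = cs_threshold)
}

# independent oracle: exhaustive enumeration of 4-edge metapath walks
# drug -> t1 -> pathway -> t2 -> drug (never touches fingerprints)
naive_path_count <- function(network, x, y) {
  tx <- network$dt_edges$target_id[network$dt_edges$drug_id == x]
  ty <- network$dt_edges$target_id[network$dt_edges$drug_id == y]
  total <- 0L
  for (p in network$pathways$ids) {
    g <- network$pathways$genes[[p]]
    for (t1 in tx) for (t2 in ty) {
      if (t1 %in% g && t2 %in% g) total <- total + 1L
    }
  }
  total
}

# random small tripartite network (drugs may end up degenerate)
random_network <- function(n_drugs = sample(2:8, 1),
                           n_targets = sample(3:25, 1),
                           n_pathways = sample(1:8, 1),
                           p_dt = 0.3, p_tp = 0.3) {
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  targets <- sprintf("t%02d", seq_len(n_targets))
  dt <- expand.grid(drug_id = drugs, target_id = targets,
                    stringsAsFactors = FALSE)
  dt <- dt[stats::runif(nrow(dt)) < p_dt, , drop = FALSE]
  # keep every drug attached so build_network sees all of them
  for (d in setdiff(drugs, unique(dt$drug_id))) {
    dt <- rbind(dt, data.frame(drug_id = d, target_id = sample(targets, 1)))
  }
  genes <- replicate(n_pathways, {
    g <- targets[stats::runif(n_targets) < p_tp]
    if (!length(g)) g <- sample(targets, 1)
    g
  }, simplify = FALSE)
  names(genes) <- sprintf("p%02d", seq_len(n_pathways))
  dt$combined_score <- 1
  build_network(dt, gene_sets(names(genes), genes = genes), cs_threshold = 0)
}

random_target_set <- function(universe = LETTERS, max_size = 8) {
  sample(universe, sample.int(max_size, 1))
}
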