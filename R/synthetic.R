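# Synthetic fixtures with planted mechanism-of-action structure:
# tripartite networks with a query-like confounder whose targets come
# from one drug group but whose pathways come from another, per-source
# evidence tables, and differential-expression tables with planted
# pathway direction.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a planted mechanism-of-action design
#'
#' Describes a synthetic world of `n_groups` drug classes with
#' mutually disjoint target pools and class-specific pathways, plus an
#' optional confounder drug that dissociates the two similarity views:
#' its targets are drawn from a dedicated bridge slice of the
#' target-donor group's pool, while exactly those bridge genes are
#' pathway members only in the pathway-donor group's pathways. Under
#' target-profile similarity the confounder therefore resembles the
#' target donor; under pathway-fingerprint (PathSim) similarity it
#' resembles the pathway donor.
#'
#' Noise is split by stage: `noise_missing` is the probability that a
#' true drug-target edge is absent from the generated network;
#' `noise_spurious` scales the rate at which false drug-target pairs
#' emit evidence records (see [generate_source_evidence()]). Noise
#' draws are coupled via uniform thresholding, so for a fixed seed the
#' perturbation set at a higher rate contains the one at a lower rate.
#'
#' @param n_groups number of drug classes (>= 2 when a confounder is
#'   requested).
#' @param drugs_per_group drugs per class (default 6, echoing a
#'   6-glucocorticoid / 7-NSAID-sized comparison; scalar or vector).
#' @param targets_per_drug targets sampled per drug (default 6).
#' @param core_targets_per_group size of each class's private target
#'   pool (default 20).
#' @param bridge_targets size of the bridge slice (default 8; must be
#'   >= `targets_per_drug`).
#' @param pathways_per_group pathways per class (default 6).
#' @param pathway_size genes sampled per pathway from the class pool
#'   (default 10).
#' @param extra_genes_per_pathway non-target filler genes added to each
#'   pathway (default 5) — present in gene sets and DE tables but never
#'   targeted.
#' @param confounder `NULL`, or list with `target_donor` and
#'   `pathway_donor` group indices (default groups 1 and 2).
#' @param noise_missing,noise_spurious rates in `[0, 1)`.
#' @param seed integer seed recorded on the design.
#' @return an object of class `planted_design`.
#' @export
planted_design <- function(n_groups = 2L, drugs_per_group = 6L,
                           targets_per_drug = 6L,
                           core_targets_per_group = 20L,
                           bridge_targets = 8L,
                           pathways_per_group = 6L, pathway_size = 10L,
                           extra_genes_per_pathway = 5L,
                           confounder = list(target_donor = 1L,
                                             pathway_donor = 2L),
                           noise_missing = 0, noise_spurious = 0,
                           seed = 1L) {
  drugs_per_group <- rep_len(as.integer(drugs_per_group), n_groups)
  counts <- c(n_groups, drugs_per_group, targets_per_drug,
              core_targets_per_group, bridge_targets, pathways_per_group,
              pathway_size)
  if (any(counts < 1)) stop("all design counts must be >= 1", call. = FALSE)
  if (any(c(noise_missing, noise_spurious) < 0) ||
      any(c(noise_missing, noise_spurious) >= 1)) {
    stop("noise rates must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(confounder)) {
    if (is.null(confounder$target_donor) || is.null(confounder$pathway_donor)) {
      stop("confounder needs both target_donor and pathway_donor", call. = FALSE)
    }
    if (confounder$target_donor == confounder$pathway_donor) {
      stop("confounder donors must be distinct groups", call. = FALSE)
    }
    if (max(confounder$target_donor, confounder$pathway_donor) > n_groups) {
      stop("confounder donor index exceeds n_groups", call. = FALSE)
    }
    if (bridge_targets < targets_per_drug) {
      stop("bridge_targets must be >= targets_per_drug", call. = FALSE)
    }
  }
  structure(list(n_groups = as.integer(n_groups),
                 drugs_per_group = drugs_per_group,
                 targets_per_drug = as.integer(targets_per_drug),
                 core_targets_per_group = as.integer(core_targets_per_group),
                 bridge_targets = as.integer(bridge_targets),
                 pathways_per_group = as.integer(pathways_per_group),
                 pathway_size = as.integer(pathway_size),
                 extra_genes_per_pathway = as.integer(extra_genes_per_pathway),
                 confounder = confounder,
                 noise_missing = noise_missing,
                 noise_spurious = noise_spurious,
                 seed = as.integer(seed)),
            class = "planted_design")
}

#' Generate a heterogeneous network with planted group structure
#'
#' @param design a [planted_design()].
#' @param seed overrides `design$seed` if given.
#' @return list of class `planted_network`: `network` (a
#'   `drug_network` built with threshold 0 from the noise-perturbed
#'   true edges), `gene_sets`, `dt_truth` (noise-free true edges),
#'   `truth` (data frame `drug_id`, `target_group`, `pathway_group`;
#'   the two differ only for the confounder, group 0 = filler-free
#'   none), and the `design`.
#' @export
generate_planted_network <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "planted_design"))
  with_seed(seed, {
    G <- design$n_groups
    conf <- design$confounder
    # target pools
    n_core <- design$core_targets_per_group
    pool_core <- lapply(seq_len(G), function(g) {
      sprintf("T%02d_%03d", g, seq_len(n_core))
    })
    bridge <- if (!is.null(conf)) {
      sprintf("TBR_%03d", seq_len(design$bridge_targets))
    } else character(0)
    # drug target sets
    drugs <- character(0); dt <- list(); truth <- list()
    for (g in seq_len(G)) {
      sample_pool <- pool_core[[g]]
      if (!is.null(conf) && g == conf$target_donor) {
        sample_pool <- c(sample_pool, bridge)
      }
      for (i in seq_len(design$drugs_per_group[g])) {
        d <- sprintf("grp%d_drug%02d", g, i)
        drugs <- c(drugs, d)
        tg <- sample(sample_pool, design$targets_per_drug)
        dt[[d]] <- tg
        truth[[d]] <- c(g, g)
      }
    }
    if (!is.null(conf)) {
      d <- "confounder"
      drugs <- c(drugs, d)
      dt[[d]] <- sample(bridge, design$targets_per_drug)
      truth[[d]] <- c(conf$target_donor, conf$pathway_donor)
    }
    # pathways: class pool (+ bridge for the pathway donor) + filler
    ids <- character(0); nms <- character(0); genes <- list()
    grp_label <- c("inflammatory", "immune", "metabolic", "proliferative",
                   "neuronal", "vascular")
    for (g in seq_len(G)) {
      gene_pool <- pool_core[[g]]
      if (!is.null(conf) && g == conf$pathway_donor) {
        gene_pool <- c(gene_pool, bridge)
      }
      lab <- grp_label[(g - 1L) %% length(grp_label) + 1L]
      for (j in seq_len(design$pathways_per_group)) {
        id <- sprintf("PW_g%d_%02d", g, j)
        memb <- sample(gene_pool, min(design$pathway_size, length(gene_pool)))
        filler <- if (design$extra_genes_per_pathway > 0) {
          sprintf("FIL%d_%02d_%02d", g, j,
                  seq_len(design$extra_genes_per_pathway))
        } else character(0)
        ids <- c(ids, id)
        nms <- c(nms, sprintf("%s response pathway %d (group %d)", lab, j, g))
        genes[[id]] <- c(memb, filler)
      }
    }
    gs <- gene_sets(ids, nms, genes, collection = "synthetic")
    dt_truth <- data.frame(
      drug_id = rep(names(dt), lengths(dt)),
      target_id = unlist(dt, use.names = FALSE),
      stringsAsFactors = FALSE)
    # missing-edge noise, coupled across rates by uniform thresholding
    u <- stats::runif(nrow(dt_truth))
    dt_obs <- dt_truth[u >= design$noise_missing, , drop = FALSE]
    interactions <- data.frame(drug_id = dt_obs$drug_id,
                               target_id = dt_obs$target_id,
                               combined_score = 1, sources = "truth",
                               n_sources = 1L, stringsAsFactors = FALSE)
    net <- build_network(interactions, gs, cs_threshold = 0)
    truth_df <- data.frame(drug_id = names(truth),
                           target_group = vapply(truth, `[`, numeric(1), 1),
                           pathway_group = vapply(truth, `[`, numeric(1), 2),
                           stringsAsFactors = FALSE)
    structure(list(network = net, gene_sets = gs, dt_truth = dt_truth,
                   dt_observed = dt_obs, truth = truth_df, design = design),
              class = "planted_network")
  })
}

#' Generate per-source evidence records for a planted network
#'
#' Each observed drug-target edge emits, independently per source, a
#' record with that source's detection probability; the per-source
#' interaction probability of a true record is drawn uniformly on
#' `[0.5, 1]`, so any detected edge passes the default 0.4
#' combined-score filter. Spurious drug-target pairs (never true) are
#' activated with probability `design$noise_spurious *
#' spurious_weight` and emit records with probabilities on `[0, 0.5]`.
#'
#' @param pnet a `planted_network`.
#' @param detect named vector of per-source detection probabilities in
#'   `(0, 1]` (default stitch 0.9, pubchem 0.7, batman 0.8).
#' @param spurious_weight multiplier applied to the design's spurious
#'   rate per candidate false pair (default 0.05).
#' @param seed RNG seed (default `design$seed + 1000`).
#' @return evidence data frame (`drug_id`, `target_id`, `source`,
#'   `probability`) in the dialect of [read_evidence()].
#' @export
generate_source_evidence <- function(pnet,
                                     detect = c(stitch = 0.9, pubchem = 0.7,
                                                batman = 0.8),
                                     spurious_weight = 0.05,
                                     seed = pnet$design$seed + 1000L) {
  stopifnot(inherits(pnet, "planted_network"))
  if (any(detect <= 0) || any(detect > 1)) {
    stop("detection probabilities must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    edges <- pnet$dt_observed
    rows <- list()
    for (s in names(detect)) {
      hit <- stats::runif(nrow(edges)) < detect[[s]]
      if (any(hit)) {
        rows[[s]] <- data.frame(drug_id = edges$drug_id[hit],
                                target_id = edges$target_id[hit],
                                source = s,
                                probability = stats::runif(sum(hit), 0.5, 1),
                                stringsAsFactors = FALSE)
      }
    }
    ev <- do.call(rbind, rows)
    # spurious pairs, coupled across rates by uniform thresholding
    rate <- pnet$design$noise_spurious * spurious_weight
    drugs <- pnet$truth$drug_id
    targets <- sort(unique(pnet$dt_truth$target_id))
    cand <- expand.grid(drug_id = drugs, target_id = targets,
                        stringsAsFactors = FALSE)
    key <- paste(cand$drug_id, cand$target_id)
    truekey <- paste(pnet$dt_truth$drug_id, pnet$dt_truth$target_id)
    cand <- cand[!key %in% truekey, , drop = FALSE]
    u <- stats::runif(nrow(cand))
    fake <- cand[u < rate, , drop = FALSE]
    if (nrow(fake)) {
      frows <- list()
      for (s in names(detect)) {
        hit <- stats::runif(nrow(fake)) < detect[[s]]
        if (any(hit)) {
          frows[[s]] <- data.frame(drug_id = fake$drug_id[hit],
                                   target_id = fake$target_id[hit],
                                   source = s,
                                   probability = stats::runif(sum(hit), 0, 0.5),
                                   stringsAsFactors = FALSE)
        }
      }
      ev <- rbind(ev, do.call(rbind, frows))
    }
    ev <- ev[order(ev$drug_id, ev$target_id, ev$source), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}

#' Generate a differential-expression table with planted direction
#'
#' Genes of up-planted pathways receive fold changes near `effect_fc`
#' with small FDR; down-planted pathways receive fold changes near
#' `1 / effect_fc`. Genes of unplanted pathways and `n_noise_genes`
#' extra genes receive fold changes near 1 and/or large FDR. A gene in
#' several planted pathways takes the direction of the first pathway
#' listing it.
#'
#' @param pnet a `planted_network` (or any list with `gene_sets`).
#' @param planted named character vector: pathway id -> `"up"` or
#'   `"down"`; all ids must exist in the gene sets.
#' @param effect_fc planted linear fold change (> 1; default 2).
#' @param fc_jitter_sd standard deviation of the lognormal jitter on
#'   fold changes (default 0.1).
#' @param responsive_fraction fraction of member genes that respond
#'   (default 1; non-responders behave like noise genes).
#' @param n_noise_genes extra unrelated genes (default 200).
#' @param contrast contrast label written into the table.
#' @param seed RNG seed (default `design seed + 2000` when available).
#' @return DE data frame (`gene`, `fc`, `fdr`, `contrast`) readable by
#'   [classify_de()].
#' @export
generate_expression_table <- function(pnet, planted, effect_fc = 2,
                                      fc_jitter_sd = 0.1,
                                      responsive_fraction = 1,
                                      n_noise_genes = 200L,
                                      contrast = "drug_vs_model",
                                      seed = NULL) {
  gs <- if (inherits(pnet, "gene_sets")) pnet else pnet$gene_sets
  if (is.null(seed)) {
    seed <- if (inherits(pnet, "planted_network"))
      pnet$design$seed + 2000L else 2000L
  }
  if (effect_fc <= 1) stop("effect_fc must exceed 1", call. = FALSE)
  unknown <- setdiff(names(planted), gs$ids)
  if (length(unknown)) {
    stop("planted pathway(s) not in network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(planted %in% c("up", "down"))) {
    stop("planted directions must be 'up' or 'down'", call. = FALSE)
  }
  with_seed(seed, {
    direction <- character(0)  # first-listed pathway wins
    for (p in names(planted)) {
      g <- setdiff(gs$genes[[p]], names(direction))
      direction[g] <- planted[[p]]
    }
    all_genes <- unique(unlist(gs$genes, use.names = FALSE))
    noise_genes <- c(setdiff(all_genes, names(direction)),
                     if (n_noise_genes > 0)
                       sprintf("NOISE_%04d", seq_len(n_noise_genes)))
    sig <- names(direction)
    respond <- stats::runif(length(sig)) < responsive_fraction
    fc <- numeric(length(sig))
    fdr <- numeric(length(sig))
    base <- ifelse(direction == "up", effect_fc, 1 / effect_fc)
    fc[respond] <- base[respond] * exp(stats::rnorm(sum(respond), 0, fc_jitter_sd))
    fdr[respond] <- stats::runif(sum(respond), 0, 0.05)
    fc[!respond] <- exp(stats::rnorm(sum(!respond), 0, fc_jitter_sd))
    fdr[!respond] <- stats::runif(sum(!respond), 0.2, 1)
    out <- data.frame(
      gene = c(sig, noise_genes),
      fc = c(fc, exp(stats::rnorm(length(noise_genes), 0, fc_jitter_sd))),
      fdr = c(fdr, stats::runif(length(noise_genes), 0.2, 1)),
      contrast = contrast, stringsAsFactors = FALSE)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
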