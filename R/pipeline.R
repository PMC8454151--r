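# Run configuration and the end-to-end pipeline: evidence -> combined
# scores -> network -> both similarity views -> clustering -> pathway
# prediction -> regulation reports.

#' Default run configuration
#'
#' All analysis defaults in one place: CS threshold 0.4 (strict),
#' complete linkage, DE-gene ratio denominator, neutral band
#' `[0.4, 0.6]`, DE thresholds FDR 0.1 / FC 1.5.
#'
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    evidence = "", compositions = "", gene_sets = "", de_tables = "",
    out_dir = ".", query = "", k = 2L,
    cs_threshold = 0.4, linkage = "complete",
    fdr_cutoff = 0.1, fc_cutoff = 1.5,
    ratio_denominator = "de",
    neutral_band_low = 0.4, neutral_band_high = 0.6,
    restrict_keyword = "", top_n = 20L, seed = 1L
  ), class = "run_config")
}

config_types <- c(k = "integer", top_n = "integer", seed = "integer",
                  cs_threshold = "numeric", fdr_cutoff = "numeric",
                  fc_cutoff = "numeric", neutral_band_low = "numeric",
                  neutral_band_high = "numeric")

#' Read a run configuration file
#'
#' Plain `key: value` lines (one per key), `#` comments and blank
#' lines ignored; unknown keys are rejected. Unset keys keep their
#' defaults ([default_run_config()]).
#'
#' @param path path to the config file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", sQuote(ln), call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    type <- unname(config_types[key])
    cfg[[key]] <- if (is.na(type)) val
      else if (type == "integer") as.integer(val)
      else as.numeric(val)
  }
  cfg
}

#' Write a run configuration file
#'
#' Inverse of [read_run_config()]; round-trips losslessly.
#'
#' @param config a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", if (is.numeric(v)) format(v, digits = 15) else v)
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

log_stage <- function(...) message("[pathfp] ", ...)

num6 <- function(df) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6L)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(num6(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: read evidence (and optional composition map); combine
#' per-source probabilities and merge compositions; build the
#' thresholded drug-target-pathway network with the GMT collection
#' (optionally restricted by keyword); compute target-profile and
#' PathSim similarity matrices; cluster both views (writing Newick
#' dendrograms and flat k-cluster tables); rank references for the
#' query drug by PathSim; predict the query's pathways from the top
#' reference; and, if DE tables are supplied, score regulation
#' direction of each predicted pathway per contrast. All outputs are
#' plain text under `config$out_dir`; floats carry 6 significant
#' digits; the run is deterministic.
#'
#' @param config a `run_config` (list or path to a config file).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  log_stage("stage score: reading evidence ", config$evidence)
  ev <- read_evidence(config$evidence)
  comp <- if (nzchar(config$compositions))
    read_composition_map(config$compositions) else NULL
  inter <- score_interactions(ev, comp)
  log_stage("scored ", nrow(inter), " interactions from ", nrow(ev), " records")
  paths$interactions <- write_tsv(inter, file.path(out, "interactions.tsv"))

  log_stage("stage build: gene sets ", config$gene_sets,
            ", CS > ", config$cs_threshold)
  gs <- read_gmt(config$gene_sets)
  net <- build_network(inter, gs, cs_threshold = config$cs_threshold)
  if (nzchar(config$restrict_keyword)) {
    net <- restrict_pathways(net, keyword = config$restrict_keyword)
    log_stage("restricted to ", length(net$pathways$ids), " pathways matching ",
              sQuote(config$restrict_keyword))
  }
  paths$network <- file.path(out, "network")
  write_network(net, paths$network)

  log_stage("stage similarity: target Jaccard and PathSim")
  st <- target_similarity_matrix(net)
  sp <- pathsim_matrix(net)
  paths$sim_target <- write_similarity_matrix(st, file.path(out, "sim_target.tsv"))
  paths$sim_pathsim <- write_similarity_matrix(sp, file.path(out, "sim_pathsim.tsv"))

  log_stage("stage cluster: ", config$linkage, " linkage, k = ", config$k)
  for (view in c("target", "pathsim")) {
    sim <- if (view == "target") st else sp
    dend <- hierarchical_cluster(similarity_to_distance(sim),
                                 linkage = config$linkage)
    nwk <- file.path(out, paste0("dendrogram_", view, ".nwk"))
    write_newick(dend, nwk)
    cl <- cut_clusters(dend, config$k)
    tab <- data.frame(drug_id = names(cl), cluster = unname(cl))
    paths[[paste0("dendrogram_", view)]] <- nwk
    paths[[paste0("clusters_", view)]] <-
      write_tsv(tab, file.path(out, paste0("clusters_", view, ".tsv")))
  }

  reports <- NULL
  if (nzchar(config$query)) {
    if (!config$query %in% net$drugs) {
      stop("query drug ", sQuote(config$query), " not in network", call. = FALSE)
    }
    log_stage("stage predict: query ", config$query)
    ranked <- rank_references(sp, config$query)
    paths$ranked_references <-
      write_tsv(ranked, file.path(out, "ranked_references.tsv"))
    reference <- ranked$drug_id[1]
    pred <- predict_pathways(net, config$query, reference,
                             top_n = config$top_n)
    log_stage("top reference ", reference, "; ", nrow(pred),
              " predicted pathway(s)")
    paths$predicted_pathways <-
      write_tsv(pred, file.path(out, "predicted_pathways.tsv"))

    if (nzchar(config$de_tables)) {
      files <- trimws(strsplit(config$de_tables, ",", fixed = TRUE)[[1]])
      log_stage("stage regulate: ", length(files), " DE table(s)")
      rows <- list()
      for (f in files) {
        de <- read_de_table(f)
        for (ctr in unique(de$contrast)) {
          calls <- classify_de(de[de$contrast == ctr, , drop = FALSE],
                               fdr_cutoff = config$fdr_cutoff,
                               fc_cutoff = config$fc_cutoff)
          for (p in pred$pathway_id) {
            rows[[length(rows) + 1L]] <- regulation_ratio(
              calls, net$pathways$genes[[p]],
              denominator = config$ratio_denominator,
              pathway_id = p, contrast = ctr)
          }
        }
      }
      reports <- do.call(rbind, rows)
      paths$regulation <- write_tsv(reports, file.path(out, "regulation.tsv"))
    }
  }

  write_run_config(config, file.path(out, "config_used.txt"))
  paths$config <- file.path(out, "config_used.txt")
  log_stage("pipeline complete: ", length(paths), " artifact(s) in ", out)
  invisible(paths)
}
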