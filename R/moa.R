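# Mechanism-of-action inference: shared metapath subgraphs, pathway
# prediction for a query drug, and regulation direction from
# differential-expression tables.

#' Extract the shared metapath subgraph of two drugs
#'
#' All pathways through which at least one drug-target-pathway-target-
#' drug instance connects the query to the reference, i.e. pathways
#' containing a target of each. Per pathway the mediating targets are
#' partitioned into common / query-only / reference-only, and the
#' pathway's path-instance contribution `F_q[p] * F_r[p]` is recorded;
#' the contributions sum to `count_path_instances(query, reference)`.
#'
#' @param network a `drug_network`.
#' @param query,reference drug ids.
#' @return an object of class `metapath_subgraph`: list with `query`,
#'   `reference`, `pathways` (data frame `pathway_id`, `pathway_name`,
#'   `n_query`, `n_reference`, `n_common`, `contribution`, sorted by
#'   descending contribution then id) and `targets` (named list per
#'   pathway with elements `common`, `query_only`, `reference_only`).
#' @export
shared_pathway_subgraph <- function(network, query, reference) {
  F <- pathway_fingerprints(network)
  for (d in c(query, reference)) {
    if (!d %in% rownames(F)) stop("unknown drug id: ", d, call. = FALSE)
  }
  tq <- drug_targets(network)[[query]]
  tr <- drug_targets(network)[[reference]]
  shared <- colnames(F)[F[query, ] > 0 & F[reference, ] > 0]
  if (!length(shared)) {
    warning("no shared metapath instances between ", query, " and ",
            reference, call. = FALSE)
  }
  gs <- network$pathways
  targets <- stats::setNames(lapply(shared, function(p) {
    g <- gs$genes[[p]]
    mq <- intersect(tq, g); mr <- intersect(tr, g)
    list(common = sort(intersect(mq, mr)),
         query_only = sort(setdiff(mq, mr)),
         reference_only = sort(setdiff(mr, mq)))
  }), shared)
  tab <- data.frame(
    pathway_id = shared,
    pathway_name = gs$names[match(shared, gs$ids)],
    n_query = as.integer(F[query, shared]),
    n_reference = as.integer(F[reference, shared]),
    n_common = vapply(targets, function(t) length(t$common), integer(1)),
    contribution = as.integer(F[query, shared] * F[reference, shared]),
    stringsAsFactors = FALSE)
  ord <- order(-tab$contribution, tab$pathway_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(query = query, reference = reference,
                 pathways = tab, targets = targets[tab$pathway_id]),
            class = "metapath_subgraph")
}

#' @export
print.metapath_subgraph <- function(x, ...) {
  cat("metapath_subgraph: ", x$query, " ~ ", x$reference, ", ",
      nrow(x$pathways), " shared pathway(s), total contribution ",
      sum(x$pathways$contribution), "\n", sep = "")
  if (nrow(x$pathways)) print(utils::head(x$pathways, 10L))
  invisible(x)
}

#' Write a metapath subgraph as edge-list + node-attribute tables
#'
#' `<stem>_edges.tsv` holds drug-target and target-pathway edges of the
#' subgraph; `<stem>_nodes.tsv` labels each node with its type and
#' target partition (common / query_only / reference_only), suitable
#' for network viewers.
#'
#' @param subgraph a `metapath_subgraph`.
#' @param stem output path stem.
#' @return the files written, invisibly.
#' @export
write_subgraph <- function(subgraph, stem) {
  edges <- list(); nodes <- list()
  for (p in subgraph$pathways$pathway_id) {
    part <- subgraph$targets[[p]]
    for (lab in names(part)) {
      for (t in part[[lab]]) {
        if (lab != "reference_only")
          edges[[length(edges) + 1L]] <- c(subgraph$query, t, "drug-target")
        if (lab != "query_only")
          edges[[length(edges) + 1L]] <- c(subgraph$reference, t, "drug-target")
        edges[[length(edges) + 1L]] <- c(t, p, "target-pathway")
        nodes[[t]] <- c(t, "target", lab)
      }
    }
    nodes[[p]] <- c(p, "pathway", "shared")
  }
  nodes[[subgraph$query]] <- c(subgraph$query, "drug", "query")
  nodes[[subgraph$reference]] <- c(subgraph$reference, "drug", "reference")
  edf <- unique(as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE))
  names(edf) <- c("from", "to", "edge_type")
  ndf <- as.data.frame(do.call(rbind, nodes), stringsAsFactors = FALSE)
  names(ndf) <- c("node", "node_type", "partition")
  files <- c(paste0(stem, "_edges.tsv"), paste0(stem, "_nodes.tsv"))
  utils::write.table(edf, files[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ndf, files[2], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Predict pathway associations of a query drug from a reference
#'
#' The shared pathways of query and reference, ranked by descending
#' path-instance contribution (ties by pathway id): the reference
#' drug's pathway associations that the query plausibly shares.
#'
#' @param network a `drug_network`.
#' @param query,reference drug ids.
#' @param top_n keep at most this many pathways (default all).
#' @return the ranked pathway data frame of
#'   [shared_pathway_subgraph()].
#' @export
predict_pathways <- function(network, query, reference, top_n = Inf) {
  sg <- shared_pathway_subgraph(network, query, reference)
  utils::head(sg$pathways, top_n)
}

#' Read a differential-expression table
#'
#' TSV with header; required columns `gene`, `fdr`, and either `fc`
#' (linear fold change, > 0) or `log2fc` (signed log2 fold change,
#' converted to linear). The fold-change convention is declared by the
#' column name, never sniffed from values. An optional `contrast`
#' column labels the comparison.
#'
#' @param path path to the TSV.
#' @return data frame with columns `gene`, `fc` (linear), `fdr`, and
#'   `contrast` (empty string if absent).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  if (!all(c("gene", "fdr") %in% names(df))) {
    stop("DE table needs columns gene, fdr", call. = FALSE)
  }
  if ("fc" %in% names(df)) {
    fc <- as.numeric(df$fc)
  } else if ("log2fc" %in% names(df)) {
    fc <- 2^as.numeric(df$log2fc)
  } else {
    stop("DE table needs a fold-change column named fc or log2fc",
         call. = FALSE)
  }
  if (anyNA(fc) || any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be finite and positive on the linear scale",
         call. = FALSE)
  }
  fdr <- as.numeric(df$fdr)
  if (anyNA(fdr) || any(fdr < 0 | fdr > 1)) {
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  }
  data.frame(gene = toupper(df$gene), fc = fc, fdr = fdr,
             contrast = if ("contrast" %in% names(df))
               as.character(df$contrast) else "",
             stringsAsFactors = FALSE)
}

#' Classify genes as up / down / not significant
#'
#' A gene is differentially expressed when `fdr <= fdr_cutoff` and its
#' linear fold change is `>= fc_cutoff` (up) or `<= 1 / fc_cutoff`
#' (down); both boundaries are inclusive. Everything else is `ns`.
#'
#' @param records DE data frame for a single contrast: columns `gene`,
#'   `fc` (linear) or `log2fc`, `fdr`. Duplicate genes are rejected.
#' @param fdr_cutoff FDR threshold (default 0.1, inclusive).
#' @param fc_cutoff linear fold-change threshold (default 1.5,
#'   inclusive; must be > 1).
#' @return data frame `gene`, `fc`, `fdr`, `call` with `call` in
#'   `{"up", "down", "ns"}`.
#' @export
classify_de <- function(records, fdr_cutoff = 0.1, fc_cutoff = 1.5) {
  if (fc_cutoff <= 1) stop("fc_cutoff must exceed 1", call. = FALSE)
  df <- records
  if (!"fc" %in% names(df) && "log2fc" %in% names(df)) df$fc <- 2^df$log2fc
  if (!all(c("gene", "fc", "fdr") %in% names(df))) {
    stop("records need columns gene, fc (or log2fc), fdr", call. = FALSE)
  }
  df$gene <- toupper(df$gene)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene(s) within the contrast: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  sig <- df$fdr <= fdr_cutoff
  call <- rep("ns", nrow(df))
  call[sig & df$fc >= fc_cutoff] <- "up"
  call[sig & df$fc <= 1 / fc_cutoff] <- "down"
  data.frame(gene = df$gene, fc = df$fc, fdr = df$fdr, call = call,
             stringsAsFactors = FALSE)
}

#' Regulation direction of a pathway after treatment
#'
#' Counts the up- and down-regulated differentially expressed genes
#' inside a gene set and reports the up-regulated ratio. The default
#' denominator is the number of DE genes in the set (`n_up + n_down`,
#' policy `"de"`); policy `"measured"` divides by all genes of the set
#' present in the DE table. When the denominator is 0 the ratio is
#' `NA`.
#'
#' @param de_calls output of [classify_de()].
#' @param gene_set character vector of gene symbols (non-empty).
#' @param denominator `"de"` (default) or `"measured"`.
#' @param pathway_id,contrast labels carried into the report.
#' @return one-row data frame (class `regulation_report`): `contrast`,
#'   `pathway_id`, `n_up`, `n_down`, `n_de`, `n_measured`, `ratio_up`,
#'   `denominator_policy`.
#' @export
regulation_ratio <- function(de_calls, gene_set,
                             denominator = c("de", "measured"),
                             pathway_id = "", contrast = "") {
  denominator <- match.arg(denominator)
  if (!length(gene_set)) stop("gene_set must be non-empty", call. = FALSE)
  inset <- de_calls[de_calls$gene %in% toupper(gene_set), , drop = FALSE]
  n_up <- sum(inset$call == "up")
  n_down <- sum(inset$call == "down")
  denom <- if (denominator == "de") n_up + n_down else nrow(inset)
  out <- data.frame(contrast = contrast, pathway_id = pathway_id,
                    n_up = n_up, n_down = n_down, n_de = n_up + n_down,
                    n_measured = nrow(inset),
                    ratio_up = if (denom > 0) n_up / denom else NA_real_,
                    denominator_policy = denominator,
                    stringsAsFactors = FALSE)
  class(out) <- c("regulation_report", "data.frame")
  out
}

#' Compare the regulation direction of one pathway under two contrasts
#'
#' With a neutral band (default `[0.4, 0.6]`): both ratios above the
#' band is concordant (up), both below concordant (down), opposite
#' sides discordant, and any ratio inside the band (inclusive) or
#' missing is indeterminate.
#'
#' @param report_a,report_b one-row [regulation_ratio()] reports for
#'   the same pathway.
#' @param neutral_band numeric length-2, lower and upper bound.
#' @return one of `"concordant"`, `"discordant"`, `"indeterminate"`;
#'   concordant results carry the shared direction in attribute
#'   `direction`.
#' @export
compare_regulation <- function(report_a, report_b,
                               neutral_band = c(0.4, 0.6)) {
  if (!identical(report_a$pathway_id, report_b$pathway_id)) {
    stop("reports describe different pathways: ",
         report_a$pathway_id, " vs ", report_b$pathway_id, call. = FALSE)
  }
  side <- function(r) {
    if (is.na(r)) return(0L)
    if (r > neutral_band[2]) return(1L)
    if (r < neutral_band[1]) return(-1L)
    0L
  }
  sa <- side(report_a$ratio_up); sb <- side(report_b$ratio_up)
  if (sa == 0L || sb == 0L) return("indeterminate")
  if (sa == sb) {
    structure("concordant", direction = if (sa > 0) "up" else "down")
  } else {
    "discordant"
  }
}
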