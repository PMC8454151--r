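# Gene sets (GMT) and the drug-target-pathway heterogeneous network.

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: set id, description, then one gene per
#' field. Gene symbols are upper-cased; duplicate genes within a set are
#' dropped.
#'
#' @param path path to the GMT file.
#' @param collection label recorded on the collection (e.g. "GOBP").
#' @return an object of class `gene_sets`: a list with `ids`, `names`
#'   (descriptions), `genes` (list of character vectors, named by id),
#'   and `collection`.
#' @export
read_gmt <- function(path, collection = "unspecified") {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("GMT file ", path, " contains no gene sets", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop("GMT file ", path, ": line(s) with fewer than 3 fields: ",
         paste(utils::head(which(short), 5L), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("GMT file ", path, ": duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])])))
  names(genes) <- ids
  gene_sets(ids, vapply(fields, `[[`, character(1), 2L), genes, collection)
}

#' Construct a gene-set collection in memory
#'
#' @param ids pathway identifiers (unique).
#' @param names pathway descriptions (defaults to `ids`).
#' @param genes list of character vectors of gene symbols, same length
#'   as `ids`.
#' @param collection label for the collection.
#' @return a `gene_sets` object.
#' @export
gene_sets <- function(ids, names = ids, genes, collection = "unspecified") {
  stopifnot(length(ids) == length(genes), length(ids) == length(names))
  genes <- lapply(genes, function(g) unique(toupper(g)))
  if (any(vapply(genes, length, integer(1)) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  names(genes) <- ids
  structure(list(ids = as.character(ids), names = as.character(names),
                 genes = genes, collection = collection),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("gene_sets:", length(x$ids), "sets, collection", sQuote(x$collection),
      "\n  sizes:", paste(range(vapply(x$genes, length, integer(1))),
                          collapse = "-"), "genes\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gs a `gene_sets` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(seq_along(gs$ids), function(i) {
    paste(c(gs$ids[i], gs$names[i], gs$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

subset_gene_sets <- function(gs, keep) {
  structure(list(ids = gs$ids[keep], names = gs$names[keep],
                 genes = gs$genes[keep], collection = gs$collection),
            class = "gene_sets")
}

#' Build the drug-target-pathway heterogeneous network
#'
#' Applies the confidence-score filter (strict `>`) to merged
#' interactions and assembles the tripartite network: drug-target edges
#' from the retained interactions, target-pathway edges from gene-set
#' membership. By default target-pathway incidence is restricted to
#' genes that are a target of at least one drug — non-target genes
#' cannot mediate any metapath instance, so pathway fingerprints are
#' unaffected; the full gene sets are retained on the object for
#' display and regulation scoring.
#'
#' @param interactions merged interaction table (see
#'   [score_interactions()]).
#' @param gene_sets a `gene_sets` object.
#' @param cs_threshold confidence-score threshold (default 0.4,
#'   strict).
#' @param restrict_tp if `TRUE` (default) restrict target-pathway
#'   incidence to drug targets.
#' @return an object of class `drug_network` with elements `drugs`,
#'   `targets`, `pathways` (the `gene_sets`), `dt_edges` (data frame
#'   `drug_id`, `target_id`, `combined_score`), `tp_edges` (data frame
#'   `target_id`, `pathway_id`), `cs_threshold`.
#' @export
build_network <- function(interactions, gene_sets, cs_threshold = 0.4,
                          restrict_tp = TRUE) {
  if (!inherits(gene_sets, "gene_sets")) {
    stop("gene_sets must be a gene_sets object (see read_gmt)", call. = FALSE)
  }
  kept <- filter_interactions(interactions, cs_threshold)
  if (nrow(kept) == 0L) {
    stop("no interactions survive the CS > ", cs_threshold,
         " filter; network would be empty", call. = FALSE)
  }
  kept$target_id <- toupper(kept$target_id)
  drugs <- sort(unique(kept$drug_id))
  targets <- sort(unique(kept$target_id))
  tp <- do.call(rbind, lapply(seq_along(gene_sets$ids), function(i) {
    g <- gene_sets$genes[[i]]
    if (restrict_tp) g <- intersect(g, targets)
    if (!length(g)) return(NULL)
    data.frame(target_id = g, pathway_id = gene_sets$ids[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tp)) {
    tp <- data.frame(target_id = character(0), pathway_id = character(0))
  }
  dt <- kept[c("drug_id", "target_id")]
  dt$combined_score <- kept$combined_score  # metadata only; edges unweighted
  rownames(dt) <- NULL
  structure(list(drugs = drugs, targets = targets, pathways = gene_sets,
                 dt_edges = dt, tp_edges = tp, cs_threshold = cs_threshold),
            class = "drug_network")
}

#' @export
print.drug_network <- function(x, ...) {
  cat("drug_network: ", length(x$drugs), " drugs, ", length(x$targets),
      " targets, ", length(x$pathways$ids), " pathways\n",
      "  dt edges: ", nrow(x$dt_edges), " (CS > ", x$cs_threshold, ")",
      "; tp edges: ", nrow(x$tp_edges), "\n", sep = "")
  invisible(x)
}

#' Target set of each drug in a network
#'
#' @param network a `drug_network`.
#' @return named list mapping drug id to its character vector of
#'   targets.
#' @export
drug_targets <- function(network) {
  out <- split(network$dt_edges$target_id, network$dt_edges$drug_id)
  out <- lapply(out, unique)
  out[network$drugs]
}

#' Restrict a network to a subset of pathways
#'
#' Selection is either an explicit vector of pathway ids or a
#' case-insensitive substring match against pathway names (and ids).
#' Drug-target edges are unchanged; target-pathway edges are induced.
#'
#' @param network a `drug_network`.
#' @param pathways character vector of pathway ids.
#' @param keyword single string matched as a substring (fixed, not
#'   regex) against pathway names and ids, case-insensitively. Exactly
#'   one of `pathways` / `keyword` must be given.
#' @return the restricted `drug_network`.
#' @export
restrict_pathways <- function(network, pathways = NULL, keyword = NULL) {
  if (is.null(pathways) == is.null(keyword)) {
    stop("give exactly one of `pathways` or `keyword`", call. = FALSE)
  }
  gs <- network$pathways
  if (!is.null(pathways)) {
    if (!length(pathways)) stop("empty pathway selection", call. = FALSE)
    missing_ids <- setdiff(pathways, gs$ids)
    if (length(missing_ids)) {
      stop("pathway id(s) not in network: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    keep <- gs$ids %in% pathways
  } else {
    kw <- tolower(keyword)
    keep <- grepl(kw, tolower(gs$names), fixed = TRUE) |
      grepl(kw, tolower(gs$ids), fixed = TRUE)
    if (!any(keep)) {
      stop("keyword ", sQuote(keyword), " matches no pathway", call. = FALSE)
    }
  }
  out <- network
  out$pathways <- subset_gene_sets(gs, keep)
  out$tp_edges <- network$tp_edges[
    network$tp_edges$pathway_id %in% out$pathways$ids, , drop = FALSE]
  rownames(out$tp_edges) <- NULL
  out
}

#' Pathway fingerprints of all drugs
#'
#' The fingerprint of a drug is its vector of per-pathway target
#' counts: `F[x, p] = |targets(x) intersect genes(p)|` over the
#' thresholded network. Inner products of fingerprints count metapath
#' instances (drug-target-pathway-target-drug walks).
#'
#' @param network a `drug_network`.
#' @return integer matrix, drugs x pathways, dimnames set.
#' @export
pathway_fingerprints <- function(network) {
  drugs <- network$drugs
  paths <- network$pathways$ids
  D <- matrix(0L, length(drugs), length(network$targets),
              dimnames = list(drugs, network$targets))
  D[cbind(network$dt_edges$drug_id, network$dt_edges$target_id)] <- 1L
  M <- matrix(0L, length(network$targets), length(paths),
              dimnames = list(network$targets, paths))
  tp <- network$tp_edges[network$tp_edges$target_id %in% network$targets, ,
                         drop = FALSE]
  if (nrow(tp)) M[cbind(tp$target_id, tp$pathway_id)] <- 1L
  F <- D %*% M
  storage.mode(F) <- "integer"
  F
}

#' Serialize a network to plain-text files
#'
#' Writes `<stem>_dt_edges.tsv`, `<stem>_tp_edges.tsv`,
#' `<stem>_pathways.gmt` and a JSON header `<stem>_header.json`
#' carrying the threshold and collection label.
#'
#' @param network a `drug_network`.
#' @param stem output path stem.
#' @return character vector of the files written, invisibly.
#' @export
write_network <- function(network, stem) {
  files <- c(dt = paste0(stem, "_dt_edges.tsv"),
             tp = paste0(stem, "_tp_edges.tsv"),
             gmt = paste0(stem, "_pathways.gmt"),
             hdr = paste0(stem, "_header.json"))
  dt <- network$dt_edges
  dt$combined_score <- signif(dt$combined_score, 6L)
  utils::write.table(dt, files["dt"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$tp_edges, files["tp"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(network$pathways, files["gmt"])
  jsonlite::write_json(list(cs_threshold = network$cs_threshold,
                            collection = network$pathways$collection,
                            n_drugs = length(network$drugs),
                            n_targets = length(network$targets),
                            n_pathways = length(network$pathways$ids)),
                       files["hdr"], auto_unbox = TRUE, digits = NA)
  invisible(unname(files))
}

#' Read a network serialized by [write_network()]
#'
#' @param stem the path stem used at write time.
#' @return a `drug_network`.
#' @export
read_network <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, "_header.json"), simplifyVector = TRUE)
  dt <- utils::read.table(paste0(stem, "_dt_edges.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  tp <- utils::read.table(paste0(stem, "_tp_edges.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE)
  gs <- read_gmt(paste0(stem, "_pathways.gmt"), collection = hdr$collection)
  structure(list(drugs = sort(unique(dt$drug_id)),
                 targets = sort(unique(dt$target_id)),
                 pathways = gs, dt_edges = dt, tp_edges = tp,
                 cs_threshold = hdr$cs_threshold),
            class = "drug_network")
}
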