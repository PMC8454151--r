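# Drug-drug similarity: target-profile Jaccard and PathSim over the
# drug-target-pathway-target-drug metapath.

#' Jaccard similarity of two target sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets have no defined
#' similarity; the score is reported as 0 with a warning.
#'
#' @param t_a,t_b character vectors of target gene symbols.
#' @return a number in `[0, 1]`.
#' @export
target_jaccard <- function(t_a, t_b) {
  a <- unique(toupper(t_a)); b <- unique(toupper(t_b))
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both target sets empty; Jaccard similarity undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Count metapath instances between two drugs
#'
#' The number of 4-edge walks drug x -> target t1 -> pathway p ->
#' target t2 -> drug y, where (x, t1) and (y, t2) are thresholded
#' drug-target edges and t1, t2 are members of p. A walk with t1 = t2
#' (one shared target) is a valid instance. Equals the inner product of
#' the two pathway fingerprints.
#'
#' @param network a `drug_network`.
#' @param x,y drug ids (x = y allowed: the self path count).
#' @return a non-negative integer.
#' @export
count_path_instances <- function(network, x, y) {
  F <- pathway_fingerprints(network)
  for (d in c(x, y)) {
    if (!d %in% rownames(F)) stop("unknown drug id: ", d, call. = FALSE)
  }
  sum(as.numeric(F[x, ]) * as.numeric(F[y, ]))
}

#' PathSim similarity of two drugs
#'
#' `s(x, y) = 2 c(x, y) / (c(x, x) + c(y, y))`, where `c` counts
#' metapath instances ([count_path_instances()]). Bounded in `[0, 1]`
#' (Cauchy-Schwarz on the fingerprint vectors); `s(x, x) = 1` whenever
#' the drug has at least one self instance. A drug with no targets in
#' any pathway is degenerate: its similarities are reported as 0 with a
#' warning.
#'
#' @param network a `drug_network`.
#' @param x,y drug ids.
#' @return a number in `[0, 1]`.
#' @export
pathsim <- function(network, x, y) {
  cxx <- count_path_instances(network, x, x)
  cyy <- count_path_instances(network, y, y)
  if (cxx + cyy == 0) {
    warning("drugs ", x, " and ", y,
            " have no metapath instances; PathSim undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  2 * count_path_instances(network, x, y) / (cxx + cyy)
}

new_similarity_matrix <- function(values, method, provenance) {
  structure(values, class = c("similarity_matrix", "matrix", "array"),
            method = method, provenance = provenance)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (", attr(x, "method"), "): ", nrow(x), " drugs\n",
      sep = "")
  print(signif(unclass(x)[, , drop = FALSE], 4L), ...)
  invisible(x)
}

#' All-pairs PathSim matrix
#'
#' Computed through the fingerprint formulation: with fingerprint
#' matrix F, the commuting matrix `C = F F^T` holds all path-instance
#' counts and `s(x, y) = 2 C[x, y] / (C[x, x] + C[y, y])`. Degenerate
#' drugs (zero self count) get similarity 0 everywhere, 0 on the
#' diagonal, with one warning naming them.
#'
#' @param network a `drug_network`.
#' @return a `similarity_matrix` (symmetric, values in `[0, 1]`, unit
#'   diagonal for non-degenerate drugs) with attribute `method =
#'   "pathsim"`.
#' @export
pathsim_matrix <- function(network) {
  F <- pathway_fingerprints(network)
  C <- F %*% t(F)
  d <- diag(C)
  denom <- outer(d, d, `+`)
  S <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  ok <- denom > 0
  S[ok] <- 2 * C[ok] / denom[ok]
  degenerate <- names(d)[d == 0]
  if (length(degenerate)) {
    warning("degenerate drug(s) with no metapath instances: ",
            paste(degenerate, collapse = ", "), "; similarities set to 0",
            call. = FALSE)
    S[degenerate, ] <- 0
    S[, degenerate] <- 0
  }
  new_similarity_matrix(S, "pathsim",
                        list(cs_threshold = network$cs_threshold,
                             collection = network$pathways$collection,
                             n_pathways = length(network$pathways$ids)))
}

#' All-pairs target-profile similarity matrix
#'
#' Pairwise Jaccard similarity of the drugs' filtered target sets.
#'
#' @param x a `drug_network`, or a named list mapping drug id to a
#'   character vector of targets (at least 2 drugs).
#' @return a `similarity_matrix` with attribute `method =
#'   "target_jaccard"`.
#' @export
target_similarity_matrix <- function(x) {
  sets <- if (inherits(x, "drug_network")) drug_targets(x) else
    lapply(x, function(t) unique(toupper(t)))
  if (length(sets) < 2L) {
    stop("need at least 2 drugs for a similarity matrix", call. = FALSE)
  }
  drugs <- names(sets)
  n <- length(drugs)
  S <- diag(1, n)
  dimnames(S) <- list(drugs, drugs)
  empty <- vapply(sets, length, integer(1)) == 0L
  diag(S) <- ifelse(empty, 0, 1)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- if (empty[i] && empty[j]) 0 else
        length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
      S[i, j] <- S[j, i] <- s
    }
  }
  if (any(empty)) {
    warning("drug(s) with empty target sets: ",
            paste(drugs[empty], collapse = ", "), call. = FALSE)
  }
  new_similarity_matrix(S, "target_jaccard", list(n_drugs = n))
}

#' Write a similarity matrix as TSV with a JSON sidecar
#'
#' @param sim a `similarity_matrix`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  m <- signif(unclass(sim), 6L)
  df <- data.frame(drug_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(method = attr(sim, "method")),
                         attr(sim, "provenance")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#'
#' @param path the TSV path.
#' @return a `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$drug_id
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_similarity_matrix(m, meta$method, meta[setdiff(names(meta), "method")])
}
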