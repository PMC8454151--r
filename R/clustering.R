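# Agglomerative hierarchical clustering of drugs on 1 - similarity,
# with deterministic tie-breaking, flat cuts, and reference ranking.
#
# The linkage update is implemented here rather than delegated to
# stats::hclust so that stats::hclust can serve as an independent
# cross-check in the test suite.

#' Convert a bounded similarity matrix to a distance matrix
#'
#' `d = 1 - s`; the diagonal is forced to exactly 0. Input must be
#' symmetric to within 1e-9 with values in `[0, 1]`.
#'
#' @param sim a `similarity_matrix` (or plain symmetric matrix).
#' @return a symmetric distance matrix with zero diagonal, drug ids as
#'   dimnames.
#' @export
similarity_to_distance <- function(sim) {
  m <- unclass(sim)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-9) {
    stop("similarity matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  }
  if (anyNA(m) || any(m < -1e-12 | m > 1 + 1e-12)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  d <- 1 - (m + t(m)) / 2  # symmetrize away rounding noise
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering
#'
#' Standard bottom-up clustering under complete, average (UPGMA) or
#' single linkage. Ties in the minimum inter-cluster distance are
#' broken deterministically: the candidate pair whose member clusters
#' contain the smallest original leaf indices wins. The result
#' mirrors the `stats::hclust` structure (`merge`, `height`, `order`,
#' `labels`) and inherits from class `hclust`, so `cutree()`,
#' `plot()` and `ape::as.phylo()` apply.
#'
#' @param distances symmetric numeric distance matrix (zero diagonal)
#'   or a `dist` object; at least 2 items.
#' @param linkage one of `"complete"` (default), `"average"`,
#'   `"single"`.
#' @return an object of classes `drug_dendrogram` and `hclust`.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(distances, "dist")) as.matrix(distances) else
    as.matrix(distances)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (anyNA(d)) stop("distance matrix contains NA/NaN", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active cluster state: id in merge-matrix convention (negative leaf,
  # positive merge step), size, smallest original leaf index (tie key)
  D <- d
  active <- rep(TRUE, n)
  id <- -seq_len(n)
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_len(length(idx) - 1L)) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        if (dij < best_d - 1e-15) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-15 && !is.null(best)) {
          # tie: prefer the pair with lexicographically smallest
          # (min leaf of first, min leaf of second) key
          cand <- sort(c(minleaf[i], minleaf[j]))
          inc <- sort(c(minleaf[best[1]], minleaf[best[2]]))
          if (cand[1] < inc[1] || (cand[1] == inc[1] && cand[2] < inc[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    # hclust convention: singletons listed before clusters, else by id
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- best_d
    # Lance-Williams update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- switch(linkage,
        complete = max(D[i, k], D[j, k]),
        single   = min(D[i, k], D[j, k]),
        average  = (size[i] * D[i, k] + size[j] * D[j, k]) /
                   (size[i] + size[j]))
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height,
                 order = leaf_order(merge, n), labels = labels,
                 method = linkage, dist.method = "1 - similarity"),
            class = c("drug_dendrogram", "hclust"))
}

# left-to-right leaf order by recursive traversal of the merge matrix
leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Cut a dendrogram into k flat clusters
#'
#' Replays the first `n - k` merges; cluster labels are assigned in
#' order of each cluster's first appearance among the leaves (so labels
#' are stable up to relabeling under input permutation).
#'
#' @param dendrogram an `hclust`-like object (e.g. from
#'   [hierarchical_cluster()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector mapping drug id to cluster label.
#' @export
cut_clusters <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n) {
    stop("k must be an integer in [1, ", n, "]", call. = FALSE)
  }
  k <- as.integer(k)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_step <- integer(n - 1L)  # representative leaf per merge step
  nsteps <- n - k
  for (step in seq_len(nsteps)) {
    m <- dendrogram$merge[step, ]
    reps <- vapply(m, function(node) {
      if (node < 0) -node else cluster_of_step[node]
    }, integer(1))
    r1 <- find(reps[1]); r2 <- find(reps[2])
    parent[max(r1, r2)] <- min(r1, r2)
    cluster_of_step[step] <- min(r1, r2)
  }
  # steps beyond the cut still need representatives defined
  if (nsteps < n - 1L) {
    for (step in (nsteps + 1L):(n - 1L)) {
      m <- dendrogram$merge[step, 1]
      cluster_of_step[step] <- if (m < 0) -m else cluster_of_step[m]
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels_in_order <- unique(root)
  out <- match(root, labels_in_order)
  names(out) <- dendrogram$labels
  out
}

#' Rank reference drugs by similarity to a query
#'
#' All drugs other than the query, sorted by descending similarity;
#' ties broken by lexicographic drug id.
#'
#' @param sim a `similarity_matrix`.
#' @param query a drug id present in the matrix.
#' @return data frame with columns `drug_id`, `similarity`, ranked.
#' @export
rank_references <- function(sim, query) {
  m <- unclass(sim)
  if (!query %in% rownames(m)) {
    stop("query drug ", sQuote(query), " not in similarity matrix",
         call. = FALSE)
  }
  others <- setdiff(rownames(m), query)
  s <- m[query, others]
  ord <- order(-s, others)
  data.frame(drug_id = others[ord], similarity = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of merge heights, via
#' `ape::as.phylo()`.
#'
#' @param dendrogram an `hclust`-like object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}
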