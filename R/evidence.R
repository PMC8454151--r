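# Multi-source drug-target evidence: ingestion, noisy-OR confidence
# integration, composition merging, thresholding, class consensus.

#' Map a bioassay outcome label to an interaction probability
#'
#' PubChem-style bioassay outcomes are encoded as probabilities:
#' `active` = 1, `inactive` = 0, `inconclusive` (aliases `unspecific`,
#' `unspecified`) = 0.5. Matching is case-insensitive.
#'
#' @param outcome character vector of outcome labels.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' map_bioassay_outcome(c("active", "Inactive", "unspecific"))
#' @export
map_bioassay_outcome <- function(outcome) {
  key <- tolower(trimws(as.character(outcome)))
  lut <- c(active = 1, inactive = 0, inconclusive = 0.5,
           unspecific = 0.5, unspecified = 0.5)
  bad <- !is.na(key) & !(key %in% names(lut))
  if (any(bad)) {
    stop("unknown bioassay outcome label(s): ",
         paste(sQuote(unique(key[bad])), collapse = ", "), call. = FALSE)
  }
  unname(lut[key])
}

#' Combine per-source interaction probabilities into one confidence score
#'
#' Noisy-OR aggregation: `CS = 1 - prod(1 - P_s)` over the evidence
#' sources. A source with no record contributes probability 0 (an
#' identity factor), so only the probabilities present need to be
#' supplied. The result is monotone non-decreasing in every source
#' probability, permutation-invariant, and absorbs at 1.
#'
#' @param per_source numeric vector of per-source probabilities, each in
#'   `[0, 1]` (names optional; empty vector gives 0).
#' @return the combined confidence score, a single number in `[0, 1]`.
#' @examples
#' combine_confidence(c(stitch = 0.3, pubchem = 0.5, batman = 0.2)) # 0.72
#' @export
combine_confidence <- function(per_source) {
  p <- as.numeric(per_source)
  if (length(p) == 0L) return(0)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("per-source probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - p)
}

#' Read a drug-target evidence table
#'
#' Tab-separated with a header and columns `drug_id`, `target_id`,
#' `source`, `probability`. Lines starting with `#` are skipped. The
#' probability column may carry bioassay outcome labels (e.g. `active`)
#' for assay-derived sources; these are mapped with
#' [map_bioassay_outcome()]. Target gene symbols are upper-cased to
#' absorb case drift between sources.
#'
#' @param path path to the TSV file.
#' @return a data frame with columns `drug_id`, `target_id`, `source`,
#'   `probability` (numeric).
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id", "source", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("evidence table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  prob <- suppressWarnings(as.numeric(df$probability))
  labelled <- is.na(prob) & !is.na(df$probability) & nzchar(df$probability)
  if (any(labelled)) prob[labelled] <- map_bioassay_outcome(df$probability[labelled])
  bad <- which(is.na(prob) | prob < 0 | prob > 1)
  if (length(bad)) {
    stop("evidence table ", path, ": probability outside [0, 1] or missing ",
         "on data row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  data.frame(drug_id = df$drug_id, target_id = toupper(df$target_id),
             source = tolower(df$source), probability = prob,
             stringsAsFactors = FALSE)
}

#' Write a drug-target evidence table
#'
#' Inverse of [read_evidence()] (round-trip safe for numeric
#' probabilities).
#'
#' @param evidence data frame as returned by [read_evidence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a composition-to-drug map
#'
#' Multi-composition preparations (e.g. an injection containing several
#' related active compounds) are represented by one row per composition:
#' columns `composition_id`, `drug_id`. Evidence recorded under a
#' `composition_id` is merged into the parent `drug_id` by the max rule
#' (see [score_interactions()]).
#'
#' @param path path to the two-column TSV.
#' @return data frame with columns `composition_id`, `drug_id`.
#' @export
read_composition_map <- function(path) {
  if (!file.exists(path)) stop("composition map not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("composition_id", "drug_id")
  if (!all(need %in% names(df))) {
    stop("composition map needs columns composition_id, drug_id", call. = FALSE)
  }
  df[need]
}

#' Score drug-target interactions from multi-source evidence
#'
#' Per (drug, target, source), duplicate records are resolved by keeping
#' the maximum probability. Per (drug, target), the surviving per-source
#' probabilities are combined by noisy-OR ([combine_confidence()]).
#' If a composition map is supplied, the per-composition combined scores
#' are then collapsed into the parent drug by taking, for each target,
#' the largest combined score over compositions (sources are unioned).
#' The threshold is deliberately NOT applied here; see
#' [filter_interactions()] — filtering must happen after the max merge.
#'
#' @param evidence data frame with columns `drug_id`, `target_id`,
#'   `source`, `probability` (numeric in `[0, 1]`).
#' @param composition_map optional data frame from
#'   [read_composition_map()].
#' @return data frame with columns `drug_id`, `target_id`,
#'   `combined_score`, `sources` (comma-joined sorted source names),
#'   `n_sources`, sorted by drug then target.
#' @export
score_interactions <- function(evidence, composition_map = NULL) {
  need <- c("drug_id", "target_id", "source", "probability")
  if (!all(need %in% names(evidence))) {
    stop("evidence needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  ev <- evidence
  ev$target_id <- toupper(ev$target_id)
  ev$source <- tolower(ev$source)
  if (!is.numeric(ev$probability) || anyNA(ev$probability) ||
      any(ev$probability < 0 | ev$probability > 1)) {
    stop("evidence probabilities must be numeric in [0, 1]", call. = FALSE)
  }
  # within-source duplicates: keep the maximum probability
  key3 <- paste(ev$drug_id, ev$target_id, ev$source, sep = "\r")
  pmaxd <- tapply(ev$probability, key3, max)
  parts <- do.call(rbind, strsplit(names(pmaxd), "\r", fixed = TRUE))
  ev <- data.frame(drug_id = parts[, 1], target_id = parts[, 2],
                   source = parts[, 3], probability = as.numeric(pmaxd),
                   stringsAsFactors = FALSE)
  # noisy-OR across sources per (drug, target)
  key2 <- paste(ev$drug_id, ev$target_id, sep = "\r")
  cs <- tapply(ev$probability, key2, function(p) 1 - prod(1 - p))
  src <- tapply(ev$source, key2, function(s) paste(sort(unique(s)), collapse = ","))
  nsrc <- tapply(ev$source, key2, function(s) length(unique(s)))
  parts <- do.call(rbind, strsplit(names(cs), "\r", fixed = TRUE))
  out <- data.frame(drug_id = parts[, 1], target_id = parts[, 2],
                    combined_score = as.numeric(cs),
                    sources = as.character(src),
                    n_sources = as.integer(nsrc),
                    stringsAsFactors = FALSE)
  if (!is.null(composition_map)) {
    idx <- match(out$drug_id, composition_map$composition_id)
    mapped <- !is.na(idx)
    out$drug_id[mapped] <- composition_map$drug_id[idx[mapped]]
    out <- collapse_max(out)
  }
  out <- out[order(out$drug_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# max combined score / union of sources per (drug, target)
collapse_max <- function(tbl) {
  key <- paste(tbl$drug_id, tbl$target_id, sep = "\r")
  cs <- tapply(tbl$combined_score, key, max)
  src <- tapply(tbl$sources, key, function(s) {
    paste(sort(unique(unlist(strsplit(s, ",", fixed = TRUE)))), collapse = ",")
  })
  parts <- do.call(rbind, strsplit(names(cs), "\r", fixed = TRUE))
  data.frame(drug_id = parts[, 1], target_id = parts[, 2],
             combined_score = as.numeric(cs), sources = as.character(src),
             n_sources = vapply(strsplit(as.character(src), ",", fixed = TRUE),
                                function(x) length(x[nzchar(x)]), integer(1)),
             stringsAsFactors = FALSE)
}

#' Merge per-composition interaction sets into one drug profile
#'
#' When one preparation is represented by several compositions, the
#' final confidence score of each target is the largest combined score
#' that any composition achieved for it; contributing sources are
#' unioned.
#'
#' @param per_composition non-empty list of interaction data frames
#'   (columns `target_id`, `combined_score`, optionally `sources`).
#' @param drug_id drug identifier assigned to the merged profile.
#' @return one interaction data frame for `drug_id`, one row per target.
#' @export
merge_composition_targets <- function(per_composition, drug_id = "merged") {
  if (!is.list(per_composition) || length(per_composition) == 0L ||
      is.data.frame(per_composition)) {
    stop("per_composition must be a non-empty list of interaction tables",
         call. = FALSE)
  }
  tabs <- lapply(per_composition, function(x) {
    if (!all(c("target_id", "combined_score") %in% names(x))) {
      stop("each composition table needs target_id and combined_score",
           call. = FALSE)
    }
    data.frame(drug_id = drug_id, target_id = toupper(x$target_id),
               combined_score = x$combined_score,
               sources = if ("sources" %in% names(x)) x$sources else "",
               stringsAsFactors = FALSE)
  })
  out <- collapse_max(do.call(rbind, tabs))
  out <- out[order(out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter interactions by combined confidence score
#'
#' Retains interactions with `combined_score` strictly greater than the
#' threshold; the boundary value itself is excluded.
#'
#' @param interactions data frame with a `combined_score` column.
#' @param threshold retention threshold in `[0, 1]` (default 0.4).
#' @return the retained rows, original order preserved.
#' @export
filter_interactions <- function(interactions, threshold = 0.4) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  out <- interactions[interactions$combined_score > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus targets of a drug class
#'
#' Targets hit by at least `min_support` drugs of a class (e.g. the
#' common targets of the glucocorticoids, defined as targeted by at
#' least two of them).
#'
#' @param targets_by_drug named list mapping drug id to a character
#'   vector of its (filtered) targets.
#' @param min_support minimum number of supporting drugs (default 2).
#' @return sorted character vector of consensus targets (possibly
#'   empty).
#' @export
class_consensus_targets <- function(targets_by_drug, min_support = 2L) {
  if (!is.numeric(min_support) || min_support < 1) {
    stop("min_support must be >= 1", call. = FALSE)
  }
  per_drug <- lapply(targets_by_drug, function(x) unique(toupper(x)))
  counts <- table(unlist(per_drug, use.names = FALSE))
  sort(names(counts)[counts >= min_support])
}
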