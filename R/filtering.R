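# Non-specific protein filtering and the experiment-similarity (Jaccard)
# graph. Abundant "sticky" contaminants (heat-shock, ribosomal, hnRNP
# proteins, ...) appear in most pull-downs regardless of bait and would
# otherwise dominate co-occurrence scores.

#' Remove sticky (non-specific) proteins from a count matrix
#'
#' Drops the rows of `matrix` whose protein identifier is on the sticky
#' list; columns are untouched. Sticky identifiers absent from the matrix
#' are ignored (their count is reported). Idempotent.
#'
#' @param matrix an [spc_matrix].
#' @param sticky character vector of non-specific protein identifiers.
#' @return A filtered [spc_matrix]. An empty result (all proteins sticky)
#'   is allowed, with a warning.
#' @export
apply_sticky_filter <- function(matrix, sticky) {
  stopifnot(inherits(matrix, "spc_matrix"))
  sticky <- unique(as.character(sticky))
  pid <- protein_ids(matrix)
  hit <- pid %in% sticky
  unused <- setdiff(sticky, pid)
  message(sum(hit), " sticky protein(s) removed (", length(unused),
          " list entries absent from the matrix)")
  keep <- pid[!hit]
  if (!length(keep)) warning("sticky filter removed every protein")
  out <- matrix
  out$spc <- matrix$spc[keep, , drop = FALSE]
  out$q <- matrix$q[keep, , drop = FALSE]
  out$mw <- matrix$mw[keep]
  out
}

#' Jaccard distance between two identified-protein sets
#'
#' `JD(A, B) = 1 - |A intersect B| / |A union B|`; a metric on sets, used to
#' relate pull-down experiments by the overlap of their protein lists.
#'
#' @param set_a,set_b character vectors (duplicates ignored). At least one
#'   must be non-empty.
#' @return Jaccard distance in \[0, 1\].
#' @export
jaccard_distance <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) stop_usage("Jaccard distance undefined for two empty sets")
  1 - length(intersect(set_a, set_b)) / u
}

#' Experiment-similarity graph from pull-down protein lists
#'
#' Scores every experiment pair by Jaccard distance between their
#' identified-protein sets and keeps an edge where `JD < threshold`
#' (default 0.7). Experiments left without any edge are dropped, so the
#' graph shows only the clusters of mutually similar pull-downs.
#'
#' @param experiments an [experiment_table].
#' @param threshold keep-edge cutoff in (0, 1\].
#' @return A list of class `similarity_graph` with `nodes` (data frame:
#'   `experiment`, `list_size`) and `edges` (data frame: `experiment_a`,
#'   `experiment_b`, `jd`).
#' @export
build_similarity_graph <- function(experiments, threshold = 0.7) {
  stopifnot(inherits(experiments, "experiment_table"))
  if (!(threshold > 0 && threshold <= 1))
    stop_usage("threshold must be in (0, 1]")
  sets <- experiments$protein_sets
  eid <- names(sets)
  prot <- unique(unlist(sets, use.names = FALSE))
  # incidence matrix -> all pairwise intersection sizes in one crossprod
  inc <- vapply(sets, function(s) prot %in% s, logical(length(prot)))
  inc <- matrix(as.numeric(inc), nrow = length(prot),
                dimnames = list(prot, eid))
  inter <- crossprod(inc)
  sz <- colSums(inc)
  uni <- outer(sz, sz, "+") - inter
  jd <- ifelse(uni > 0, 1 - inter / uni, NA_real_)
  ut <- which(upper.tri(jd) & !is.na(jd) & jd < threshold, arr.ind = TRUE)
  edges <- data.frame(experiment_a = eid[ut[, 1]],
                      experiment_b = eid[ut[, 2]],
                      jd = jd[ut], stringsAsFactors = FALSE)
  edges <- edges[order(edges$experiment_a, edges$experiment_b), , drop = FALSE]
  rownames(edges) <- NULL
  keep <- eid[eid %in% c(edges$experiment_a, edges$experiment_b)]
  nodes <- data.frame(experiment = keep,
                      list_size = unname(lengths(sets)[keep]),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d experiments, %d edges (JD < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Flag frequently appearing proteins as sticky candidates
#'
#' Helper to derive a non-specific list directly from the data: proteins
#' identified in more than `fraction` of all experiments are flagged. This
#' is a convenience heuristic; a curated list from nuclear-extract controls
#' is the preferred input to [apply_sticky_filter()].
#'
#' @param matrix an [spc_matrix].
#' @param fraction appearance-frequency cutoff in (0, 1\] (default 0.5).
#' @return character vector of flagged protein identifiers.
#' @export
derive_sticky_list <- function(matrix, fraction = 0.5) {
  stopifnot(inherits(matrix, "spc_matrix"))
  freq <- rowMeans(matrix$spc > 0)
  protein_ids(matrix)[freq > fraction]
}
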