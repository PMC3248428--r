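# Prediction networks and complex extraction. High-confidence pair sets
# are turned into undirected simple graphs, pruned to edges supported by
# three-node cliques (triangles), and split into connected components that
# are reported as predicted protein complexes.

#' Build a prediction network from a pair set
#'
#' Nodes are the distinct proteins of the pair set, annotated with role
#' `"bait"` if the protein served as bait in at least one experiment and
#' `"prey"` otherwise. Edges carry the score columns of the input and,
#' when a reference set is given, a `class` label from [classify_edges()].
#'
#' @param pair_set data frame with columns `protein_a`, `protein_b` and
#'   optional score columns (e.g. from [top_fraction_intersection()]).
#' @param experiments optional [experiment_table] used for bait roles.
#' @param known optional reference interactions for edge classification.
#' @return List of class `ppi_network` with `nodes` (data frame: `id`,
#'   `role`) and `edges` (the pair set, deduplicated, plus `class` if
#'   classified).
#' @export
build_network <- function(pair_set, experiments = NULL, known = NULL) {
  edges <- as.data.frame(pair_set)
  if (nrow(edges)) {
    cp <- canonical_pairs(edges$protein_a, edges$protein_b)
    edges$protein_a <- cp$protein_a; edges$protein_b <- cp$protein_b
    edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
    edges <- edges[!duplicated(pair_key(edges$protein_a, edges$protein_b)), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  ids <- sort(unique(c(edges$protein_a, edges$protein_b)))
  baits <- character(0)
  if (!is.null(experiments)) {
    stopifnot(inherits(experiments, "experiment_table"))
    baits <- unique(experiments$info$bait)
  }
  nodes <- data.frame(id = ids,
                      role = ifelse(ids %in% baits, "bait", "prey"),
                      stringsAsFactors = FALSE)
  if (!is.null(known) && nrow(edges))
    edges$class <- classify_edges(edges[c("protein_a", "protein_b")], known)
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes (%d bait), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "bait"), nrow(x$edges)))
  invisible(x)
}

#' Keep only edges supported by a three-node clique
#'
#' Retains exactly the edges that participate in at least one triangle of
#' the input network, then drops nodes left without edges. Because every
#' edge of a surviving triangle survives, the operation is idempotent.
#'
#' @param network a `ppi_network`.
#' @return The filtered `ppi_network`.
#' @export
triangle_filter <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  edges <- network$edges
  if (!nrow(edges)) return(network)
  a <- edges$protein_a; b <- edges$protein_b
  nbr <- lapply(split(c(b, a), c(a, b)), unique)
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    length(intersect(nbr[[a[i]]], nbr[[b[i]]])) > 0
  }, logical(1))
  out <- network
  out$edges <- edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  live <- unique(c(out$edges$protein_a, out$edges$protein_b))
  out$nodes <- network$nodes[network$nodes$id %in% live, , drop = FALSE]
  rownames(out$nodes) <- NULL
  out
}

#' Extract predicted complexes from a triangle-supported network
#'
#' Re-applies the triangle filter (a no-op if already applied) and reports
#' each connected component of the result as one predicted complex, sorted
#' by size descending. Every complex therefore has at least three members
#' and each of its edges sits in a triangle.
#'
#' @param network a `ppi_network`.
#' @return List of class `complex_set`: `complexes` (named list; each with
#'   `members`, `edges`, `size`, `density`) and `summary` (data frame).
#' @export
extract_complexes <- function(network) {
  net <- triangle_filter(network)
  if (!nrow(net$edges)) {
    return(structure(list(complexes = list(),
                          summary = data.frame(complex = character(0),
                                               size = integer(0),
                                               n_edges = integer(0),
                                               density = numeric(0))),
                     class = "complex_set"))
  }
  g <- igraph::graph_from_data_frame(
    net$edges[c("protein_a", "protein_b")], directed = FALSE,
    vertices = net$nodes$id)
  comp <- igraph::components(g)
  member_of <- comp$membership[net$nodes$id]
  ord <- order(-comp$csize, vapply(split(net$nodes$id, member_of),
                                   min, character(1)))
  ekey_comp <- member_of[net$edges$protein_a]
  complexes <- lapply(seq_along(ord), function(k) {
    cid <- ord[k]
    members <- sort(net$nodes$id[member_of == cid])
    ed <- net$edges[ekey_comp == cid, , drop = FALSE]
    rownames(ed) <- NULL
    s <- length(members)
    list(members = members, edges = ed, size = s,
         density = nrow(ed) / (s * (s - 1) / 2))
  })
  names(complexes) <- sprintf("complex_%03d", seq_along(complexes))
  summary <- data.frame(
    complex = names(complexes),
    size = vapply(complexes, `[[`, 0L, "size"),
    n_edges = vapply(complexes, function(x) nrow(x$edges), 0L),
    density = vapply(complexes, `[[`, 0, "density"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(complexes = complexes, summary = summary),
            class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  n <- length(x$complexes)
  if (!n) { cat("complex_set: empty\n"); return(invisible(x)) }
  cat(sprintf("complex_set: %d complexes, sizes %d-%d\n",
              n, min(x$summary$size), max(x$summary$size)))
  invisible(x)
}

#' Percent overlap between predicted and reference complexes
#'
#' For predicted complex A and reference complex B, the overlap is
#' `100 * |A intersect B| / |A|`. Both orientations are returned, since
#' "percent of the prediction explained" and "percent of the reference
#' recovered" answer different questions.
#'
#' @param complexes a `complex_set` or named list of member vectors.
#' @param reference_complexes named list of reference member vectors.
#' @return List with matrices `by_predicted` (denominator = predicted
#'   size) and `by_reference` (denominator = reference size); rows =
#'   predicted, columns = reference.
#' @export
complex_overlap <- function(complexes, reference_complexes) {
  if (inherits(complexes, "complex_set"))
    complexes <- lapply(complexes$complexes, `[[`, "members")
  if (!length(reference_complexes))
    stop_usage("reference complex set is empty")
  inter <- outer(seq_along(complexes), seq_along(reference_complexes),
                 Vectorize(function(i, j)
                   length(intersect(complexes[[i]],
                                    reference_complexes[[j]]))))
  dimnames(inter) <- list(names(complexes), names(reference_complexes))
  szp <- lengths(complexes); szr <- lengths(reference_complexes)
  list(by_predicted = 100 * inter / szp,
       by_reference = 100 * sweep(inter, 2, szr, "/"))
}

#' Write complexes as GMT-style text
#'
#' One complex per line: name, tab, description (size), then member
#' identifiers, tab-separated.
#'
#' @param complexes a `complex_set` or named list of member vectors.
#' @param path output path.
#' @export
write_gmt <- function(complexes, path) {
  if (inherits(complexes, "complex_set"))
    complexes <- lapply(complexes$complexes, `[[`, "members")
  lines <- vapply(seq_along(complexes), function(i) {
    paste(c(names(complexes)[i], paste0("size=", length(complexes[[i]])),
            complexes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}
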