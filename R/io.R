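# Readers and writers for pair sets, domain annotations, sticky lists and
# network exports. All formats are plain delimited text so fixtures and
# results remain diffable and portable.

#' Read a reference interaction set
#'
#' Accepts a two-column delimited file of identifier pairs (an optional
#' third column is kept as an evidence tag), or the Cytoscape SIF dialect
#' (`a <relation> b`). Pairs are unordered: `(a,b)` and `(b,a)` collapse to
#' one entry, self-pairs are dropped (with a message reporting how many),
#' and duplicates are removed.
#'
#' @param path input file path.
#' @param sep field separator (default any whitespace, which also covers SIF).
#' @return A data frame of class `pair_set` with columns `protein_a`,
#'   `protein_b` (lexicographically ordered within each row) and, when
#'   present in the input, `evidence`.
#' @export
read_pair_set <- function(path, sep = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) &&
      grepl("^(protein|domain)_a\\b", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) return(empty_pair_set())
  toks <- strsplit(lines, if (identical(sep, "")) "[ \t]+" else sep)
  nt <- lengths(toks)
  if (any(nt < 2))
    stop_usage("pair file row(s) with fewer than 2 columns: line ",
               which(nt < 2)[1])
  # SIF dialect: 3 tokens with a relation word in the middle
  is_sif <- all(nt == 3) &&
    length(unique(vapply(toks, `[[`, "", 2L))) == 1L
  if (is_sif) {
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 3L)
    ev <- NULL
  } else {
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 2L)
    ev <- if (all(nt >= 3)) vapply(toks, `[[`, "", 3L) else NULL
  }
  pair_set(a, b, evidence = ev)
}

#' Construct a pair set from two identifier vectors
#'
#' @param a,b character vectors of equal length.
#' @param evidence optional evidence tags (first tag kept per unique pair).
#' @return `pair_set` data frame (see [read_pair_set()]).
#' @export
pair_set <- function(a, b, evidence = NULL) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-pair(s) dropped")
    a <- a[!self]; b <- b[!self]
    if (!is.null(evidence)) evidence <- evidence[!self]
  }
  df <- canonical_pairs(a, b)
  if (!is.null(evidence)) df$evidence <- evidence
  df <- df[!duplicated(pair_key(df$protein_a, df$protein_b)), , drop = FALSE]
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pair_set", "data.frame")
  df
}

empty_pair_set <- function() {
  df <- data.frame(protein_a = character(0), protein_b = character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("pair_set", "data.frame")
  df
}

#' Write a pair set as two-column TSV
#' @param x a `pair_set` (or any data frame with two identifier columns).
#' @param path output path.
#' @export
write_pair_set <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read protein-to-domain annotations
#'
#' One row per (protein, domain accession) occurrence; repeated rows encode
#' multiplicity, since a domain may occur several times within one protein.
#'
#' @param path delimited file with two columns: protein identifier, domain
#'   accession. A header line is detected and skipped if its first field is
#'   "protein".
#' @param sep field separator (default tab).
#' @return A named list of class `domain_annotation`; each element is a
#'   character vector of domain accessions with repeats preserving
#'   multiplicity. Lookup of an unannotated protein yields `character(0)`
#'   via [domains_of()].
#' @export
read_domain_annotation <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE,
                           col.names = c("protein", "domain"))
  if (nrow(tab) && identical(tolower(tab$protein[1]), "protein"))
    tab <- tab[-1, , drop = FALSE]
  domain_annotation(tab$protein, tab$domain)
}

#' Construct a domain annotation from parallel vectors
#' @param protein,domain character vectors, one entry per domain occurrence.
#' @return `domain_annotation` (see [read_domain_annotation()]).
#' @export
domain_annotation <- function(protein, domain) {
  protein <- as.character(protein); domain <- as.character(domain)
  if (any(!nzchar(protein))) stop_usage("empty protein identifier")
  if (any(!nzchar(domain))) stop_usage("empty domain accession")
  ann <- split(domain, protein)
  structure(ann, class = "domain_annotation")
}

#' Look up the domain multiset of one protein
#' @param annot a `domain_annotation`.
#' @param protein protein identifier.
#' @return character vector of accessions (empty if unannotated).
#' @export
domains_of <- function(annot, protein) {
  d <- annot[[protein]]
  if (is.null(d)) character(0) else d
}

#' Write a domain annotation as (protein, domain) rows
#' @param annot a `domain_annotation`.
#' @param path output path.
#' @export
write_domain_annotation <- function(annot, path) {
  df <- data.frame(protein = rep(names(annot), lengths(annot)),
                   domain = unlist(annot, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Read a sticky ("non-specific") protein list
#'
#' One identifier per line; `#` starts a comment.
#' @param path input path.
#' @return character vector of protein identifiers.
#' @export
read_sticky_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  unique(trimws(lines[nzchar(trimws(lines))]))
}

#' Export a network for Cytoscape or downstream analysis
#'
#' Supported formats: `"sif"` (plus sidecar `<path>.edge-attrs.tsv` /
#' `<path>.node-attrs.tsv` attribute tables when attributes are present),
#' `"graphml"` (attributes embedded, written via igraph), and `"tsv"`
#' (edge list with attribute columns, plus `<path>.nodes.tsv`).
#'
#' @param nodes data frame with column `id` and optional attribute columns
#'   (e.g. `role` = bait/prey).
#' @param edges data frame with columns `protein_a`, `protein_b` (or first
#'   two columns as endpoints) and optional attribute columns (e.g. `class`
#'   = recalled/indirect/novel).
#' @param path output path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @param relation SIF relation word (default `"pp"`).
#' @export
write_network <- function(nodes, edges, path, format = c("sif", "graphml", "tsv"),
                          relation = "pp") {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_usage("unknown network format"))
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!nrow(nodes) && nrow(edges))
    nodes <- data.frame(id = unique(c(edges[[1]], edges[[2]])))
  if (!"id" %in% names(nodes)) names(nodes)[1] <- "id"
  ecols <- names(edges)
  if (!all(c("protein_a", "protein_b") %in% ecols) && length(ecols) >= 2)
    names(edges)[1:2] <- c("protein_a", "protein_b")
  if (format == "sif") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(edges)) {
      writeLines(paste(edges$protein_a, relation, edges$protein_b), con)
    }
    # isolated nodes appear as bare identifiers, per SIF convention
    iso <- setdiff(nodes$id, c(edges$protein_a, edges$protein_b))
    if (length(iso)) writeLines(iso, con)
    eattr <- setdiff(names(edges), c("protein_a", "protein_b"))
    if (length(eattr) && nrow(edges)) {
      utils::write.table(edges, paste0(path, ".edge-attrs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    nattr <- setdiff(names(nodes), "id")
    if (length(nattr) && nrow(nodes)) {
      utils::write.table(nodes, paste0(path, ".node-attrs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges else data.frame(protein_a = character(0),
                                             protein_b = character(0)),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
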