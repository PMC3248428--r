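# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

# random count matrix with ~60% zeros, plus molecular weights
random_spc_matrix <- function(n = 15, m = 10, seed = 1, max_count = 20) {
  set.seed(seed)
  spc <- matrix(rbinom(n * m, 1, 0.4) * sample.int(max_count, n * m, TRUE),
                n, m,
                dimnames = list(sprintf("P%02d", seq_len(n)),
                                sprintf("E%02d", seq_len(m))))
  mw <- setNames(round(runif(n, 10, 200), 1), rownames(spc))
  spc_matrix(spc, mw)
}

# a matrix from hand-specified columns (list of named count vectors)
spc_from_columns <- function(cols, mw = NULL) {
  prot <- sort(unique(unlist(lapply(cols, names))))
  spc <- sapply(cols, function(co) {
    v <- setNames(rep(0L, length(prot)), prot)
    v[names(co)] <- as.integer(co)
    v
  })
  colnames(spc) <- names(cols) %||% sprintf("E%d", seq_along(cols))
  if (is.null(mw)) mw <- setNames(rep(1, length(prot)), prot)
  spc_matrix(spc, mw)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random simple undirected graph as an edge data frame
random_graph_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  cmb <- t(combn(ids, 2))
  keep <- runif(nrow(cmb)) < p_edge
  data.frame(protein_a = cmb[keep, 1], protein_b = cmb[keep, 2],
             stringsAsFactors = FALSE)
}

# small synthetic study shared by the slower tests
small_sim_config <- function(seed = 11, ...) {
  generator_config(n_proteins = 300, n_complexes = 12,
                   complex_size_range = c(3, 10), n_experiments = 80,
                   list_size_range = c(10, 80), n_sticky = 10,
                   seed = seed, ...)
}
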