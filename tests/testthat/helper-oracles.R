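# Independent brute-force oracles. Each re-derives a quantity from its
# definition by direct enumeration, sharing no code with the package
# implementation it checks.

oracle_sorensen <- function(mat, a, b) {
  MA <- which(mat$spc[a, ] > 0); MB <- which(mat$spc[b, ] > 0)
  2 * length(intersect(MA, MB)) / (length(MA) + length(MB))
}

# textbook covariance / sd closed form
oracle_pearson <- function(mat, a, b) {
  x <- mat$q[a, ]; y <- mat$q[b, ]
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

oracle_e3 <- function(mat, a, b) {
  total <- 0
  for (j in seq_len(ncol(mat$spc))) {
    col <- mat$spc[, j]
    if (col[a] == 0 || col[b] == 0) next
    present <- names(col)[col > 0]
    rk <- setNames(vapply(present, function(p)
      sum(col[present] > col[p]) + 1L, 1L), present)
    total <- total + (col[[a]] + col[[b]]) / (abs(rk[[a]] - rk[[b]]) + 1)
  }
  total / ncol(mat$spc)
}

oracle_ab <- function(mat, a, b) {
  x <- as.numeric(mat$spc[a, ]); y <- as.numeric(mat$spc[b, ])
  mean(x * y) / (mean(x) + mean(y))
}

# enumerate every (PPI, domain-occurrence pair) incidence explicitly
oracle_ddi <- function(ppis, annot, score_col) {
  acc <- list(); lam <- list()
  for (i in seq_len(nrow(ppis))) {
    da <- domains_of(annot, ppis$protein_a[i])
    db <- domains_of(annot, ppis$protein_b[i])
    if (!length(da) || !length(db)) next
    seen <- character(0)
    for (x in da) for (y in db) {
      key <- paste(min(x, y), max(x, y))
      acc[[key]] <- (acc[[key]] %||% 0) +
        ppis[[score_col]][i] / (length(da) * length(db))
      seen <- union(seen, key)
    }
    for (key in seen) lam[[key]] <- (lam[[key]] %||% 0L) + 1L
  }
  list(score = acc, lambda = lam)
}

# an edge survives triangle filtering iff a third node closes a triangle
oracle_triangle_edges <- function(edges) {
  if (!nrow(edges)) return(logical(0))
  key <- paste(pmin(edges$protein_a, edges$protein_b),
               pmax(edges$protein_a, edges$protein_b))
  has_edge <- function(x, y) paste(pmin(x, y), pmax(x, y)) %in% key
  nodes <- unique(c(edges$protein_a, edges$protein_b))
  vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    any(vapply(setdiff(nodes, c(a, b)), function(c)
      has_edge(a, c) && has_edge(b, c), logical(1)))
  }, logical(1))
}

rank_desc_test <- function(s, a, b) {
  r <- integer(length(s)); r[order(-s, a, b)] <- seq_along(s); r
}
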