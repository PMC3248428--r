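# Domain-domain interaction scoring. A predicted prey-prey interaction is
# propagated onto the Pfam domains of its two proteins: every domain pair
# with one side on each protein inherits a share of the PPI score. Because
# proteins carry several domains, and a domain may occur more than once in
# the same protein, the share is the PPI score split uniformly over all
# |D_A| x |D_B| domain-occurrence pairs; this conserves the PPI's score
# mass across its domain pairs, keeping contributions comparable between
# proteins with few and with many domains.

#' Propagate PPI scores onto domain pairs
#'
#' For each contributing protein pair (A, B) with score `s` and domain
#' occurrence multisets `D_A`, `D_B`, every unordered accession pair
#' `(d_a, d_b)` with `d_a` from A and `d_b` from B accumulates
#' `s * mult_a * mult_b / (|D_A| * |D_B|)` (or the raw score `s` when
#' `normalize = FALSE`). Independently of the scores, the lambda index of
#' a domain pair counts the protein pairs presenting it — one increment
#' per supporting PPI, however many occurrence combinations map to it.
#' Homodomain pairs (`d_a == d_b`) are retained. Protein pairs in which
#' either protein lacks annotation contribute nothing (their count is
#' reported).
#'
#' @param ppis data frame with columns `protein_a`, `protein_b` and the
#'   score column named by `score_col` (typically a `scored_pairs` table).
#' @param annot a `domain_annotation` (see [read_domain_annotation()]).
#' @param score_col name of the score column to propagate.
#' @param top_fraction use only the top fraction of `ppis` by that score
#'   (default 1 = all scored pairs). Undefined (`NA`) scores never
#'   contribute.
#' @param normalize split each PPI's score uniformly over its domain pairs
#'   (default) rather than assigning the raw score to every pair.
#' @param keep_support record the supporting protein pairs per domain pair.
#' @return A data frame of class `ddi_scores` with columns `domain_a`,
#'   `domain_b`, `ddi_score`, `lambda`, `rank` (by descending score, ties
#'   broken lexicographically) and, if requested, a `support` list column.
#' @export
score_ddis <- function(ppis, annot, score_col = "e3_sor", top_fraction = 1,
                       normalize = TRUE, keep_support = FALSE) {
  stopifnot(inherits(annot, "domain_annotation"))
  if (!score_col %in% names(ppis))
    stop_usage("score column '", score_col, "' not in ppis")
  sc <- ppis[[score_col]]
  ok <- !is.na(sc)
  ppis <- ppis[ok, , drop = FALSE]; sc <- sc[ok]
  if (top_fraction < 1) {
    k <- ceiling(top_fraction * nrow(ppis))
    o <- order(-sc, ppis$protein_a, ppis$protein_b)
    ppis <- ppis[o[seq_len(k)], , drop = FALSE]
    sc <- sc[o[seq_len(k)]]
  }
  acc <- new.env(parent = emptyenv())
  lam <- new.env(parent = emptyenv())
  sup <- if (keep_support) new.env(parent = emptyenv()) else NULL
  n_unannotated <- 0L
  for (i in seq_len(nrow(ppis))) {
    da <- annot[[ppis$protein_a[i]]]
    db <- annot[[ppis$protein_b[i]]]
    if (is.null(da) || is.null(db) || !length(da) || !length(db)) {
      n_unannotated <- n_unannotated + 1L
      next
    }
    ta <- table(da); tb <- table(db)
    w <- outer(as.numeric(ta), as.numeric(tb))
    if (normalize) w <- w / (length(da) * length(db)) else w[] <- 1
    contrib <- sc[i] * w
    keys <- outer(names(ta), names(tb),
                  function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\t"))
    # occurrence pairs mapping to the same unordered accession pair merge
    for (k in seq_along(keys)) {
      key <- keys[k]
      acc[[key]] <- (acc[[key]] %||% 0) + contrib[k]
    }
    pk <- pair_key(ppis$protein_a[i], ppis$protein_b[i])
    for (key in unique(as.vector(keys))) {
      lam[[key]] <- (lam[[key]] %||% 0L) + 1L
      if (keep_support) sup[[key]] <- c(sup[[key]], pk)
    }
  }
  if (n_unannotated)
    message(n_unannotated, " protein pair(s) lacked annotation on one side")
  keys <- ls(acc)
  if (!length(keys)) {
    out <- data.frame(domain_a = character(0), domain_b = character(0),
                      ddi_score = numeric(0), lambda = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("ddi_scores", "data.frame")
    return(out)
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(domain_a = vapply(parts, `[[`, "", 1L),
                    domain_b = vapply(parts, `[[`, "", 2L),
                    ddi_score = vapply(keys, function(k) acc[[k]], 0),
                    lambda = vapply(keys, function(k) lam[[k]], 0L),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (keep_support)
    out$support <- I(lapply(keys, function(k) unique(sup[[k]])))
  out$rank <- rank_desc(out$ddi_score, out$domain_a, out$domain_b)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ddi_scores", "data.frame")
  out
}

#' Combine domain-pair rankings across scoring methods
#'
#' Aggregates per-method domain-pair tables (all over the same pair
#' universe) by the mean of their per-method ranks; optionally the lambda
#' index enters multiplicatively (each method's score becomes
#' `ddi_score * lambda` before ranking), which pushes domain pairs
#' supported by a single protein pair down the list.
#'
#' @param tables named list of `ddi_scores` tables (one per method).
#' @param use_lambda multiply scores by lambda before ranking.
#' @return Data frame with `domain_a`, `domain_b`, `lambda`, one
#'   `rank_<method>` column per table, `mean_rank` and the final `rank`
#'   (ties broken lexicographically).
#' @export
combine_ddi_rankings <- function(tables, use_lambda = FALSE) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("method", seq_along(tables))
  keys <- lapply(tables, function(t) pair_key(t$domain_a, t$domain_b))
  universe <- sort(keys[[1]])
  for (k in keys[-1])
    if (!identical(sort(k), universe))
      stop_usage("ddi tables cover different domain-pair universes")
  ref <- tables[[1]][order(keys[[1]]), , drop = FALSE]
  out <- data.frame(domain_a = ref$domain_a, domain_b = ref$domain_b,
                    lambda = ref$lambda, stringsAsFactors = FALSE)
  rank_cols <- character(0)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    t <- t[match(universe, pair_key(t$domain_a, t$domain_b)), , drop = FALSE]
    sc <- t$ddi_score
    if (use_lambda) sc <- sc * t$lambda
    col <- paste0("rank_", nm)
    out[[col]] <- rank_desc(sc, out$domain_a, out$domain_b)
    rank_cols <- c(rank_cols, col)
  }
  out$mean_rank <- rowMeans(out[, rank_cols, drop = FALSE])
  out$rank <- rank_desc(-out$mean_rank, out$domain_a, out$domain_b)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
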