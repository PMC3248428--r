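# Benchmarking of ranked predictions against reference interaction sets:
# GSEA-style running sum, ROC/AUC, sliding-window recall, shuffled-rank
# nulls, and edge classification (recalled / indirect / novel).

ranked_keys <- function(ranked_pairs) {
  if (is.data.frame(ranked_pairs)) {
    cols <- intersect(c("protein_a", "protein_b", "domain_a", "domain_b"),
                      names(ranked_pairs))
    if (length(cols) >= 2)
      return(pair_key(ranked_pairs[[cols[1]]], ranked_pairs[[cols[2]]]))
    return(pair_key(ranked_pairs[[1]], ranked_pairs[[2]]))
  }
  as.character(ranked_pairs)
}

known_keys <- function(known) {
  if (is.data.frame(known)) pair_key(known[[1]], known[[2]])
  else as.character(known)
}

hit_vector <- function(ranked_pairs, known) {
  ranked_keys(ranked_pairs) %in% known_keys(known)
}

#' GSEA-style running sum over a ranked prediction list
#'
#' Walks down the ranking and accumulates `sqrt((u - t) / t)` at each known
#' interaction and `-sqrt(t / (u - t))` otherwise, where `u` is the number
#' of predictions in the list and `t` the number of known interactions
#' among them. The step sizes make the walk end at exactly zero, so the
#' peak deviation measures how strongly known interactions concentrate at
#' the top of the ranking.
#'
#' @param ranked_pairs predictions in rank order: a data frame with two
#'   identifier columns, or a vector of pair keys.
#' @param known reference interactions (a `pair_set` or two-column data
#'   frame); only those present in the ranked list count towards `t`.
#' @return List of class `running_sum` with `curve` (cumulative sum per
#'   rank), `u`, `t`, `peak` (signed value of the largest absolute
#'   deviation) and `peak_rank`.
#' @export
running_sum <- function(ranked_pairs, known) {
  hits <- hit_vector(ranked_pairs, known)
  u <- length(hits); t <- sum(hits)
  if (t == 0 || t == u)
    stop_usage("running sum undefined: need 0 < t < u (t = ", t,
               ", u = ", u, ")")
  up <- sqrt((u - t) / t)
  down <- sqrt(t / (u - t))
  curve <- cumsum(ifelse(hits, up, -down))
  ipk <- which.max(abs(curve))
  structure(list(curve = curve, u = u, t = t,
                 peak = curve[ipk], peak_rank = ipk),
            class = "running_sum")
}

#' @export
print.running_sum <- function(x, ...) {
  cat(sprintf("running_sum: u = %d, t = %d, peak %.3f at rank %d, final %.2e\n",
              x$u, x$t, x$peak, x$peak_rank, x$curve[x$u]))
  invisible(x)
}

#' ROC curve and AUC of a ranked prediction list
#'
#' Labels each ranked pair by membership in the reference set and computes
#' the ROC curve by the trapezoidal rule. When scores are supplied, tied
#' scores are grouped so that ties contribute their averaged rank
#' (Mann-Whitney convention); without scores the list order is taken as a
#' strict ranking.
#'
#' @inheritParams running_sum
#' @param scores optional numeric scores aligned with `ranked_pairs`
#'   (larger = better); used only to group ties.
#' @return List of class `roc_curve` with `fpr`, `tpr`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(ranked_pairs, known, scores = NULL) {
  hits <- hit_vector(ranked_pairs, known)
  n_pos <- sum(hits); n_neg <- sum(!hits)
  if (n_pos == 0 || n_neg == 0)
    stop_usage("ROC undefined: both classes must be present")
  if (is.null(scores)) scores <- -seq_along(hits)
  stopifnot(length(scores) == length(hits))
  o <- order(scores, decreasing = TRUE)
  lab <- hits[o]; sc <- scores[o]
  grp <- cumsum(!duplicated(sc))
  tp_g <- as.numeric(tapply(lab, grp, sum))
  n_g <- as.numeric(tapply(lab, grp, length))
  tpr <- c(0, cumsum(tp_g) / n_pos)
  fpr <- c(0, cumsum(n_g - tp_g) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sliding-window recall along a ranking
#'
#' At each rank position, the fraction of predictions in the trailing
#' window that are known interactions. The window is truncated at the
#' start of the list.
#'
#' @inheritParams running_sum
#' @param window window size in ranks (default 2000). If larger than the
#'   list, a single full-list point is returned with a warning.
#' @return Data frame with columns `rank` and `recall`.
#' @export
sliding_recall <- function(ranked_pairs, known, window = 2000) {
  if (window < 1) stop_usage("window must be >= 1")
  hits <- hit_vector(ranked_pairs, known)
  u <- length(hits)
  if (window > u) {
    warning("window exceeds list length; returning the overall precision")
    return(data.frame(rank = u, recall = mean(hits)))
  }
  cs <- c(0, cumsum(hits))
  i <- seq_len(u)
  lo <- pmax(0, i - window)
  data.frame(rank = i, recall = (cs[i + 1] - cs[lo + 1]) / (i - lo))
}

#' Shuffled-rank null for the running sum
#'
#' Recomputes the running sum after randomly permuting the positions of
#' the known interactions in the list, `n_shuffles` times, and returns the
#' pointwise mean and min/max envelope. A well-behaved null hovers around
#' zero at every rank.
#'
#' @inheritParams running_sum
#' @param n_shuffles number of permutations (>= 1).
#' @param seed integer seed; required, so null curves are reproducible.
#' @return List of class `shuffled_null` with `mean`, `lo`, `hi` (numeric
#'   vectors over ranks), `u`, `t`, `n_shuffles`.
#' @export
shuffled_null <- function(ranked_pairs, known, n_shuffles = 1000, seed) {
  if (missing(seed)) stop_usage("a seed is required")
  if (n_shuffles < 1) stop_usage("n_shuffles must be >= 1")
  hits <- hit_vector(ranked_pairs, known)
  u <- length(hits); t <- sum(hits)
  if (t == 0 || t == u) stop_usage("need 0 < t < u")
  up <- sqrt((u - t) / t); down <- sqrt(t / (u - t))
  set.seed(seed)
  mean_c <- numeric(u); lo <- rep(Inf, u); hi <- rep(-Inf, u)
  for (s in seq_len(n_shuffles)) {
    curve <- cumsum(ifelse(sample(hits), up, -down))
    mean_c <- mean_c + curve
    lo <- pmin(lo, curve); hi <- pmax(hi, curve)
  }
  structure(list(mean = mean_c / n_shuffles, lo = lo, hi = hi,
                 u = u, t = t, n_shuffles = n_shuffles),
            class = "shuffled_null")
}

#' Classify predicted edges against the known interactome
#'
#' A predicted pair is `recalled` if it is itself a known interaction,
#' `indirect` if the known interactome connects its endpoints through one
#' intermediate (a path of length two), and `novel` otherwise.
#'
#' @param pairs data frame with two identifier columns (first two used).
#' @param known reference interactions (two-column data frame or
#'   `pair_set`).
#' @return Character vector of labels, one per row of `pairs`.
#' @export
classify_edges <- function(pairs, known) {
  ka <- as.character(known[[1]]); kb <- as.character(known[[2]])
  kk <- pair_key(ka, kb)
  nb <- lapply(split(c(kb, ka), c(ka, kb)), unique)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  keys <- pair_key(a, b)
  vapply(seq_along(keys), function(i) {
    if (keys[i] %in% kk) return("recalled")
    na_ <- nb[[a[i]]]; nb_ <- nb[[b[i]]]
    if (!is.null(na_) && !is.null(nb_) && length(intersect(na_, nb_)))
      "indirect"
    else "novel"
  }, character(1))
}
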