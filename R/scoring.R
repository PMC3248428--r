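# Prey-prey pair scoring. Four statistics aggregate evidence for a direct
# interaction between two prey proteins across all pull-down experiments,
# regardless of which baits were used:
#
#   sor - Sorensen set-overlap of the experiments containing each protein;
#   pr  - Pearson correlation of the MW-normalised abundance profiles;
#   e3  - rank-proximity score: per experiment, the summed counts of the
#         pair divided by (1 + the gap between their within-experiment
#         SPC ranks), averaged over experiments;
#   ab  - mean product of the two SPC profiles divided by the sum of their
#         mean SPCs.
#
# e3 and ab were designed to reward pairs that sit near the top of the
# same pull-down lists with similar counts; sor and pr are classical.

#' Sorensen similarity of two proteins' experiment sets
#'
#' `Sor(A, B) = 2 |M_AB| / (|M_A| + |M_B|)` where `M_A` is the set of
#' experiments in which protein A was identified (SPC > 0), likewise `M_B`,
#' and `M_AB` the experiments containing both. Ranges from 0 (never
#' co-identified) to 1 (identical presence profiles).
#'
#' @param matrix an [spc_matrix].
#' @param a,b distinct protein identifiers present in the matrix.
#' @return Sorensen coefficient in \[0, 1\], or `NA` (undefined sentinel)
#'   when either protein appears in no experiment.
#' @export
sorensen <- function(matrix, a, b) {
  p <- presence_pair(matrix, a, b)
  na <- sum(p$pa); nb <- sum(p$pb)
  if (na + nb == 0) return(NA_real_)
  2 * sum(p$pa & p$pb) / (na + nb)
}

#' Pearson correlation of two abundance profiles
#'
#' Standard Pearson correlation of the full-length abundance vectors
#' `q = SPC / MW` across all experiments, zeros included.
#'
#' @inheritParams sorensen
#' @return Correlation in \[-1, 1\], or `NA` when either profile has zero
#'   variance (undefined sentinel, excluded from rankings).
#' @export
pearson <- function(matrix, a, b) {
  check_pair(matrix, a, b)
  qa <- matrix$q[a, ]; qb <- matrix$q[b, ]
  if (stats::sd(qa) == 0 || stats::sd(qb) == 0) return(NA_real_)
  stats::cor(qa, qb)
}

#' Rank-proximity score of a protein pair
#'
#' For each experiment `j` in which both proteins were identified, the
#' term `(SPC_a + SPC_b) / (|rank_a - rank_b| + 1)` is computed, with
#' ranks assigned by descending SPC among the proteins identified in that
#' experiment (rank 1 = highest count, ties share the smallest rank). The
#' `+ 1` keeps the ratio finite when the two proteins tie. The final score
#' averages these terms over experiments; by default every experiment
#' counts in the denominator (experiments lacking either protein
#' contribute 0), so rarely co-occurring pairs are penalised.
#'
#' @inheritParams sorensen
#' @param denominator `"all"` (default): average over all experiments;
#'   `"cooccurring"`: average only over experiments containing both.
#' @return Non-negative score (0 if the pair never co-occurs).
#' @export
e3 <- function(matrix, a, b, denominator = c("all", "cooccurring")) {
  denominator <- match.arg(denominator)
  check_pair(matrix, a, b)
  spc <- matrix$spc
  terms <- vapply(seq_len(ncol(spc)), function(j) {
    va <- spc[a, j]; vb <- spc[b, j]
    if (va == 0 || vb == 0) return(0)
    col <- spc[, j]
    r <- rank(-col[col > 0], ties.method = "min")
    (va + vb) / (abs(r[[a]] - r[[b]]) + 1)
  }, numeric(1))
  co <- sum(spc[a, ] > 0 & spc[b, ] > 0)
  den <- if (denominator == "all") ncol(spc) else max(co, 1L)
  sum(terms) / den
}

#' Count-product score of a protein pair
#'
#' `AB(a, b) = mean_j(SPC_a,j * SPC_b,j) / (mean_j(SPC_a,j) + mean_j(SPC_b,j))`.
#' Zero exactly when the proteins never co-occur; grows when both carry
#' high counts in the same experiments.
#'
#' @inheritParams sorensen
#' @param use_abundance score on `q = SPC/MW` instead of raw SPC.
#' @return Non-negative score, or `NA` when both profiles are all-zero.
#' @export
ab_correlation <- function(matrix, a, b, use_abundance = FALSE) {
  check_pair(matrix, a, b)
  m <- if (use_abundance) matrix$q else matrix$spc
  xa <- as.numeric(m[a, ]); xb <- as.numeric(m[b, ])
  den <- mean(xa) + mean(xb)
  if (den == 0) return(NA_real_)
  mean(xa * xb) / den
}

presence_pair <- function(matrix, a, b) {
  check_pair(matrix, a, b)
  list(pa = matrix$spc[a, ] > 0, pb = matrix$spc[b, ] > 0)
}

check_pair <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "spc_matrix"))
  if (identical(a, b)) stop_usage("self-pairs are not scored")
  pid <- protein_ids(matrix)
  missing <- setdiff(c(a, b), pid)
  if (length(missing))
    stop_usage("unknown protein(s): ", paste(missing, collapse = ", "))
  invisible(NULL)
}

#' Score every co-occurring prey pair with the requested methods
#'
#' Enumerates all unordered protein pairs whose co-occurrence (number of
#' experiments containing both) is at least `min_cooccurrence` and scores
#' each with every requested method. Pairs are ranked per method by
#' descending score with deterministic tie-breaking on the lexicographic
#' pair identifiers; undefined scores (`NA` sentinels: zero-variance or
#' all-zero profiles) are excluded from that method's ranking.
#'
#' @param matrix an [spc_matrix] with at least 2 proteins and 2 experiments.
#' @param methods subset of `c("sor", "pr", "e3", "ab")`.
#' @param min_cooccurrence minimum number of shared experiments (>= 1).
#' @param e3_denominator see [e3()].
#' @param ab_use_abundance see [ab_correlation()].
#' @return A data frame of class `scored_pairs` with columns `protein_a`,
#'   `protein_b`, `cooc`, one score column per method and one
#'   `rank_<method>` column per method. The table is sorted by the first
#'   requested method's ranking.
#' @export
score_all_pairs <- function(matrix, methods = c("sor", "pr", "e3", "ab"),
                            min_cooccurrence = 1,
                            e3_denominator = c("all", "cooccurring"),
                            ab_use_abundance = FALSE) {
  stopifnot(inherits(matrix, "spc_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  e3_denominator <- match.arg(e3_denominator)
  if (min_cooccurrence < 1) stop_usage("min_cooccurrence must be >= 1")
  spc <- matrix$spc
  n <- nrow(spc); m <- ncol(spc)
  if (n < 2 || m < 2)
    stop_usage("need at least 2 proteins and 2 experiments")
  pid <- rownames(spc)
  pres <- array(as.numeric(spc > 0), dim = dim(spc),
                dimnames = dimnames(spc))
  cooc <- tcrossprod(pres)
  sel <- which(upper.tri(cooc) & cooc >= min_cooccurrence, arr.ind = TRUE)
  ia <- sel[, 1]; ib <- sel[, 2]
  out <- canonical_pairs(pid[ia], pid[ib])
  out$cooc <- as.integer(cooc[sel])
  lin <- function(mat) mat[sel]  # upper-triangle extraction, pair order
  if ("sor" %in% methods) {
    npres <- rowSums(pres)
    denom <- outer(npres, npres, "+")
    sor <- ifelse(denom > 0, 2 * cooc / denom, NA_real_)
    out$sor <- lin(sor)
  }
  if ("pr" %in% methods) {
    pr <- suppressWarnings(stats::cor(t(matrix$q)))
    out$pr <- lin(pr)
  }
  if ("e3" %in% methods) {
    acc <- array(0, dim = c(n, n), dimnames = list(pid, pid))
    for (j in seq_len(m)) {
      idx <- which(spc[, j] > 0)
      if (length(idx) < 2) next
      v <- spc[idx, j]
      r <- rank(-v, ties.method = "min")
      acc[idx, idx] <- acc[idx, idx] +
        outer(v, v, "+") / (abs(outer(r, r, "-")) + 1)
    }
    den <- if (e3_denominator == "all") m else pmax(cooc, 1)
    out$e3 <- lin(acc / den)
  }
  if ("ab" %in% methods) {
    s <- if (ab_use_abundance) matrix$q else spc
    mp <- tcrossprod(s) / m
    means <- rowMeans(s)
    denom <- outer(means, means, "+")
    abm <- ifelse(denom > 0, mp / denom, NA_real_)
    out$ab <- lin(abm)
  }
  for (meth in methods)
    out[[paste0("rank_", meth)]] <-
      rank_desc(out[[meth]], out$protein_a, out$protein_b)
  out <- out[order(out[[paste0("rank_", methods[1])]], na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(methods = methods,
                              min_cooccurrence = min_cooccurrence,
                              e3_denominator = e3_denominator,
                              ab_use_abundance = ab_use_abundance,
                              n_proteins = n, n_experiments = m)
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Combine a base score with the Sorensen coefficient
#'
#' Multiplies a base method's score by the pair's Sorensen coefficient,
#' which zeroes any pair that never shares an experiment and damps pairs
#' with dissimilar presence profiles. Pearson scores are affinely mapped
#' from \[-1, 1\] to \[0, 1\] first so that the product stays monotone in
#' both factors. Adds a `<base>_sor` score column and its rank column.
#'
#' @param scores a `scored_pairs` table containing `sor` and the base column.
#' @param base_method one of `"e3"`, `"ab"`, `"pr"`.
#' @return The augmented `scored_pairs` table.
#' @export
combine_with_sorensen <- function(scores, base_method = c("e3", "ab", "pr")) {
  base_method <- match.arg(base_method)
  if (!all(c("sor", base_method) %in% names(scores)))
    stop_usage("scores table must contain 'sor' and '", base_method, "'")
  base <- scores[[base_method]]
  if (base_method == "pr") base <- (base + 1) / 2
  comb <- base * scores$sor
  col <- paste0(base_method, "_sor")
  scores[[col]] <- comb
  scores[[paste0("rank_", col)]] <-
    rank_desc(comb, scores$protein_a, scores$protein_b)
  scores
}

#' Pairs ranked in the top fraction by every method
#'
#' Takes, for each listed method, the pairs whose rank falls within the
#' top `ceiling(fraction * N)` of that method's ranking (N = number of
#' pairs with a defined score under that method), and intersects the
#' resulting sets. This is the edge-selection rule behind the global
#' interaction network (fraction 0.10) and the complex map (fraction 0.01).
#'
#' @param scores a `scored_pairs` table, or a list of such tables over the
#'   same pair universe (one per method; each contributes its first ranked
#'   method).
#' @param methods score columns to intersect (default: the three combined
#'   scores).
#' @param fraction top fraction in (0, 1\].
#' @return The subset of rows of `scores` (first table if a list) whose
#'   pair is in every method's top fraction.
#' @export
top_fraction_intersection <- function(scores,
                                      methods = c("e3_sor", "ab_sor", "pr_sor"),
                                      fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 1))
    stop_usage("fraction must be in (0, 1]")
  if (is.list(scores) && !is.data.frame(scores)) {
    keys <- lapply(scores, function(s) pair_key(s$protein_a, s$protein_b))
    if (length(unique(lapply(keys, sort))) != 1L)
      stop_usage("score tables cover different pair universes")
    merged <- scores[[1]]
    for (i in seq_along(scores)[-1]) {
      extra <- scores[[i]]
      newcols <- setdiff(names(extra), names(merged))
      merged[match(keys[[1]], keys[[i]]), newcols] <- NA
      merged[newcols] <- extra[match(keys[[1]], keys[[i]]), newcols]
    }
    scores <- merged
  }
  missing <- setdiff(methods, names(scores))
  if (length(missing))
    stop_usage("method column(s) not present: ", paste(missing, collapse = ", "))
  keep <- rep(TRUE, nrow(scores))
  for (meth in methods) {
    rk <- scores[[paste0("rank_", meth)]]
    if (is.null(rk)) rk <- rank_desc(scores[[meth]], scores$protein_a,
                                     scores$protein_b)
    k <- ceiling(fraction * sum(!is.na(rk)))
    keep <- keep & !is.na(rk) & rk <= k
  }
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
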