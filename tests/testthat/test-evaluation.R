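ranked_df <- function(keys) {
  parts <- strsplit(keys, "-", fixed = TRUE)
  data.frame(protein_a = vapply(parts, `[[`, "", 1L),
             protein_b = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

test_that("running sum follows the hand-computed walk", {
  ranked <- ranked_df(c("a-b", "c-d", "e-f", "g-h"))
  known <- data.frame(x = c("a", "c"), y = c("b", "d"))
  rs <- running_sum(ranked, known)     # u=4, t=2, steps of 1
  expect_equal(rs$curve, c(1, 2, 1, 0))
  expect_equal(rs$peak, 2)
  expect_equal(rs$peak_rank, 2L)
  # hits at the bottom mirror the walk
  known2 <- data.frame(x = c("e", "g"), y = c("f", "h"))
  rs2 <- running_sum(ranked, known2)
  expect_equal(rs2$curve, c(-1, -2, -1, 0))
  expect_equal(rs2$peak, -2)
  expect_error(running_sum(ranked, data.frame(x = "q", y = "z")), "0 < t < u")
})

test_that("running sum terminates at zero for random compositions", {
  set.seed(17)
  for (i in 1:20) {
    u <- sample(10:400, 1); t <- sample(seq_len(u - 1), 1)
    keys <- sprintf("p%04d-q%04d", 1:u, 1:u)
    hits <- sample(u, t)
    known <- data.frame(a = sprintf("p%04d", hits), b = sprintf("q%04d", hits))
    rs <- running_sum(ranked_df(keys), known)
    expect_lt(abs(rs$curve[u]), 1e-9)
  }
})

test_that("ROC reaches the analytic extremes and matches Mann-Whitney", {
  ranked <- ranked_df(sprintf("a%03d-b%03d", 1:40, 1:40))
  known_top <- data.frame(a = sprintf("a%03d", 1:10), b = sprintf("b%03d", 1:10))
  expect_equal(roc_auc(ranked, known_top)$auc, 1.0)
  known_bot <- data.frame(a = sprintf("a%03d", 31:40), b = sprintf("b%03d", 31:40))
  expect_equal(roc_auc(ranked, known_bot)$auc, 0.0)
  expect_error(roc_auc(ranked, ranked), "both classes")
  # Mann-Whitney oracle with averaged tie ranks, to 1e-9
  set.seed(23)
  for (i in 1:5) {
    u <- 500
    sc <- sample(round(runif(u, 0, 10), 1))   # many ties
    pos <- runif(u) < 0.2
    if (!any(pos) || all(pos)) next
    keys <- sprintf("x%04d-y%04d", 1:u, 1:u)
    known <- data.frame(a = sprintf("x%04d", which(pos)),
                        b = sprintf("y%04d", which(pos)))
    got <- roc_auc(ranked_df(keys), known, scores = sc)$auc
    r <- rank(sc)                             # ascending, ties averaged
    mw <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
    expect_equal(got, mw, tolerance = 1e-9)
  }
})

test_that("random rankings give chance-level AUC", {
  set.seed(29)
  u <- 1000
  keys <- sprintf("r%04d-s%04d", 1:u, 1:u)
  pos <- sample(u, 200)
  known <- data.frame(a = sprintf("r%04d", pos), b = sprintf("s%04d", pos))
  auc <- roc_auc(ranked_df(keys), known)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("sliding recall averages the trailing window", {
  ranked <- ranked_df(sprintf("a%02d-b%02d", 1:8, 1:8))
  odd <- seq(1, 8, 2)
  known <- data.frame(a = sprintf("a%02d", odd), b = sprintf("b%02d", odd))
  sw <- sliding_recall(ranked, known, window = 2)
  expect_equal(sw$recall[seq(2, 8, 2)], rep(0.5, 4))
  # window = list length: final point equals overall precision t/u
  full <- sliding_recall(ranked, known, window = 8)
  expect_equal(full$recall[8], 0.5)
  # all-miss list is all zeros
  none <- sliding_recall(ranked, data.frame(a = "q", b = "z"), window = 3)
  expect_true(all(none$recall == 0))
  expect_warning(big <- sliding_recall(ranked, known, window = 99),
                 "window exceeds")
  expect_equal(big$recall, 0.5)
})

test_that("shuffled null is reproducible, ends at zero, and centres on zero", {
  u <- 100
  keys <- sprintf("m%03d-n%03d", 1:u, 1:u)
  pos <- seq(1, 100, 10)
  known <- data.frame(a = sprintf("m%03d", pos), b = sprintf("n%03d", pos))
  ranked <- ranked_df(keys)
  n1 <- shuffled_null(ranked, known, n_shuffles = 50, seed = 5)
  n2 <- shuffled_null(ranked, known, n_shuffles = 50, seed = 5)
  expect_identical(n1$mean, n2$mean)
  expect_lt(abs(n1$mean[u]), 1e-9)     # every shuffled walk ends at 0
  # convergence: more shuffles pull the pointwise mean towards 0
  n3 <- shuffled_null(ranked, known, n_shuffles = 1000, seed = 5)
  expect_lt(max(abs(n3$mean)), max(max(abs(n1$mean)), 0.5))
  expect_error(shuffled_null(ranked, known, n_shuffles = 10), "seed")
})

test_that("edges classify as recalled, indirect or novel", {
  known <- data.frame(a = c("A", "C"), b = c("B", "B"))
  pairs <- data.frame(x = c("A", "A", "Q"), y = c("B", "C", "Z"))
  expect_equal(classify_edges(pairs, known),
               c("recalled", "indirect", "novel"))
})
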