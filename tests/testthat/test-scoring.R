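# Hand-computed and brute-force checks for the four pair-scoring
# statistics (oracles live in helper-oracles.R).

test_that("sorensen matches set enumeration on toy profiles", {
  mat <- spc_from_columns(list(e1 = c(a = 1, z = 1), e2 = c(a = 2, b = 1),
                               e3 = c(b = 3, z = 1)))
  expect_equal(sorensen(mat, "a", "b"), 0.5)   # 2*1/(2+2)
  expect_equal(sorensen(mat, "a", "z"), sorensen(mat, "z", "a"))
  ident <- spc_from_columns(list(e1 = c(a = 1, b = 2), e2 = c(a = 3, b = 1)))
  expect_equal(sorensen(ident, "a", "b"), 1)
  disj <- spc_from_columns(list(e1 = c(a = 1), e2 = c(b = 1)))
  expect_equal(sorensen(disj, "a", "b"), 0)
  expect_error(sorensen(mat, "a", "a"), "self-pairs")
})

test_that("pearson reproduces textbook covariance/sd arithmetic", {
  lin <- spc_from_columns(list(e1 = c(a = 1, b = 2), e2 = c(a = 2, b = 4),
                               e3 = c(a = 3, b = 6)))
  expect_equal(pearson(lin, "a", "b"), 1)
  anti <- spc_from_columns(list(e1 = c(a = 1, b = 3), e2 = c(a = 2, b = 2),
                               e3 = c(a = 3, b = 1)))
  expect_equal(pearson(anti, "a", "b"), -1)
  mix <- spc_from_columns(list(e1 = c(b = 1), e2 = c(a = 1),
                               e3 = c(b = 3), e4 = c(a = 2)))
  expect_equal(pearson(mix, "a", "b"), oracle_pearson(mix, "a", "b"))
  # closed form for q_a=(0,1,0,2), q_b=(1,0,3,0): cov = -3/4 (n denom);
  # sds sqrt(11/16), sqrt(3/2) -> r = -0.75/sqrt(0.6875*1.5)
  expect_equal(pearson(mix, "a", "b"), -0.75 / sqrt((11 / 16) * (3 / 2)))
  flat <- spc_from_columns(list(e1 = c(a = 1, b = 1), e2 = c(a = 1, b = 2)))
  expect_true(is.na(pearson(flat, "a", "b")))   # zero variance sentinel
})

test_that("e3 follows the rank-gap decomposition", {
  m1 <- spc_from_columns(list(e1 = c(a = 10, b = 8, c = 3, d = 1)))
  expect_equal(e3(m1, "a", "b"), 9)           # (10+8)/(|1-2|+1), 1 experiment
  expect_equal(e3(m1, "a", "c"), 13 / 3)      # (10+3)/(|1-3|+1)
  # never co-occurring -> 0
  disj <- spc_from_columns(list(e1 = c(a = 5, z = 1), e2 = c(b = 5, z = 1)))
  expect_equal(e3(disj, "a", "b"), 0)
  # doubling all counts in one experiment doubles that experiment's term:
  # terms (18/2, 6/2) -> mean 6; doubling e1 gives (36/2, 6/2) -> mean 10.5
  two <- spc_from_columns(list(e1 = c(a = 10, b = 8), e2 = c(a = 4, b = 2)))
  twod <- spc_from_columns(list(e1 = c(a = 20, b = 16), e2 = c(a = 4, b = 2)))
  expect_equal(e3(two, "a", "b"), 6)
  expect_equal(e3(twod, "a", "b"), 10.5)
  # denominator switch: cooccurring averages over shared experiments only
  sparse <- spc_from_columns(list(e1 = c(a = 6, b = 2), e2 = c(a = 1, z = 1),
                                  e3 = c(z = 2)))
  expect_equal(e3(sparse, "a", "b", denominator = "cooccurring"),
               3 * e3(sparse, "a", "b"))
  # ties share the minimum rank
  tie <- spc_from_columns(list(e1 = c(a = 5, b = 5, c = 9)))
  expect_equal(e3(tie, "a", "b"), 10)          # gap 0 -> (5+5)/1
})

test_that("ab correlation matches hand arithmetic and is symmetric", {
  mat <- spc_from_columns(list(e1 = c(a = 2, b = 3), e2 = c(z = 1)))
  expect_equal(ab_correlation(mat, "a", "b"), 3 / 2.5)  # 1.2
  disj <- spc_from_columns(list(e1 = c(a = 5, z = 1), e2 = c(b = 5, z = 1)))
  expect_equal(ab_correlation(disj, "a", "b"), 0)
  rmat <- random_spc_matrix(10, 8, seed = 12)
  ids <- protein_ids(rmat)
  for (i in 1:10) {
    p <- sample(ids, 2)
    expect_equal(ab_correlation(rmat, p[1], p[2]),
                 ab_correlation(rmat, p[2], p[1]))
  }
})

test_that("score_all_pairs equals the brute-force nested loop", {
  mat <- random_spc_matrix(15, 10, seed = 4)
  tab <- score_all_pairs(mat)
  expect_gt(nrow(tab), 0)
  for (i in seq_len(nrow(tab))) {
    a <- tab$protein_a[i]; b <- tab$protein_b[i]
    expect_equal(tab$sor[i], oracle_sorensen(mat, a, b), tolerance = 1e-12)
    expect_equal(tab$e3[i], oracle_e3(mat, a, b), tolerance = 1e-12)
    expect_equal(tab$ab[i], oracle_ab(mat, a, b), tolerance = 1e-12)
    o <- oracle_pearson(mat, a, b)
    if (is.nan(o)) expect_true(is.na(tab$pr[i]))
    else expect_equal(tab$pr[i], o, tolerance = 1e-12)
  }
  # universe = co-occurring pairs only
  expect_true(all(tab$cooc >= 1))
  expect_error(score_all_pairs(random_spc_matrix(1, 5)), "at least 2")
})

test_that("score bounds and symmetry invariants hold on random matrices", {
  for (seed in c(2, 8)) {
    mat <- random_spc_matrix(12, 9, seed = seed)
    tab <- score_all_pairs(mat)
    expect_true(all(tab$sor >= 0 & tab$sor <= 1, na.rm = TRUE))
    expect_true(all(tab$pr >= -1 - 1e-12 & tab$pr <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(tab$e3 >= 0, na.rm = TRUE))
    expect_true(all(tab$ab >= 0, na.rm = TRUE))
  }
})

test_that("duplicating every experiment leaves sor, pr, ab and e3 invariant", {
  mat <- random_spc_matrix(10, 6, seed = 14)
  spc2 <- cbind(mat$spc, mat$spc)
  colnames(spc2) <- sprintf("E%02d", seq_len(ncol(spc2)))
  mat2 <- spc_matrix(spc2, mat$mw)
  t1 <- score_all_pairs(mat)
  t2 <- score_all_pairs(mat2)
  key <- paste(t1$protein_a, t1$protein_b)
  m <- match(key, paste(t2$protein_a, t2$protein_b))
  for (col in c("sor", "pr", "e3", "ab"))
    expect_equal(t2[[col]][m], t1[[col]], tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("raising min_cooccurrence never adds pairs", {
  mat <- random_spc_matrix(12, 8, seed = 6)
  n_prev <- Inf
  for (mc in 1:4) {
    n <- nrow(score_all_pairs(mat, methods = "sor", min_cooccurrence = mc))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("sorensen combination annihilates and preserves order as expected", {
  mat <- random_spc_matrix(12, 9, seed = 10)
  tab <- combine_with_sorensen(score_all_pairs(mat), "e3")
  zero <- !is.na(tab$sor) & tab$sor == 0
  expect_true(all(tab$e3_sor[zero] == 0))
  # sor = 1 everywhere: combined rank order equals base rank order
  ident <- spc_from_columns(list(e1 = c(a = 5, b = 3, c = 1),
                                 e2 = c(a = 2, b = 6, c = 9)))
  ti <- combine_with_sorensen(score_all_pairs(ident), "e3")
  expect_true(all(ti$sor == 1))
  expect_identical(ti$rank_e3_sor, ti$rank_e3)
  # mapped pearson keeps the product monotone
  tp <- combine_with_sorensen(score_all_pairs(mat), "pr")
  expect_true(all(tp$pr_sor >= 0, na.rm = TRUE))
})

test_that("top fraction intersection honours per-method cuts", {
  mat <- random_spc_matrix(14, 10, seed = 16)
  tab <- score_all_pairs(mat)
  # identical rankings: intersection is exactly the shared top 10%
  one <- top_fraction_intersection(tab, methods = c("sor", "sor"),
                                   fraction = 0.1)
  k <- ceiling(0.1 * sum(!is.na(tab$rank_sor)))
  expect_equal(nrow(one), k)
  # intersection can never exceed the smallest per-method cut
  both <- top_fraction_intersection(tab, methods = c("sor", "e3"),
                                    fraction = 0.2)
  expect_lte(nrow(both), ceiling(0.2 * sum(!is.na(tab$rank_sor))))
  # reversed-order tables with distinct scores share nothing below 50%
  n <- 10
  up <- data.frame(protein_a = sprintf("a%02d", 1:n), protein_b = "z",
                   s1 = 1:n, s2 = n:1)
  up$rank_s1 <- rank_desc_test(up$s1, up$protein_a, up$protein_b)
  up$rank_s2 <- rank_desc_test(up$s2, up$protein_a, up$protein_b)
  expect_equal(nrow(top_fraction_intersection(up, c("s1", "s2"), 0.3)), 0L)
  expect_error(top_fraction_intersection(tab, "nope", 0.1), "not present")
})
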