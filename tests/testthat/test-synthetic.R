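test_that("generator configs are validated before any sampling", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(capture_probability = 1.2, seed = 1),
               "probabilities")
  expect_error(generator_config(complex_size_range = c(9, 3), seed = 1),
               "complex_size_range")
  expect_error(generate_ipms(generator_config(n_proteins = 20, seed = 1)),
               "too small")
})

test_that("a fixed seed reproduces the study bit for bit", {
  cfg <- small_sim_config(seed = 11)
  s1 <- generate_ipms(cfg)
  s2 <- generate_ipms(cfg)
  expect_identical(s1$matrix$spc, s2$matrix$spc)
  expect_identical(s1$experiments$info, s2$experiments$info)
  expect_identical(unclass(s1$annotation), unclass(s2$annotation))
  expect_identical(s1$truth$complexes, s2$truth$complexes)
  s3 <- generate_ipms(small_sim_config(seed = 12))
  expect_false(identical(s1$matrix$spc, s3$matrix$spc))
})

test_that("the noise-free limit recovers pulled complexes exactly", {
  cfg <- generator_config(n_proteins = 120, n_complexes = 6,
                          complex_size_range = c(3, 8), n_experiments = 30,
                          list_size_range = c(1, 500),
                          capture_probability = 1, background_rate = 0,
                          n_sticky = 0, sticky_rate = 0,
                          antibody_crossreact_probability = 0,
                          heavy_tail_prob = 0, seed = 3)
  sim <- generate_ipms(cfg)
  memb <- sim$truth$complexes
  bait_cx <- vapply(sim$experiments$info$bait, function(b)
    names(memb)[vapply(memb, function(m) b %in% m, logical(1))], "")
  for (j in seq_len(nrow(sim$experiments$info)))
    expect_setequal(sim$experiments$protein_sets[[j]], memb[[bait_cx[j]]])
})

test_that("ground truth is internally consistent", {
  sim <- generate_ipms(small_sim_config(seed = 19))
  truth <- sim$truth
  # true PPIs = union of within-complex unordered pairs
  expected <- do.call(rbind, lapply(truth$complexes, function(m) {
    cmb <- combn(sort(m), 2)
    data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ])
  }))
  expect_equal(nrow(truth$true_ppis), nrow(expected))
  expect_setequal(paste(truth$true_ppis$protein_a, truth$true_ppis$protein_b),
                  paste(expected$protein_a, expected$protein_b))
  expect_true(all(truth$true_ppis$protein_a < truth$true_ppis$protein_b))
  # every complex's planted domain pair is carried by its members
  for (k in seq_along(truth$complexes)) {
    doms <- unlist(lapply(truth$complexes[[k]],
                          function(p) domains_of(sim$annotation, p)))
    expect_true(all(c(truth$true_ddis$domain_a[k],
                      truth$true_ddis$domain_b[k]) %in% doms))
  }
  # sticky proteins exist in the matrix and are flagged
  expect_true(all(truth$sticky %in% protein_ids(sim$matrix)))
})

test_that("list sizes respect the configured range without heavy tails", {
  cfg <- generator_config(n_proteins = 400, n_complexes = 10,
                          complex_size_range = c(3, 10), n_experiments = 60,
                          list_size_range = c(20, 60), heavy_tail_prob = 0,
                          background_rate = 0.05, n_sticky = 10, seed = 23)
  sim <- generate_ipms(cfg)
  sz <- lengths(sim$experiments$protein_sets)
  expect_true(all(sz >= 20 & sz <= 60))
})

test_that("degrading the truth subsamples at the requested rate", {
  sim <- generate_ipms(small_sim_config(seed = 27))
  full <- degrade(sim$truth, 1)
  expect_equal(nrow(full), nrow(sim$truth$true_ppis))
  none <- degrade(sim$truth, 0, seed = 1)
  expect_equal(nrow(none), 0L)
  n <- nrow(sim$truth$true_ppis)
  kept <- nrow(degrade(sim$truth, 0.4, seed = 5))
  # binomial 99.9% band around 0.4 n
  expect_lt(abs(kept - 0.4 * n), 3.3 * sqrt(n * 0.4 * 0.6) + 1)
  expect_error(degrade(sim$truth, 1.5), "fraction")
})

test_that("stronger capture lifts scoring performance monotonically", {
  mean_auc <- function(capture) {
    aucs <- vapply(1:5, function(s) {
      sim <- generate_ipms(small_sim_config(
        seed = 100 + s, capture_probability = capture))
      mat <- suppressMessages(apply_sticky_filter(sim$matrix,
                                                  sim$truth$sticky))
      sc <- score_all_pairs(mat, methods = c("sor", "ab"))
      ok <- !is.na(sc$rank_ab)
      ranked <- sc[ok, ][order(sc$rank_ab[ok]), ]
      roc_auc(ranked, sim$truth$true_ppis, scores = ranked$ab)$auc
    }, numeric(1))
    mean(aucs)
  }
  a <- vapply(c(0.4, 0.7, 0.95), mean_auc, numeric(1))
  expect_true(all(diff(a) > 0))
})
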