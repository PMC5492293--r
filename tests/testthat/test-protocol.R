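test_that("stratified folds and splits preserve class proportions", {
  labels <- factor(c(rep("NF", 43), rep("PF", 28)), levels = c("NF", "PF"))
  fold <- turngait:::stratified_folds(labels, 5, seed = 3)
  for (f in 1:5) {
    tab <- table(labels[fold == f])
    expect_lt(abs(tab["NF"] - 43 / 5), 1)
    expect_lt(abs(tab["PF"] - 28 / 5), 1)
  }
  expect_identical(sort(unique(fold)), 1:5)
  test_idx <- turngait:::stratified_split(labels, 0.2, seed = 3)
  tab <- table(labels[test_idx])
  expect_identical(as.integer(tab["NF"]), 9L)
  expect_identical(as.integer(tab["PF"]), 6L)
})

test_that("five-fold CV uses every sample exactly once as test", {
  labels <- factor(rep(c("NF", "PF"), each = 10), levels = c("NF", "PF"))
  fold <- turngait:::stratified_folds(labels, 5, seed = 1)
  expect_identical(as.integer(table(fold)), rep(4L, 5))
})

test_that("five-fold CV is perfect on a separable cohort", {
  fm <- toy_feature_matrix(n_per_class = 10, n_noise = 10, sep = 8)
  cv <- five_fold_cv(fm, cmfs_combinations(models = "RF",
                                           selectors = "S5B"), seed = 2)
  expect_equal(unname(cv$means["RF S5B", "ACC"]), 1)
  expect_error(five_fold_cv(toy_feature_matrix(n_per_class = 4),
                            cmfs_combinations()), "at least 5")
})

test_that("the rank tie rule reproduces its worked example", {
  scores <- matrix(c(9, 8, 7, 7, 7, 6, 5), ncol = 1,
                   dimnames = list(paste0("m", 1:7), "ACC"))
  rt <- rank_combinations(scores, metrics = "ACC")
  expect_identical(rt$ACC[order(rownames(rt))], c(1L, 2L, 3L, 3L, 3L, 6L, 7L))
})

test_that("rank sums are permutation invariant with conserved totals", {
  set.seed(8)
  m <- matrix(runif(18 * 7), 18,
              dimnames = list(paste0("c", 1:18), turngait:::metric_names))
  rt <- rank_combinations(m)
  perm <- sample(18)
  rt2 <- rank_combinations(m[perm, ])
  expect_equal(rt2[rownames(rt), "rank_sum"], rt$rank_sum)
  # per metric, tie-adjusted ranks of distinct values sum to n(n+1)/2
  expect_equal(sum(rt$ACC), sum(1:18))
  all_tied <- matrix(1, 4, 7,
                     dimnames = list(paste0("c", 1:4),
                                     turngait:::metric_names))
  rt3 <- rank_combinations(all_tied)
  expect_true(all(rt3$rank_sum == 7))
})

test_that("pruning keeps 5 classifiers x 2 selectors and drops the weakest", {
  mk_table <- function(order) {
    combos <- cmfs_combinations()
    m <- matrix(rev(seq_len(18)), 18, 7,
                dimnames = list(combos$combo[order],
                                turngait:::metric_names))
    rank_combinations(m)
  }
  # put every SVM_poly5 and RFE combination at the bottom
  combos <- cmfs_combinations()
  bad <- combos$model == "SVM_poly5" | combos$selector == "RFE"
  ord <- c(which(!bad), which(bad))
  rt <- mk_table(ord)
  pruned <- prune_after_test1(rt, rt)
  expect_identical(pruned$dropped_model, "SVM_poly5")
  expect_identical(pruned$dropped_selector, "RFE")
  expect_length(pruned$models, 5)
  expect_length(pruned$selectors, 2)
  expect_identical(nrow(cmfs_combinations(pruned$models,
                                          pruned$selectors)), 10L)
})

test_that("RSS CV reports the CI convention and n_iter = 1 degenerates", {
  fm <- toy_feature_matrix(n_per_class = 8, n_noise = 6, sep = 1)
  combos <- cmfs_combinations(models = "kNN3", selectors = "S5B")
  cv <- rss_cv(fm, combos, n_iter = 20, seed = 4)
  expect_equal(cv$cis, 1.96 * cv$sds / sqrt(20))
  one <- rss_cv(fm, combos, n_iter = 1, seed = 4)
  expect_true(all(one$sds == 0))
  expect_true(all(one$cis == 0))
})

test_that("RSS selection frequencies are conserved for S5B", {
  fm <- toy_feature_matrix(n_per_class = 8, n_noise = 12, sep = 2)
  combos <- cmfs_combinations(models = "kNN3", selectors = "S5B")
  cv <- rss_cv(fm, combos, n_iter = 25, seed = 4)
  expect_identical(sum(cv$sel_freq$S5B), 5L * 25L)
  expect_lte(max(cv$sel_freq$S5B), 25L)
})

test_that("RSS CV is deterministic under a fixed seed", {
  fm <- toy_feature_matrix(n_per_class = 8, n_noise = 6, sep = 2)
  combos <- cmfs_combinations(models = c("RF", "kNN3"), selectors = "S5B")
  a <- rss_cv(fm, combos, n_iter = 10, seed = 11)
  b <- rss_cv(fm, combos, n_iter = 10, seed = 11)
  expect_identical(a$samples, b$samples)
})

test_that("reduced-iteration RSS means agree within CI multiples", {
  fm <- toy_feature_matrix(n_per_class = 10, n_noise = 10, sep = 1.5)
  combos <- cmfs_combinations(models = "kNN3", selectors = "S5B")
  big <- rss_cv(fm, combos, n_iter = 400, seed = 6)
  small <- rss_cv(fm, combos, n_iter = 100, seed = 7)
  for (m in c("ACC", "MCC"))
    expect_lt(abs(big$means[1, m] - small$means[1, m]),
              3 * big$sds[1, m] / sqrt(100) + 3 * big$cis[1, m] + 1e-9)
})

test_that("MFO subsets are nested with alphabetical tie-breaks", {
  freq <- c(b = 300L, a = 300L, c = 500L, d = 100L)
  ms <- mfo_subsets(freq, threshold = 250)
  expect_identical(ms$features, c("c", "a", "b"))
  expect_identical(ms$subsets[[1]], c("c", "a", "b"))
  expect_identical(ms$subsets[[3]], "c")
  for (i in seq_len(length(ms$subsets) - 1))
    expect_true(all(ms$subsets[[i + 1]] %in% ms$subsets[[i]]))
  expect_error(mfo_subsets(c(a = 10L), threshold = 250), "threshold")
})

test_that("the MFO sweep runs one summary per subset size", {
  fm <- toy_feature_matrix(n_per_class = 8, n_noise = 6, sep = 3)
  freq <- setNames(c(20L, 15L, 12L, 2L),
                   c("signal", "noise1", "noise2", "noise3"))
  sw <- mfo_sweep(fm, freq, "kNN3", threshold = 10, n_iter = 15, seed = 2)
  expect_length(sw$summaries, 3)
  expect_identical(rownames(sw$means), c("3", "2", "1"))
})

test_that("Welch test matches its closed form and degenerate cases", {
  w <- welch_t(1:4, 2:5)
  v <- var(1:4)
  expect_equal(w$t, (2.5 - 3.5) / sqrt(v / 4 + v / 4))
  expect_equal(w$df, 6)
  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- welch_t(rnorm(30, 0, 0.01), rnorm(30, 5, 0.01))
  expect_lt(sep$p, 1e-3)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("the full protocol emits the 18/10/8 test-structure", {
  fm_s <- toy_feature_matrix(n_per_class = 8, n_noise = 25, sep = 0.5,
                             seed = 21)
  fm_t <- toy_feature_matrix(n_per_class = 8, n_noise = 25, sep = 3,
                             seed = 22)
  fm_c <- fm_s
  fm_c$x <- cbind(fm_s$x, fm_t$x)
  colnames(fm_c$x) <- c(paste0("straight|", colnames(fm_s$x)),
                        paste0("turn|", colnames(fm_t$x)))
  rep <- run_protocol(fm_s, fm_t, fm_c, n_iter = 15, seed = 3)
  expect_identical(nrow(rep$test1$ranks_straight), 18L)
  expect_identical(nrow(rep$test2$ranks_turn), 10L)
  expect_identical(nrow(rep$test4$ranks), 8L)
  expect_length(rep$welch, 7)
  # the planted turn-only signal makes the turn side win
  expect_gt(rep$test2$turn$means[rep$test2$best_turn, "ACC"],
            rep$test2$straight$means[rep$test2$best_straight, "ACC"])
})
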