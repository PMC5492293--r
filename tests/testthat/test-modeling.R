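test_that("min-max normalization follows its defining map", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  np <- fit_normalizer(x)
  out <- apply_normalizer(np, x)
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE)  # constant -> 0
  # test values outside the training range are not clamped
  test <- cbind(a = 8, b = 2)
  expect_equal(apply_normalizer(np, test)[1, "a"], 1.5, ignore_attr = TRUE)
  expect_error(apply_normalizer(np, cbind(a = 1)), "unknown feature")
})

test_that("normalizing twice is the identity on the second pass", {
  set.seed(3)
  x <- matrix(rnorm(60), 10)
  colnames(x) <- paste0("f", 1:6)
  once <- apply_normalizer(fit_normalizer(x), x)
  np2 <- fit_normalizer(once)
  expect_equal(unname(np2$y_min), rep(0, 6))
  expect_equal(unname(np2$y_max), rep(1, 6))
  expect_equal(apply_normalizer(np2, once), once)
})

test_that("S5B returns exactly k features and finds a planted signal", {
  fm <- toy_feature_matrix(n_per_class = 15, n_noise = 49, sep = 2)
  sel <- select_features("S5B", fm$x, fm$labels, k = 5)
  expect_length(sel, 5)
  # a feature equal to the class indicator plus tiny noise must rank first
  hits <- vapply(1:40, function(i) {
    set.seed(i)
    n <- 20
    labels <- factor(rep(c("NF", "PF"), each = n / 2),
                     levels = c("NF", "PF"))
    x <- matrix(rnorm(n * 50), n)
    colnames(x) <- c("signal", paste0("noise", 1:49))
    x[, "signal"] <- as.numeric(labels == "PF") + rnorm(n, 0, 0.1)
    select_features("S5B", x, labels, k = 5)[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant features are never selected by any method", {
  fm <- toy_feature_matrix(n_per_class = 8, n_noise = 10)
  fm$x <- cbind(fm$x, flat = rep(1, nrow(fm$x)))
  for (m in c("S5B", "SEL"))
    expect_false("flat" %in% select_features(m, fm$x, fm$labels, k = 5))
  sel <- select_features("RFE", fm$x, fm$labels, k = 3, seed = 1)
  expect_false("flat" %in% sel)
  expect_length(sel, 3)
})

test_that("SEL unions the FPR and FDR filters, ordered by p-value", {
  fm <- toy_feature_matrix(n_per_class = 15, n_noise = 30, sep = 3)
  sel <- select_features("SEL", fm$x, fm$labels, alpha = 0.05)
  expect_identical(sel[1], "signal")
  expect_identical(anyDuplicated(sel), 0L)
  av <- turngait:::anova_f(fm$x, fm$labels)
  manual <- colnames(fm$x)[av$p < 0.05 | p.adjust(av$p, "BH") < 0.05]
  expect_setequal(sel, manual)
})

test_that("selection is deterministic and errors on one-class labels", {
  fm <- toy_feature_matrix()
  expect_identical(select_features("RFE", fm$x, fm$labels, k = 4, seed = 7),
                   select_features("RFE", fm$x, fm$labels, k = 4, seed = 7))
  one <- factor(rep("NF", nrow(fm$x)), levels = c("NF", "PF"))
  expect_error(select_features("S5B", fm$x, one), "two classes")
})

test_that("metric formulas match the hand-worked confusion example", {
  m <- metrics_from_counts(tp = 2, fp = 1, tn = 3, fn = 2)
  expect_equal(unname(m["ACC"]), 0.625)
  expect_equal(unname(m["SENS"]), 0.5)
  expect_equal(unname(m["SPEC"]), 0.75)
  expect_equal(unname(m["PPV"]), 2 / 3)
  expect_equal(unname(m["NPV"]), 0.6)
  expect_equal(unname(m["F1"]), 2 * (2 / 3) * 0.5 / (2 / 3 + 0.5))
  expect_equal(unname(m["MCC"]), (2 * 3 - 1 * 2) / sqrt(3 * 4 * 4 * 5))
})

test_that("degenerate confusion counts follow the 0/0 -> 0 policy", {
  m <- metrics_from_counts(tp = 0, fp = 2, tn = 3, fn = 0)
  expect_equal(unname(m["SENS"]), 0)
  expect_equal(unname(m["MCC"]), 0)
  perfect <- metrics_from_counts(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unname(perfect[c("ACC", "SENS", "SPEC", "PPV", "NPV", "F1",
                                "MCC")]), rep(1, 7))
  expect_error(metrics_from_counts(0, 0, 0, 0), "positive sum")
})

test_that("MCC magnitude is invariant under swapping class labels", {
  set.seed(11)
  for (i in 1:20) {
    cts <- rpois(4, 5) + 1
    a <- metrics_from_counts(cts[1], cts[2], cts[3], cts[4])
    b <- metrics_from_counts(cts[3], cts[4], cts[1], cts[2])
    expect_equal(abs(unname(a["MCC"])), abs(unname(b["MCC"])))
  }
})

test_that("every classifier is perfect on separable clusters", {
  fm <- toy_feature_matrix(n_per_class = 12, n_noise = 4, sep = 10)
  test <- toy_feature_matrix(n_per_class = 6, n_noise = 4, sep = 10,
                             seed = 99)
  for (model in turngait:::classifier_models) {
    m <- train_and_evaluate(model, fm, test, c("signal", "noise1"),
                            seed = 2)
    expect_equal(unname(m["ACC"]), 1)
    expect_equal(unname(m["MCC"]), 1)
  }
})

test_that("kNN3 predicts the majority label of the three nearest points", {
  train <- list(
    x = cbind(f1 = c(0, 0.1, 0.2, 1.0, 1.1), f2 = c(0, 0, 0.1, 1, 1)),
    labels = factor(c("NF", "NF", "NF", "PF", "PF"),
                    levels = c("NF", "PF")))
  rownames(train$x) <- paste0("P", 1:5)
  test <- list(x = cbind(f1 = c(0.15, 1.05)), labels = factor(c("PF", "PF"),
               levels = c("NF", "PF")))
  test$x <- cbind(test$x, f2 = c(0.05, 0.95))
  # nearest 3 to (0.15, 0.05): the three NF points; to (1.05, 0.95): 2 PF + 1 NF
  m <- train_and_evaluate("kNN3", train, test, c("f1", "f2"))
  expect_equal(unname(m["TP"]), 1)   # second point classified PF
  expect_equal(unname(m["FN"]), 1)   # first point classified NF
})

test_that("label-independent features give near-zero MCC", {
  set.seed(5)
  n <- 200
  fm <- list(x = matrix(rnorm(n * 3), n,
                        dimnames = list(NULL, c("a", "b", "c"))),
             labels = factor(rep(c("NF", "PF"), n / 2),
                             levels = c("NF", "PF")))
  te <- list(x = matrix(rnorm(n * 3), n,
                        dimnames = list(NULL, c("a", "b", "c"))),
             labels = factor(rep(c("NF", "PF"), n / 2),
                             levels = c("NF", "PF")))
  m <- train_and_evaluate("kNN5", fm, te, c("a", "b", "c"), seed = 1)
  expect_lt(abs(unname(m["MCC"])), 0.15)
})
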