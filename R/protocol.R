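#' All classifier-model / feature-selector combinations
#'
#' @param models Classifier names (subset of
#'   `kNN3, kNN5, SVM_linear, SVM_poly3, SVM_poly5, RF`).
#' @param selectors Selector names (subset of `S5B, SEL, RFE`).
#' @return Data frame with columns `model`, `selector`, `combo`.
#' @export
cmfs_combinations <- function(models = classifier_models,
                              selectors = c("S5B", "SEL", "RFE")) {
  g <- expand.grid(model = models, selector = selectors,
                   stringsAsFactors = FALSE)
  g$combo <- paste(g$model, g$selector)
  g
}

# deterministic per-iteration seed derived from the base seed; kept < 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 1664525) %% 2147483587)
}

# stratified indices: per class, shuffle and deal into k folds
stratified_folds <- function(labels, k = 5, seed = 1) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# stratified test-set indices at the given fraction (rounded per class)
stratified_split <- function(labels, test_frac = 0.2, seed = 1) {
  set.seed(as.integer(seed))
  test <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_frac * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

subset_fm <- function(fm, rows) {
  list(x = fm$x[rows, , drop = FALSE], labels = droplevels(fm$labels[rows]),
       participants = fm$participants[rows])
}

#' Stratified five-fold cross-validation over CM-FS combinations (Test I)
#'
#' The data are partitioned into five stratified folds; for each fold, each
#' selector is run on the four training folds, every classifier is trained on
#' the selected normalized features, and the held-out fold is scored. The
#' seven metrics are averaged over the five folds per combination.
#'
#' @param fm A `feature_matrix`.
#' @param combos Data frame from [cmfs_combinations()].
#' @param seed Integer seed.
#' @param k_features,alpha Selector parameters (see [select_features()]).
#' @return A `cv_summary`: list with `means` (combos x 7 metric matrix),
#'   `per_fold` (list of per-fold metric matrices), `combos`, `n_iterations`.
#' @export
five_fold_cv <- function(fm, combos = cmfs_combinations(), seed = 1,
                         k_features = 5, alpha = 0.05) {
  labels <- fm$labels
  if (any(table(labels) < 5)) stop("each class needs at least 5 members",
                                   call. = FALSE)
  fold <- stratified_folds(labels, 5, seed)
  selectors <- unique(combos$selector)
  acc <- array(NA_real_, dim = c(nrow(combos), length(metric_names), 5),
               dimnames = list(combos$combo, metric_names, NULL))
  for (f in 1:5) {
    tr <- subset_fm(fm, which(fold != f))
    te <- subset_fm(fm, which(fold == f))
    sel_sets <- lapply(stats::setNames(selectors, selectors), function(s)
      select_features(s, tr$x, tr$labels, k = k_features, alpha = alpha,
                      seed = derive_seed(seed, f)))
    for (i in seq_len(nrow(combos))) {
      m <- train_and_evaluate(combos$model[i], tr, te,
                              sel_sets[[combos$selector[i]]],
                              seed = derive_seed(seed, f * 100 + i))
      acc[i, , f] <- m[metric_names]
    }
  }
  means <- apply(acc, c(1, 2), mean)
  structure(list(means = means, per_fold = acc, combos = combos,
                 n_iterations = 5, scheme = "5FCV"),
            class = "cv_summary")
}

#' Stratified random-shuffle-split cross-validation (Tests II-IV)
#'
#' Each iteration draws a fresh stratified 80/20 train/test split (iteration
#' seeds derived deterministically from the base seed), performs feature
#' selection on the training rows only (unless `fixed_features` is given),
#' fits every combination, and scores the test rows. Reports mean, SD, and
#' the 95% confidence-interval half-width `1.96 * SD / sqrt(n_iter)` per
#' metric, plus per-feature selection frequencies per selector.
#'
#' @param fm A `feature_matrix`.
#' @param combos Data frame from [cmfs_combinations()].
#' @param n_iter Number of iterations (2500 in the full protocol).
#' @param test_frac Held-out fraction, default 0.2.
#' @param seed Integer seed.
#' @param fixed_features Optional character vector: skip per-iteration
#'   selection and use this feature set throughout (the MFO sweep mode).
#' @param k_features,alpha Selector parameters.
#' @return A `cv_summary` with `means`, `sds`, `cis`, per-iteration `samples`
#'   (combo x metric x iteration array), `sel_freq` (per-selector named
#'   selection counts), `combos`, `n_iterations`.
#' @export
rss_cv <- function(fm, combos = cmfs_combinations(), n_iter = 2500,
                   test_frac = 0.2, seed = 1, fixed_features = NULL,
                   k_features = 5, alpha = 0.05) {
  stopifnot(n_iter >= 1)
  labels <- fm$labels
  selectors <- unique(combos$selector)
  samples <- array(NA_real_,
                   dim = c(nrow(combos), length(metric_names), n_iter),
                   dimnames = list(combos$combo, metric_names, NULL))
  sel_freq <- lapply(stats::setNames(selectors, selectors), function(s)
    stats::setNames(integer(ncol(fm$x)), colnames(fm$x)))
  for (it in seq_len(n_iter)) {
    s_it <- derive_seed(seed, it)
    repeat {
      test_idx <- stratified_split(labels, test_frac, s_it)
      te <- subset_fm(fm, test_idx)
      tr <- subset_fm(fm, setdiff(seq_along(labels), test_idx))
      if (nlevels(te$labels) == 2 && nlevels(tr$labels) == 2) break
      s_it <- derive_seed(s_it, 999983)   # degenerate split: redraw
    }
    sel_sets <- if (is.null(fixed_features)) {
      lapply(stats::setNames(selectors, selectors), function(s)
        select_features(s, tr$x, tr$labels, k = k_features, alpha = alpha,
                        seed = s_it))
    } else {
      lapply(stats::setNames(selectors, selectors),
             function(s) fixed_features)
    }
    if (is.null(fixed_features))
      for (s in selectors)
        sel_freq[[s]][sel_sets[[s]]] <- sel_freq[[s]][sel_sets[[s]]] + 1L
    for (i in seq_len(nrow(combos))) {
      m <- train_and_evaluate(combos$model[i], tr, te,
                              sel_sets[[combos$selector[i]]],
                              seed = derive_seed(s_it, i))
      samples[i, , it] <- m[metric_names]
    }
  }
  means <- apply(samples, c(1, 2), mean)
  sds <- if (n_iter >= 2) apply(samples, c(1, 2), stats::sd) else
    means * 0
  cis <- 1.96 * sds / sqrt(n_iter)
  structure(list(means = means, sds = sds, cis = cis, samples = samples,
                 sel_freq = sel_freq, combos = combos,
                 n_iterations = n_iter, scheme = "RSS"),
            class = "cv_summary")
}

#' Rank CM-FS combinations across the seven metrics
#'
#' Within each metric, combinations are sorted descending (higher is better)
#' and ranked 1, 2, ...; ties share the minimal position and the next
#' distinct value takes its ordinal position (a three-way tie at position
#' three gives 1, 2, 3, 3, 3, 6, 7, ...). Ranks are summed across metrics;
#' the lowest rank sum is the best combination.
#'
#' @param means Combination x metric matrix (e.g. `cv_summary$means`), or a
#'   `cv_summary`.
#' @param metrics Metric columns to rank over, default all seven.
#' @return A `rank_table` data frame: per-metric ranks, `rank_sum`, ordered
#'   ascending by `rank_sum`.
#' @export
rank_combinations <- function(means, metrics = metric_names) {
  if (inherits(means, "cv_summary")) means <- means$means
  means <- means[, metrics, drop = FALSE]
  ranks <- apply(means, 2, function(v) rank(-v, ties.method = "min"))
  ranks <- matrix(ranks, nrow = nrow(means),
                  dimnames = list(rownames(means), metrics))
  out <- as.data.frame(ranks)
  out$rank_sum <- rowSums(ranks)
  out <- out[order(out$rank_sum), , drop = FALSE]
  class(out) <- c("rank_table", class(out))
  out
}

#' Discard the weakest classifier and selector after Test I
#'
#' Counts how often each classifier and each selector appears within the top
#' nine combinations of the straight and turn rank tables (pooled), and
#' removes the least frequent of each; frequency ties are broken by the worse
#' (larger) best rank sum. With six classifiers and three selectors this
#' leaves the 5 x 2 = 10 combinations carried into Test II.
#'
#' @param straight,turn `rank_table`s over all 18 combinations.
#' @param top_n Size of the examined head of each table, default 9.
#' @return List with `models` (kept classifiers), `selectors` (kept
#'   selectors), `dropped_model`, `dropped_selector`.
#' @export
prune_after_test1 <- function(straight, turn, top_n = 9) {
  split_combo <- function(tab) {
    nm <- rownames(tab)
    parts <- strsplit(nm, " ", fixed = TRUE)
    data.frame(model = vapply(parts, `[`, "", 1),
               selector = vapply(parts, `[`, "", 2),
               rank_sum = tab$rank_sum)
  }
  all_s <- split_combo(straight)
  all_t <- split_combo(turn)
  top <- rbind(utils::head(all_s, top_n), utils::head(all_t, top_n))
  pool <- rbind(all_s, all_t)
  drop_least <- function(field) {
    universe <- unique(pool[[field]])
    counts <- stats::setNames(integer(length(universe)), universe)
    tt <- table(top[[field]])
    counts[names(tt)] <- as.integer(tt)
    least <- names(counts)[counts == min(counts)]
    if (length(least) > 1) {
      best_rs <- vapply(least, function(v)
        min(pool$rank_sum[pool[[field]] == v]), numeric(1))
      least <- least[which.max(best_rs)]
    }
    least
  }
  dm <- drop_least("model")
  ds <- drop_least("selector")
  list(models = setdiff(unique(pool$model), dm),
       selectors = setdiff(unique(pool$selector), ds),
       dropped_model = dm, dropped_selector = ds)
}

#' Most-frequently-occurring feature subsets
#'
#' Features selected in at least `threshold` iterations, ordered by selection
#' frequency descending (ties alphabetical), yield nested subsets
#' `X_0 = (f_0 ... f_n)`, `X_1 = (f_0 ... f_{n-1})`, ..., `X_n = (f_0)`.
#'
#' @param freq Named selection counts (one selector's entry of
#'   `cv_summary$sel_freq`).
#' @param threshold Minimum selection count, default 250 (10% of 2500).
#' @return List with `features` (ordered) and `subsets` (list of vectors).
#' @export
mfo_subsets <- function(freq, threshold = 250) {
  keep <- freq[freq >= threshold]
  if (!length(keep)) stop("no feature reaches the MFO threshold",
                          call. = FALSE)
  ord <- names(keep)[order(-keep, names(keep))]
  n <- length(ord)
  subsets <- lapply(seq_len(n), function(i) ord[seq_len(n - i + 1)])
  list(features = ord, subsets = subsets)
}

#' MFO feature-subset sweep (Test III)
#'
#' Builds the nested most-frequently-occurring subsets from a Test II
#' selection-frequency table and reruns random-shuffle-split CV for the best
#' classifier with each fixed subset (no per-iteration selection).
#'
#' @param fm The condition's `feature_matrix`.
#' @param freq Named selection counts from Test II.
#' @param model The best Test II classifier.
#' @param threshold MFO threshold (250 of 2500 in the full protocol).
#' @param n_iter RSS iterations per subset.
#' @param seed Integer seed.
#' @return List with `subsets` and `summaries` (one `cv_summary` per subset,
#'   largest first), plus `means` (subset-size x metric matrix).
#' @export
mfo_sweep <- function(fm, freq, model, threshold = 250, n_iter = 2500,
                      seed = 1) {
  ms <- mfo_subsets(freq, threshold)
  combos <- cmfs_combinations(models = model, selectors = "S5B")
  summaries <- lapply(ms$subsets, function(sub)
    rss_cv(fm, combos, n_iter = n_iter, seed = seed, fixed_features = sub))
  means <- do.call(rbind, lapply(summaries, function(s) s$means[1, ]))
  rownames(means) <- vapply(ms$subsets, length, integer(1))
  list(subsets = ms$subsets, summaries = summaries, means = means)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (wraps [stats::t.test()]).
#'
#' @param a,b Numeric samples (>= 2 values each; not both zero-variance).
#' @return Named list `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (all(a[1] == c(a, b))) return(list(t = 0, df = length(a) +
                                            length(b) - 2, p = 1))
    stop("zero variance in both samples", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Run the full four-test evaluation protocol
#'
#' Executes the study's test sequence on a pair of condition feature
#' matrices: Test I (stratified five-fold CV over all 18 CM-FS combinations,
#' straight and turn), pruning of the weakest classifier and selector, Test
#' II (random-shuffle-split CV over the 10 surviving combinations, with
#' Welch's t-tests comparing the best straight against the best turn
#' combination on every metric), Test III (MFO subset sweeps per condition
#' with the best Test II classifier), and Test IV (the 592-feature combined
#' matrix with the top four Test II classifiers and both surviving
#' selectors).
#'
#' @param straight,turn,combined `feature_matrix` objects sharing
#'   participants (e.g. from [cohort_features()]).
#' @param n_iter RSS iterations (2500 in the full protocol).
#' @param mfo_threshold MFO selection-count threshold; defaults to 10% of
#'   `n_iter`.
#' @param seed Integer seed.
#' @return A `protocol_report` list with `test1`, `pruned`, `test2`,
#'   `welch`, `test3`, `test4` components (summaries, rank tables, best
#'   combinations).
#' @export
run_protocol <- function(straight, turn, combined, n_iter = 2500,
                         mfo_threshold = ceiling(0.1 * n_iter), seed = 1) {
  stopifnot(identical(straight$participants, turn$participants))

  all18 <- cmfs_combinations()
  t1_s <- five_fold_cv(straight, all18, seed = derive_seed(seed, 11))
  t1_t <- five_fold_cv(turn, all18, seed = derive_seed(seed, 12))
  r1_s <- rank_combinations(t1_s)
  r1_t <- rank_combinations(t1_t)
  pruned <- prune_after_test1(r1_s, r1_t)

  combos10 <- cmfs_combinations(models = pruned$models,
                                selectors = pruned$selectors)
  t2_s <- rss_cv(straight, combos10, n_iter = n_iter,
                 seed = derive_seed(seed, 21))
  t2_t <- rss_cv(turn, combos10, n_iter = n_iter,
                 seed = derive_seed(seed, 22))
  r2_s <- rank_combinations(t2_s)
  r2_t <- rank_combinations(t2_t)
  best_s <- rownames(r2_s)[1]
  best_t <- rownames(r2_t)[1]
  welch <- lapply(stats::setNames(metric_names, metric_names), function(m)
    welch_t(t2_t$samples[best_t, m, ], t2_s$samples[best_s, m, ]))

  best_t_model <- strsplit(best_t, " ")[[1]][1]
  best_s_model <- strsplit(best_s, " ")[[1]][1]
  # MFO lists come from a size-limited selector (S5B and RFE contribute
  # exactly k names per iteration, so "frequent" is meaningful). SEL's
  # unrestricted lists can mark most of the feature bank as frequent; if
  # only SEL survives, its frequency table is truncated to the top 20.
  mfo_selector <- intersect(c("S5B", "RFE"), pruned$selectors)[1]
  if (is.na(mfo_selector)) mfo_selector <- pruned$selectors[1]
  mfo_freq <- function(sf) {
    f <- sf[[mfo_selector]]
    if (mfo_selector == "SEL")
      f <- f[rank(-f, ties.method = "first") <= 20]
    f
  }
  t3 <- list(
    straight = tryCatch(
      mfo_sweep(straight, mfo_freq(t2_s$sel_freq), best_s_model,
                threshold = mfo_threshold, n_iter = n_iter,
                seed = derive_seed(seed, 31)),
      error = function(e) NULL),
    turn = tryCatch(
      mfo_sweep(turn, mfo_freq(t2_t$sel_freq), best_t_model,
                threshold = mfo_threshold, n_iter = n_iter,
                seed = derive_seed(seed, 32)),
      error = function(e) NULL))

  # Test IV: top four classifiers from the Test II turn table, both selectors
  top_models <- unique(vapply(strsplit(rownames(r2_t), " "), `[`, "", 1))
  top4 <- utils::head(top_models, 4)
  combos8 <- cmfs_combinations(models = top4, selectors = pruned$selectors)
  t4 <- rss_cv(combined, combos8, n_iter = n_iter,
               seed = derive_seed(seed, 41))
  r4 <- rank_combinations(t4)

  structure(list(
    test1 = list(straight = t1_s, turn = t1_t, ranks_straight = r1_s,
                 ranks_turn = r1_t),
    pruned = pruned,
    test2 = list(straight = t2_s, turn = t2_t, ranks_straight = r2_s,
                 ranks_turn = r2_t, best_straight = best_s,
                 best_turn = best_t),
    welch = welch,
    test3 = t3,
    test4 = list(summary = t4, ranks = r4, best = rownames(r4)[1]),
    n_iter = n_iter, seed = seed
  ), class = "protocol_report")
}
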