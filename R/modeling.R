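#' Min-max normalization learned on the training rows
#'
#' Each feature is mapped to `(y - y_min) / (y_max - y_min)` with the
#' extremes taken over the training set only, so the training rows land in
#' `[0, 1]` and test rows may fall outside (they are deliberately not
#' clamped). A feature constant on the training set maps to 0.
#'
#' @param x Numeric training matrix (participants x features).
#' @return A `normalizer`: list with `y_min`, `y_max` per feature.
#' @export
fit_normalizer <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0) stop("empty training matrix",
                                          call. = FALSE)
  structure(list(y_min = apply(x, 2, min), y_max = apply(x, 2, max),
                 features = colnames(x)),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param np A `normalizer` from [fit_normalizer()].
#' @param rows Numeric matrix with the same feature columns.
#' @export
apply_normalizer <- function(np, rows) {
  stopifnot(inherits(np, "normalizer"))
  if (!is.null(np$features)) {
    missing <- setdiff(np$features, colnames(rows))
    if (length(missing))
      stop("unknown feature(s) at apply time: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    rows <- rows[, np$features, drop = FALSE]
  }
  rng <- np$y_max - np$y_min
  out <- sweep(rows, 2, np$y_min)
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

# vectorized two-class one-way ANOVA F statistic and p-value per column
anova_f <- function(x, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("training labels must contain two classes",
                                 call. = FALSE)
  n <- nrow(x)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((x[g1, , drop = FALSE] -
                    matrix(m1, n1, ncol(x), byrow = TRUE))^2) +
    colSums((x[!g1, , drop = FALSE] -
               matrix(m2, n2, ncol(x), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb == 0] <- 0        # constant feature: no signal
  f[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  list(f = f, p = p)
}

#' Feature selection on training data
#'
#' Three selectors are available, all operating on the (normalized) training
#' rows only:
#' \describe{
#'   \item{S5B}{select-k-best by two-class ANOVA F statistic (k = 5 by
#'     default).}
#'   \item{SEL}{union of a false-positive-rate filter (raw ANOVA p < alpha)
#'     and a false-discovery-rate filter (Benjamini-Hochberg adjusted
#'     p < alpha), duplicates removed, ordered by p-value. If the union is
#'     empty the single best-p feature is returned.}
#'   \item{RFE}{recursive feature elimination driven by random-forest
#'     impurity importances, down to k features. Each round refits the
#'     forest and drops the least important 10% of the surviving features
#'     (at least one), switching to one-at-a-time elimination for the last
#'     30; the geometric schedule keeps per-call cost bounded so RFE remains
#'     usable inside per-iteration-selection cross-validation.}
#' }
#'
#' @param method `"S5B"`, `"SEL"`, or `"RFE"`.
#' @param x Training matrix (participants x features, named columns).
#' @param labels Factor of training labels (two classes).
#' @param k Target size for S5B and RFE, default 5.
#' @param alpha Significance level for SEL, default 0.05.
#' @param seed Integer seed (RFE's forests).
#' @param rfe_ntree Trees per forest during RFE's elimination rounds (the
#'   final classifiers always use their own `n_trees`).
#' @return Ordered character vector of selected feature names.
#' @export
select_features <- function(method = c("S5B", "SEL", "RFE"), x, labels,
                            k = 5, alpha = 0.05, seed = 1, rfe_ntree = 50) {
  method <- match.arg(method)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("training labels must contain two classes",
                                 call. = FALSE)
  if (method %in% c("S5B", "SEL")) {
    av <- anova_f(x, labels)
    if (method == "S5B") {
      ord <- order(av$f, decreasing = TRUE)
      return(colnames(x)[ord[seq_len(min(k, ncol(x)))]])
    }
    keep <- av$p < alpha | stats::p.adjust(av$p, "BH") < alpha
    keep[!is.finite(av$p)] <- FALSE
    if (!any(keep)) keep[which.min(av$p)] <- TRUE   # never-empty fallback
    sel <- colnames(x)[keep]
    return(sel[order(av$p[keep])])
  }
  # RFE: geometric elimination (10% per round, single steps for the tail)
  set.seed(as.integer(seed))
  remaining <- colnames(x)
  while (length(remaining) > k) {
    fit <- randomForest::randomForest(x[, remaining, drop = FALSE], labels,
                                      ntree = rfe_ntree)
    imp <- randomForest::importance(fit)[, 1]
    n_drop <- if (length(remaining) > 30)
      max(1L, floor(0.1 * length(remaining))) else 1L
    n_drop <- min(n_drop, length(remaining) - k)
    remaining <- remaining[-order(imp)[seq_len(n_drop)]]
  }
  fit <- randomForest::randomForest(x[, remaining, drop = FALSE], labels,
                                    ntree = rfe_ntree)
  remaining[order(randomForest::importance(fit)[, 1], decreasing = TRUE)]
}

classifier_models <- c("kNN3", "kNN5", "SVM_linear", "SVM_poly3",
                       "SVM_poly5", "RF")

fit_predict <- function(model, train_x, train_y, test_x, seed = 1,
                        n_trees = 100) {
  model <- match.arg(model, classifier_models)
  set.seed(as.integer(seed))
  if (model %in% c("kNN3", "kNN5")) {
    k <- if (model == "kNN3") 3 else 5
    return(class::knn(train_x, test_x, train_y, k = k))
  }
  if (startsWith(model, "SVM")) {
    kernel <- if (model == "SVM_linear") "linear" else "polynomial"
    degree <- switch(model, SVM_poly3 = 3, SVM_poly5 = 5, 3)
    # kernel scale 1/(d * Var(X)), the "scale" convention; cost 1, coef0 0
    v <- stats::var(as.vector(train_x))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(train_x) * v) else
      1 / ncol(train_x)
    fit <- e1071::svm(train_x, train_y, kernel = kernel, degree = degree,
                      cost = 1, coef0 = 0, gamma = gamma, scale = FALSE)
    return(stats::predict(fit, test_x))
  }
  fit <- randomForest::randomForest(train_x, train_y, ntree = n_trees)
  stats::predict(fit, test_x)
}

#' Seven performance metrics from confusion counts
#'
#' Prospective fallers (PF) are the positive class. Any metric whose
#' denominator is zero is defined as 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (sum > 0).
#' @return Named numeric vector `ACC, SENS, SPEC, PPV, NPV, F1, MCC` plus the
#'   four counts.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn == 0)
    stop("counts must be non-negative with positive sum", call. = FALSE)
  safe <- function(num, den) if (den == 0) 0 else num / den
  acc <- (tp + tn) / (tp + fp + tn + fn)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp)
  npv <- safe(tn, tn + fn)
  f1 <- safe(2 * ppv * sens, ppv + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  c(ACC = acc, SENS = sens, SPEC = spec, PPV = ppv, NPV = npv, F1 = f1,
    MCC = mcc, TP = tp, FP = fp, TN = tn, FN = fn)
}

metric_names <- c("ACC", "SENS", "SPEC", "PPV", "NPV", "F1", "MCC")

#' Train one classifier on a split and evaluate it on the held-out rows
#'
#' Normalization parameters and the selected feature list must be derived
#' from the training rows only; this function fits the min-max normalizer on
#' the training rows of the selected columns, applies it to both sides, fits
#' the classifier, and scores the predictions with PF as the positive class.
#'
#' @param model One of `kNN3, kNN5, SVM_linear, SVM_poly3, SVM_poly5, RF`.
#' @param train,test `feature_matrix` objects (or lists with `x`, `labels`).
#' @param selected Character vector of feature names chosen on `train`.
#' @param seed Integer seed (random forest and tie-breaking).
#' @param n_trees Trees for the random forest, default 100.
#' @return The named metric vector of [metrics_from_counts()].
#' @export
train_and_evaluate <- function(model, train, test, selected, seed = 1,
                               n_trees = 100) {
  if (!length(selected)) stop("empty selected feature list", call. = FALSE)
  missing <- setdiff(selected, colnames(test$x))
  if (length(missing)) stop("test matrix lacks feature(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  np <- fit_normalizer(train$x[, selected, drop = FALSE])
  trx <- apply_normalizer(np, train$x[, selected, drop = FALSE])
  tex <- apply_normalizer(np, test$x[, selected, drop = FALSE])
  pred <- fit_predict(model, trx, train$labels, tex, seed = seed,
                      n_trees = n_trees)
  truth <- test$labels
  metrics_from_counts(tp = sum(pred == "PF" & truth == "PF"),
                      fp = sum(pred == "PF" & truth == "NF"),
                      tn = sum(pred == "NF" & truth == "NF"),
                      fn = sum(pred == "NF" & truth == "PF"))
}
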