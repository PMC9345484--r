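## Modeling: repeated stratified-split evaluation of logistic regression,
## k-nearest neighbours and random forest (AUC), random hyperparameter
## search with stratified cross-validation, permutation importance, and
## one-sample t-tests of importances against the overall mean.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores numeric scores, higher = more positive.
#' @param y binary labels (see [random_forest()] for the convention).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  yb <- binarize_labels(y)
  npos <- sum(yb == 1L); nneg <- sum(yb == 0L)
  if (npos == 0L || nneg == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[yb == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified train/test split
#'
#' Samples `train_frac` of each class into the training set (rounded, but
#' always leaving at least one observation of each class on each side), so
#' label proportions are preserved within one row.
#'
#' @param y labels.
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_frac = 0.8, seed = 1L) {
  yb <- binarize_labels(y)
  if (any(table(yb) < 2L))
    stop("each class needs at least 2 observations to split")
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(yb)) {
      idx <- which(yb == cl)
      n_tr <- min(max(round(train_frac * length(idx)), 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(yb), train))
  })
}

## stratified k-fold assignment (round-robin within class after shuffling)
stratified_folds <- function(y, k, seed = 1L) {
  yb <- binarize_labels(y)
  with_seed(seed, {
    fold <- integer(length(yb))
    for (cl in unique(yb)) {
      idx <- sample(which(yb == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit one of the three pre-selection classifiers
#'
#' `"logistic"` is an unpenalized binomial GLM, `"knn"` a k-nearest
#' neighbour vote (k = 5), `"rf"` the package's [random_forest()] with its
#' pinned defaults. Fit randomness (bootstrap samples) is controlled by the
#' caller's RNG state.
#'
#' @param model `"logistic"`, `"knn"` or `"rf"`.
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param params named list of overrides passed to the model.
#' @return fitted model of class `oc_classifier`.
#' @export
fit_classifier <- function(model = c("logistic", "knn", "rf"), X, y,
                           params = list()) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  yb <- binarize_labels(y)
  fit <- switch(model,
    logistic = {
      df <- data.frame(.y = yb, X, check.names = TRUE)
      suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
    },
    knn = list(X = X, y = yb, k = min(params$k %||% 5L, nrow(X))),
    rf = do.call(random_forest,
                 c(list(X = X, y = yb), params)))
  structure(list(model = model, fit = fit, cols = colnames(X)),
            class = "oc_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param object fitted `oc_classifier`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @rdname fit_classifier
#' @export
predict.oc_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$cols
  switch(object$model,
    logistic = {
      df <- data.frame(newdata, check.names = TRUE)
      suppressWarnings(as.numeric(predict(object$fit, df,
                                          type = "response")))
    },
    knn = {
      pred <- FNN::knn(object$fit$X, newdata, factor(object$fit$y),
                       k = object$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    rf = predict(object$fit, newdata))
}

#' Model pre-selection by repeated stratified splits
#'
#' Each model is evaluated on `n_runs` fresh stratified 80/20 splits (the
#' same splits for all models, for variance reduction) with its default
#' parameters; the holdout AUC of each run and per-model means/SDs are
#' returned.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param models character vector of model names (see [fit_classifier()]).
#' @param n_runs number of repeated splits (default 50).
#' @param train_frac training fraction.
#' @param seed master seed; split `i` uses `seed + i`, model fits use
#'   derived offsets.
#' @param rf_params,knn_params parameter overrides.
#' @return object of class `oc_model_report`: list with `auc` (runs x
#'   models matrix) and `summary` (model, mean_auc, sd_auc).
#' @export
model_preselection <- function(X, y, models = c("logistic", "knn", "rf"),
                               n_runs = 50L, train_frac = 0.8, seed = 1L,
                               rf_params = list(), knn_params = list()) {
  X <- as.matrix(X)
  yb <- binarize_labels(y)
  if (length(unique(yb)) < 2L) stop("both labels must be present")
  auc <- matrix(NA_real_, n_runs, length(models),
                dimnames = list(NULL, models))
  for (run in seq_len(n_runs)) {
    sp <- stratified_split(yb, train_frac, seed + run)
    for (m in models) {
      params <- switch(m, rf = rf_params, knn = knn_params, list())
      fit <- with_seed(seed + 1000L * match(m, models) + run,
                       fit_classifier(m, X[sp$train, , drop = FALSE],
                                      yb[sp$train], params))
      auc[run, m] <- auc_score(predict(fit, X[sp$test, , drop = FALSE]),
                               yb[sp$test])
    }
  }
  summary <- data.frame(model = models,
                        mean_auc = colMeans(auc),
                        sd_auc = apply(auc, 2, sd), row.names = NULL)
  structure(list(auc = auc, summary = summary), class = "oc_model_report")
}

#' @export
print.oc_model_report <- function(x, ...) {
  cat("<oc_model_report>", nrow(x$auc), "runs\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Random hyperparameter search for the random forest
#'
#' Per run: one stratified 80/20 split; `n_candidates` hyperparameter
#' combinations sampled uniformly (number of trees from 10-200 step 1;
#' maximum depth from 1-30 plus "unlimited", each of the 31 options with
#' probability 1/31); each candidate scored by mean AUC over `n_folds`
#' stratified folds of the training set; the best candidate is refit on the
#' full training set and scored on the holdout. Repeated `n_runs` times with
#' derived seeds; means and SDs over runs are reported together with a
#' ranked table of the top candidates.
#'
#' @inheritParams model_preselection
#' @param n_candidates candidate combinations per run (default 500).
#' @param n_folds cross-validation folds (default 5).
#' @param keep_top number of ranked candidates retained per run.
#' @return object of class `oc_search_report`: `per_run` (chosen candidate
#'   and AUCs per run), `summary`, and `top_table` (per rank: mean CV AUC,
#'   mean trees, mean finite depth, fraction unlimited).
#' @export
random_search_rf <- function(X, y, n_candidates = 500L, n_runs = 50L,
                             n_folds = 5L, train_frac = 0.8, seed = 1L,
                             keep_top = 3L) {
  if (n_candidates < 1L) stop("`n_candidates` must be at least 1")
  X <- as.matrix(X)
  yb <- binarize_labels(y)
  per_run <- vector("list", n_runs)
  ranked <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    sp <- stratified_split(yb, train_frac, seed + run)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- yb[sp$train]
    cand <- with_seed(seed + 10000L + run, data.frame(
      n_trees = sample(10:200, n_candidates, replace = TRUE),
      max_depth = sample(0:30, n_candidates, replace = TRUE))) # 0 = unlimited
    fold <- stratified_folds(ytr, n_folds, seed + 20000L + run)
    cv <- numeric(n_candidates)
    for (ci in seq_len(n_candidates)) {
      fa <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit <- with_seed(seed + 30000L + run * 100L + ci * 7L + f,
          random_forest(Xtr[tr, , drop = FALSE], ytr[tr],
                        n_trees = cand$n_trees[ci],
                        max_depth = cand$max_depth[ci]))
        fa[f] <- auc_score(predict(fit, Xtr[!tr, , drop = FALSE]), ytr[!tr])
      }
      cv[ci] <- mean(fa)
    }
    best <- which.max(cv)
    fit <- with_seed(seed + 40000L + run,
                     random_forest(Xtr, ytr, n_trees = cand$n_trees[best],
                                   max_depth = cand$max_depth[best]))
    test_auc <- auc_score(predict(fit, X[sp$test, , drop = FALSE]),
                          yb[sp$test])
    per_run[[run]] <- data.frame(run = run, n_trees = cand$n_trees[best],
                                 max_depth = cand$max_depth[best],
                                 cv_auc = cv[best], test_auc = test_auc)
    ord <- order(-cv)[seq_len(min(keep_top, n_candidates))]
    ranked[[run]] <- data.frame(run = run, rank = seq_along(ord),
                                n_trees = cand$n_trees[ord],
                                max_depth = cand$max_depth[ord],
                                cv_auc = cv[ord])
  }
  per_run <- do.call(rbind, per_run)
  ranked <- do.call(rbind, ranked)
  top <- do.call(rbind, lapply(split(ranked, ranked$rank), function(d) {
    fin <- d$max_depth > 0
    data.frame(rank = d$rank[1], mean_cv_auc = mean(d$cv_auc),
               mean_n_trees = mean(d$n_trees),
               mean_depth_finite = if (any(fin)) mean(d$max_depth[fin])
                                   else NA_real_,
               frac_unlimited = mean(!fin))
  }))
  summary <- data.frame(mean_cv_auc = mean(per_run$cv_auc),
                        sd_cv_auc = sd(per_run$cv_auc),
                        mean_test_auc = mean(per_run$test_auc),
                        sd_test_auc = sd(per_run$test_auc))
  structure(list(per_run = per_run, ranked = ranked, top_table = top,
                 summary = summary), class = "oc_search_report")
}

#' @export
print.oc_search_report <- function(x, ...) {
  cat("<oc_search_report>", nrow(x$per_run), "runs\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Permutation importance on a holdout set
#'
#' The importance of a feature is the mean drop in holdout AUC over
#' `n_repeats` independent permutations of that feature's column. Each
#' permutation uses a derived seed (`seed + (j - 1) * n_repeats + r - 1` for
#' feature `j`, repeat `r`), so importances are exactly reproducible.
#'
#' @param fit fitted model (`oc_classifier`, `oc_rf`, or anything with a
#'   `predict` method returning positive-class scores).
#' @param X holdout feature matrix (>= 2 rows, both classes present).
#' @param y holdout labels.
#' @param n_repeats permutations per feature (default 10).
#' @param seed base seed for the derived permutation seeds.
#' @return named numeric vector of importances with attributes `base_auc`
#'   and `repeats` (features x repeats AUC-drop matrix).
#' @export
permutation_importance <- function(fit, X, y, n_repeats = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("holdout must contain at least 2 rows")
  yb <- binarize_labels(y)
  base <- auc_score(predict(fit, X), yb)
  p <- ncol(X)
  drops <- matrix(NA_real_, p, n_repeats)
  for (j in seq_len(p)) {
    for (r in seq_len(n_repeats)) {
      perm <- with_seed(seed + (j - 1L) * n_repeats + r - 1L,
                        sample(nrow(X)))
      Xp <- X
      Xp[, j] <- X[perm, j]
      drops[j, r] <- base - auc_score(predict(fit, Xp), yb)
    }
  }
  structure(stats::setNames(rowMeans(drops), colnames(X)),
            base_auc = base, repeats = drops)
}

#' t-tests of per-feature importances against the overall mean
#'
#' The grand mean is the mean of all features' importances over all runs;
#' each feature's run values are compared to it with a two-sided one-sample
#' t-test. Significance requires `p < alpha` (strict). A feature with zero
#' variance across runs gets `p = 0` if its mean differs from the grand
#' mean and `p = 1` otherwise (with a message).
#'
#' @param importances runs x features numeric matrix.
#' @param alpha significance level (default 0.05).
#' @return data frame of class `oc_importance_report`: `feature`,
#'   `mean_importance`, `ci_lo`, `ci_hi` (95 percent), `t`, `p`,
#'   `significant`, `direction` (`"above"`/`"below"` the grand mean), plus
#'   attribute `grand_mean`.
#' @export
importance_t_tests <- function(importances, alpha = 0.05) {
  imp <- as.matrix(importances)
  if (nrow(imp) < 2L) stop("need at least 2 runs")
  grand <- mean(imp)
  rows <- lapply(seq_len(ncol(imp)), function(j) {
    v <- imp[, j]
    if (sd(v) == 0) {
      message("zero importance variance for feature ", j)
      pv <- if (mean(v) != grand) 0 else 1
      tt <- if (mean(v) != grand) sign(mean(v) - grand) * Inf else 0
      ci <- c(mean(v), mean(v))
    } else {
      ht <- t.test(v, mu = grand)
      pv <- ht$p.value; tt <- unname(ht$statistic); ci <- ht$conf.int
    }
    data.frame(feature = colnames(imp)[j] %||% paste0("f", j),
               mean_importance = mean(v), ci_lo = ci[1], ci_hi = ci[2],
               t = tt, p = pv, significant = pv < alpha,
               direction = if (mean(v) >= grand) "above" else "below")
  })
  out <- do.call(rbind, rows)
  attr(out, "grand_mean") <- grand
  class(out) <- c("oc_importance_report", "data.frame")
  out
}

#' Linear and polynomial regression of heart rate on features
#'
#' Ordinary least squares of per-chunk heart rate on the feature columns
#' (train rows), plus a second model adding the square of every column (no
#' interaction terms). R-squared is evaluated on the held-out test rows and
#' may be negative out of sample.
#'
#' @param X feature matrix.
#' @param hr per-chunk heart rate, bpm, aligned with the rows of `X`.
#' @param train_frac training fraction (default 0.8; plain random split --
#'   the outcome is continuous).
#' @param seed split seed.
#' @return data frame with `model` (`"linear"`, `"polynomial"`) and `r2`.
#' @export
fit_regressions <- function(X, hr, train_frac = 0.8, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(hr))
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows to split into train and test")
  n_tr <- min(max(2L, round(train_frac * n)), n - 1L)
  tr <- with_seed(seed, sort(sample(n, n_tr)))
  te <- setdiff(seq_len(n), tr)
  Xsq <- X^2
  colnames(Xsq) <- paste0(colnames(X) %||% paste0("V", seq_len(ncol(X))),
                          "_sq")
  r2 <- function(Xd) {
    df <- data.frame(.hr = hr, Xd, check.names = TRUE)
    fit <- suppressWarnings(lm(.hr ~ ., data = df[tr, , drop = FALSE]))
    pred <- suppressWarnings(predict(fit, df[te, , drop = FALSE]))
    1 - sum((hr[te] - pred)^2) / sum((hr[te] - mean(hr[te]))^2)
  }
  data.frame(model = c("linear", "polynomial"),
             r2 = c(r2(X), r2(cbind(X, Xsq))))
}
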