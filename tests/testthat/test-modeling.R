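## Modeling: AUC, splits, regressions, pre-selection, search, permutation
## importance, importance t-tests.

test_that("AUC matches hand-computed values including ties", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("stratified splits preserve class proportions within one row and
           partition the data; folds balance classes", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(30:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    sp <- stratified_split(y, 0.8, seed)
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0)
    for (cl in 0:1) {
      expect_lte(abs(sum(y[sp$train] == cl) - 0.8 * sum(y == cl)), 1)
    }
    fold <- oculocardiac:::stratified_folds(y, 5, seed)
    tab <- table(fold, y)
    expect_lte(max(tab[, 1]) - min(tab[, 1]), 1)
    expect_lte(max(tab[, 2]) - min(tab[, 2]), 1)
  }
})

test_that("regressions: exact linear fit gives test R2 = 1, a quadratic
           signal favours the polynomial model, and independent noise
           yields R2 near zero", {
  set.seed(7)
  X <- cbind(a = rnorm(120), b = rnorm(120))
  r <- fit_regressions(X, 3 * X[, "a"] + 5, seed = 1)
  expect_equal(r$r2[r$model == "linear"], 1, tolerance = 1e-9)

  hrq <- X[, "a"]^2 + rnorm(120, 0, 0.05)
  rq <- fit_regressions(X, hrq, seed = 1)
  expect_gt(rq$r2[rq$model == "polynomial"],
            rq$r2[rq$model == "linear"])

  null_r2 <- vapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(200 * 12), 200)
    fit_regressions(Xn, rnorm(200), seed = s)$r2[1]
  }, numeric(1))
  expect_lte(mean(null_r2), 0.05)
})

test_that("pre-selection: perfectly separable data is classified at AUC
           about 1 by all three models", {
  set.seed(1)
  y <- rep(c("low", "high"), each = 40)
  X <- cbind(sig = ifelse(y == "high", 1, -1) + rnorm(80, 0, 0.05),
             junk = rnorm(80))
  rep <- model_preselection(X, y, n_runs = 10, seed = 3)
  expect_true(all(rep$summary$mean_auc > 0.99))
  expect_equal(dim(rep$auc), c(10L, 3L))
})

test_that("pre-selection on permuted labels sits near chance", {
  set.seed(2)
  X <- matrix(rnorm(150 * 6), 150)
  y <- sample(rep(c("low", "high"), c(70, 80)))
  rep <- model_preselection(X, y, n_runs = 20, seed = 5)
  expect_true(all(rep$summary$mean_auc > 0.38 &
                    rep$summary$mean_auc < 0.62))
})

test_that("random search: candidate bounds honoured, reruns deterministic,
           and no optimism leak on null data", {
  set.seed(3)
  X <- matrix(rnorm(90 * 5), 90)
  y <- rep(c("low", "high"), length.out = 90)
  s1 <- random_search_rf(X, y, n_candidates = 12, n_runs = 3, seed = 4)
  s2 <- random_search_rf(X, y, n_candidates = 12, n_runs = 3, seed = 4)
  expect_identical(s1$per_run, s2$per_run)
  expect_true(all(s1$ranked$n_trees >= 10 & s1$ranked$n_trees <= 200))
  expect_true(all(s1$ranked$max_depth >= 0 & s1$ranked$max_depth <= 30))
  expect_equal(nrow(s1$top_table), 3L)
  expect_error(random_search_rf(X, y, n_candidates = 0), "at least 1")

  ## depth sampler covers 1..30 plus unlimited (0), each ~1/31
  cand <- with_seed_test(9, sample(0:30, 5000, replace = TRUE))
  expect_setequal(sort(unique(cand)), 0:30)
  expect_equal(mean(cand == 0), 1 / 31, tolerance = 0.3)

  ## null data: CV-selected candidates do not inflate the holdout AUC
  hold <- vapply(1:10, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(300 * 6), 300)
    yn <- rep(c("low", "high"), length.out = 300)
    random_search_rf(Xn, yn, n_candidates = 40, n_runs = 1,
                     seed = 100 + s)$per_run$test_auc
  }, numeric(1))
  expect_gt(mean(hold), 0.44)
  expect_lt(mean(hold), 0.56)
})

test_that("permutation importance equals a seed-matched manual shuffle,
           is 0 for constant columns, and isolates a single predictor", {
  set.seed(4)
  y <- rep(0:1, each = 30)
  X <- cbind(sig = y + rnorm(60, 0, 0.1), const = rep(2, 60),
             junk = rnorm(60))
  fit <- with_seed_test(5, random_forest(X, y))
  imp <- permutation_importance(fit, X, y, n_repeats = 4, seed = 21)

  ## oracle: recompute the drops with manually shuffled columns
  base <- auc_score(predict(fit, X), y)
  for (j in 1:3) {
    drops <- vapply(1:4, function(r) {
      perm <- with_seed_test(21 + (j - 1) * 4 + r - 1, sample(60))
      Xp <- X; Xp[, j] <- X[perm, j]
      base - auc_score(predict(fit, Xp), y)
    }, numeric(1))
    expect_equal(unname(imp[j]), mean(drops), tolerance = 1e-12)
  }
  expect_identical(unname(imp["const"]), 0)
  expect_gt(imp["sig"], 0.3)
  expect_lt(abs(imp["junk"]), 0.05)
  expect_error(permutation_importance(fit, X[1, , drop = FALSE], y[1]),
               "at least 2")
})

test_that("importance t-tests: identical importances give no significance,
           a shifted feature is detected, zero-variance rules apply", {
  flat <- matrix(0.1, nrow = 10, ncol = 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  rep0 <- suppressMessages(importance_t_tests(flat))
  expect_false(any(rep0$significant))

  set.seed(6)
  imp <- matrix(rnorm(50 * 4, 0.05, 0.002), 50,
                dimnames = list(NULL, paste0("f", 1:4)))
  imp[, 2] <- imp[, 2] + 0.05
  rep1 <- importance_t_tests(imp)
  expect_true(rep1$significant[2])
  expect_equal(rep1$direction[2], "above")
  expect_true(all(rep1$significant == (rep1$p < 0.05)))
  expect_true(all(rep1$ci_lo <= rep1$mean_importance &
                    rep1$mean_importance <= rep1$ci_hi))

  ## zero variance, mean different from the grand mean -> p = 0
  zv <- cbind(a = rep(0.2, 8), b = rep(0.4, 8), c = rnorm(8, 0.3, 0.01))
  repz <- suppressMessages(importance_t_tests(zv))
  expect_equal(repz$p[repz$feature == "a"], 0)
  expect_error(importance_t_tests(imp[1, , drop = FALSE]), "at least 2")
})

test_that("classifier wrapper: knn and logistic produce usable scores on a
           known geometry", {
  set.seed(8)
  y <- rep(c("low", "high"), each = 50)
  X <- cbind(x1 = ifelse(y == "high", 2, -2) + rnorm(100, 0, 0.4))
  for (m in c("logistic", "knn")) {
    fit <- fit_classifier(m, X, y)
    expect_gt(auc_score(predict(fit, X), y), 0.97)
  }
})
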