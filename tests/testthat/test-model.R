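test_that("F1 follows the printed formula and the harmonic-mean identity", {
  expect_equal(f1_score(2, 1, 1), 2 / 3)
  expect_equal(f1_score(5, 0, 0), 1)
  f0 <- f1_score(0, 0, 0)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "degenerate"))

  set.seed(10)
  for (i in 1:100) {
    tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(f1_score(tp, fp, fn), 2 * prec * rec / (prec + rec),
                 tolerance = 1e-12)
  }
  expect_error(f1_score(-1, 0, 0), "nonnegative")
})

test_that("Cohen's kappa matches the textbook formula", {
  expect_equal(cohen_kappa(c(tp = 10, fp = 0, fn = 0, tn = 30)), 1)
  # marginally independent table: agreement exactly at chance
  expect_equal(cohen_kappa(c(tp = 8, fp = 12, fn = 32, tn = 48)), 0)
  # pe = 1: all one class on both sides
  expect_equal(cohen_kappa(c(tp = 0, fp = 0, fn = 0, tn = 25)), 0)

  set.seed(20)
  for (i in 1:100) {
    cc <- setNames(sample(0:40, 4, replace = TRUE), c("tp", "fp", "fn", "tn"))
    if (sum(cc) == 0) next
    n <- sum(cc)
    po <- (cc["tp"] + cc["tn"]) / n
    pe <- ((cc["tp"] + cc["fp"]) * (cc["tp"] + cc["fn"]) +
             (cc["fn"] + cc["tn"]) * (cc["fp"] + cc["tn"])) / n^2
    want <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
    expect_equal(cohen_kappa(cc), unname(want), tolerance = 1e-12)
    expect_gte(cohen_kappa(cc), -1)
    expect_lte(cohen_kappa(cc), 1)
  }
})

test_that("max_features fraction maps to the per-split candidate count", {
  expect_equal(mtry_from_fraction(rf_params(max_features = 0.1), 924), 92L)
  expect_equal(mtry_from_fraction(rf_params(max_features = 1), 10), 10L)
  expect_equal(mtry_from_fraction(rf_params(max_features = 0.01), 50), 1L)
})

test_that("leave-one-patient-out folds partition the rows by patient", {
  set.seed(31)
  fm <- make_feature_matrix(matrix(rnorm(60 * 5), 60),
                            label = rep(c("normal", "prefog"), 30),
                            patient_id = rep(sprintf("P%02d", 1:6), each = 10))
  folds <- lopo_split(fm)
  expect_length(folds, 6)
  test_union <- integer(0)
  for (f in folds) {
    expect_false(any(f$train & f$test))
    expect_true(all(f$train | f$test))
    expect_length(unique(fm$patient_id[f$test]), 1)
    test_union <- c(test_union, which(f$test))
  }
  expect_setequal(test_union, 1:60)
  expect_equal(length(test_union), 60)

  one <- make_feature_matrix(matrix(rnorm(10), 5), rep("normal", 5), rep("P", 5))
  expect_error(lopo_split(one), ">= 2 patients")
})

test_that("a separable fixture is classified perfectly in every fold", {
  set.seed(41)
  n <- 240
  lab <- rep(c("normal", "prefog"), n / 2)
  X <- matrix(rnorm(n * 20), n) + ifelse(lab == "prefog", 5, 0)
  fm <- make_feature_matrix(X, lab, rep(sprintf("P%d", 1:3), each = n / 3))
  folds <- train_and_eval(fm, rf_params(n_estimators = 100, seed = 2))
  expect_length(folds, 3)
  for (f in folds) {
    expect_equal(f$F1, 1)
    expect_equal(f$kappa, 1)
    expect_equal(sum(f$counts), sum(fm$patient_id == f$patient))
  }
  agg <- pool_fold_metrics(folds)
  expect_equal(agg$F1, 1)
  expect_equal(agg$kappa, 1)
})

test_that("fold metrics are deterministic under a fixed seed", {
  set.seed(52)
  n <- 120
  lab <- sample(c("normal", "prefog"), n, TRUE)
  X <- matrix(rnorm(n * 15), n) + ifelse(lab == "prefog", 0.8, 0)
  fm <- make_feature_matrix(X, lab, rep(c("Pa", "Pb", "Pc"), each = 40))
  p <- rf_params(n_estimators = 80, seed = 7)
  a <- pool_fold_metrics(train_and_eval(fm, p))
  b <- pool_fold_metrics(train_and_eval(fm, p))
  expect_identical(a, b)
})

test_that("permuted labels give chance-level kappa", {
  set.seed(63)
  n <- 180
  X <- matrix(rnorm(n * 12), n)
  base_lab <- rep(c("normal", "prefog"), c(120, 60))
  kk <- numeric(20)
  for (i in 1:20) {
    lab <- sample(base_lab)
    fm <- make_feature_matrix(X, lab, rep(c("Pa", "Pb", "Pc"), each = 60))
    kk[i] <- pool_fold_metrics(
      train_and_eval(fm, rf_params(n_estimators = 60, seed = i)))$kappa
  }
  expect_lt(abs(mean(kk)), 0.1)
})

test_that("top-K selection finds planted informative columns", {
  set.seed(74)
  n <- 300
  lab <- rep(c("normal", "prefog"), n / 2)
  X <- matrix(rnorm(n * 30), n)
  X[, c(2, 11, 25)] <- X[, c(2, 11, 25)] + ifelse(lab == "prefog", 4, 0)
  fm <- make_feature_matrix(X, lab, rep(sprintf("P%d", 1:3), each = 100))
  planted <- colnames(fm$X)[c(2, 11, 25)]

  sel <- topk_select(fm, rf_params(n_estimators = 100, seed = 3),
                     k_grid = c(3, 10, 30))
  expect_true(all(planted %in% sel$ranking[1:3]))
  expect_equal(sel$k, 3)            # ties broken toward smaller K
  expect_setequal(sel$selected, planted)
  expect_true(all(grepl("^F\\d\\d$", sel$base_feature_report)))
  expect_true(all(grepl("^F\\d\\d$", names(sel$base_feature_importance))))
})

test_that("selecting all features reproduces the unselected run", {
  set.seed(85)
  n <- 150
  lab <- sample(rep(c("normal", "prefog"), c(100, 50)))
  X <- matrix(rnorm(n * 10), n) + ifelse(lab == "prefog", 1, 0)
  fm <- make_feature_matrix(X, lab, rep(c("Pa", "Pb", "Pc"), each = 50))
  p <- rf_params(n_estimators = 60, seed = 9)
  sel <- topk_select(fm, p, k_grid = ncol(fm$X))
  agg <- pool_fold_metrics(train_and_eval(fm, p))
  expect_equal(sel$k, ncol(fm$X))
  expect_setequal(sel$selected, colnames(fm$X))
  expect_equal(sel$F1, agg$F1)
  expect_equal(sel$kappa, agg$kappa)
})

test_that("fold-honest feature ranking does not leak test labels", {
  # A deliberately leaky variant (ranking features on ALL rows, including the
  # held-out patient) must inflate apparent skill on label-permuted data
  # relative to the package's fold-honest top-K path.
  set.seed(96)
  n <- 120
  X <- matrix(rnorm(n * 200), n)
  honest <- numeric(8)
  leaky <- numeric(8)
  for (i in 1:8) {
    lab <- sample(rep(c("normal", "prefog"), c(80, 40)))
    fm <- make_feature_matrix(X, lab, rep(c("Pa", "Pb", "Pc"), each = 40))
    p <- rf_params(n_estimators = 60, seed = i)
    honest[i] <- topk_select(fm, p, k_grid = 5)$F1

    # leaky oracle coded here in the test: rank by |t| against ALL labels
    tt <- abs(apply(X, 2, function(col) {
      t.test(col[lab == "prefog"], col[lab == "normal"])$statistic
    }))
    cols <- order(tt, decreasing = TRUE)[1:5]
    leaky[i] <- pool_fold_metrics(
      train_and_eval(subset_cols_fm(fm, cols), p))$F1
  }
  expect_gt(mean(leaky), mean(honest))
})
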