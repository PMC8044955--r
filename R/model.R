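# Random-forest preFOG classifier under leave-one-patient-out
# cross-validation, window-based metrics, and top-K feature selection.

#' Random-forest hyperparameters
#'
#' Defaults are the study's optimized tuple (800, 0.1, 4, 4, 4).
#'
#' @param n_estimators number of trees.
#' @param max_features fraction in (0, 1\] of the feature columns offered at
#'   each split; the per-split candidate count is
#'   `floor(max_features * n_features)` (0.1 of 924 gives 92).
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param min_samples_leaf minimum samples per leaf.
#' @param seed integer seed.
#' @param class_weights optional named weights for `normal` / `prefog`
#'   (default unweighted).
#' @return an object of class `rf_params`.
#' @export
rf_params <- function(n_estimators = 800L, max_features = 0.1, max_depth = 4L,
                      min_samples_split = 4L, min_samples_leaf = 4L,
                      seed = 1L, class_weights = NULL) {
  if (!is_count(n_estimators)) stopf("n_estimators must be a positive integer")
  if (!is_number(max_features) || max_features <= 0 || max_features > 1) {
    stopf("max_features must lie in (0, 1]")
  }
  if (!is_count(max_depth)) stopf("max_depth must be a positive integer")
  if (!is_count(min_samples_split)) stopf("min_samples_split must be a positive integer")
  if (!is_count(min_samples_leaf)) stopf("min_samples_leaf must be a positive integer")
  structure(
    list(n_estimators = as.integer(n_estimators), max_features = max_features,
         max_depth = as.integer(max_depth),
         min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         seed = as.integer(seed), class_weights = class_weights),
    class = "rf_params"
  )
}

#' Per-split feature-candidate count implied by `max_features`
#' @param p an [rf_params()] object.
#' @param n_features total number of feature columns.
#' @return integer `floor(max_features * n_features)`, at least 1.
#' @export
mtry_from_fraction <- function(p, n_features) {
  max(1L, as.integer(floor(p$max_features * n_features)))
}

#' Leave-one-patient-out folds
#'
#' @param fm a `feature_matrix`.
#' @return list of folds, each with `patient` and logical `train` / `test`
#'   masks partitioning the rows.
#' @export
lopo_split <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  pats <- unique(fm$patient_id)
  if (length(pats) < 2) stopf("leave-one-patient-out needs >= 2 patients")
  lapply(pats, function(p) {
    test <- fm$patient_id == p
    list(patient = p, train = !test, test = test)
  })
}

# Fit one random forest; x is the (already standardized) feature matrix.
fit_rf <- function(x, y, p, importance = "none") {
  ranger::ranger(
    x = x, y = factor(y, levels = c("normal", "prefog")),
    num.trees = p$n_estimators,
    mtry = mtry_from_fraction(p, ncol(x)),
    max.depth = p$max_depth,
    min.node.size = p$min_samples_split,   # minimal node size to split at
    min.bucket = p$min_samples_leaf,       # minimal terminal node size
    importance = importance,
    class.weights = if (is.null(p$class_weights)) NULL else
      p$class_weights[c("normal", "prefog")],
    seed = p$seed,
    num.threads = 1,
    verbose = FALSE
  )
}

confusion_counts <- function(truth, pred) {
  c(
    tp = sum(pred == "prefog" & truth == "prefog"),
    fp = sum(pred == "prefog" & truth == "normal"),
    fn = sum(pred == "normal" & truth == "prefog"),
    tn = sum(pred == "normal" & truth == "normal")
  )
}

#' Train and evaluate the classifier under leave-one-patient-out CV
#'
#' Per fold: the feature matrix is standardized on the training rows only,
#' a random forest is fitted on the training patients, the held-out patient's
#' windows are predicted, and the preFOG-class confusion counts, F1 and
#' Cohen's kappa are recorded. Deterministic given `p$seed`.
#'
#' @param fm a raw (unstandardized) `feature_matrix` with both classes.
#' @param p an [rf_params()] object.
#' @param feature_cols optional subset of feature columns to use.
#' @return list of `fold_result` objects (`patient`, `pred`, `counts`, `F1`,
#'   `kappa`, window table of the held-out patient). Folds whose training
#'   side has a single class are skipped with a message.
#' @export
train_and_eval <- function(fm, p = rf_params(), feature_cols = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(p, "rf_params"))
  if (!is.null(feature_cols)) fm <- subset_features(fm, feature_cols)
  folds <- lopo_split(fm)
  out <- list()
  for (f in folds) {
    ytr <- fm$label[f$train]
    if (length(unique(ytr)) < 2) {
      message(sprintf("fold %s skipped: training side has a single class", f$patient))
      next
    }
    sfm <- standardize(fm, f$train)
    pf <- p
    pf$seed <- derive_seed(p$seed, paste0("fold", f$patient))
    fit <- fit_rf(sfm$X[f$train, , drop = FALSE], ytr, pf)
    # tied tree votes are broken with R's RNG: scope it for determinism
    pred <- with_seed(derive_seed(pf$seed, "predict"), {
      as.character(predict(fit, data = sfm$X[f$test, , drop = FALSE],
                           num.threads = 1)$predictions)
    })
    truth <- fm$label[f$test]
    cc <- confusion_counts(truth, pred)
    out[[length(out) + 1]] <- structure(
      list(patient = f$patient, pred = pred, counts = cc,
           F1 = f1_score(cc["tp"], cc["fp"], cc["fn"]),
           kappa = cohen_kappa(cc),
           windows = fm$windows[f$test, , drop = FALSE]),
      class = "fold_result"
    )
  }
  out
}

#' Pool fold metrics
#'
#' Micro pooling sums the confusion counts over folds before computing F1 and
#' kappa (the default reported numbers); macro averages the per-fold metrics.
#'
#' @param folds list of `fold_result` objects.
#' @param method `"micro"` or `"macro"`.
#' @return list with `F1`, `kappa`, and the pooled `counts`.
#' @export
pool_fold_metrics <- function(folds, method = c("micro", "macro")) {
  method <- match.arg(method)
  if (!length(folds)) stopf("no folds to pool")
  counts <- Reduce(`+`, lapply(folds, `[[`, "counts"))
  if (method == "micro") {
    list(F1 = f1_score(counts["tp"], counts["fp"], counts["fn"]),
         kappa = cohen_kappa(counts), counts = counts)
  } else {
    list(F1 = mean(vapply(folds, `[[`, numeric(1), "F1")),
         kappa = mean(vapply(folds, `[[`, numeric(1), "kappa")),
         counts = counts)
  }
}

#' F1 score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FN + FP)`, the harmonic mean of precision and recall
#' for the positive (preFOG) class. When TP = FP = FN = 0 the score is
#' defined as 0 and flagged.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return F1 in \[0, 1\]; attribute `degenerate` when the all-zero rule fired.
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be nonnegative")
  denom <- 2 * tp + fn + fp
  if (denom == 0) return(structure(0, degenerate = TRUE))
  as.numeric(2 * tp / denom)
}

#' Cohen's kappa from a 2x2 confusion
#'
#' `(po - pe) / (1 - pe)` with observed agreement `po` and chance agreement
#' `pe` from the marginals; returns 0 when `pe = 1`.
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn` (or a 2x2 matrix
#'   in that layout).
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(counts) {
  if (is.matrix(counts)) {
    counts <- c(tp = counts[1, 1], fp = counts[1, 2], fn = counts[2, 1],
                tn = counts[2, 2])
  }
  n <- sum(counts)
  if (n <= 0) stopf("total count must be positive")
  po <- (counts[["tp"]] + counts[["tn"]]) / n
  p_pred_pos <- (counts[["tp"]] + counts[["fp"]]) / n
  p_true_pos <- (counts[["tp"]] + counts[["fn"]]) / n
  pe <- p_pred_pos * p_true_pos + (1 - p_pred_pos) * (1 - p_true_pos)
  if (abs(1 - pe) < 1e-15) return(0)
  as.numeric((po - pe) / (1 - pe))
}

#' Top-K feature selection
#'
#' Features are ranked by their mean random-forest impurity importance across
#' leave-one-patient-out training folds (never using held-out rows). For each
#' K in `k_grid` the LOPO evaluation is re-run on the top-K columns; the
#' winning subset maximizes mean micro F1, with ties broken by higher kappa
#' and then smaller K. Importances are also aggregated per base feature
#' (summed over sensors and channels sharing the `Fkk` suffix) for
#' compact reporting such as `{"F03", "F05", ...}`.
#'
#' @param fm a `feature_matrix`.
#' @param p an [rf_params()] object.
#' @param k_grid integer vector of subset sizes (each <= total features).
#' @return list with `selected` (winning column names), `k`, `F1`, `kappa`,
#'   `ranking` (all columns, best first), `base_feature_importance` (named,
#'   decreasing), `base_feature_report` (base ids of the winning subset), and
#'   the per-K `results` table.
#' @export
topk_select <- function(fm, p = rf_params(), k_grid) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(k_grid)) stopf("k_grid must not be empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1) || any(k_grid > ncol(fm$X))) {
    stopf("k_grid values must lie in [1, %d]", ncol(fm$X))
  }
  folds <- lopo_split(fm)
  folds <- Filter(function(f) length(unique(fm$label[f$train])) == 2, folds)
  if (!length(folds)) stopf("no fold has two training classes")
  imp <- numeric(ncol(fm$X))
  for (f in folds) {
    sfm <- standardize(fm, f$train)
    pf <- p
    pf$seed <- derive_seed(p$seed, paste0("imp", f$patient))
    fit <- fit_rf(sfm$X[f$train, , drop = FALSE], fm$label[f$train], pf,
                  importance = "impurity")
    imp <- imp + fit$variable.importance[colnames(fm$X)] / length(folds)
  }
  names(imp) <- colnames(fm$X)
  ranking <- names(sort(imp, decreasing = TRUE))

  res <- data.frame(k = k_grid, F1 = NA_real_, kappa = NA_real_)
  for (i in seq_along(k_grid)) {
    # canonical column order, so K = n_features reproduces the full run
    cols <- intersect(colnames(fm$X), ranking[seq_len(k_grid[i])])
    agg <- pool_fold_metrics(train_and_eval(fm, p, feature_cols = cols))
    res$F1[i] <- agg$F1
    res$kappa[i] <- agg$kappa
  }
  ord <- order(-res$F1, -res$kappa, res$k)
  best <- ord[1]
  selected <- intersect(colnames(fm$X), ranking[seq_len(res$k[best])])

  base <- sub("^.*_(F\\d\\d)$", "\\1", names(imp))
  base_imp <- sort(tapply(imp, base, sum), decreasing = TRUE)
  list(
    selected = selected,
    k = res$k[best],
    F1 = res$F1[best],
    kappa = res$kappa[best],
    ranking = ranking,
    base_feature_importance = base_imp,
    base_feature_report = sort(unique(sub("^.*_(F\\d\\d)$", "\\1", selected))),
    results = res
  )
}
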