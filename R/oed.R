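# Taguchi L16(4^3) orthogonal design: construction, balance verification,
# design execution, and main-effect / interaction / LogWorth analysis.

# Level-index array of the L16(4^3) orthogonal array of strength 2: columns
# are (window_size, step, prefog_duration); each pairwise level combination
# occurs exactly once.
L16_4_3_INDEX <- cbind(
  f1 = rep(1:4, each = 4),
  f2 = rep(1:4, times = 4),
  f3 = c(1, 2, 3, 4,
         2, 1, 4, 3,
         3, 4, 1, 2,
         4, 3, 2, 1)
)

#' Factor specification for the experimental design
#'
#' @param name factor name; the design factors of the study are
#'   `window_size`, `step` and `prefog_duration`.
#' @param levels distinct increasing positive integers (the L16(4^3) design
#'   requires exactly 4). The studied levels are window size
#'   \{128, 256, 400, 500\}, step \{5, 10, 20, 30\} and preFOG duration
#'   \{150, 250, 500, 600\} sampling points.
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stopf("factor name must be a non-empty string")
  }
  levels <- as.integer(levels)
  if (length(levels) < 2 || anyDuplicated(levels) || any(levels <= 0) ||
      is.unsorted(levels, strictly = TRUE)) {
    stopf("factor '%s' needs >= 2 distinct increasing positive levels", name)
  }
  structure(list(name = name, levels = levels), class = "factor_spec")
}

#' Default factor specifications of the study
#' @return list of three [factor_spec()] objects.
#' @export
default_factors <- function() {
  list(
    factor_spec("window_size", c(128L, 256L, 400L, 500L)),
    factor_spec("step", c(5L, 10L, 20L, 30L)),
    factor_spec("prefog_duration", c(150L, 250L, 500L, 600L))
  )
}

as_design_table <- function(runs, design_name) {
  structure(list(runs = runs, design_name = design_name), class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %s, %d runs\n", x$design_name, nrow(x$runs)))
  print(utils::head(x$runs, 4))
  invisible(x)
}

#' Build the L16(4^3) orthogonal design
#'
#' Sixteen runs T01...T16 over three 4-level factors, balanced so every level
#' of every factor appears exactly four times and every pairwise level
#' combination exactly once. With the study's levels, run T15 is
#' (500, 20, 250).
#'
#' @param factors list of exactly three [factor_spec()] objects in the order
#'   window_size, step, prefog_duration.
#' @return a `design_table` with columns `run_id` and one column per factor.
#' @export
build_l16_4_3 <- function(factors = default_factors()) {
  if (length(factors) != 3 || !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stopf("need exactly 3 factor_spec objects")
  }
  if (any(vapply(factors, function(f) length(f$levels), integer(1)) != 4)) {
    stopf("the L16(4^3) design needs exactly 4 levels per factor")
  }
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("factor names must be distinct")
  runs <- data.frame(run_id = sprintf("T%02d", 1:16))
  for (j in 1:3) runs[[nm[j]]] <- factors[[j]]$levels[L16_4_3_INDEX[, j]]
  as_design_table(runs, "L16(4^3)")
}

#' Full factorial design
#'
#' Cartesian product of the factor levels in deterministic lexicographic
#' order (first factor slowest).
#'
#' @param factors list of [factor_spec()] objects.
#' @return a `design_table`.
#' @export
full_factorial <- function(factors = default_factors()) {
  if (!length(factors)) stopf("need at least one factor")
  nm <- vapply(factors, `[[`, character(1), "name")
  grid <- rev(expand.grid(rev(lapply(factors, `[[`, "levels")),
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- nm
  runs <- cbind(data.frame(run_id = sprintf("T%02d", seq_len(nrow(grid)))), grid)
  as_design_table(runs, sprintf("full-%d^%d", length(factors[[1]]$levels),
                                length(factors)))
}

#' Verify orthogonal-array balance
#'
#' Checks (a) that each level of each factor appears equally often
#' (runs / 4 times for 4-level factors) and (b) that for every factor pair
#' each ordered level combination appears with equal frequency (exactly once
#' for the L16(4^3); the strength-2 orthogonal-array definition only
#' requires equal frequency, so a full factorial also passes).
#'
#' @param d a `design_table`.
#' @return an object of class `balance_report`: list with `pass` (overall),
#'   per-factor level counts, per-pair frequency checks, and the offending
#'   factors/pairs when a check fails.
#' @export
verify_orthogonality <- function(d) {
  stopifnot(inherits(d, "design_table"))
  runs <- d$runs
  fac <- setdiff(names(runs), "run_id")
  n <- nrow(runs)

  level_counts <- lapply(fac, function(f) table(runs[[f]]))
  names(level_counts) <- fac
  level_ok <- vapply(level_counts, function(tb) length(unique(as.integer(tb))) == 1,
                     logical(1))

  pairs <- if (length(fac) >= 2) utils::combn(fac, 2, simplify = FALSE) else list()
  pair_freq <- list()
  pair_ok <- logical(0)
  for (pr in pairs) {
    tb <- table(runs[[pr[1]]], runs[[pr[2]]])
    key <- paste(pr, collapse = ":")
    pair_freq[[key]] <- tb
    pair_ok[key] <- length(unique(as.integer(tb))) == 1
  }
  structure(
    list(
      pass = all(level_ok) && all(pair_ok),
      level_counts = level_counts,
      level_balanced = level_ok,
      pair_frequency = pair_freq,
      pair_balanced = pair_ok,
      failing_factors = names(level_ok)[!level_ok],
      failing_pairs = names(pair_ok)[!pair_ok]
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  if (length(x$failing_factors)) {
    cat("  unbalanced factor(s):", paste(x$failing_factors, collapse = ", "), "\n")
  }
  if (length(x$failing_pairs)) {
    cat("  unbalanced pair(s):", paste(x$failing_pairs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Execute a design over a cohort
#'
#' For every design run: segment and label the (already cleaned) recordings
#' with the run's (window size, step, preFOG duration), extract the feature
#' matrix, and train/evaluate the random forest under leave-one-patient-out
#' cross-validation with per-fold standardization. Window-based F1 (preFOG
#' positive class) and Cohen's kappa are pooled over folds (micro).
#'
#' @param d a `design_table`.
#' @param recordings named list of [imu_recording()] (>= 2 patients).
#' @param annotations named list of matching [event_annotation()].
#' @param rf_params an [rf_params()] object.
#' @param seeds integer vector; one replicate per seed (the random-forest
#'   seed varies across replicates).
#' @param preprocess apply [replace_outliers()] + [highpass_detrend()] first
#'   (done once, outside the run loop).
#' @param verbose print one line per run.
#' @return a `response_table` data frame with columns `run_id`, the factor
#'   levels, `replicate`, `seed`, `F1`, `kappa`, `n_windows`, `n_prefog`.
#'   Runs yielding no preFOG windows get `NA` metrics and a logged cause.
#' @export
run_design <- function(d, recordings, annotations, rf_params = rf_params(),
                       seeds = rf_params$seed, preprocess = TRUE,
                       verbose = FALSE) {
  stopifnot(inherits(d, "design_table"))
  if (length(recordings) < 2) stopf("need >= 2 patients for leave-one-patient-out")
  need <- c("window_size", "step", "prefog_duration")
  if (!all(need %in% names(d$runs))) {
    stopf("design must have factors %s", paste(need, collapse = ", "))
  }
  if (preprocess) recordings <- lapply(recordings, preprocess_recording)

  rows <- list()
  for (i in seq_len(nrow(d$runs))) {
    run <- d$runs[i, ]
    sp <- segmentation_params(run$window_size, run$step, run$prefog_duration)
    wsets <- lapply(names(recordings), function(pid) {
      segment_and_label(recordings[[pid]], annotations[[pid]], sp)
    })
    fm <- extract_matrix(wsets)
    n_prefog <- sum(fm$label == "prefog")
    for (r in seq_along(seeds)) {
      row <- data.frame(run$run_id, run$window_size, run$step,
                        run$prefog_duration, r, seeds[r],
                        stringsAsFactors = FALSE)
      names(row) <- c("run_id", need, "replicate", "seed")
      if (n_prefog == 0 || n_prefog == nrow(fm$X)) {
        message(sprintf("run %s: degenerate labels (%d/%d prefog); metrics recorded as missing",
                        run$run_id, n_prefog, nrow(fm$X)))
        row$F1 <- NA_real_
        row$kappa <- NA_real_
      } else {
        p <- rf_params
        p$seed <- derive_seed(seeds[r], paste0("run", run$run_id))
        folds <- train_and_eval(fm, p)
        agg <- pool_fold_metrics(folds)
        row$F1 <- agg$F1
        row$kappa <- agg$kappa
      }
      row$n_windows <- nrow(fm$X)
      row$n_prefog <- n_prefog
      rows[[length(rows) + 1]] <- row
    }
    if (verbose) {
      message(sprintf("run %s (%d, %d, %d): F1=%.3f kappa=%.3f [%d windows]",
                      run$run_id, run$window_size, run$step, run$prefog_duration,
                      rows[[length(rows)]]$F1, rows[[length(rows)]]$kappa,
                      nrow(fm$X)))
    }
  }
  resp <- do.call(rbind, rows)
  rownames(resp) <- NULL
  class(resp) <- c("response_table", "data.frame")
  resp
}

#' Main-effect, interaction and LogWorth analysis of a response table
#'
#' Fits a linear model of the chosen response on the design factors and the
#' requested two-factor interactions, and reports per-term p-values and
#' LogWorth = -log10(p). With a single replicate of the saturated L16 layout
#' the factors are coded numerically (centered level values) and each
#' requested interaction enters as a product term; with replicates (or when
#' no interaction is requested) the factors are treated as 4-level
#' categorical terms and ANOVA F-tests are reported. Per-level response
#' means (each over the runs at that level) are attached for main-effect
#' plots and for [select_best()].
#'
#' @param d a `design_table`.
#' @param r a `response_table` from [run_design()], or any data frame with a
#'   `run_id` column and the response column.
#' @param response `"F1"` or `"kappa"`.
#' @param interactions list of 2-element character vectors naming factor
#'   pairs, e.g. `list(c("window_size", "prefog_duration"))`. Three-factor
#'   interactions are rejected: higher-order interactions are assumed
#'   non-existent.
#' @return an object of class `effect_summary`: data frame with columns
#'   `term`, `estimate`, `p_value`, `logworth`, plus attributes
#'   `level_means` (per factor, named numeric of 4 means), `response`, and
#'   `coding` (`"numeric"` or `"categorical"`).
#' @export
effects_analysis <- function(d, r, response = c("F1", "kappa"),
                             interactions = list()) {
  stopifnot(inherits(d, "design_table"))
  response <- match.arg(response)
  fac <- setdiff(names(d$runs), "run_id")
  if (length(interactions)) {
    bad <- vapply(interactions, function(p) length(p) != 2 || !all(p %in% fac),
                  logical(1))
    if (any(bad)) {
      stopf("interactions must be pairs of design factors; higher-order interactions are assumed to be non-existent")
    }
  }
  dat <- merge(as.data.frame(r), d$runs[, c("run_id", fac)], by = "run_id",
               suffixes = c("", ".design"))
  for (f in fac) if (!f %in% names(dat)) dat[[f]] <- dat[[paste0(f, ".design")]]
  dat$y <- dat[[response]]
  if (anyNA(dat$y)) {
    warning(sprintf("%d run(s) with missing %s excluded from the effect fit",
                    sum(is.na(dat$y)), response))
    dat <- dat[!is.na(dat$y), , drop = FALSE]
  }
  if (!nrow(dat)) stopf("no usable responses")

  level_means <- lapply(fac, function(f) {
    v <- tapply(dat$y, factor(dat[[f]], levels = sort(unique(d$runs[[f]]))), mean)
    setNames(as.numeric(v), names(v))
  })
  names(level_means) <- fac

  replicated <- anyDuplicated(dat$run_id) > 0
  use_numeric <- length(interactions) > 0 && !replicated

  constant_y <- sd(dat$y) < 1e-14
  if (constant_y) {
    # a flat response carries no effect information: every term gets p = 1
    inames <- vapply(interactions, function(p) paste(p, collapse = "*"), character(1))
    term_names <- c(fac, inames)
    est <- rep(0, length(term_names))
    pv <- rep(1, length(term_names))
    coding <- if (use_numeric) "numeric" else "categorical"
  } else if (use_numeric) {
    # centered numeric coding: linear main effects + product interactions
    for (f in fac) dat[[paste0(".c_", f)]] <- dat[[f]] - mean(dat[[f]])
    terms <- paste0(".c_", fac)
    inames <- vapply(interactions, function(p) paste(p, collapse = "*"), character(1))
    for (k in seq_along(interactions)) {
      p <- interactions[[k]]
      dat[[paste0(".i_", k)]] <- dat[[paste0(".c_", p[1])]] * dat[[paste0(".c_", p[2])]]
      terms <- c(terms, paste0(".i_", k))
    }
    fit <- lm(stats::reformulate(terms, "y"), data = dat)
    sm <- summary(fit)$coefficients
    term_names <- c(fac, inames)
    rown <- c(paste0(".c_", fac), if (length(interactions)) paste0(".i_", seq_along(interactions)))
    est <- sm[rown, "Estimate"]
    pv <- sm[rown, "Pr(>|t|)"]
    coding <- "numeric"
  } else {
    for (f in fac) dat[[paste0(".f_", f)]] <- factor(dat[[f]])
    terms <- paste0(".f_", fac)
    inames <- character(0)
    if (length(interactions)) {
      inames <- vapply(interactions, function(p) paste(p, collapse = "*"), character(1))
      terms <- c(terms, vapply(interactions, function(p) {
        paste(paste0(".f_", p), collapse = ":")
      }, character(1)))
    }
    fit <- lm(stats::reformulate(terms, "y"), data = dat)
    av <- anova(fit)
    term_names <- c(fac, inames)
    rown <- terms
    est <- av[rown, "Sum Sq"]
    pv <- av[rown, "Pr(>F)"]
    coding <- "categorical"
  }
  pv <- as.numeric(pv)
  if (constant_y) pv[] <- 1
  pv[is.na(pv)] <- 1
  out <- data.frame(
    term = term_names,
    estimate = as.numeric(est),
    p_value = pv,
    logworth = -log10(pv),
    stringsAsFactors = FALSE
  )
  attr(out, "level_means") <- level_means
  attr(out, "response") <- response
  attr(out, "coding") <- coding
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Select the best level per factor from an effect summary
#'
#' Returns, per factor, the level maximizing the mean response. Ties are
#' broken deterministically toward the cheaper / more causal setting:
#' smaller window, larger step, smaller preFOG duration.
#'
#' @param e an `effect_summary` from [effects_analysis()].
#' @return a [segmentation_params()] with the selected levels.
#' @export
select_best <- function(e) {
  lm_ <- attr(e, "level_means")
  if (is.null(lm_) || !all(c("window_size", "step", "prefog_duration") %in% names(lm_))) {
    stopf("effect summary lacks per-level means for the three factors")
  }
  pick <- function(means, prefer_small) {
    if (anyNA(means)) stopf("missing level means")
    lev <- as.integer(names(means))
    ord <- order(if (prefer_small) lev else -lev)
    lev <- lev[ord]
    means <- means[ord]
    lev[which.max(means)]   # first max in preference order
  }
  segmentation_params(
    window_size = pick(lm_$window_size, prefer_small = TRUE),
    step = pick(lm_$step, prefer_small = FALSE),
    prefog_duration = pick(lm_$prefog_duration, prefer_small = TRUE)
  )
}
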