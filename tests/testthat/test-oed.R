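# Golden fixture: the 16-run L16(4^3) layout over the studied levels
# (window size, step, preFOG duration), rows T01..T16.
L16_GOLDEN <- data.frame(
  run_id = sprintf("T%02d", 1:16),
  window_size = rep(c(128L, 256L, 400L, 500L), each = 4),
  step = rep(c(5L, 10L, 20L, 30L), times = 4),
  prefog_duration = c(150L, 250L, 500L, 600L,
                      250L, 150L, 600L, 500L,
                      500L, 600L, 150L, 250L,
                      600L, 500L, 250L, 150L)
)

test_that("the generated L16(4^3) design reproduces the golden layout", {
  d <- build_l16_4_3()
  expect_equal(nrow(d$runs), 16)
  expect_equal(d$runs, L16_GOLDEN)
  expect_equal(unlist(d$runs[d$runs$run_id == "T15", -1], use.names = FALSE),
               c(500L, 20L, 250L))
  expect_equal(unlist(d$runs[d$runs$run_id == "T01", -1], use.names = FALSE),
               c(128L, 5L, 150L))
  expect_equal(unlist(d$runs[d$runs$run_id == "T08", -1], use.names = FALSE),
               c(256L, 30L, 500L))
  expect_equal(unlist(d$runs[d$runs$run_id == "T16", -1], use.names = FALSE),
               c(500L, 30L, 150L))
})

test_that("orthogonal-array balance: levels 4x each, pairs exactly once", {
  d <- build_l16_4_3()
  rep_ <- verify_orthogonality(d)
  expect_true(rep_$pass)
  for (f in c("window_size", "step", "prefog_duration")) {
    expect_equal(unname(as.integer(rep_$level_counts[[f]])), rep(4L, 4))
  }
  for (tb in rep_$pair_frequency) {
    expect_true(all(as.integer(tb) == 1L))
  }
})

test_that("a single-cell perturbation is detected with the offending pair", {
  d <- build_l16_4_3()
  d$runs$step[7] <- 5L    # was 20
  rep_ <- verify_orthogonality(d)
  expect_false(rep_$pass)
  expect_true(any(grepl("step", rep_$failing_pairs)))
})

test_that("a full factorial passes the equal-frequency balance check", {
  expect_true(verify_orthogonality(full_factorial())$pass)
})

test_that("full factorial enumerates the Cartesian product deterministically", {
  d <- full_factorial()
  expect_equal(nrow(d$runs), 64)
  expect_equal(nrow(unique(d$runs[, -1])), 64)
  expect_equal(d$runs$window_size[1:5], c(128L, 128L, 128L, 128L, 128L))

  d1 <- full_factorial(list(factor_spec("window_size", c(1L, 2L, 3L, 4L))))
  expect_equal(nrow(d1$runs), 4)
  d9 <- full_factorial(list(factor_spec("a", c(1L, 2L, 3L)),
                            factor_spec("b", c(4L, 5L, 6L))))
  expect_equal(nrow(d9$runs), 9)
})

test_that("a flat response yields p = 1 everywhere and the tie-break tuple", {
  d <- build_l16_4_3()
  r <- data.frame(run_id = d$runs$run_id, F1 = 0.5, kappa = 0.2)
  eff <- effects_analysis(d, r, "F1",
                          interactions = list(c("window_size", "prefog_duration")))
  expect_equal(eff$p_value, rep(1, 4))
  expect_equal(eff$logworth, rep(0, 4))
  best <- select_best(eff)
  expect_equal(best$window_size, 128L)   # smaller window preferred
  expect_equal(best$step, 30L)           # larger step preferred
  expect_equal(best$prefog_duration, 150L)
})

test_that("LogWorth is -log10(p) and monotone in significance", {
  set.seed(14)
  d <- build_l16_4_3()
  w <- d$runs$window_size
  r <- data.frame(run_id = d$runs$run_id,
                  F1 = 0.5 + 0.001 * scale(w)[, 1] + rnorm(16, 0, 0.01))
  eff <- effects_analysis(d, r, "F1",
                          interactions = list(c("window_size", "prefog_duration")))
  expect_equal(eff$logworth, -log10(eff$p_value))
  ord <- order(eff$p_value)
  expect_equal(order(eff$logworth, decreasing = TRUE), ord)
  expect_true(all(eff$logworth >= 0))
  # the p < 0.01 <=> LogWorth > 2 correspondence
  expect_identical(eff$p_value < 0.01, eff$logworth > 2)
})

test_that("three-factor interactions are rejected", {
  d <- build_l16_4_3()
  r <- data.frame(run_id = d$runs$run_id, F1 = runif(16))
  expect_error(
    effects_analysis(d, r, "F1",
                     interactions = list(c("window_size", "step", "prefog_duration"))),
    "higher-order")
})

test_that("effects analysis ranks planted factors and recovers the optimum", {
  d <- build_l16_4_3()
  lev <- list(window_size = c(128, 256, 400, 500), step = c(5, 10, 20, 30),
              prefog_duration = c(150, 250, 500, 600))
  idx <- function(f) match(d$runs[[f]], lev[[f]])

  rank_ok <- 0
  opt_ok <- 0
  set.seed(909)
  for (b in 1:100) {
    # additive linear effects with distinct known magnitudes
    y <- 0.5 + 0.05 * idx("window_size") + 0.02 * idx("prefog_duration") +
      0.005 * idx("step") + rnorm(16, 0, 0.01)
    eff <- effects_analysis(d, data.frame(run_id = d$runs$run_id, F1 = y), "F1")
    lw <- setNames(eff$logworth, eff$term)
    if (lw["window_size"] > lw["prefog_duration"] &&
        lw["prefog_duration"] > lw["step"]) rank_ok <- rank_ok + 1

    # planted optimum at (256, 10, 150)
    y2 <- 0.5 + 0.05 * (d$runs$window_size == 256) +
      0.04 * (d$runs$step == 10) + 0.03 * (d$runs$prefog_duration == 150) +
      rnorm(16, 0, 0.01)
    eff2 <- effects_analysis(d, data.frame(run_id = d$runs$run_id, F1 = y2), "F1")
    best <- select_best(eff2)
    if (best$window_size == 256 && best$step == 10 && best$prefog_duration == 150) {
      opt_ok <- opt_ok + 1
    }
  }
  expect_gte(rank_ok, 95)
  expect_gte(opt_ok, 95)
})

test_that("L16 selection agrees with the 64-run full factorial on additive surfaces", {
  d16 <- build_l16_4_3()
  d64 <- full_factorial()
  agree <- 0
  set.seed(4242)
  for (b in 1:100) {
    f <- function(runs) {
      0.5 + 0.03 * match(runs$window_size, c(128, 256, 400, 500)) -
        0.02 * match(runs$step, c(5, 10, 20, 30)) +
        0.02 * (runs$prefog_duration == 250) +
        rnorm(nrow(runs), 0, 0.01)
    }
    b16 <- select_best(effects_analysis(
      d16, data.frame(run_id = d16$runs$run_id, F1 = f(d16$runs)), "F1"))
    b64 <- select_best(effects_analysis(
      d64, data.frame(run_id = d64$runs$run_id, F1 = f(d64$runs)), "F1"))
    if (identical(unclass(b16), unclass(b64))) agree <- agree + 1
  }
  expect_gte(agree, 95)
})

test_that("noiseless additive responses reproduce level means exactly", {
  d64 <- full_factorial()
  y <- 0.1 * match(d64$runs$window_size, c(128, 256, 400, 500)) +
    0.03 * match(d64$runs$step, c(5, 10, 20, 30))
  eff <- suppressWarnings(
    effects_analysis(d64, data.frame(run_id = d64$runs$run_id, F1 = y), "F1"))
  lm_ <- attr(eff, "level_means")
  expect_equal(unname(lm_$window_size),
               0.1 * (1:4) + 0.03 * mean(1:4), tolerance = 1e-9)
  expect_equal(unname(lm_$step), 0.03 * (1:4) + 0.1 * mean(1:4), tolerance = 1e-9)
})

test_that("replicated responses use categorical ANOVA with interactions", {
  d <- build_l16_4_3()
  set.seed(77)
  r <- do.call(rbind, lapply(1:3, function(rep_) {
    data.frame(run_id = d$runs$run_id, replicate = rep_,
               F1 = 0.5 + 0.02 * match(d$runs$window_size, c(128, 256, 400, 500)) +
                 rnorm(16, 0, 0.005))
  }))
  eff <- effects_analysis(d, r, "F1",
                          interactions = list(c("window_size", "prefog_duration")))
  expect_equal(attr(eff, "coding"), "categorical")
  expect_lt(eff$p_value[eff$term == "window_size"], 0.01)
})

test_that("design execution produces one response row per run and replicate", {
  cohort <- simulate_cohort(3, 20, fog_schedule = list(c(8, 2), c(16, 2)),
                            seed = 61)
  d <- build_l16_4_3()
  d$runs <- d$runs[c(1, 6), ]     # two cheap runs
  rp <- rf_params(n_estimators = 30, seed = 5)
  resp <- run_design(d, cohort$recordings, cohort$annotations, rp,
                     seeds = c(11, 12))
  expect_equal(nrow(resp), 4)
  expect_equal(sort(table(resp$run_id)), sort(table(c("T01", "T01", "T06", "T06"))))
  expect_true(all(is.finite(resp$F1)))
  expect_true(all(resp$kappa > -1 & resp$kappa <= 1))
})
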