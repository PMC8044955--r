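test_that("scheduled FOG episodes land at exact sample bounds", {
  p <- gait_sim_params(seed = 3)
  sim <- simulate_recording(p, 60, list(c(30, 5)))
  expect_equal(nrow(sim$recording$signals), 6000)
  expect_equal(ncol(sim$recording$signals), 42)
  ev <- sim$annotation$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_sample, 3000L)
  expect_equal(ev$end_sample, 3500L)
  expect_identical(colnames(sim$recording$signals)[1:7],
                   c("sensor1_accX", "sensor1_accY", "sensor1_accZ",
                     "sensor1_gyrX", "sensor1_gyrY", "sensor1_gyrZ",
                     "sensor2_accX"))
})

test_that("the generator is bitwise deterministic given the seed", {
  p <- gait_sim_params(seed = 42)
  a <- simulate_recording(p, 20, list(c(8, 2)))
  b <- simulate_recording(p, 20, list(c(8, 2)))
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$annotation$events, b$annotation$events)
  p2 <- gait_sim_params(seed = 43)
  c_ <- simulate_recording(p2, 20, list(c(8, 2)))
  expect_false(identical(a$recording$signals, c_$recording$signals))
})

test_that("conflicting FOG schedules are rejected", {
  p <- gait_sim_params(seed = 1)
  expect_error(simulate_recording(p, 60, list(c(10, 5), c(12, 5))),
               "schedule-conflict")
  expect_error(simulate_recording(p, 60, list(c(10, 5), c(17, 5))),
               "schedule-conflict")              # onset 2s after prev offset
  expect_error(simulate_recording(p, 60, list(c(58, 5))), "schedule-conflict")
  expect_error(simulate_recording(p, 60, list(c(3, 5))), "schedule-conflict")
})

test_that("freeze-band (3-8 Hz) power is elevated inside FOG episodes", {
  # 50 episodes across 10 recordings; band power by direct DFT on segments
  wins <- 0L
  total <- 0L
  for (r in 1:10) {
    p <- gait_sim_params(seed = 100 + r, fog_amplitude = 2, gait_amplitude = 1)
    sched <- lapply(seq(10, 58, by = 10), function(o) c(o, 4))
    sim <- simulate_recording(p, 64, sched)
    for (k in seq_len(nrow(sim$annotation$events))) {
      o <- sim$annotation$events$start_sample[k]
      fogseg <- sim$recording$signals[(o + 51):(o + 306), 1]
      # normal gait: after the previous offset, before this episode's ramp
      normseg <- sim$recording$signals[(o - 590):(o - 335), 1]
      total <- total + 1L
      if (band_power(fogseg, 100, 3, 8) > band_power(normseg, 100, 3, 8)) {
        wins <- wins + 1L
      }
    }
  }
  expect_equal(total, 50L)
  expect_gte(wins, 49L)
})

test_that("noise-free FOG-free gait is periodic at the step frequency", {
  p <- gait_sim_params(seed = 9, noise_sd = 0, burst_outlier_rate = 0)
  sim <- simulate_recording(p, 41, list())
  for (j in c(1, 10, 25, 42)) {
    x <- sim$recording$signals[1:4096, j]
    sp <- Mod(fft(x))[2:2048]
    fdom <- which.max(sp) * 100 / 4096
    expect_lte(abs(fdom - 1.8), 100 / 4096)
  }
})

test_that("preFOG windows separate from normal windows in variance", {
  # drift >= 0.4 must produce |Cohen's d| > 0.5 on per-window variance (F10)
  p <- gait_sim_params(seed = 5, prefog_drift = 0.4)
  sched <- lapply(seq(10, 80, by = 12), function(o) c(o, 3))
  sim <- simulate_recording(p, 90, sched)
  # the variance contrast is a property of the cleaned signal: burst
  # outliers would otherwise dominate per-window variance
  rec <- preprocess_recording(sim$recording)
  ws <- segment_and_label(rec, sim$annotation,
                          segmentation_params(128, 10, 300))
  fm <- extract_matrix(ws)
  v <- fm$X[, "sensor1_accX_F10"]
  pre <- v[fm$label == "prefog"]
  nor <- v[fm$label == "normal"]
  expect_gte(length(pre) + length(nor), 100)
  sd_pool <- sqrt(((length(pre) - 1) * var(pre) + (length(nor) - 1) * var(nor)) /
                    (length(pre) + length(nor) - 2))
  d <- (mean(nor) - mean(pre)) / sd_pool
  expect_gt(abs(d), 0.5)
})

test_that("CSV/JSON round trip preserves signals and annotations", {
  p <- gait_sim_params(seed = 13, n_sensors = 2)
  sim <- simulate_recording(p, 10, list())
  dir <- withr::local_tempdir()
  write_recording(sim$recording, sim$annotation, dir)
  rt <- read_recording(dir, "P01")
  rel <- abs(rt$recording$signals - sim$recording$signals) /
    pmax(abs(sim$recording$signals), 1e-12)
  expect_lt(max(rel), 1e-8)
  expect_identical(rt$annotation$events, sim$annotation$events)
  expect_equal(rt$recording$sampling_rate_hz, 100)
})

test_that("malformed signal and annotation files are rejected by name", {
  p <- gait_sim_params(seed = 13, n_sensors = 1)
  sim <- simulate_recording(p, 10, list())
  dir <- withr::local_tempdir()
  write_recording(sim$recording, sim$annotation, dir)

  # drop one canonical column
  csv <- file.path(dir, "P01_signals.csv")
  tab <- read.csv(csv)
  write.csv(tab[, setdiff(names(tab), "sensor1_gyrY")], csv, row.names = FALSE)
  expect_error(read_recording(dir, "P01"), "sensor1_gyrY")

  # non-numeric cell
  write.csv(tab, csv, row.names = FALSE)
  lines <- readLines(csv)
  lines[3] <- sub("^([^,]*),[^,]*", "\\1,oops", lines[3])
  writeLines(lines, csv)
  expect_error(read_recording(dir, "P01"), "non-numeric")

  # inverted event bounds in the JSON
  write.csv(tab, csv, row.names = FALSE)
  jf <- file.path(dir, "P01_events.json")
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  meta$events <- data.frame(label = "FOG", start_sample = 500, end_sample = 400)
  jsonlite::write_json(meta, jf, auto_unbox = TRUE)
  expect_error(read_recording(dir, "P01"), "end_sample")
})

test_that("annotation invariants are enforced", {
  expect_error(event_annotation("P", data.frame(
    label = c("FOG", "FOG"), start_sample = c(10, 5), end_sample = c(20, 8))),
    "sorted")
  expect_error(event_annotation("P", data.frame(
    label = c("FOG", "FOG"), start_sample = c(10, 15), end_sample = c(20, 25))),
    "overlap")
  expect_error(event_annotation("P", data.frame(
    label = "FOG", start_sample = 10, end_sample = 10)), "exceed")
})
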