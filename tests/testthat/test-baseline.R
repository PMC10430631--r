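test_that("baseline segments follow the buffered-removal arithmetic", {
  blocks <- data.frame(block_id = 1L, kind = "airflow", start_ms = 0,
                       end_ms = 10000)
  events <- data.frame(event_id = 1L, block_id = 1L, modality = "airflow",
                       location = 1L, onset_ms = 4000, offset_ms = 5000)
  s <- session("b", blocks, events, NULL,
               list(spike_train("u", "amygdala", c(100, 3600, 5400, 9999))))
  seg <- baseline_segments(s, 1L)
  expect_equal(seg, rbind(c(0, 3700), c(5300, 10000)))  # 3.7 + 4.7 = 8.4 s
  ser <- extract_baseline_bins(s, "u", block_ids = 1L)
  expect_equal(nrow(ser$bins), 8L)                      # trailing 0.4 s dropped
  # spikes at 100 and 3600 land in bins 1 and 4; 5400 maps to concatenated
  # coordinate 3800 -> bin 4; 9999 -> 8399 -> dropped partial bin
  expect_equal(ser$bins$rate_hz, c(1, 0, 0, 2, 0, 0, 0, 0))
})

test_that("a stimulus-free block yields floor(duration) bins", {
  blocks <- data.frame(block_id = 1L, kind = "grooming", start_ms = 0,
                       end_ms = 12700)
  ev <- data.frame(event_id = integer(), block_id = integer(),
                   modality = character(), location = integer(),
                   onset_ms = numeric(), offset_ms = numeric())
  s <- session("b", blocks, ev, NULL, list(spike_train("u", "amygdala", 500)))
  expect_equal(nrow(extract_baseline_bins(s, "u")$bins), 12L)
})

test_that("extraction equals the 1-ms mask brute-force oracle", {
  for (seed in 1:10) {
    s <- random_small_session(seed)
    tr <- s$units[[1]]
    ser <- extract_baseline_bins(s, tr)
    for (bid in s$blocks$block_id) {
      got <- ser$bins$rate_hz[ser$bins$block_id == bid]
      expect_equal(got, as.numeric(oracle_block_bins(s, tr, bid)),
                   label = sprintf("seed %d block %d", seed, bid))
    }
  }
})

test_that("cohens_ds matches hand arithmetic and is scale invariant", {
  expect_equal(cohens_ds(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_ds(c(2, 4, 6), c(2, 4, 6)), 0)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(cohens_ds(3.7 * x, 3.7 * y), cohens_ds(x, y))
  expect_equal(cohens_ds(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_error(cohens_ds(c(1, 1), c(2, 2)), "zero pooled SD")
})

test_that("ds estimates converge to the generating standardized shift", {
  set.seed(202)
  est <- replicate(150, {
    cohens_ds(rnorm(240, 5.5, 1), rnorm(240, 5, 1))
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("the context rule reproduces its defining examples", {
  expect_equal(context_label(0.49, 0.10, 0.10), "context_groom_up")
  expect_equal(context_label(0.19, 0.01, 0.01), "not_context")
  expect_equal(context_label(0.30, 0.25, 0.10), "not_context")  # ratio fails
  expect_equal(context_label(-0.60, 0.10, 0.10), "context_groom_down")
  # sign of within-block drift is irrelevant: absolute values are compared
  expect_equal(context_label(0.49, -0.10, 0.10), "context_groom_up")
})

test_that("units with too few bins are excluded with a warning, not an error", {
  cfg <- baseline_only_config(
    list(unit_spec("u", baseline_hz = c(airflow = 5))), seed = 4, block_s = 30)
  s <- generate_session(cfg)
  ser <- extract_baseline_bins(s, "u")
  expect_warning(res <- classify_context(ser, s), "excluded")
  expect_null(res)
})

test_that("context classification recovers configured shifts on full sessions", {
  lam_g <- 6.18  # (6.18 - 5) / sqrt((6.18 + 5) / 2) ~ 0.5 standardized
  units <- c(
    lapply(1:10, function(i) unit_spec(sprintf("shift%02d", i),
      baseline_hz = c(airflow = 5, grooming = lam_g))),
    lapply(1:10, function(i) unit_spec(sprintf("null%02d", i),
      baseline_hz = c(airflow = 5))))
  s <- generate_session(baseline_only_config(units, seed = 55, block_s = 70))
  res <- do.call(rbind, lapply(s$units, function(u)
    classify_context(extract_baseline_bins(s, u), s)))
  shift_lab <- res$label[grepl("^shift", res$unit_id)]
  null_lab <- res$label[grepl("^null", res$unit_id)]
  expect_gt(mean(shift_lab == "context_groom_up"), 0.7)
  expect_lt(mean(null_lab != "not_context"), 0.3)
})

test_that("groomer presence recovers intermediate baseline steps", {
  units <- lapply(1:8, function(i) unit_spec(sprintf("g%02d", i),
    baseline_hz = c(airflow = 5, airflow_groomer_present = 5.5, grooming = 6)))
  cfg <- baseline_only_config(
    units, seed = 66, block_s = 120,
    kinds = c("airflow", "grooming", "airflow", "grooming",
              "airflow_groomer_present"))
  s <- generate_session(cfg)
  series <- lapply(s$units, function(u) extract_baseline_bins(s, u))
  gp <- groomer_presence_effect(series, s)
  # per-unit SE of a condition mean ~ sqrt(5/120); steps of 0.5 within 3 SE
  se_step <- sqrt(2 * 5.5 / 120) / sqrt(8)
  expect_lt(abs(gp$step_present_vs_absent - 0.5), 3 * se_step)
  expect_lt(abs(gp$step_groom_vs_present - 0.5), 3 * se_step)
  expect_lt(gp$p_present_vs_absent, 0.05)
  # flat configuration: no step, p not small
  units0 <- lapply(1:8, function(i) unit_spec(sprintf("f%02d", i),
    baseline_hz = c(airflow = 5, airflow_groomer_present = 5, grooming = 5)))
  s0 <- generate_session(baseline_only_config(
    units0, seed = 67, block_s = 120,
    kinds = c("airflow", "grooming", "airflow", "grooming",
              "airflow_groomer_present")))
  gp0 <- groomer_presence_effect(
    lapply(s0$units, function(u) extract_baseline_bins(s0, u)), s0)
  expect_lt(abs(gp0$step_present_vs_absent), 3 * se_step)
  expect_gt(gp0$p_present_vs_absent, 0.05)
  expect_error(groomer_presence_effect(series[1], s), ">= 2 units")
})
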