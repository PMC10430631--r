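test_that("unit inclusion enforces the rate floor, trial counts, and stability", {
  ext <- 100000
  ev <- do.call(rbind, lapply(1:2, function(loc)
    data.frame(event_id = (loc - 1) * 10 + 1:10, block_id = 1L,
               modality = "grooming", location = loc,
               onset_ms = 0, offset_ms = 1000)))
  slow <- spike_train("slow", "amygdala", seq(0, ext - 1, by = 2001))  # 0.5 Hz
  fast <- spike_train("fast", "amygdala", seq(0, ext - 1, by = 200))   # 5 Hz
  expect_false(unit_inclusion(slow, ev, ext))
  expect_true(unit_inclusion(fast, ev, ext))
  # 9 trials at one location excludes the unit
  ev9 <- ev[-1, ]
  expect_false(unit_inclusion(fast, ev9, ext))
  unstable <- spike_train("u", "amygdala", seq(0, ext - 1, by = 200),
                          stable = FALSE)
  expect_false(unit_inclusion(unstable, ev, ext))
})

make_trial_events <- function(n, spacing_ms = 6000, dur_ms = 1000,
                              modality = "airflow", location = 2L) {
  onset <- 2000 + (0:(n - 1)) * spacing_ms
  data.frame(event_id = seq_len(n), block_id = 1L, modality = modality,
             location = location, onset_ms = onset,
             offset_ms = onset + dur_ms)
}

# spikes giving an exact per-trial rate in the pre window (750 ms) and post
# window (800 ms for a 1-s stimulus)
deterministic_train <- function(events, n_pre, n_post) {
  sp <- unlist(lapply(events$onset_ms, function(on) {
    pre <- if (n_pre > 0) seq(on - 990, on - 260, length.out = n_pre) else NULL
    post <- if (n_post > 0) seq(on + 210, on + 990, length.out = n_post) else NULL
    c(pre, post)
  }))
  spike_train("d", "amygdala", round(sp))
}

test_that("the response test recovers a simulated evoked rate change", {
  cfg <- session_config(
    block_kinds = c("airflow", "grooming", "airflow", "grooming", "airflow"),
    units = list(unit_spec("e", baseline_hz = c(airflow = 5),
                           gain_airflow = 10, latency_ms = 0)),
    seed = 21)
  s <- generate_session(cfg)
  ev <- s$events[s$events$modality == "airflow" & s$events$location == 2, ]
  rt <- test_stimulus_response(s$units[["e"]], ev)
  expect_true(rt$responsive)
  # post window [on+200, off) sees the sustained gain only: delta ~ 10 Hz
  expect_lt(abs(rt$delta_hz - 10), 2.5)   # ~3 empirical SE at 30 trials
  expect_lt(rt$p_value, 0.001)
})

test_that("the 1-Hz floor vetoes significant but small rate changes", {
  ev <- make_trial_events(12)
  # constant small shift: p trivially small but |delta| < 1 Hz
  tr <- deterministic_train(ev, n_pre = 3, n_post = 3)  # 4 vs 3.75 Hz
  rt <- test_stimulus_response(tr, ev)
  expect_lt(abs(rt$delta_hz), 1)
  expect_lt(rt$p_value, 0.05)
  expect_false(rt$responsive)
  # constant large shift is responsive
  tr2 <- deterministic_train(ev, n_pre = 3, n_post = 6)  # 4 vs 7.5 Hz
  rt2 <- test_stimulus_response(tr2, ev)
  expect_gte(abs(rt2$delta_hz), 1)
  expect_true(rt2$responsive)
})

test_that("fewer than 10 trials is an error, not a silent answer", {
  ev <- make_trial_events(9)
  expect_error(test_stimulus_response(deterministic_train(ev, 2, 2), ev),
               ">= 10")
})

test_that("false-positive rate of the response test stays at or below alpha", {
  set.seed(404)
  ev <- make_trial_events(100)
  hits <- vapply(1:300, function(i) {
    ext <- max(ev$offset_ms) + 2000
    tr <- spike_train("n", "amygdala",
                      sort(sample(0:(ext - 1), rpois(1, 5 * ext / 1000))))
    test_stimulus_response(tr, ev)$responsive
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("responsivity labels follow the groomed-location rule", {
  row <- function(mod, loc, resp)
    data.frame(unit_id = "u", modality = mod, location = loc, n_trials = 10,
               mean_pre_hz = 5, mean_post_hz = 5 + 2 * resp, delta_hz = 2 * resp,
               p_value = ifelse(resp, 0.001, 0.8), responsive = resp)
  groomed <- c(2L, 3L)
  t1 <- rbind(row("airflow", 2, TRUE), row("airflow", 5, TRUE),
              row("grooming", 2, FALSE), row("grooming", 3, FALSE))
  expect_equal(classify_tactile_responsivity(t1, groomed)$label, "airflow_only")
  # any-location criterion per modality: airflow@3 + grooming@2 -> both
  t2 <- rbind(row("airflow", 3, TRUE), row("airflow", 2, FALSE),
              row("grooming", 2, TRUE), row("grooming", 3, FALSE))
  expect_equal(classify_tactile_responsivity(t2, groomed)$label, "both")
  t3 <- rbind(row("airflow", 2, FALSE), row("grooming", 2, FALSE),
              row("grooming", 3, FALSE))
  expect_equal(classify_tactile_responsivity(t3, groomed)$label, "none")
  # responses at non-groomed locations never drive the label
  t4 <- rbind(row("airflow", 7, TRUE), row("airflow", 2, FALSE),
              row("grooming", 2, FALSE))
  expect_equal(classify_tactile_responsivity(t4, groomed)$label, "none")
  # sham is scored separately
  t5 <- rbind(t1, row("sham", 11, TRUE))
  r5 <- classify_tactile_responsivity(t5, groomed)
  expect_equal(r5$label, "airflow_only")
  expect_true(r5$sham_responsive)
  expect_error(classify_tactile_responsivity(
    rbind(row("airflow", 2, TRUE)), groomed), "no grooming tests")
})

test_that("generated airflow-only units are recovered as airflow-only", {
  units <- lapply(1:20, function(i)
    unit_spec(sprintf("a%02d", i), baseline_hz = c(airflow = 5),
              gain_airflow = 10))
  cfg <- session_config(block_kinds = c("airflow", "grooming"),
                        groom_sets = 1, units = units, seed = 99)
  s <- generate_session(cfg)
  groomed <- sort(unique(s$events$location[s$events$modality == "grooming"]))
  labels <- vapply(s$units, function(u)
    classify_tactile_responsivity(test_all_responses(s, u), groomed)$label, "")
  expect_gt(mean(labels == "airflow_only"), 0.9)
})

test_that("chi-squared proportion comparison matches the 2x2 formula", {
  oracle_chi2 <- function(k1, n1, k2, n2) {
    a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2; N <- n1 + n2
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  same <- compare_proportions(20, 40, 20, 40)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  r <- compare_proportions(30, 40, 10, 40)
  expect_equal(r$chi2, oracle_chi2(30, 40, 10, 40))
  expect_equal(r$p, pchisq(oracle_chi2(30, 40, 10, 40), 1, lower.tail = FALSE))
  r2 <- compare_proportions(0, 10, 10, 10)
  expect_equal(r2$chi2, oracle_chi2(0, 10, 10, 10))
  expect_lt(r2$p, 0.001)
  expect_error(compare_proportions(5, 0, 1, 10))
})
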