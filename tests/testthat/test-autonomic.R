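test_that("instantaneous HR inverts IBIs and masks implausible beats", {
  h <- seq(0, 60000, by = 600)               # constant 100 BPM
  hs <- instantaneous_hr(h)
  expect_true(all(hs$ibi$ok))
  expect_true(all(abs(hs$hr_grid - 100) < 1e-6))
  # a long dropout IBI is masked and bridged near the surrounding rate
  h2 <- c(seq(0, 12000, by = 600), seq(14000, 26000, by = 600))
  hs2 <- instantaneous_hr(h2)
  expect_equal(sum(!hs2$ibi$ok), 1L)
  expect_equal(nrow(hs2$artifact_mask), 1L)
  gap <- hr_in_span(hs2, 12000, 14000)
  expect_true(all(abs(gap - 100) < 1))
  # strict bounds: IBIs of exactly 1500 and 250 ms are rejected
  h3 <- c(0, 1500, seq(2100, 8100, by = 600), 8350)
  hs3 <- instantaneous_hr(h3)
  expect_false(hs3$ibi$ok[1])
  expect_false(hs3$ibi$ok[nrow(hs3$ibi)])
  expect_true(hs3$ibi$ok[2])
  expect_error(instantaneous_hr(c(0, 2000)), "all beats rejected")
  expect_error(instantaneous_hr(0), ">= 2")
})

test_that("Slepian tapers are orthonormal with the stated smoothing", {
  tap <- dpss_tapers(240, nw = 4, k = 7)
  expect_equal(dim(tap), c(240L, 7L))
  expect_equal(crossprod(tap), diag(7), tolerance = 1e-8)
  expect_gt(sum(tap[, 1]), 0)
  # (K+1)/(2T) with K = 7 tapers on a 60-s window stays within +/-0.07 Hz
  expect_lte((7 + 1) / (2 * 60), 0.07)
})


test_that("the spectrogram recovers RSA frequency within one half-bandwidth", {
  for (f in c(0.26, 0.30, 0.42)) {
    sg <- hr_spectrogram(sim_groom_heart(300, depth = 0.1, freq = f)$hs)
    rsa <- rsa_strength(sg)
    expect_lt(abs(median(rsa$peak_freq_hz, na.rm = TRUE) - f),
              sg$half_bandwidth_hz, label = sprintf("f = %.2f", f))
  }
})

test_that("a constant heart rate gives a near-zero spectrum and no episodes", {
  sh <- sim_groom_heart(180, depth = 0)
  sg <- hr_spectrogram(sh$hs)
  expect_lt(max(sg$psd), 1e-4 * (110^2))
  eps <- detect_high_hr_episodes(sh$hs, cbind(0, 180000))
  expect_equal(nrow(eps), 0L)
})

test_that("short records yield an empty spectrogram", {
  sh <- sim_groom_heart(30, depth = 0.05)
  sg <- hr_spectrogram(sh$hs)
  expect_equal(nrow(sg$psd), 0L)
  expect_error(rsa_strength(sg), "empty")
})

test_that("RSA normalization is zero at the median window", {
  sg <- hr_spectrogram(sim_groom_heart(300, depth = 0.08)$hs)
  rsa <- rsa_strength(sg)
  mu <- median(rsa$strength)
  expect_equal(rsa$rsa_norm, (rsa$strength - mu) / mu)
  expect_lt(abs(median(rsa$rsa_norm)), 1e-12)  # the median window sits at zero
  # constant strength series: all zero
  sg$psd <- matrix(rep(sg$psd[1, ], nrow(sg$psd)), nrow = nrow(sg$psd),
                   byrow = TRUE)
  expect_true(all(rsa_strength(sg)$rsa_norm == 0))
})

test_that("episode detection keeps 30-s excursions and rejects 5-s ones", {
  eps30 <- data.frame(start_ms = 200000, duration_ms = 30000, delta_bpm = 35)
  sh <- sim_groom_heart(400, depth = 0.03, episodes = eps30)
  got <- detect_high_hr_episodes(sh$hs, cbind(0, 400000))
  expect_equal(nrow(got), 1L)
  expect_lt(abs(got$start_ms - 200000), 3000)
  expect_lt(abs(got$end_ms - 230000), 3000)
  expect_gte(got$end_ms - got$start_ms, 10000)
  eps5 <- data.frame(start_ms = 200000, duration_ms = 5000, delta_bpm = 35)
  sh5 <- sim_groom_heart(400, depth = 0.03, episodes = eps5)
  expect_equal(nrow(detect_high_hr_episodes(sh5$hs, cbind(0, 400000))), 0L)
})

test_that("episode detection is invariant to a 1-ms shift of the record", {
  eps30 <- data.frame(start_ms = 150000, duration_ms = 30000, delta_bpm = 35)
  blocks <- data.frame(block_id = 1L, kind = "grooming", start_ms = 0,
                       end_ms = 400000)
  spec <- heart_spec(mean_hr_bpm = c(grooming = 110, airflow = 110),
                     rsa_depth = c(grooming = 0.03, airflow = 0.03),
                     episodes = eps30)
  rw <- simulate_heart(spec, blocks)
  a <- detect_high_hr_episodes(instantaneous_hr(rw), cbind(0, 400000))
  b <- detect_high_hr_episodes(instantaneous_hr(rw + 1), cbind(1, 400001))
  expect_equal(b$start_ms - a$start_ms, rep(1, nrow(a)))
  expect_equal(nrow(a), nrow(b))
})

test_that("grooming HR deficits are recovered across sessions", {
  mk <- function(air_bpm, grm_bpm) {
    blocks <- data.frame(block_id = 1:2, kind = c("airflow", "grooming"),
                         start_ms = c(0, 60000), end_ms = c(60000, 120000))
    spec <- heart_spec(mean_hr_bpm = c(airflow = air_bpm, grooming = grm_bpm),
                       rsa_depth = c(airflow = 0.02, grooming = 0.05))
    list(hs = instantaneous_hr(simulate_heart(spec, blocks)), blocks = blocks)
  }
  sessions <- lapply(0:6, function(i) mk(118 + i, 108 + i))
  cmp <- block_hr_comparison(sessions)
  expect_lt(cmp$mean_grooming, cmp$mean_airflow)
  expect_lt(cmp$p, 0.05)
  expect_lt(abs(cmp$mean_difference + 10), 1)
  same <- block_hr_comparison(lapply(0:3, function(i) mk(115 + i, 115 + i)))
  expect_lt(abs(same$mean_difference), 0.5)
  single <- block_hr_comparison(sessions[1])
  expect_true(is.na(single$p))
})

test_that("grooming responsivity during episodes follows the standard rule", {
  onsets <- 200000 + (0:11) * 2000
  ev <- data.frame(event_id = 1:12, block_id = 1L, modality = "grooming",
                   location = 2L, onset_ms = onsets, offset_ms = onsets + 1500)
  eps <- data.frame(start_ms = 199000, end_ms = 226000, mean_hr_bpm = 140)
  # evoked unit: strong sustained response during each sweep
  sp_resp <- unlist(lapply(onsets, function(on)
    c(seq(on - 900, on - 300, by = 150), seq(on + 250, on + 1450, by = 55))))
  r <- grooming_response_during_episodes(
    spike_train("r", "amygdala", sp_resp), ev, eps)
  expect_true(r$responsive)
  # silent unit: flat before and during
  sp_flat <- unlist(lapply(onsets, function(on)
    seq(on - 900, on + 1400, by = 300)))
  r0 <- grooming_response_during_episodes(
    spike_train("f", "amygdala", sp_flat), ev, eps)
  expect_false(r0$responsive)
  # sweeps outside the episodes: insufficient data
  far <- grooming_response_during_episodes(
    spike_train("r", "amygdala", sp_resp), ev,
    eps <- data.frame(start_ms = 0, end_ms = 1000, mean_hr_bpm = 150))
  expect_equal(far$status, "insufficient_data")
})
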