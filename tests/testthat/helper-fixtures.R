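# Fixtures are generated in code; no data files are shipped.

# A baseline_series built directly from per-block rate vectors
# (blocks 1/3 airflow, 2/4 grooming), bypassing spike simulation.
fake_series <- function(unit_id, a1, g1, a2, g2) {
  bins <- rbind(
    data.frame(block_id = 1L, block_kind = "airflow",
               bin_index = seq_along(a1), rate_hz = a1),
    data.frame(block_id = 2L, block_kind = "grooming",
               bin_index = seq_along(g1), rate_hz = g1),
    data.frame(block_id = 3L, block_kind = "airflow",
               bin_index = seq_along(a2), rate_hz = a2),
    data.frame(block_id = 4L, block_kind = "grooming",
               bin_index = seq_along(g2), rate_hz = g2))
  mu <- mean(bins$rate_hz); sd0 <- stats::sd(bins$rate_hz)
  bins$z <- if (sd0 > 0) (bins$rate_hz - mu) / sd0 else NA_real_
  structure(list(unit_id = unit_id, bins = bins), class = "baseline_series")
}

# Poisson 1-s bin rates per block, standardized context shift set by rates
poisson_series <- function(unit_id, lam_air, lam_groom, bins_per_block = 60,
                           seed = 1) {
  set.seed(seed)
  fake_series(unit_id,
              a1 = rpois(bins_per_block, lam_air),
              g1 = rpois(bins_per_block, lam_groom),
              a2 = rpois(bins_per_block, lam_air),
              g2 = rpois(bins_per_block, lam_groom))
}

# Gaussian bin rates with exact standardized separation `shift`
gauss_series <- function(unit_id, shift, bins_per_block = 60, seed = 1,
                         base = 5) {
  set.seed(seed)
  fake_series(unit_id,
              a1 = rnorm(bins_per_block, base, 1),
              g1 = rnorm(bins_per_block, base + shift, 1),
              a2 = rnorm(bins_per_block, base, 1),
              g2 = rnorm(bins_per_block, base + shift, 1))
}

# Small deterministic hand-built session for IO / baseline arithmetic
tiny_session <- function() {
  blocks <- data.frame(block_id = 1:2,
                       kind = c("airflow", "grooming"),
                       start_ms = c(0, 12000), end_ms = c(10000, 30000))
  events <- data.frame(
    event_id = 1:2, block_id = 1:2,
    modality = c("airflow", "grooming"), location = c(2L, 2L),
    onset_ms = c(4000, 14000), offset_ms = c(5000, 15500))
  rewards <- data.frame(block_id = 2L, start_ms = 26000, end_ms = 27000)
  units <- list(
    spike_train("u1", "amygdala", c(100, 500, 3650, 4100, 8000, 13000, 20000)),
    spike_train("u2", "SI", numeric(0)))
  session("tiny", blocks, events, rewards, units,
          heart = seq(0, 30000, by = 600),
          metadata = list(monkey = "Z", note = "fixture"))
}

# Random valid small session for the extraction oracle property
random_small_session <- function(seed) {
  set.seed(seed)
  n_blocks <- sample(2:3, 1)
  kinds <- sample(c("airflow", "grooming"), n_blocks, replace = TRUE)
  start <- 0
  blocks <- NULL; events <- NULL; rewards <- NULL; eid <- 0L
  for (i in seq_len(n_blocks)) {
    dur <- sample(8000:20000, 1)
    b <- data.frame(block_id = i, kind = kinds[i], start_ms = start,
                    end_ms = start + dur)
    blocks <- rbind(blocks, b)
    t <- start + sample(0:1500, 1)
    while (TRUE) {
      edur <- if (kinds[i] == "airflow") sample(1000:1500, 1)
              else sample(1000:2000, 1)
      if (t + edur + 500 > b$end_ms) break
      eid <- eid + 1L
      events <- rbind(events, data.frame(
        event_id = eid, block_id = i, modality = kinds[i],
        location = sample(1:10, 1), onset_ms = t, offset_ms = t + edur))
      t <- t + edur + sample(1500:4000, 1)
    }
    if (runif(1) < 0.5) {
      rs <- start + sample(0:(dur - 600), 1)
      rewards <- rbind(rewards,
                       data.frame(block_id = i, start_ms = rs,
                                  end_ms = rs + sample(200:600, 1)))
    }
    start <- b$end_ms + sample(1000:3000, 1)
  }
  if (is.null(events))
    events <- data.frame(event_id = integer(), block_id = integer(),
                         modality = character(), location = integer(),
                         onset_ms = numeric(), offset_ms = numeric())
  ext <- max(blocks$end_ms)
  u <- spike_train("r1", "amygdala", sort(sample(0:(ext - 1), rpois(1, ext / 50))))
  session(paste0("rand", seed), blocks, events, rewards, list(u))
}

# Brute-force 1-ms mask oracle for baseline bin extraction in one block
oracle_block_bins <- function(s, train, bid, buffer = 300) {
  b <- s$blocks[s$blocks$block_id == bid, ]
  ms <- seq(b$start_ms, b$end_ms - 1)
  keep <- rep(TRUE, length(ms))
  ev <- s$events[s$events$block_id == bid, , drop = FALSE]
  for (j in seq_len(nrow(ev)))
    keep[ms >= ev$onset_ms[j] - buffer & ms < ev$offset_ms[j] + buffer] <- FALSE
  rw <- s$rewards[s$rewards$block_id == bid, , drop = FALSE]
  for (j in seq_len(nrow(rw)))
    keep[ms >= rw$start_ms[j] & ms < rw$end_ms[j]] <- FALSE
  kept_ms <- ms[keep]
  n_bins <- floor(length(kept_ms) / 1000)
  if (n_bins < 1) return(integer(0))
  pos <- match(train$spike_times_ms, kept_ms)
  pos <- pos[!is.na(pos)]
  tabulate(floor((pos - 1) / 1000) + 1L, nbins = n_bins)
}

# Baseline-only session config: four alternating blocks, no stimuli
baseline_only_config <- function(units, seed, block_s = 70,
                                 kinds = c("airflow", "grooming",
                                           "airflow", "grooming")) {
  session_config(block_kinds = kinds,
                 block_durations_ms = rep(block_s * 1000, length(kinds)),
                 airflow_repeats = 0, groom_sets = 0,
                 units = units, seed = seed)
}

# Grooming-block EKG simulation shared by autonomic tests
sim_groom_heart <- function(dur_s, depth, freq = 0.3, bpm = 110,
                            episodes = NULL) {
  blocks <- data.frame(block_id = 1L, kind = "grooming", start_ms = 0,
                       end_ms = dur_s * 1000)
  spec <- heart_spec(mean_hr_bpm = c(grooming = bpm, airflow = bpm),
                     rsa_depth = c(grooming = depth, airflow = depth),
                     rsa_freq_hz = freq, episodes = episodes)
  list(hs = instantaneous_hr(simulate_heart(spec, blocks)), blocks = blocks)
}
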