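#' @title Synthetic session generator
#'
#' @description
#' Generates sessions with the statistical structure the analysis pipeline
#' assumes: alternating airflow and grooming blocks (typically
#' airflow-grooming-airflow-grooming-airflow), airflow stimuli of 1 s with a
#' 3 s inter-stimulus interval delivered in pseudo-random sets over 11
#' locations (location 11 being a sham nozzle pointed away from the animal)
#' repeated 10 times per block, grooming sweeps of 1--2 s with 2--4 s
#' intervals in 5 sets of 10 sweeps per groomed location, block-dependent
#' baseline firing, additive phasic evoked responses, and an EKG R-wave train
#' with block-dependent heart rate and respiratory sinus arrhythmia (RSA)
#' modulation near 0.3 Hz.
#'
#' Spike trains are inhomogeneous Poisson draws from
#' \code{rate(t) = baseline(block kind at t) + sum of evoked kernels}; R-wave
#' times come from integrate-to-threshold over the instantaneous heart rate.
#' A single master seed drives the whole session; each unit's spike stream is
#' a sub-stream derived by stable hashing of its unit id, so adding a unit
#' never changes another unit's spikes.
#'
#' @name synthetic-session
NULL

#' Specify a synthetic unit
#'
#' @param unit_id character id.
#' @param region \code{"amygdala"} or \code{"SI"}.
#' @param baseline_hz named numeric: baseline rate in Hz per block kind;
#'   names among \code{"airflow"}, \code{"grooming"},
#'   \code{"airflow_groomer_present"}. A missing kind defaults to the
#'   \code{"airflow"} entry.
#' @param gain_airflow,gain_grooming,gain_sham additive evoked rate in Hz:
#'   either a scalar (all locations) or a named numeric keyed by location id.
#' @param response_shape \code{"transient_plus_sustained"} (rectangular
#'   sustained gain plus a 100-ms onset transient at 3x gain, the typical
#'   airflow response) or \code{"ramp"} (triangular profile peaking
#'   mid-stimulus at 2x gain, tracking grooming contact pressure).
#' @param latency_ms response onset latency, ms.
#' @return An object of class \code{unit_spec}.
#' @export
unit_spec <- function(unit_id, region = "amygdala",
                      baseline_hz = c(airflow = 5),
                      gain_airflow = 0, gain_grooming = 0, gain_sham = 0,
                      response_shape = c("transient_plus_sustained", "ramp"),
                      latency_ms = 50) {
  response_shape <- match.arg(response_shape)
  stopifnot(all(baseline_hz >= 0), all(gain_airflow >= 0),
            all(gain_grooming >= 0), all(gain_sham >= 0), latency_ms >= 0)
  if (is.null(names(baseline_hz))) names(baseline_hz) <- "airflow"
  structure(list(unit_id = as.character(unit_id), region = region,
                 baseline_hz = baseline_hz, gain_airflow = gain_airflow,
                 gain_grooming = gain_grooming, gain_sham = gain_sham,
                 response_shape = response_shape, latency_ms = latency_ms),
            class = "unit_spec")
}

baseline_for <- function(spec, kind) {
  r <- spec$baseline_hz
  unname(if (kind %in% names(r)) r[[kind]] else r[["airflow"]])
}

gain_for <- function(spec, modality, location) {
  g <- switch(modality, airflow = spec$gain_airflow,
              grooming = spec$gain_grooming, sham = spec$gain_sham)
  if (is.null(names(g))) return(unname(g[1]))
  key <- as.character(location)
  unname(if (key %in% names(g)) g[[key]] else 0)
}

#' Specify the synthetic EKG
#'
#' @param mean_hr_bpm named numeric: mean heart rate (BPM, 40--240) per block
#'   kind; a missing kind falls back to the \code{"airflow"} entry.
#' @param rsa_depth fractional inter-beat-interval modulation amplitude in
#'   [0, 1); scalar or named per block kind (grooming typically deeper).
#' @param rsa_freq_hz RSA (respiratory) frequency in (0, 0.5].
#' @param episodes data.frame with columns \code{start_ms},
#'   \code{duration_ms}, \code{delta_bpm}: tachycardia episodes injected as
#'   additive rate offsets.
#' @return An object of class \code{heart_spec}.
#' @export
heart_spec <- function(mean_hr_bpm = c(airflow = 120, grooming = 110),
                       rsa_depth = c(airflow = 0.02, grooming = 0.10),
                       rsa_freq_hz = 0.3, episodes = NULL) {
  stopifnot(all(mean_hr_bpm >= 40), all(mean_hr_bpm <= 240),
            all(rsa_depth >= 0), all(rsa_depth < 1),
            rsa_freq_hz > 0, rsa_freq_hz <= 0.5)
  if (is.null(names(mean_hr_bpm))) names(mean_hr_bpm) <- "airflow"
  if (is.null(names(rsa_depth))) names(rsa_depth) <- "airflow"
  if (is.null(episodes))
    episodes <- data.frame(start_ms = numeric(), duration_ms = numeric(),
                           delta_bpm = numeric())
  structure(list(mean_hr_bpm = mean_hr_bpm, rsa_depth = rsa_depth,
                 rsa_freq_hz = rsa_freq_hz, episodes = episodes),
            class = "heart_spec")
}

kind_value <- function(x, kind) {
  unname(if (kind %in% names(x)) x[[kind]]
         else if ("airflow" %in% names(x)) x[["airflow"]] else x[[1]])
}

#' Configure a synthetic session
#'
#' Defaults reproduce the standard block design: three airflow blocks
#' interspersed with two grooming blocks, 10 pseudo-random sets of the 11
#' airflow locations per airflow block (1 s stimuli, 3 s ISI, juice reward
#' after each set) and 5 sets of 10 sweeps to each of two groomed facial
#' locations per grooming block (1--2 s sweeps, 2--4 s ISI, reward at block
#' end).
#'
#' @param block_kinds character vector of block kinds in order.
#' @param block_durations_ms numeric vector of block durations (ms);
#'   \code{NULL} sizes each block to fit its events at worst-case spacing.
#' @param airflow_repeats sets of 11 airflow locations per airflow block.
#' @param airflow_stim_ms,airflow_isi_ms airflow stimulus duration and ISI.
#' @param groom_locations two location ids receiving grooming sweeps.
#' @param groom_sweeps_per_set,groom_sets sweeps per location per set; sets
#'   per grooming block.
#' @param groom_dur_range_ms,groom_isi_range_ms uniform ranges for sweep
#'   duration and ISI.
#' @param inter_block_gap_ms gap between consecutive blocks.
#' @param start_pad_ms silent time at the head of each block.
#' @param units list of \code{\link{unit_spec}}.
#' @param heart a \code{\link{heart_spec}} or \code{NULL}.
#' @param seed mandatory integer master seed.
#' @param session_id character id.
#' @return An object of class \code{session_config}.
#' @export
session_config <- function(
    block_kinds = c("airflow", "grooming", "airflow", "grooming", "airflow"),
    block_durations_ms = NULL,
    airflow_repeats = 10, airflow_stim_ms = 1000, airflow_isi_ms = 3000,
    groom_locations = c(2L, 3L),
    groom_sweeps_per_set = 10, groom_sets = 5,
    groom_dur_range_ms = c(1000, 2000), groom_isi_range_ms = c(2000, 4000),
    inter_block_gap_ms = 5000, start_pad_ms = 2000,
    units = list(), heart = NULL, seed, session_id = "synthetic") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(block_kinds %in% BLOCK_KINDS),
            airflow_repeats >= 0, airflow_stim_ms > 0, airflow_isi_ms > 0,
            length(groom_locations) %in% c(0L, 2L),
            groom_sweeps_per_set >= 0, groom_sets >= 0,
            diff(groom_dur_range_ms) >= 0, diff(groom_isi_range_ms) >= 0)
  if (is.null(block_durations_ms)) {
    per_air <- start_pad_ms +
      airflow_repeats * 11 * (airflow_stim_ms + airflow_isi_ms) + 2000
    per_grm <- start_pad_ms + groom_sets * 2 * groom_sweeps_per_set *
      (groom_dur_range_ms[2] + groom_isi_range_ms[2]) + 4000
    block_durations_ms <- ifelse(block_kinds == "grooming", per_grm, per_air)
  }
  stopifnot(length(block_durations_ms) == length(block_kinds),
            all(block_durations_ms > 0))
  structure(list(
    block_kinds = block_kinds, block_durations_ms = block_durations_ms,
    airflow_repeats = airflow_repeats, airflow_stim_ms = airflow_stim_ms,
    airflow_isi_ms = airflow_isi_ms, groom_locations = as.integer(groom_locations),
    groom_sweeps_per_set = groom_sweeps_per_set, groom_sets = groom_sets,
    groom_dur_range_ms = groom_dur_range_ms,
    groom_isi_range_ms = groom_isi_range_ms,
    inter_block_gap_ms = inter_block_gap_ms, start_pad_ms = start_pad_ms,
    units = units, heart = heart, seed = as.integer(seed),
    session_id = session_id), class = "session_config")
}

#' Build the block / event / reward schedule
#'
#' Airflow (and groomer-present airflow) blocks receive
#' \code{airflow_repeats} independently permuted sets of the 11 locations;
#' grooming blocks receive \code{groom_sets} sets of 10 sweeps to location A
#' then 10 to location B with durations and ISIs drawn uniformly. A reward
#' window follows each airflow set and each grooming block.
#'
#' @param config a \code{\link{session_config}}.
#' @return list with data.frames \code{blocks}, \code{events},
#'   \code{rewards}. Errors if the drawn events cannot fit a stated block
#'   duration.
#' @export
make_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(derive_seed(config$seed, "schedule"), {
    starts <- cumsum(c(0, utils::head(config$block_durations_ms, -1) +
                            config$inter_block_gap_ms))
    blocks <- data.frame(block_id = seq_along(config$block_kinds),
                         kind = config$block_kinds,
                         start_ms = starts,
                         end_ms = starts + config$block_durations_ms)
    ev <- list(); rw <- list(); eid <- 0L
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      t <- b$start_ms + config$start_pad_ms
      if (b$kind %in% c("airflow", "airflow_groomer_present")) {
        for (set in seq_len(config$airflow_repeats)) {
          locs <- sample(11L)
          for (loc in locs) {
            onset <- t; offset <- t + config$airflow_stim_ms
            eid <- eid + 1L
            ev[[eid]] <- data.frame(
              event_id = eid, block_id = b$block_id,
              modality = if (loc == SHAM_LOCATION) "sham" else "airflow",
              location = loc, onset_ms = onset, offset_ms = offset)
            t <- offset + config$airflow_isi_ms
          }
          # juice reward inside the ISI after the set's last stimulus
          rw[[length(rw) + 1L]] <- data.frame(
            block_id = b$block_id, start_ms = t - config$airflow_isi_ms + 500,
            end_ms = t - config$airflow_isi_ms + 1500)
        }
      } else if (b$kind == "grooming" && length(config$groom_locations) == 2L) {
        for (set in seq_len(config$groom_sets)) {
          for (loc in config$groom_locations) {
            for (sw in seq_len(config$groom_sweeps_per_set)) {
              dur <- round(stats::runif(1, config$groom_dur_range_ms[1],
                                        config$groom_dur_range_ms[2]))
              isi <- round(stats::runif(1, config$groom_isi_range_ms[1],
                                        config$groom_isi_range_ms[2]))
              onset <- t; offset <- t + dur
              eid <- eid + 1L
              ev[[eid]] <- data.frame(
                event_id = eid, block_id = b$block_id, modality = "grooming",
                location = loc, onset_ms = onset, offset_ms = offset)
              t <- offset + isi
            }
          }
        }
        if (config$groom_sets > 0)
          rw[[length(rw) + 1L]] <- data.frame(
            block_id = b$block_id, start_ms = t + 500, end_ms = t + 2500)
      }
      if (t > b$end_ms)
        stop_load("block %d (%s): events (last at %d ms) exceed block end %d ms",
                  b$block_id, b$kind, as.integer(t), as.integer(b$end_ms))
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(event_id = integer(), block_id = integer(),
                 modality = character(), location = integer(),
                 onset_ms = numeric(), offset_ms = numeric())
    rewards <- if (length(rw)) do.call(rbind, rw) else
      data.frame(block_id = integer(), start_ms = numeric(),
                 end_ms = numeric())
    rewards <- rewards[rewards$end_ms <= blocks$end_ms[
      match(rewards$block_id, blocks$block_id)], , drop = FALSE]
    rownames(events) <- rownames(rewards) <- NULL
    list(blocks = blocks, events = events, rewards = rewards)
  })
}

evoked_kernel_per_ms <- function(spec, gain, onset, offset) {
  t0 <- onset + spec$latency_ms
  if (t0 >= offset || gain <= 0) return(NULL)
  ms <- seq(t0, offset - 1)
  lam <- rep(gain, length(ms))
  if (spec$response_shape == "transient_plus_sustained") {
    lam[ms < t0 + 100] <- 3 * gain
  } else {  # ramp: triangular, peak 2x gain mid-window, mean = gain
    mid <- (t0 + offset) / 2
    half <- (offset - t0) / 2
    lam <- 2 * gain * pmax(0, 1 - abs(ms - mid) / half)
  }
  list(ms = ms, lam = lam)
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson draw from the block-kind baseline rate plus the sum
#' of evoked kernels over events; spike times are rounded to the nearest
#' millisecond (duplicates collapse). The unit's RNG sub-stream is derived
#' from \code{seed} and a stable hash of \code{unit_id}.
#'
#' @param spec a \code{\link{unit_spec}}.
#' @param blocks,events schedule data.frames (see \code{\link{make_schedule}}).
#' @param seed session master seed.
#' @return A \code{\link{spike_train}}.
#' @export
simulate_spike_train <- function(spec, blocks, events, seed) {
  with_seed(derive_seed(seed, paste0("unit:", spec$unit_id)), {
    sp <- numeric(0)
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      lam <- baseline_for(spec, b$kind)
      dur_s <- (b$end_ms - b$start_ms) / 1000
      n <- stats::rpois(1, lam * dur_s)
      if (n > 0) sp <- c(sp, b$start_ms + stats::runif(n) * (b$end_ms - b$start_ms))
    }
    if (nrow(events)) for (j in seq_len(nrow(events))) {
      e <- events[j, ]
      g <- gain_for(spec, e$modality, e$location)
      k <- evoked_kernel_per_ms(spec, g, e$onset_ms, e$offset_ms)
      if (is.null(k)) next
      n_ms <- stats::rpois(length(k$ms), k$lam / 1000)
      if (any(n_ms > 0)) sp <- c(sp, rep(k$ms, n_ms))
    }
    spike_train(spec$unit_id, spec$region, sp)
  })
}

#' Simulate the EKG R-wave train
#'
#' Integrate-to-threshold over the instantaneous beat rate
#' \code{r(t) = HR(block kind) / 60 * (1 + depth * sin(2 pi f t))} (beats/s),
#' evaluated on a 1-ms grid, plus injected tachycardia episodes as additive
#' offsets; an R wave is emitted each time the integral crosses the next
#' integer. Deterministic given the heart specification; the empirical mean
#' HR per block
#' matches the configured value closely for blocks of a few minutes.
#'
#' @param spec a \code{\link{heart_spec}}.
#' @param blocks schedule blocks data.frame.
#' @param seed accepted for interface uniformity; the mapping is
#'   deterministic.
#' @return Numeric vector of R-wave times (ms).
#' @export
simulate_heart <- function(spec, blocks, seed = NULL) {
  ext <- max(blocks$end_ms)
  t_ms <- seq_len(ext) - 1
  idx <- findInterval(t_ms, blocks$start_ms)
  idx[idx < 1L] <- 1L
  kind <- blocks$kind[idx]
  hr <- vapply(BLOCK_KINDS, function(k) kind_value(spec$mean_hr_bpm, k), 0)
  dp <- vapply(BLOCK_KINDS, function(k) kind_value(spec$rsa_depth, k), 0)
  base <- hr[kind] / 60000                       # beats per ms
  depth <- dp[kind]
  rate <- base * (1 + depth * sin(2 * pi * spec$rsa_freq_hz * t_ms / 1000))
  if (nrow(spec$episodes)) for (i in seq_len(nrow(spec$episodes))) {
    e <- spec$episodes[i, ]
    span <- t_ms >= e$start_ms & t_ms < e$start_ms + e$duration_ms
    rate[span] <- rate[span] + e$delta_bpm / 60000
  }
  cum <- cumsum(rate)
  which(diff(floor(c(0, cum))) >= 1) - 1
}

#' Generate a full synthetic session
#'
#' Composes \code{\link{make_schedule}}, \code{\link{simulate_spike_train}}
#' per unit, and \code{\link{simulate_heart}}; fully reproducible from the
#' config (which carries the seed).
#'
#' @param config a \code{\link{session_config}}.
#' @return A validated \code{amyg_session} with the config seed recorded in
#'   its metadata.
#' @export
generate_session <- function(config) {
  sched <- make_schedule(config)
  units <- lapply(config$units, simulate_spike_train,
                  blocks = sched$blocks, events = sched$events,
                  seed = config$seed)
  heart <- if (!is.null(config$heart))
    simulate_heart(config$heart, sched$blocks, config$seed) else NULL
  session(config$session_id, sched$blocks, sched$events, sched$rewards,
          units, heart,
          metadata = list(seed = config$seed, generator = "amygcontext",
                          n_units = length(units)))
}
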