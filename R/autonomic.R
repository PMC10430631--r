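#' @title Heart rate and respiratory sinus arrhythmia
#'
#' @description
#' Instantaneous heart rate is the inverse of each inter-beat interval (IBI):
#' \code{HR = 60000 / IBI} BPM. Biologically implausible IBIs (greater than
#' 1500 ms or less than 250 ms, i.e. HR below 40 or above 240 BPM; the
#' boundary values themselves are rejected) are masked as artifacts and the
#' remaining values are interpolated to a 1-ms grid with a modified Akima
#' cubic Hermite scheme. Heart-rate variability is estimated in sliding 60-s
#' windows with a 3-s step using a multitaper power spectral density with 7
#' Slepian tapers (time-bandwidth product NW = 4, the unique choice giving
#' K = 2NW - 1 = 7 tapers and about +/-0.07 Hz smoothing on a 60-s window).
#' RSA strength is the mean power around the spectral peak between 0.25 and
#' 0.5 Hz, normalized per session by the median strength across windows.
#' High-heart-rate episodes are maximal spans within grooming blocks of at
#' least 10 s during which HR exceeds the stable-period mean by more than
#' 2 SD.
#'
#' @name autonomic
NULL

# modified Akima slopes (four-secant weighted average, flat where degenerate)
makima_slopes <- function(x, y) {
  n <- length(x)
  d <- diff(y) / diff(x)
  if (n == 2L) return(rep(d, 2))
  d0 <- 2 * d[1] - d[2]
  dm1 <- 2 * d0 - d[1]
  dn <- 2 * d[n - 1] - d[n - 2]
  dn1 <- 2 * dn - d[n - 1]
  dd <- c(dm1, d0, d, dn, dn1)    # dd[i+2] = delta_i, i = -2 .. n+1
  m <- numeric(n)
  for (i in seq_len(n)) {
    dA <- dd[i]; dB <- dd[i + 1]; dC <- dd[i + 2]; dD <- dd[i + 3]
    w1 <- abs(dD - dC) + abs(dD + dC) / 2
    w2 <- abs(dB - dA) + abs(dB + dA) / 2
    m[i] <- if (w1 + w2 == 0) 0 else (w1 * dB + w2 * dC) / (w1 + w2)
  }
  m
}

# modified Akima cubic Hermite interpolation of (x, y) at xout
makima_interp <- function(x, y, xout) {
  stats::splinefunH(x, y, makima_slopes(x, y))(xout)
}

#' Instantaneous heart rate from R-wave times
#'
#' @param r_wave_times_ms strictly increasing R-wave times (ms); at least 2.
#' @param ibi_range_ms open interval of retained IBIs; boundary values are
#'   rejected (default \code{c(250, 1500)}).
#' @return An object of class \code{heart_series}: \code{ibi} data.frame
#'   (\code{t_ms} = time of the interval's closing beat, \code{ibi_ms},
#'   \code{hr_bpm}, \code{ok}), \code{grid_start_ms}, \code{hr_grid}
#'   (1-ms-resolution BPM over the retained record), and
#'   \code{artifact_mask} (two-column matrix of rejected spans, ms).
#' @export
instantaneous_hr <- function(r_wave_times_ms, ibi_range_ms = c(250, 1500)) {
  t <- as.numeric(r_wave_times_ms)
  if (length(t) < 2L) stop_load("instantaneous_hr: need >= 2 R waves")
  ibi <- diff(t)
  ok <- ibi > ibi_range_ms[1] & ibi < ibi_range_ms[2]
  if (!any(ok)) stop_load("instantaneous_hr: all beats rejected")
  d <- data.frame(t_ms = t[-1], ibi_ms = ibi, hr_bpm = 60000 / ibi, ok = ok)
  nodes_t <- d$t_ms[ok]
  nodes_v <- d$hr_bpm[ok]
  grid_start <- ceiling(nodes_t[1])
  grid_end <- floor(nodes_t[length(nodes_t)])
  xout <- seq(grid_start, grid_end)
  hr_grid <- if (length(nodes_t) >= 2L) makima_interp(nodes_t, nodes_v, xout)
             else rep(nodes_v, length(xout))
  mask <- if (any(!ok)) cbind(t[-length(t)][!ok], t[-1][!ok])
          else matrix(numeric(0), ncol = 2)
  structure(list(ibi = d, grid_start_ms = grid_start, hr_grid = hr_grid,
                 artifact_mask = interval_union(mask)),
            class = "heart_series")
}

#' @export
print.heart_series <- function(x, ...) {
  cat(sprintf("<heart_series> %d IBIs (%d rejected), grid %.1f-%.1f s\n",
              nrow(x$ibi), sum(!x$ibi$ok), x$grid_start_ms / 1000,
              (x$grid_start_ms + length(x$hr_grid) - 1) / 1000))
  invisible(x)
}

#' HR values on the 1-ms grid inside a half-open span
#'
#' @param hs a \code{\link{heart_series}}.
#' @param a,b span bounds, ms; clipped to the interpolated record.
#' @return numeric vector of BPM values (possibly empty).
#' @export
hr_in_span <- function(hs, a, b) {
  i0 <- max(a, hs$grid_start_ms) - hs$grid_start_ms + 1
  i1 <- min(b, hs$grid_start_ms + length(hs$hr_grid)) - hs$grid_start_ms
  if (i1 < i0) return(numeric(0))
  hs$hr_grid[i0:i1]
}

#' Mean heart rate per block kind and paired comparison across sessions
#'
#' @param sessions list; each element a list with a \code{heart_series}
#'   \code{hs} and a blocks data.frame \code{blocks}.
#' @return list with \code{per_session} data.frame (mean BPM in airflow and
#'   grooming blocks per session), \code{mean_airflow}, \code{mean_grooming},
#'   and \code{p} (paired t across sessions; \code{NA} with a single session,
#'   descriptive only).
#' @export
block_hr_comparison <- function(sessions) {
  per <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    hs <- sessions[[i]]$hs; b <- sessions[[i]]$blocks
    km <- vapply(c("airflow", "grooming"), function(k) {
      sp <- b[b$kind == k, , drop = FALSE]
      v <- unlist(lapply(seq_len(nrow(sp)), function(j)
        hr_in_span(hs, sp$start_ms[j], sp$end_ms[j])))
      mean(v)
    }, 0)
    data.frame(session = i, airflow_bpm = km[["airflow"]],
               grooming_bpm = km[["grooming"]])
  }))
  d <- per$grooming_bpm - per$airflow_bpm
  p <- if (nrow(per) < 2L) NA_real_
       else if (stats::sd(d) == 0) { if (mean(d) == 0) 1 else 0 }
       else stats::t.test(per$grooming_bpm, per$airflow_bpm, paired = TRUE)$p.value
  list(per_session = per, mean_airflow = mean(per$airflow_bpm),
       mean_grooming = mean(per$grooming_bpm), mean_difference = mean(d),
       p = p)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal
#' commuting matrix; tapers are orthonormal, ordered by concentration, with
#' the conventional sign (non-negative mean for even orders, positive
#' initial slope for odd orders).
#'
#' @param n samples per window.
#' @param nw time-bandwidth product.
#' @param k number of tapers (default \code{2 * nw - 1}).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n > k, nw > 0, k >= 1)
  w <- nw / n
  i <- seq_len(n) - 1
  md <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  od <- i[-1] * (n - i[-1]) / 2
  A <- diag(md)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2 == 1) { if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j] }
    else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper heart-rate spectrogram
#'
#' The 1-ms HR series is resampled to \code{fs} Hz (4 Hz by default: the
#' analysis band ends at 0.5 Hz, so a low even sampling rate suffices),
#' mean-removed per window, and the PSD in each 60-s window is the average
#' of the \code{k} Slepian-tapered periodograms.
#'
#' @param hs a \code{\link{heart_series}}.
#' @param window_s,step_s window length and step, s (60 / 3).
#' @param nw,k taper parameters (4 / 7, giving half-bandwidth
#'   \code{nw / window_s} of about 0.067 Hz).
#' @param fs analysis sampling rate, Hz.
#' @return An object of class \code{hr_spectrogram}: \code{window_center_s}
#'   (absolute, s), \code{freq_hz}, \code{psd} (windows x frequencies
#'   matrix), \code{half_bandwidth_hz}. Empty (zero windows) when the record
#'   is shorter than one window.
#' @export
hr_spectrogram <- function(hs, window_s = 60, step_s = 3, nw = 4, k = 7,
                           fs = 4) {
  x <- hs$hr_grid[seq(1, length(hs$hr_grid), by = round(1000 / fs))]
  n <- round(window_s * fs)
  step <- round(step_s * fs)
  starts <- if (length(x) >= n) seq(1, length(x) - n + 1, by = step)
            else integer(0)
  freq <- (0:(n %/% 2)) * fs / n
  if (!length(starts))
    return(structure(list(window_center_s = numeric(0), freq_hz = freq,
                          psd = matrix(numeric(0), ncol = length(freq)),
                          half_bandwidth_hz = nw / window_s),
                     class = "hr_spectrogram"))
  tap <- dpss_tapers(n, nw, k)
  psd <- t(vapply(starts, function(s0) {
    seg <- x[s0:(s0 + n - 1)]
    seg <- seg - mean(seg)
    sp <- vapply(seq_len(k), function(j) {
      X <- stats::fft(seg * tap[, j])
      (Mod(X)^2 / fs)[seq_along(freq)]
    }, numeric(length(freq)))
    rowMeans(sp)
  }, numeric(length(freq))))
  centers <- (hs$grid_start_ms / 1000) + (starts - 1) / fs + window_s / 2
  structure(list(window_center_s = centers, freq_hz = freq, psd = psd,
                 half_bandwidth_hz = nw / window_s),
            class = "hr_spectrogram")
}

#' RSA strength over time
#'
#' Per window, the largest local spectral maximum between \code{band[1]} and
#' \code{band[2]} Hz (respiratory rates of 15--30 breaths/min; ties broken
#' toward lower frequency) defines the RSA peak; strength is the mean PSD
#' over peak +/- \code{half_width}. Windows without an in-band local maximum
#' fall back to the band mean with the peak flagged absent. Strengths are
#' normalized as \code{(strength - mu) / mu} with \code{mu} the median
#' strength across windows.
#'
#' @param sg an \code{\link{hr_spectrogram}}.
#' @param band frequency band searched for the peak, Hz.
#' @param half_width averaging half-width around the peak, Hz (default: the
#'   spectrogram's smoothing half-bandwidth).
#' @return data.frame (class \code{rsa_series}): \code{window_center_s},
#'   \code{peak_freq_hz} (\code{NA} when absent), \code{strength},
#'   \code{rsa_norm}.
#' @export
rsa_strength <- function(sg, band = c(0.25, 0.5), half_width = NULL) {
  if (!nrow(sg$psd)) stop_load("rsa_strength: empty spectrogram")
  half_width <- half_width %||% sg$half_bandwidth_hz
  f <- sg$freq_hz
  inband <- which(f >= band[1] & f <= band[2])
  rows <- lapply(seq_len(nrow(sg$psd)), function(i) {
    p <- sg$psd[i, ]
    locmax <- inband[vapply(inband, function(j) {
      lo <- if (j > 1) p[j] > p[j - 1] else TRUE
      hi <- if (j < length(p)) p[j] >= p[j + 1] else TRUE
      lo && hi
    }, TRUE)]
    if (length(locmax)) {
      pk <- locmax[order(-p[locmax], f[locmax])][1]
      sel <- abs(f - f[pk]) <= half_width
      data.frame(window_center_s = sg$window_center_s[i],
                 peak_freq_hz = f[pk], strength = mean(p[sel]))
    } else {
      data.frame(window_center_s = sg$window_center_s[i],
                 peak_freq_hz = NA_real_, strength = mean(p[inband]))
    }
  })
  out <- do.call(rbind, rows)
  mu <- stats::median(out$strength)
  out$rsa_norm <- if (mu == 0) 0 else (out$strength - mu) / mu
  class(out) <- c("rsa_series", class(out))
  out
}

#' Auto-select a stable heart-rate period within grooming blocks
#'
#' Takes the longest artifact-free span within the grooming blocks, clipped
#' to \code{max_min} minutes, then refines once by dropping milliseconds
#' whose HR lies more than 2 SD from the span's own mean (so a transient
#' tachycardia inside the span does not inflate the reference statistics).
#'
#' @param hs a \code{\link{heart_series}}.
#' @param groom_spans two-column matrix of grooming block spans (ms).
#' @param min_min,max_min minimum / maximum stable-period duration, minutes.
#' @return list with \code{span} (start, end ms), \code{mean_bpm},
#'   \code{sd_bpm}.
#' @export
find_stable_period <- function(hs, groom_spans, min_min = 1, max_min = 20) {
  rec <- c(hs$grid_start_ms, hs$grid_start_ms + length(hs$hr_grid))
  best <- NULL
  for (i in seq_len(nrow(groom_spans))) {
    a <- max(groom_spans[i, 1], rec[1]); b <- min(groom_spans[i, 2], rec[2])
    if (b <= a) next
    kept <- interval_subtract(a, b, hs$artifact_mask)
    for (j in seq_len(nrow(kept)))
      if (is.null(best) || diff(kept[j, ]) > diff(best)) best <- kept[j, ]
  }
  if (is.null(best) || diff(best) < min_min * 60000)
    stop_load("find_stable_period: no artifact-free grooming span of %.0f min",
              min_min)
  if (diff(best) > max_min * 60000) best[2] <- best[1] + max_min * 60000
  v <- hr_in_span(hs, best[1], best[2])
  keep <- abs(v - mean(v)) <= 2 * stats::sd(v)
  v2 <- if (sum(keep) >= 1000) v[keep] else v
  list(span = best, mean_bpm = mean(v2), sd_bpm = stats::sd(v2))
}

#' Detect high-heart-rate episodes during grooming
#'
#' Maximal contiguous spans within grooming blocks during which HR exceeds
#' the stable-period mean by more than \code{sd_mult} SD, lasting at least
#' \code{min_dur_ms}.
#'
#' @param hs a \code{\link{heart_series}}.
#' @param groom_spans two-column matrix of grooming block spans (ms).
#' @param stable list as returned by \code{\link{find_stable_period}}, or
#'   \code{NULL} to auto-select.
#' @param sd_mult threshold multiplier (default 2).
#' @param min_dur_ms minimum episode duration (default 10000).
#' @return data.frame (class \code{hr_episodes}): \code{start_ms},
#'   \code{end_ms}, \code{mean_hr_bpm}; attributes \code{threshold_bpm},
#'   \code{stable}.
#' @export
detect_high_hr_episodes <- function(hs, groom_spans, stable = NULL,
                                    sd_mult = 2, min_dur_ms = 10000) {
  stable <- stable %||% find_stable_period(hs, groom_spans)
  thr <- stable$mean_bpm + sd_mult * stable$sd_bpm
  eps <- list()
  for (i in seq_len(nrow(groom_spans))) {
    a <- max(groom_spans[i, 1], hs$grid_start_ms)
    b <- min(groom_spans[i, 2], hs$grid_start_ms + length(hs$hr_grid))
    if (b <= a) next
    v <- hr_in_span(hs, a, b)
    r <- rle(v > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_dur_ms)
    for (j in hit) {
      s <- a + starts[j] - 1; e <- a + ends[j]
      eps[[length(eps) + 1L]] <- data.frame(
        start_ms = s, end_ms = e, mean_hr_bpm = mean(v[starts[j]:ends[j]]))
    }
  }
  out <- if (length(eps)) do.call(rbind, eps) else
    data.frame(start_ms = numeric(), end_ms = numeric(),
               mean_hr_bpm = numeric())
  rownames(out) <- NULL
  attr(out, "threshold_bpm") <- thr
  attr(out, "stable") <- stable
  class(out) <- c("hr_episodes", class(out))
  out
}

#' Grooming responsivity restricted to high-heart-rate episodes
#'
#' Applies the standard pre/post response test using only grooming sweeps
#' whose onsets fall inside detected episodes.
#'
#' @param train a \code{\link{spike_train}}.
#' @param events grooming event rows.
#' @param episodes an \code{\link{detect_high_hr_episodes}} result.
#' @param min_trials sweeps required inside episodes (default 10).
#' @return The \code{response_test} row, or a list
#'   \code{list(status = "insufficient_data", n_trials = ...)} when too few
#'   sweeps fall within episodes.
#' @export
grooming_response_during_episodes <- function(train, events, episodes,
                                              min_trials = 10) {
  ev <- events[events$modality == "grooming", , drop = FALSE]
  if (nrow(episodes)) {
    inside <- vapply(ev$onset_ms, function(t)
      any(t >= episodes$start_ms & t < episodes$end_ms), TRUE)
    ev <- ev[inside, , drop = FALSE]
  } else ev <- ev[0, , drop = FALSE]
  if (nrow(ev) < min_trials)
    return(list(status = "insufficient_data", n_trials = nrow(ev)))
  # pool across groomed locations: episode-restricted trials are scarce
  ev$location <- ev$location[1]
  test_stimulus_response(train, ev)
}
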