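#' @title Stimulus responsivity
#'
#' @description
#' A unit enters the analysis if its average firing rate across the
#' experiment is at least 1 Hz and at least 10 trials exist at every
#' stimulated location while the unit is flagged stable. A stimulus-induced
#' response at one location/modality is a significant paired t test (p <
#' 0.05, two-sided) between per-trial pre-stimulus rates (window 1000--250 ms
#' before onset) and post-stimulus rates (200 ms after onset to stimulus
#' end), with the mean rate change at least 1 Hz in magnitude. The
#' airflow-vs-grooming comparison considers airflow responses only at
#' locations that were also groomed; sham (auditory/alerting control)
#' responses are assessed separately and never pooled with airflow.
#'
#' @name responsivity
NULL

#' Unit inclusion rule
#'
#' @param train a \code{\link{spike_train}}.
#' @param events session event table.
#' @param extent_ms session extent in ms.
#' @param min_rate_hz minimum average rate across the experiment (default 1).
#' @param min_trials minimum trials per stimulated location (default 10).
#' @return \code{TRUE} iff the unit passes the rate floor, the per-location
#'   trial counts, and its stability flag.
#' @export
unit_inclusion <- function(train, events, extent_ms,
                           min_rate_hz = 1, min_trials = 10) {
  mean_rate <- length(train$spike_times_ms) / (extent_ms / 1000)
  if (mean_rate < min_rate_hz) return(FALSE)
  if (!isTRUE(train$stable)) return(FALSE)
  if (nrow(events)) {
    counts <- table(paste(events$modality, events$location))
    if (any(counts < min_trials)) return(FALSE)
  }
  TRUE
}

#' Test for a stimulus-induced response
#'
#' Paired two-sided t test across trials of mean pre-stimulus vs
#' post-stimulus firing rate (Hz). The post window runs to each stimulus'
#' own offset, so variable grooming sweep durations give variable windows and
#' rates, not counts, are compared.
#'
#' @param train a \code{\link{spike_train}}.
#' @param events event rows for one location/modality (>= 10 required).
#' @param alpha significance level (default 0.05).
#' @param min_delta_hz minimum absolute rate change (default 1 Hz).
#' @return A one-row data.frame (class \code{response_test}): \code{unit_id},
#'   \code{modality}, \code{location}, \code{n_trials}, \code{mean_pre_hz},
#'   \code{mean_post_hz}, \code{delta_hz}, \code{p_value},
#'   \code{responsive}.
#' @export
test_stimulus_response <- function(train, events, alpha = 0.05,
                                   min_delta_hz = 1) {
  if (nrow(events) < 10)
    stop_load("test_stimulus_response: %d events, need >= 10", nrow(events))
  if (length(unique(events$modality)) != 1L ||
      length(unique(events$location)) != 1L)
    stop_load("test_stimulus_response: events must share one location/modality")
  sp <- train$spike_times_ms
  pre <- mapply(function(on, off) window_rate_hz(sp, on - 1000, on - 250),
                events$onset_ms, events$offset_ms)
  post <- mapply(function(on, off) window_rate_hz(sp, on + 200, off),
                 events$onset_ms, events$offset_ms)
  d <- post - pre
  delta <- mean(d)
  p <- if (stats::sd(d) == 0) {
    if (delta == 0) 1 else 0   # constant nonzero shift: trivially significant
  } else stats::t.test(post, pre, paired = TRUE)$p.value
  out <- data.frame(
    unit_id = train$unit_id, modality = events$modality[1],
    location = events$location[1], n_trials = nrow(events),
    mean_pre_hz = mean(pre), mean_post_hz = mean(post), delta_hz = delta,
    p_value = p, responsive = (p < alpha) && (abs(delta) >= min_delta_hz))
  class(out) <- c("response_test", class(out))
  out
}

#' Run the response test at every (modality, location) of a session
#'
#' @param s an \code{amyg_session}.
#' @param train a \code{\link{spike_train}}.
#' @param min_trials locations with fewer events are skipped.
#' @inheritParams test_stimulus_response
#' @return data.frame of stacked \code{\link{test_stimulus_response}} rows.
#' @export
test_all_responses <- function(s, train, alpha = 0.05, min_delta_hz = 1,
                               min_trials = 10) {
  ev <- s$events
  keys <- unique(ev[c("modality", "location")])
  keys <- keys[order(keys$modality, keys$location), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ev[ev$modality == keys$modality[i] & ev$location == keys$location[i], ]
    if (nrow(sub) < min_trials) return(NULL)
    test_stimulus_response(train, sub, alpha, min_delta_hz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify tactile responsivity of one unit
#'
#' The airflow-vs-grooming label considers airflow responses only at groomed
#' locations: \code{both} if at least one groomed location is responsive
#' under each modality, else \code{airflow_only} / \code{grooming_only} /
#' \code{none}. Sham responsivity is reported separately.
#'
#' @param tests data.frame of response tests for one unit
#'   (\code{\link{test_all_responses}}).
#' @param groomed_locations integer location ids that received grooming.
#' @return A one-row data.frame: \code{unit_id}, \code{label},
#'   \code{sham_responsive}.
#' @export
classify_tactile_responsivity <- function(tests, groomed_locations) {
  stopifnot(nrow(tests) > 0)
  gl <- tests[tests$location %in% groomed_locations, , drop = FALSE]
  for (m in c("airflow", "grooming"))
    if (!any(gl$modality == m))
      stop_load("unit %s: no %s tests at groomed locations", tests$unit_id[1], m)
  air <- any(gl$responsive[gl$modality == "airflow"])
  grm <- any(gl$responsive[gl$modality == "grooming"])
  label <- if (air && grm) "both" else if (air) "airflow_only"
           else if (grm) "grooming_only" else "none"
  sham <- tests$responsive[tests$modality == "sham"]
  data.frame(unit_id = tests$unit_id[1], label = label,
             sham_responsive = if (length(sham)) any(sham) else NA)
}

#' Chi-squared comparison of two responsive proportions
#'
#' 2x2 chi-squared test of proportions without continuity correction (a
#' documented flag restores Yates' correction).
#'
#' @param k1,n1 responsive count and total in condition 1.
#' @param k2,n2 same for condition 2.
#' @param correct apply Yates' continuity correction (default \code{FALSE}).
#' @return list with \code{chi2}, \code{p}, \code{prop1}, \code{prop2}.
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (k1 / n1 == k2 / n2) return(list(chi2 = 0, p = 1, prop1 = k1 / n1,
                                      prop2 = k2 / n2))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = ht$p.value,
       prop1 = k1 / n1, prop2 = k2 / n2)
}
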