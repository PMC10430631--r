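#' @title Session data model
#'
#' @description
#' A recording session couples an experimental block schedule (alternating
#' airflow and grooming blocks, optionally airflow with the groomer present),
#' a stimulus event table, per-unit spike trains, and an optional EKG R-wave
#' train. All times are integer milliseconds from session start and all
#' intervals are half-open \code{[start, end)}, so a spike at a bin edge is
#' never counted twice.
#'
#' @name session-model
NULL

BLOCK_KINDS <- c("airflow", "grooming", "airflow_groomer_present")
MODALITIES  <- c("airflow", "grooming", "sham")
REGIONS     <- c("amygdala", "SI")
SHAM_LOCATION <- 11L

#' Construct a spike train
#'
#' Spike times are rounded to the nearest millisecond and duplicate
#' post-rounding times are collapsed to a single spike (a real neuron's
#' refractory period makes 1-ms duplicates implausible); the stored train is
#' strictly increasing.
#'
#' @param unit_id character unit label, unique within a session.
#' @param region \code{"amygdala"} or \code{"SI"} (primary somatosensory
#'   cortex).
#' @param spike_times_ms numeric vector of spike times in ms from session
#'   start.
#' @param stable logical; sorting-QC stability flag supplied by the user
#'   (defaults to \code{TRUE}).
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(unit_id, region, spike_times_ms, stable = TRUE) {
  region <- match.arg(region, REGIONS)
  t <- sort(unique(round(as.numeric(spike_times_ms))))
  if (length(t) && t[1] < 0)
    stop("spike_train '", unit_id, "': negative spike times", call. = FALSE)
  structure(
    list(unit_id = as.character(unit_id), region = region,
         spike_times_ms = t, stable = isTRUE(stable)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s] %d spikes, stable=%s\n",
              x$unit_id, x$region, length(x$spike_times_ms), x$stable))
  invisible(x)
}

#' Assemble and validate a session
#'
#' @param session_id character identifier.
#' @param blocks data.frame with columns \code{block_id}, \code{kind}
#'   (one of \code{"airflow"}, \code{"grooming"},
#'   \code{"airflow_groomer_present"}), \code{start_ms}, \code{end_ms}.
#' @param events data.frame with columns \code{event_id}, \code{block_id},
#'   \code{modality}, \code{location} (1--11; 11 is the sham nozzle),
#'   \code{onset_ms}, \code{offset_ms}.
#' @param rewards data.frame with columns \code{block_id}, \code{start_ms},
#'   \code{end_ms}; may have zero rows.
#' @param units list of \code{\link{spike_train}} objects.
#' @param heart optional numeric vector of R-wave times in ms (strictly
#'   increasing), or \code{NULL}.
#' @param metadata free-form named list (monkey id, generator config, seed).
#' @return A validated object of class \code{amyg_session}.
#' @export
session <- function(session_id, blocks, events, rewards = NULL,
                    units = list(), heart = NULL, metadata = list()) {
  if (is.null(rewards))
    rewards <- data.frame(block_id = integer(), start_ms = numeric(),
                          end_ms = numeric())
  s <- structure(
    list(session_id = as.character(session_id),
         blocks = as.data.frame(blocks), events = as.data.frame(events),
         rewards = as.data.frame(rewards), units = units, heart = heart,
         metadata = metadata),
    class = "amyg_session")
  names(s$units) <- vapply(s$units, `[[`, "", "unit_id")
  validate_session(s)
  s
}

#' Session extent in ms (end of the last block)
#' @param s an \code{amyg_session}.
#' @return numeric scalar, ms.
#' @export
session_extent_ms <- function(s) max(s$blocks$end_ms)

#' Validate session invariants
#'
#' Checks block ordering and non-overlap, event/block containment, stimulus
#' duration ranges, the sham location convention, spike-train monotonicity and
#' extent, and R-wave monotonicity. Called by \code{\link{session}} and
#' \code{\link{read_session}}.
#'
#' @param s an \code{amyg_session}.
#' @return \code{s}, invisibly; errors name the offending record.
#' @export
validate_session <- function(s) {
  b <- s$blocks
  need <- c("block_id", "kind", "start_ms", "end_ms")
  if (!all(need %in% names(b))) stop_load("blocks: missing columns")
  if (anyDuplicated(b$block_id)) stop_load("blocks: duplicate block_id")
  if (!all(b$kind %in% BLOCK_KINDS))
    stop_load("blocks: unknown kind '%s'", setdiff(b$kind, BLOCK_KINDS)[1])
  if (any(b$end_ms <= b$start_ms))
    stop_load("block %s: end_ms <= start_ms", b$block_id[b$end_ms <= b$start_ms][1])
  if (nrow(b) > 1L) {
    o <- order(b$start_ms)
    if (!identical(o, seq_len(nrow(b))))
      stop_load("blocks: not time-ordered")
    if (any(b$start_ms[-1] < b$end_ms[-nrow(b)]))
      stop_load("blocks: overlapping blocks")
  }
  ev <- s$events
  need <- c("event_id", "block_id", "modality", "location", "onset_ms", "offset_ms")
  if (!all(need %in% names(ev))) stop_load("events: missing columns")
  if (nrow(ev)) {
    if (!all(ev$modality %in% MODALITIES))
      stop_load("events: unknown modality")
    bad <- ev$offset_ms <= ev$onset_ms
    if (any(bad)) stop_load("event %s: offset_ms <= onset_ms", ev$event_id[bad][1])
    if (!all(ev$location %in% 1:11)) stop_load("events: location outside 1-11")
    if (any((ev$location == SHAM_LOCATION) != (ev$modality == "sham")))
      stop_load("events: location 11 must pair with modality sham (and only it)")
    dur <- ev$offset_ms - ev$onset_ms
    bad <- (ev$modality %in% c("airflow", "sham") & (dur < 1000 | dur > 1500)) |
           (ev$modality == "grooming" & (dur < 1000 | dur > 2000))
    if (any(bad))
      stop_load("event %s: duration %d ms outside allowed range",
                ev$event_id[bad][1], as.integer(dur[bad][1]))
    idx <- match(ev$block_id, b$block_id)
    if (anyNA(idx)) stop_load("event %s: unresolved block_id",
                              ev$event_id[is.na(idx)][1])
    bad <- ev$onset_ms < b$start_ms[idx] | ev$offset_ms > b$end_ms[idx]
    if (any(bad)) stop_load("event %s: outside its block", ev$event_id[bad][1])
  }
  rw <- s$rewards
  if (nrow(rw)) {
    idx <- match(rw$block_id, b$block_id)
    if (anyNA(idx)) stop_load("rewards: unresolved block_id")
    bad <- rw$end_ms <= rw$start_ms | rw$start_ms < b$start_ms[idx] |
      rw$end_ms > b$end_ms[idx]
    if (any(bad)) stop_load("rewards row %d: window outside its block",
                            which(bad)[1])
  }
  ext <- session_extent_ms(s)
  for (u in s$units) {
    if (!inherits(u, "spike_train")) stop_load("units: not a spike_train")
    t <- u$spike_times_ms
    if (length(t)) {
      if (is.unsorted(t, strictly = TRUE))
        stop_load("unit %s: spike times not strictly increasing", u$unit_id)
      if (t[1] < 0 || t[length(t)] > ext)
        stop_load("unit %s: spike times outside session extent", u$unit_id)
    }
  }
  if (!is.null(s$heart)) {
    h <- as.numeric(s$heart)
    if (length(h) > 1L && is.unsorted(h, strictly = TRUE))
      stop_load("heart: R-wave times not strictly increasing")
  }
  invisible(s)
}

#' @export
print.amyg_session <- function(x, ...) {
  cat(sprintf(
    "<amyg_session> %s: %d blocks (%s), %d events, %d units, %s R waves\n",
    x$session_id, nrow(x$blocks), paste(x$blocks$kind, collapse = "-"),
    nrow(x$events), length(x$units),
    if (is.null(x$heart)) "no" else format(length(x$heart))))
  invisible(x)
}

#' Block ids used for the four-block context analysis
#'
#' The context analysis requires two airflow and two grooming blocks in
#' alternation; when a session has three airflow blocks the first two airflow
#' and first two grooming blocks are used and the remaining block is reserved
#' for control analyses.
#'
#' @param s an \code{amyg_session}.
#' @return Integer block ids in time order, or an error if fewer than two
#'   blocks of either kind exist.
#' @export
analysis_block_ids <- function(s) {
  b <- s$blocks
  air <- b$block_id[b$kind == "airflow"]
  grm <- b$block_id[b$kind == "grooming"]
  if (length(air) < 2L || length(grm) < 2L)
    stop_load("session %s: context analysis needs >= 2 airflow and >= 2 grooming blocks",
              s$session_id)
  sort(c(air[1:2], grm[1:2]))
}
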