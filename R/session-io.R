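#' @title Session directory input / output
#'
#' @description
#' Sessions are stored as a plain-text directory: `blocks.csv`, `rewards.csv`,
#' `events.csv`, `spikes.csv` (long format), `rwaves.csv`, and `meta.json`
#' (session id, per-unit region/stability table, free-form metadata). Output
#' is deterministic: fixed column order, integer millisecond times, LF line
#' endings, so identical sessions always produce byte-identical files.
#'
#' @name session-io
NULL

SESSION_FILES <- c("blocks.csv", "rewards.csv", "events.csv", "spikes.csv",
                   "rwaves.csv", "meta.json")

fmt_int <- function(x) format(as.numeric(x), scientific = FALSE, trim = TRUE)

write_flat_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_int)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
}

#' Write a session to a directory
#'
#' @param s a validated \code{amyg_session}.
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_session}}
#' @export
write_session <- function(s, path) {
  validate_session(s)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop_load("cannot create directory '%s'", path)
  write_flat_csv(s$blocks[c("block_id", "kind", "start_ms", "end_ms")],
                 file.path(path, "blocks.csv"))
  write_flat_csv(s$rewards[c("block_id", "start_ms", "end_ms")],
                 file.path(path, "rewards.csv"))
  write_flat_csv(
    s$events[c("event_id", "block_id", "modality", "location", "onset_ms",
               "offset_ms")],
    file.path(path, "events.csv"))
  spikes <- if (length(s$units)) {
    do.call(rbind, lapply(s$units, function(u)
      data.frame(unit_id = rep(u$unit_id, length(u$spike_times_ms)),
                 region = rep(u$region, length(u$spike_times_ms)),
                 spike_time_ms = u$spike_times_ms)))
  } else NULL
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(), region = character(),
                         spike_time_ms = numeric())
  rownames(spikes) <- NULL
  write_flat_csv(spikes, file.path(path, "spikes.csv"))
  write_flat_csv(
    data.frame(r_wave_time_ms = as.numeric(s$heart %||% numeric(0))),
    file.path(path, "rwaves.csv"))
  meta <- list(
    session_id = s$session_id,
    units = lapply(unname(s$units), function(u)
      list(unit_id = u$unit_id, region = u$region, stable = u$stable)),
    has_heart = !is.null(s$heart),
    metadata = s$metadata)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(path, "meta.json"), useBytes = TRUE)
  invisible(path)
}

read_flat_csv <- function(path) {
  if (!file.exists(path)) stop_load("missing session file '%s'", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a session from a directory
#'
#' Reads the documented CSV/JSON layout and returns a fully validated
#' \code{amyg_session}; a missing file raises a load error naming the file and
#' any invariant violation raises a validation error naming the offending
#' record.
#'
#' @param path directory written by \code{\link{write_session}}.
#' @return An \code{amyg_session}.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop_load("session directory '%s' not found", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_load("missing session file '%s'", meta_path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
  blocks <- read_flat_csv(file.path(path, "blocks.csv"))
  rewards <- read_flat_csv(file.path(path, "rewards.csv"))
  events <- read_flat_csv(file.path(path, "events.csv"))
  spikes <- read_flat_csv(file.path(path, "spikes.csv"))
  rwaves <- read_flat_csv(file.path(path, "rwaves.csv"))
  units <- lapply(meta$units, function(u) {
    t <- spikes$spike_time_ms[spikes$unit_id == u$unit_id]
    spike_train(u$unit_id, u$region, t, stable = isTRUE(u$stable))
  })
  heart <- if (isTRUE(meta$has_heart)) as.numeric(rwaves$r_wave_time_ms)
           else NULL
  session(meta$session_id, blocks, events, rewards, units, heart,
          metadata = meta$metadata %||% list())
}
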