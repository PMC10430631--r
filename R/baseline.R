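#' @title Baseline activity and context classification
#'
#' @description
#' Baseline activity is the spiking between stimuli: block time minus a
#' 300-ms buffered window around every stimulus, minus reward windows, minus
#' inter-block intervals. The kept segments are concatenated per block and
#' cut into consecutive full 1-s bins (trailing partial bins dropped); bin
#' rates are spike counts per bin. For the context analysis each unit needs
#' at least 60 such bins in each of two airflow and two grooming blocks in
#' alternation. Context-related modulation is quantified by Cohen's
#' \eqn{d_s} for independent samples between pooled grooming and pooled
#' airflow bins, controlled against within-condition block-to-block
#' variability: a unit is context-related when \eqn{|d_s^{GA}| > 0.2} and
#' \eqn{|d_s^{GA}| \ge 1.5 \max(|d_s^{GG}|, |d_s^{AA}|)}.
#'
#' @name baseline-context
NULL

#' Baseline segments of one block
#'
#' @param s an \code{amyg_session}.
#' @param block_id block to extract.
#' @param buffer_ms buffer removed before and after each stimulus (300).
#' @return Two-column matrix of kept half-open intervals (ms).
#' @export
baseline_segments <- function(s, block_id, buffer_ms = 300) {
  b <- s$blocks[s$blocks$block_id == block_id, ]
  if (nrow(b) != 1L) stop_load("unknown block_id %s", block_id)
  ev <- s$events[s$events$block_id == block_id, , drop = FALSE]
  rw <- s$rewards[s$rewards$block_id == block_id, , drop = FALSE]
  cut <- rbind(
    if (nrow(ev)) cbind(ev$onset_ms - buffer_ms, ev$offset_ms + buffer_ms),
    if (nrow(rw)) cbind(rw$start_ms, rw$end_ms))
  interval_subtract(b$start_ms, b$end_ms, cut)
}

#' Extract 1-s baseline bins for one unit
#'
#' Kept segments are concatenated per block (segments shorter than 1 s
#' contribute jointly) and consecutive full 1-s bins are cut from the
#' concatenation; each bin's rate is the spike count falling in its (possibly
#' discontiguous) 1 s of timeline. Z-scores are computed per unit over the
#' retained bins of the four context-analysis blocks jointly (mean 0, SD 1
#' there) and applied to bins of any further blocks with the same
#' parameters.
#'
#' @param s an \code{amyg_session}.
#' @param train a \code{\link{spike_train}} (or a unit id present in
#'   \code{s}).
#' @param block_ids blocks to extract (default: all).
#' @param buffer_ms stimulus buffer, ms.
#' @return An object of class \code{baseline_series}: \code{unit_id} and a
#'   data.frame \code{bins} with \code{block_id}, \code{block_kind},
#'   \code{bin_index}, \code{rate_hz}, \code{z}.
#' @export
extract_baseline_bins <- function(s, train, block_ids = NULL,
                                  buffer_ms = 300) {
  if (is.character(train)) {
    if (is.null(s$units[[train]])) stop_load("unknown unit '%s'", train)
    train <- s$units[[train]]
  }
  block_ids <- block_ids %||% s$blocks$block_id
  sp <- train$spike_times_ms
  rows <- lapply(block_ids, function(bid) {
    seg <- baseline_segments(s, bid, buffer_ms)
    if (!nrow(seg)) return(NULL)
    off <- cumsum(c(0, utils::head(seg[, 2] - seg[, 1], -1)))
    total <- interval_total(seg)
    n_bins <- floor(total / 1000)
    if (n_bins < 1) return(NULL)
    # map each spike to its concatenated-baseline coordinate
    cc <- numeric(0)
    for (i in seq_len(nrow(seg))) {
      inseg <- sp[sp >= seg[i, 1] & sp < seg[i, 2]]
      if (length(inseg)) cc <- c(cc, off[i] + (inseg - seg[i, 1]))
    }
    counts <- tabulate(floor(cc / 1000) + 1L, nbins = n_bins)
    data.frame(block_id = bid,
               block_kind = s$blocks$kind[s$blocks$block_id == bid],
               bin_index = seq_len(n_bins), rate_hz = counts)
  })
  bins <- do.call(rbind, rows)
  if (is.null(bins))
    bins <- data.frame(block_id = integer(), block_kind = character(),
                       bin_index = integer(), rate_hz = numeric())
  rownames(bins) <- NULL
  zref <- tryCatch(analysis_block_ids(s), error = function(e) block_ids)
  ref <- bins$rate_hz[bins$block_id %in% zref]
  if (length(ref) < 2L || stats::sd(ref) == 0) {
    bins$z <- rep(NA_real_, nrow(bins))
  } else {
    bins$z <- (bins$rate_hz - mean(ref)) / stats::sd(ref)
  }
  structure(list(unit_id = train$unit_id, bins = bins),
            class = "baseline_series")
}

#' @export
print.baseline_series <- function(x, ...) {
  cat(sprintf("<baseline_series> %s: %d bins over %d blocks\n", x$unit_id,
              nrow(x$bins), length(unique(x$bins$block_id))))
  invisible(x)
}

#' Cohen's d for independent samples
#'
#' \deqn{d_s = (\bar x_1 - \bar x_2) /
#'   \sqrt{((n_1 - 1) SD_1^2 + (n_2 - 1) SD_2^2) / (n_1 + n_2 - 2)}}
#' with sample (n-1) standard deviations. Scale-invariant; zero pooled SD
#' with equal means returns 0, with unequal means it is undefined and raises.
#'
#' @param x1,x2 numeric samples, each of length >= 2.
#' @return numeric effect size.
#' @export
cohens_ds <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
               (n1 + n2 - 2))
  num <- mean(x1) - mean(x2)
  if (sp == 0) {
    if (num == 0) return(0)
    stop_load("cohens_ds: zero pooled SD with unequal means")
  }
  num / sp
}

#' Context label from the three effect sizes
#'
#' @param ds_ga grooming-vs-airflow effect size.
#' @param ds_gg grooming-block-1 vs grooming-block-2 effect size.
#' @param ds_aa airflow-block-1 vs airflow-block-2 effect size.
#' @param threshold minimum \eqn{|d_s^{GA}|} (default 0.2).
#' @param ratio required \eqn{|d_s^{GA}|} multiple of the largest
#'   within-condition effect size (default 1.5).
#' @return \code{"context_groom_up"}, \code{"context_groom_down"}, or
#'   \code{"not_context"}.
#' @export
context_label <- function(ds_ga, ds_gg, ds_aa, threshold = 0.2, ratio = 1.5) {
  within <- max(abs(ds_gg), abs(ds_aa))
  if (abs(ds_ga) > threshold && abs(ds_ga) >= ratio * within) {
    if (ds_ga > 0) "context_groom_up" else "context_groom_down"
  } else "not_context"
}

#' Classify context-related baseline modulation of one unit
#'
#' Computes \eqn{d_s^{GA}} over pooled grooming vs pooled airflow bins (raw
#' Hz; \eqn{d_s} is scale-invariant so Z-scoring would not change it),
#' \eqn{d_s^{GG}} between the two grooming blocks and \eqn{d_s^{AA}} between
#' the two airflow blocks, and applies the classification rule. Uses the
#' first two airflow and first two grooming blocks of the session.
#'
#' @param series a \code{\link{baseline_series}} (bins must cover the four
#'   analysis blocks).
#' @param s the \code{amyg_session} the series came from.
#' @param min_bins minimum bins required in each of the four blocks
#'   (default 60).
#' @inheritParams context_label
#' @return One-row data.frame (class \code{context_result}): \code{unit_id},
#'   \code{n_bins_a1}, \code{n_bins_g1}, \code{n_bins_a2}, \code{n_bins_g2},
#'   \code{ds_ga}, \code{ds_gg}, \code{ds_aa}, \code{label}; or \code{NULL}
#'   with a warning when a block has too few bins (the unit is excluded, not
#'   fatal).
#' @export
classify_context <- function(series, s, min_bins = 60, threshold = 0.2,
                             ratio = 1.5) {
  ids <- analysis_block_ids(s)
  bins <- series$bins[series$bins$block_id %in% ids, , drop = FALSE]
  per <- vapply(ids, function(b) sum(bins$block_id == b), 0L)
  if (any(per < min_bins)) {
    warning(sprintf("unit %s excluded: %d bins in block %d (< %d)",
                    series$unit_id, min(per), ids[which.min(per)], min_bins),
            call. = FALSE)
    return(NULL)
  }
  kind <- s$blocks$kind[match(ids, s$blocks$block_id)]
  air_ids <- ids[kind == "airflow"]; grm_ids <- ids[kind == "grooming"]
  r <- function(b) bins$rate_hz[bins$block_id %in% b]
  ds_ga <- cohens_ds(r(grm_ids), r(air_ids))
  ds_gg <- cohens_ds(r(grm_ids[1]), r(grm_ids[2]))
  ds_aa <- cohens_ds(r(air_ids[1]), r(air_ids[2]))
  out <- data.frame(
    unit_id = series$unit_id,
    n_bins_a1 = per[match(air_ids[1], ids)], n_bins_g1 = per[match(grm_ids[1], ids)],
    n_bins_a2 = per[match(air_ids[2], ids)], n_bins_g2 = per[match(grm_ids[2], ids)],
    ds_ga = ds_ga, ds_gg = ds_gg, ds_aa = ds_aa,
    label = context_label(ds_ga, ds_gg, ds_aa, threshold, ratio))
  class(out) <- c("context_result", class(out))
  out
}

#' Effect of groomer presence on baseline firing
#'
#' For units pre-split by context direction, compares per-unit mean baseline
#' rates (raw Hz, not Z) across three conditions — standard airflow (groomer
#' absent), airflow with the groomer present, and grooming — with paired t
#' tests on the two steps: groomer-present airflow minus standard airflow,
#' and grooming minus groomer-present airflow.
#'
#' @param series_list list of \code{\link{baseline_series}}, one per unit,
#'   extracted from sessions containing all three block kinds.
#' @param s the session (supplies block kinds).
#' @return list with per-condition mean rates per unit (\code{rates}), mean
#'   paired differences \code{step_present_vs_absent} and
#'   \code{step_groom_vs_present} (Hz), and the two paired-t p values.
#'   Errors when fewer than 2 units are supplied.
#' @export
groomer_presence_effect <- function(series_list, s) {
  if (length(series_list) < 2L)
    stop_load("groomer_presence_effect: need >= 2 units")
  cond_mean <- function(series, kind) {
    b <- series$bins[series$bins$block_kind == kind, , drop = FALSE]
    if (!nrow(b)) return(NA_real_)
    mean(b$rate_hz)
  }
  rates <- data.frame(
    unit_id = vapply(series_list, `[[`, "", "unit_id"),
    airflow = vapply(series_list, cond_mean, 0, kind = "airflow"),
    airflow_groomer_present =
      vapply(series_list, cond_mean, 0, kind = "airflow_groomer_present"),
    grooming = vapply(series_list, cond_mean, 0, kind = "grooming"))
  if (anyNA(rates[-1]))
    stop_load("groomer_presence_effect: a unit lacks bins in some condition")
  d1 <- rates$airflow_groomer_present - rates$airflow
  d2 <- rates$grooming - rates$airflow_groomer_present
  pt <- function(d) if (stats::sd(d) == 0) if (mean(d) == 0) 1 else 0
                    else stats::t.test(d)$p.value
  list(rates = rates,
       step_present_vs_absent = mean(d1), p_present_vs_absent = pt(d1),
       step_groom_vs_present = mean(d2), p_groom_vs_present = pt(d2))
}
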