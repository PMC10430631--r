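#' @title Pipeline orchestration
#'
#' @description
#' Runs simulate -> responsivity -> context -> decoding -> autonomic as one
#' reproducible pass over a session, writing CSV/JSON outputs and a summary.
#' Every random procedure receives an explicit seed derived from the run
#' seed, so two runs with the same configuration produce byte-identical
#' files. All p values are reported raw: no multiple-comparison correction
#' is applied anywhere in the pipeline.
#'
#' @name pipeline
NULL

#' Configure a pipeline run
#'
#' @param out_dir output directory.
#' @param seed run master seed (also the session seed when a session is
#'   generated).
#' @param session_config a \code{\link{session_config}}, or \code{NULL} to
#'   use \code{\link{demo_session_config}}.
#' @param session_dir read an existing session instead of generating one.
#' @param n_perm permutation count for single-unit nulls.
#' @param n_boot bootstrap draws per population set size.
#' @param set_sizes population sizes for the accuracy curve.
#' @param bins_per_block balanced bins per block for population decoding.
#' @param full restore the full resampling counts (10000 permutations and
#'   bootstrap draws) instead of the scaled-down defaults.
#' @param responsivity,context,decoding,autonomic stage toggles.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed, session_config = NULL,
                       session_dir = NULL, n_perm = 1000, n_boot = 500,
                       set_sizes = c(1, 2, 4, 8), bins_per_block = 60,
                       full = FALSE, responsivity = TRUE, context = TRUE,
                       decoding = TRUE, autonomic = TRUE) {
  if (full) { n_perm <- 10000; n_boot <- 10000 }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 session_config = session_config, session_dir = session_dir,
                 n_perm = n_perm, n_boot = n_boot, set_sizes = set_sizes,
                 bins_per_block = bins_per_block,
                 responsivity = responsivity, context = context,
                 decoding = decoding, autonomic = autonomic),
            class = "run_config")
}

#' Demonstration session configuration
#'
#' A compact standard session: three airflow-type blocks interleaved with
#' two grooming blocks (the final airflow block has the groomer present), 10
#' pseudo-random sets of the 11 airflow locations per airflow block, 3 sets
#' of 10 sweeps per groomed location per grooming block, a small mixed
#' population of amygdala units (tactile-responsive, context-modulated both
#' directions, and null), and an EKG with lower heart rate and deeper RSA
#' during grooming plus one injected 30-s tachycardia episode.
#'
#' @param seed master seed.
#' @return A \code{\link{session_config}}.
#' @export
demo_session_config <- function(seed) {
  units <- list(
    unit_spec("air1", baseline_hz = c(airflow = 6), gain_airflow = 12),
    unit_spec("air2", baseline_hz = c(airflow = 4), gain_airflow = 8),
    unit_spec("both1", baseline_hz = c(airflow = 5), gain_airflow = 10,
              gain_grooming = 8, response_shape = "ramp"),
    unit_spec("groom1", baseline_hz = c(airflow = 5), gain_grooming = 9,
              response_shape = "ramp"),
    unit_spec("ctx_up1", baseline_hz = c(airflow = 4, grooming = 7,
                                         airflow_groomer_present = 5.5)),
    unit_spec("ctx_up2", baseline_hz = c(airflow = 6, grooming = 9,
                                         airflow_groomer_present = 7.5)),
    unit_spec("ctx_down1", baseline_hz = c(airflow = 8, grooming = 5,
                                           airflow_groomer_present = 6.5)),
    unit_spec("null1", baseline_hz = c(airflow = 5)),
    unit_spec("null2", baseline_hz = c(airflow = 3)))
  session_config(
    block_kinds = c("airflow", "grooming", "airflow", "grooming",
                    "airflow_groomer_present"),
    groom_sets = 3,
    units = units,
    heart = heart_spec(
      mean_hr_bpm = c(airflow = 120, grooming = 108,
                      airflow_groomer_present = 116),
      rsa_depth = c(airflow = 0.02, grooming = 0.08,
                    airflow_groomer_present = 0.03),
      rsa_freq_hz = 0.3,
      episodes = data.frame(start_ms = 1300000, duration_ms = 30000,
                            delta_bpm = 30)),
    seed = seed, session_id = sprintf("demo-%d", seed))
}

write_out_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
}

#' Count the four-way overlap of context criteria
#'
#' Cross-tabulates effect-size context classification against SVM decoder
#' significance over the same units.
#'
#' @param context_df data.frame with \code{unit_id}, \code{label}.
#' @param decoding_df data.frame with \code{unit_id}, \code{significant}.
#' @return Named list \code{both}, \code{svm_only}, \code{effect_size_only},
#'   \code{neither}; the four counts partition the unit set.
#' @export
summarize_overlap <- function(context_df, decoding_df) {
  if (!setequal(context_df$unit_id, decoding_df$unit_id))
    stop_load("summarize_overlap: unit sets differ")
  m <- match(context_df$unit_id, decoding_df$unit_id)
  es <- context_df$label != "not_context"
  sv <- decoding_df$significant[m]
  list(both = sum(es & sv), svm_only = sum(!es & sv),
       effect_size_only = sum(es & !sv), neither = sum(!es & !sv))
}

#' Run the full pipeline
#'
#' Generates (or reads) the session, runs the enabled stages, writes
#' per-stage CSVs plus \code{summary.json} and \code{manifest.json} to the
#' output directory, and returns the summary invisibly. Excluded units are
#' recorded with their exclusion reason. Stage failures are propagated with
#' the stage name.
#'
#' @param rc a \code{\link{run_config}}.
#' @return The summary list, invisibly.
#' @export
run_all <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop_load("stage '%s' failed: %s", name, conditionMessage(e)))

  s <- stage("session", {
    if (!is.null(rc$session_dir)) read_session(rc$session_dir)
    else generate_session(rc$session_config %||% demo_session_config(rc$seed))
  })
  ext <- session_extent_ms(s)
  summary <- list(session_id = s$session_id, seed = rc$seed,
                  n_units = length(s$units))
  exclusions <- list()
  groomed <- sort(unique(s$events$location[s$events$modality == "grooming"]))

  if (rc$responsivity) stage("responsivity", {
    tests <- list(); labels <- list()
    for (u in s$units) {
      if (!unit_inclusion(u, s$events, ext)) {
        exclusions[[length(exclusions) + 1L]] <- list(
          unit_id = u$unit_id, stage = "responsivity",
          reason = "rate floor / trial count / stability")
        next
      }
      tt <- test_all_responses(s, u)
      tests[[length(tests) + 1L]] <- tt
      labels[[length(labels) + 1L]] <-
        classify_tactile_responsivity(tt, groomed)
    }
    tests <- do.call(rbind, tests)
    labels <- do.call(rbind, labels)
    write_out_csv(tests, file.path(rc$out_dir, "responses.csv"))
    write_out_csv(labels, file.path(rc$out_dir, "unit_labels.csv"))
    summary$responsivity <- list(
      n_included = nrow(labels),
      by_label = as.list(table(labels$label)),
      n_sham_responsive = sum(labels$sham_responsive, na.rm = TRUE))
  })

  series <- NULL; ctx <- NULL
  if (rc$context || rc$decoding) stage("context", {
    ids <- analysis_block_ids(s)
    series <- lapply(s$units, function(u) extract_baseline_bins(s, u))
    ctx_rows <- list()
    for (ser in series) {
      r <- withCallingHandlers(
        classify_context(ser, s),
        warning = function(w) {
          exclusions[[length(exclusions) + 1L]] <<- list(
            unit_id = ser$unit_id, stage = "context",
            reason = conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (!is.null(r)) ctx_rows[[length(ctx_rows) + 1L]] <- r
    }
    ctx <- do.call(rbind, ctx_rows)
    if (rc$context) {
      write_out_csv(ctx, file.path(rc$out_dir, "context.csv"))
      summary$context <- list(n_classified = nrow(ctx),
                               by_label = as.list(table(ctx$label)),
                               median_abs_ds_ga_context = {
        v <- abs(ctx$ds_ga[ctx$label != "not_context"])
        if (length(v)) stats::median(v) else NA })
      if (sum(s$blocks$kind == "airflow_groomer_present") > 0) {
        for (dir_label in c("context_groom_up", "context_groom_down")) {
          ids_dir <- ctx$unit_id[ctx$label == dir_label]
          if (length(ids_dir) >= 2) {
            gp <- groomer_presence_effect(series[ids_dir], s)
            summary$groomer_presence[[dir_label]] <- list(
              n = length(ids_dir),
              step_present_vs_absent_hz = gp$step_present_vs_absent,
              p_present_vs_absent = gp$p_present_vs_absent,
              step_groom_vs_present_hz = gp$step_groom_vs_present,
              p_groom_vs_present = gp$p_groom_vs_present)
          }
        }
      }
    }
  })

  if (rc$decoding) stage("decoding", {
    usable <- Filter(function(ser) {
      tb <- table(ser$bins$block_kind[ser$bins$block_kind %in%
                                        c("airflow", "grooming")])
      length(tb) == 2 && min(tb) >= 20
    }, series)
    dec <- do.call(rbind, lapply(usable, function(ser)
      decode_unit(ser, n_perm = rc$n_perm,
                  seed = derive_seed(rc$seed, paste0("dec:", ser$unit_id)))))
    write_out_csv(dec, file.path(rc$out_dir, "decoding.csv"))
    dz <- vapply(usable, context_z_difference, 0)
    names(dz) <- vapply(usable, `[[`, "", "unit_id")
    rho <- accuracy_rate_correlation(dec, dz)
    pc <- population_curve(usable, rc$set_sizes, n_boot = rc$n_boot,
                           bins_per_block = rc$bins_per_block,
                           seed = derive_seed(rc$seed, "popcurve"))
    write_out_csv(pc$curve, file.path(rc$out_dir, "population_curve.csv"))
    summary$decoding <- list(
      n_units = nrow(dec), n_significant = sum(dec$significant),
      rho_neg = rho$rho_neg, rho_pos = rho$rho_pos,
      min_n_for_threshold = pc$min_n_for_threshold)
    if (!is.null(ctx) && nrow(ctx)) {
      common <- intersect(ctx$unit_id, dec$unit_id)
      summary$overlap <- summarize_overlap(
        ctx[ctx$unit_id %in% common, ], dec[dec$unit_id %in% common, ])
    }
  })

  if (rc$autonomic && !is.null(s$heart)) stage("autonomic", {
    hs <- instantaneous_hr(s$heart)
    per_kind <- lapply(split(s$blocks, s$blocks$kind), function(b) {
      v <- unlist(lapply(seq_len(nrow(b)), function(j)
        hr_in_span(hs, b$start_ms[j], b$end_ms[j])))
      mean(v)
    })
    hrk <- data.frame(kind = names(per_kind),
                      mean_hr_bpm = unlist(per_kind))
    write_out_csv(hrk, file.path(rc$out_dir, "hr_per_block_kind.csv"))
    sg <- hr_spectrogram(hs)
    rsa <- rsa_strength(sg)
    write_out_csv(rsa, file.path(rc$out_dir, "rsa.csv"))
    gs <- s$blocks[s$blocks$kind == "grooming", ]
    groom_spans <- cbind(gs$start_ms, gs$end_ms)
    eps <- detect_high_hr_episodes(hs, groom_spans)
    write_out_csv(as.data.frame(eps), file.path(rc$out_dir, "episodes.csv"))
    in_groom <- vapply(rsa$window_center_s * 1000, function(t)
      any(t >= gs$start_ms & t < gs$end_ms), TRUE)
    ep_resp <- NA_integer_
    if (nrow(eps)) {
      tested <- vapply(s$units, function(u) {
        r <- grooming_response_during_episodes(u, s$events, eps)
        if (is.list(r) && identical(r$status, "insufficient_data")) NA
        else r$responsive
      }, TRUE)
      ep_resp <- sum(tested, na.rm = TRUE)
    }
    summary$autonomic <- list(
      mean_hr_by_kind = as.list(stats::setNames(hrk$mean_hr_bpm, hrk$kind)),
      mean_rsa_norm_grooming = mean(rsa$rsa_norm[in_groom]),
      mean_rsa_norm_other = mean(rsa$rsa_norm[!in_groom]),
      n_episodes = nrow(eps),
      n_units_grooming_responsive_in_episodes = ep_resp)
  })

  summary$exclusions <- exclusions
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             file.path(rc$out_dir, "summary.json"), useBytes = TRUE)
  manifest <- list(package = "amygcontext",
                   version = as.character(utils::packageVersion("amygcontext")),
                   seed = rc$seed,
                   stages = list(responsivity = rc$responsivity,
                                 context = rc$context,
                                 decoding = rc$decoding,
                                 autonomic = rc$autonomic),
                   n_perm = rc$n_perm, n_boot = rc$n_boot,
                   set_sizes = rc$set_sizes)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), file.path(rc$out_dir, "manifest.json"),
             useBytes = TRUE)
  invisible(summary)
}
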