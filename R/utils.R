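# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded internals never
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stable 31-bit hash of a character string
#'
#' Polynomial rolling hash over UTF-8 bytes, independent of R's internals, so
#' that per-unit RNG sub-streams are reproducible across platforms and
#' sessions. Returns an integer in [0, 2^31 - 1).
#' @noRd
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

#' Derive a sub-seed below 2^31 from a master seed and a string key
#' @noRd
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + stable_hash(key)) %% 2147483647)
}

# ---- half-open interval arithmetic (integer ms) ----------------------------

#' Normalize a two-column matrix of half-open intervals [start, end):
#' drop empties, sort, merge overlaps/adjacency.
#' @noRd
interval_union <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], iv[i, 2])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Subtract the union of intervals `cut` from interval [a, b); returns the
#' kept sub-intervals as a two-column matrix.
#' @noRd
interval_subtract <- function(a, b, cut) {
  cut <- interval_union(cut)
  kept <- matrix(numeric(0), ncol = 2)
  pos <- a
  if (nrow(cut)) for (i in seq_len(nrow(cut))) {
    s <- max(cut[i, 1], a); e <- min(cut[i, 2], b)
    if (e <= s) next
    if (s > pos) kept <- rbind(kept, c(pos, s))
    pos <- max(pos, e)
  }
  if (pos < b) kept <- rbind(kept, c(pos, b))
  kept
}

#' Sum of interval lengths
#' @noRd
interval_total <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

#' Mean firing rate (Hz) of spike times within half-open window [a, b) in ms
#' @noRd
window_rate_hz <- function(spikes_ms, a, b) {
  sum(spikes_ms >= a & spikes_ms < b) / ((b - a) / 1000)
}

stop_load <- function(...) stop(sprintf(...), call. = FALSE)
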