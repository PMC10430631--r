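#' @title Context decoding
#'
#' @description
#' Decodes block context (airflow vs grooming) from 1-s baseline bins. Per
#' neuron: a linear support-vector classifier on the unit's bin rates with
#' stratified 10-fold cross-validation on class-balanced bin counts; the
#' chance distribution is obtained by shuffling the block labels and
#' re-running the full cross-validation (the null is centered on 50%;
#' cross-validated accuracy itself can fall below 50%). A unit decodes
#' context significantly when its accuracy exceeds the upper bound of the
#' permutation null's 95% percentile interval. Population decoding uses
#' pseudo-population vectors: because units come from different sessions, no
#' bin correspondence exists and same-context bins are paired uniformly at
#' random across units within each bootstrap draw.
#'
#' @name decoding
NULL

# bins usable for decoding: airflow vs grooming contexts only
decoding_bins <- function(series) {
  b <- series$bins[series$bins$block_kind %in% c("airflow", "grooming"), ,
                   drop = FALSE]
  feat <- if (all(is.na(b$z))) b$rate_hz else b$z
  data.frame(x = feat, y = b$block_kind)
}

balance_classes <- function(df, seed) {
  with_seed(seed, {
    n <- min(table(df$y))
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$y),
                         function(i) if (length(i) > n) sample(i, n) else i))
    df[sort(idx), , drop = FALSE]
  })
}

# stratified k-fold CV of a linear SVM; returns mean per-fold accuracy
svm_cv_accuracy <- function(x, y, folds = 10, cost = 1, seed = 1) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop_load("svm_cv_accuracy: single-class input")
  if (min(table(y)) < folds)
    stop_load("svm_cv_accuracy: fewer than %d bins in a class", folds)
  x <- as.matrix(x)
  fold <- integer(length(y))
  with_seed(seed, for (lv in levels(y)) {
    i <- which(y == lv)
    fold[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  })
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- suppressWarnings(
      e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                 cost = cost, scale = FALSE))
    mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, 0)
  mean(acc)
}

#' Single-neuron cross-validated decoding accuracy
#'
#' @param series a \code{\link{baseline_series}} whose bins cover the two
#'   airflow and two grooming analysis blocks.
#' @param seed integer seed (balancing and fold assignment).
#' @param folds number of CV folds (default 10).
#' @param cost SVM regularization constant (default 1; on 1-D inputs the
#'   accuracy is insensitive to it over a wide range).
#' @return Mean held-out accuracy over the folds (0--1).
#' @export
svm_accuracy_single <- function(series, seed, folds = 10, cost = 1) {
  df <- balance_classes(decoding_bins(series), derive_seed(seed, "balance"))
  svm_cv_accuracy(df$x, df$y, folds, cost, derive_seed(seed, "folds"))
}

#' Permutation null of single-neuron decoding accuracy
#'
#' Shuffles the context labels of the balanced bin set and re-runs the full
#' stratified cross-validation for each permutation.
#'
#' @inheritParams svm_accuracy_single
#' @param n_perm number of label shuffles (default 10000; fewer than 100
#'   gives an unstable interval and warns).
#' @return list with \code{null} (accuracy per permutation), \code{mean},
#'   and \code{ci} (2.5/97.5 percentiles).
#' @export
permutation_null <- function(series, n_perm = 10000, seed = 1, folds = 10,
                             cost = 1) {
  if (n_perm < 1) stop_load("permutation_null: n_perm must be >= 1")
  if (n_perm < 100)
    warning("permutation_null: n_perm < 100, CI unstable", call. = FALSE)
  df <- balance_classes(decoding_bins(series), derive_seed(seed, "balance"))
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- with_seed(derive_seed(seed, paste0("perm:", i)),
                    sample(df$y))
    svm_cv_accuracy(df$x, yp, folds, cost, derive_seed(seed, paste0("fold:", i)))
  }, 0)
  list(null = null, mean = mean(null),
       ci = unname(stats::quantile(null, c(0.025, 0.975))))
}

#' Decode one unit with its permutation null
#'
#' @inheritParams permutation_null
#' @return One-row data.frame (class \code{decoding_result}):
#'   \code{unit_id}, \code{cv_accuracy}, \code{null_mean},
#'   \code{null_ci_lower}, \code{null_ci_upper}, \code{significant}
#'   (\code{cv_accuracy > null_ci_upper}).
#' @export
decode_unit <- function(series, n_perm = 10000, seed = 1, folds = 10,
                        cost = 1) {
  acc <- svm_accuracy_single(series, seed, folds, cost)
  nul <- permutation_null(series, n_perm, seed, folds, cost)
  out <- data.frame(unit_id = series$unit_id, cv_accuracy = acc,
                    null_mean = nul$mean, null_ci_lower = nul$ci[1],
                    null_ci_upper = nul$ci[2],
                    significant = acc > nul$ci[2])
  class(out) <- c("decoding_result", class(out))
  out
}

# per-unit context pools of feature values
context_pools <- function(series_list) {
  lapply(series_list, function(s) {
    df <- decoding_bins(s)
    list(unit_id = s$unit_id,
         airflow = df$x[df$y == "airflow"],
         grooming = df$x[df$y == "grooming"])
  })
}

sample_pool <- function(pool, n) {
  if (length(pool) >= n) sample(pool, n) else sample(pool, n, replace = TRUE)
}

#' Assemble one pseudo-population bin matrix
#'
#' Pairs same-context bins uniformly at random across units (units are not
#' simultaneously recorded, so no true bin correspondence exists).
#'
#' @param series_list list of \code{\link{baseline_series}}.
#' @param bins_per_block balanced bins per block (default 60; each context
#'   contributes twice this many rows, one block's worth per airflow /
#'   grooming block).
#' @param seed integer seed.
#' @return list with matrix \code{x} (bins x units) and factor \code{y}
#'   of context labels.
#' @export
build_pseudo_population <- function(series_list, bins_per_block = 60,
                                    seed = 1) {
  pools <- context_pools(series_list)
  n_ctx <- 2 * bins_per_block
  with_seed(seed, {
    x <- vapply(pools, function(p)
      c(sample_pool(p$airflow, n_ctx), sample_pool(p$grooming, n_ctx)),
      numeric(2 * n_ctx))
    list(x = matrix(x, ncol = length(pools)),
         y = factor(rep(c("airflow", "grooming"), each = n_ctx)))
  })
}

#' Population decoding accuracy versus set size
#'
#' For each set size, draws \code{n_boot} bootstrap sets of units (with
#' replacement by default), forms a pseudo-population bin matrix per draw,
#' and runs the stratified cross-validated linear SVM; reports the mean and
#' the percentile 95% interval over draws. The criterion accuracy of a set
#' size is the interval's lower bound.
#'
#' @param series_list list of \code{\link{baseline_series}}; every unit must
#'   supply at least \code{bins_per_block} bins per analysis block.
#' @param set_sizes integer vector of population sizes.
#' @param n_boot bootstrap draws per size (default 10000).
#' @param bins_per_block balanced bins per block (default 60).
#' @param threshold accuracy the lower CI bound must exceed (default 0.95).
#' @param seed integer seed.
#' @param with_replacement draw units with replacement (default \code{TRUE}).
#' @param folds,cost CV parameters.
#' @return An object of class \code{population_curve}: data.frame
#'   \code{curve} (\code{set_size}, \code{mean_accuracy}, \code{ci_lower},
#'   \code{ci_upper}) and \code{min_n_for_threshold} (smallest size whose
#'   \code{ci_lower} exceeds \code{threshold}, or \code{NA} if none).
#' @export
population_curve <- function(series_list, set_sizes, n_boot = 10000,
                             bins_per_block = 60, threshold = 0.95, seed = 1,
                             with_replacement = TRUE, folds = 10, cost = 1) {
  stopifnot(length(series_list) >= 1, all(set_sizes >= 1),
            all(set_sizes <= length(series_list) | with_replacement))
  pools <- context_pools(series_list)
  short <- vapply(pools, function(p)
    min(length(p$airflow), length(p$grooming)) < bins_per_block, TRUE)
  if (any(short))
    stop_load("population_curve: unit %s has fewer than %d bins per context",
              pools[[which(short)[1]]]$unit_id, bins_per_block)
  n_units <- length(series_list)
  rows <- lapply(set_sizes, function(sz) {
    acc <- vapply(seq_len(n_boot), function(b) {
      sub_seed <- derive_seed(seed, sprintf("boot:%d:%d", sz, b))
      pick <- with_seed(sub_seed, sample(n_units, sz,
                                         replace = with_replacement))
      pp <- build_pseudo_population(series_list[pick], bins_per_block,
                                    derive_seed(sub_seed, "pair"))
      svm_cv_accuracy(pp$x, pp$y, folds, cost, derive_seed(sub_seed, "cv"))
    }, 0)
    ci <- stats::quantile(acc, c(0.025, 0.975))
    data.frame(set_size = sz, mean_accuracy = mean(acc),
               ci_lower = unname(ci[1]), ci_upper = unname(ci[2]))
  })
  curve <- do.call(rbind, rows)
  hit <- curve$set_size[curve$ci_lower > threshold]
  structure(list(curve = curve,
                 min_n_for_threshold = if (length(hit)) min(hit) else NA,
                 threshold = threshold),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("<population_curve> %d sizes; min n for >%.0f%%: %s\n",
              nrow(x$curve), 100 * x$threshold,
              format(x$min_n_for_threshold)))
  print(x$curve)
  invisible(x)
}

#' Correlation of decoding accuracy with baseline-rate separation
#'
#' Pearson correlation of single-unit accuracy against the grooming-minus-
#' airflow difference of mean Z-scored baseline rate, computed separately for
#' units with negative and positive differences.
#'
#' @param results data.frame with columns \code{unit_id},
#'   \code{cv_accuracy}.
#' @param delta_z named numeric (by unit id) of grooming-minus-airflow mean Z
#'   differences.
#' @param min_units minimum units per branch (default 3).
#' @return list with \code{rho_neg}, \code{rho_pos} (\code{NA} when a branch
#'   has too few units or zero variance).
#' @export
accuracy_rate_correlation <- function(results, delta_z, min_units = 3) {
  d <- delta_z[match(results$unit_id, names(delta_z))]
  branch_cor <- function(sel) {
    if (sum(sel) < min_units) return(NA_real_)
    if (stats::sd(d[sel]) == 0 || stats::sd(results$cv_accuracy[sel]) == 0)
      return(NA_real_)
    stats::cor(d[sel], results$cv_accuracy[sel])
  }
  list(rho_neg = branch_cor(!is.na(d) & d < 0),
       rho_pos = branch_cor(!is.na(d) & d > 0))
}

#' Mean Z difference (grooming minus airflow) of a baseline series
#' @param series a \code{\link{baseline_series}}.
#' @return numeric scalar.
#' @export
context_z_difference <- function(series) {
  b <- series$bins
  mean(b$z[b$block_kind == "grooming"], na.rm = TRUE) -
    mean(b$z[b$block_kind == "airflow"], na.rm = TRUE)
}

#' PCA separability of a population bin matrix
#'
#' Projects the bins-by-units matrix onto its first principal component and
#' clusters the projections with 2-means; accuracy is the best cluster-to-
#' label assignment against the true context labels. Invariant to unit
#' ordering.
#'
#' @param x numeric matrix, bins x units.
#' @param y context labels (two classes).
#' @param seed integer seed for k-means starts.
#' @return Clustering accuracy in [0.5, 1].
#' @export
pca_separability <- function(x, y, seed = 1) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(x) == length(y))
  if (all(apply(x, 2, stats::sd) == 0))
    stop_load("pca_separability: degenerate constant matrix")
  pc1 <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, 1]
  km <- with_seed(seed, stats::kmeans(pc1, centers = 2, nstart = 10))
  a1 <- mean((km$cluster == 1) == (y == levels(y)[1]))
  max(a1, 1 - a1)
}
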