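# Column-name encoding of (parameter, descriptor) pairs in a feature table:
#   <param>__below_q05 .. <param>__below_q95   (19 threshold fractions)
#   <param>__median
#   <param>__ks_stat
QUANTILE_PROBS <- seq(0.05, 0.95, by = 0.05)

quantile_tags <- function() sprintf("below_q%02d", round(QUANTILE_PROBS * 100))

feature_metadata_cols <- c("margin_id", "label", "mbd", "orientation")

#' Pooled quantile threshold grid
#'
#' For each of the five parameters, pools the finite pixels of every margin
#' into a single vector and takes its 0.05-0.95 quantiles in 0.05 increments
#' (19 values, linear-interpolation quantile rule). Thresholding on pooled
#' data quantiles splits the margins evenly on the actual data distribution
#' rather than the (outlier-sensitive) data range.
#'
#' @param cohort List of [margin_image] objects, each carrying all five maps
#'   (run [compute_ratio_maps] first if needed).
#' @return A `threshold_grid`: named list, 19 non-decreasing values per
#'   parameter, with the pooled pixel counts as attribute `pool_n`.
#' @export
pooled_quantile_thresholds <- function(cohort) {
  if (length(cohort) == 0L) stop_ms("empty cohort")
  grid <- list()
  pool_n <- integer(0)
  for (p in MARGIN_PARAMETERS) {
    pool <- unlist(lapply(cohort, function(m) {
      if (is.null(m$maps[[p]])) stop_ms("margin ", m$margin_id, " lacks map '", p, "'")
      finite_vals(m$maps[[p]])
    }), use.names = FALSE)
    if (length(pool) < 2L) stop_ms("pooled pixel vector for '", p, "' too small")
    grid[[p]] <- unname(quantile(pool, probs = QUANTILE_PROBS, type = 7))
    pool_n[p] <- length(pool)
  }
  structure(grid, class = "threshold_grid", pool_n = pool_n)
}

#' Fraction of pixels strictly below a threshold
#'
#' @param map Numeric matrix (or vector) of pixel values; non-finite pixels
#'   are excluded.
#' @param threshold Scalar threshold in the map's units.
#' @return Proportion in \[0,1\]: (# pixels < threshold) / (# finite pixels).
#' @export
fraction_below <- function(map, threshold) {
  v <- finite_vals(as.numeric(map))
  if (length(v) == 0L) stop_ms("map has no finite pixels")
  mean(v < threshold)
}

#' Median pixel value of a map
#'
#' @param map Numeric matrix; non-finite pixels excluded.
#' @return Median (average of the middle two values for even counts).
#' @export
image_median <- function(map) {
  v <- finite_vals(as.numeric(map))
  if (length(v) == 0L) stop_ms("map has no finite pixels")
  median(v)
}

#' Pooled positive-margin reference distributions
#'
#' For each parameter, pools the finite pixels of every margin labeled close
#' or positive. A margin's KS statistic against this pool
#' ([ks_vs_positive_reference]) measures how unlike a positive-margin pixel
#' distribution its own pixels are: statistics near 0 mark margins whose
#' distribution mimics the positive pool.
#'
#' @param cohort List of [margin_image] objects.
#' @param exclude_margin_id Optional margin id to leave out of the pool
#'   (leave-one-margin-out variant; the default reference includes every
#'   positive margin's own pixels).
#' @return A `positive_reference`: named list of pooled pixel vectors.
#' @export
positive_reference <- function(cohort, exclude_margin_id = NULL) {
  pos <- Filter(function(m) m$label %in% c("close", "positive") &&
                  !identical(m$margin_id, exclude_margin_id), cohort)
  if (length(pos) == 0L) stop_ms("no close/positive margins to build the reference")
  ref <- lapply(setNames(nm = MARGIN_PARAMETERS), function(p)
    unlist(lapply(pos, function(m) finite_vals(m$maps[[p]])), use.names = FALSE))
  if (any(vapply(ref, length, 0L) == 0L)) stop_ms("empty reference pool")
  structure(ref, class = "positive_reference")
}

#' KS statistic of one margin map against the positive reference
#'
#' @param map Numeric matrix of the margin's pixels for `parameter`.
#' @param reference A [positive_reference].
#' @param parameter Parameter name.
#' @return Two-sample KS statistic D.
#' @export
ks_vs_positive_reference <- function(map, reference, parameter) {
  if (!inherits(reference, "positive_reference"))
    stop_ms("`reference` must be a positive_reference")
  pool <- reference[[parameter]]
  if (is.null(pool) || length(pool) == 0L)
    stop_ms("empty reference for '", parameter, "'")
  ks_two_sample(finite_vals(map), pool)
}

#' Reduce a cohort to the full 105-variable feature table
#'
#' For each margin and each of the 5 parameters, computes 19
#' fraction-below-threshold variables (pooled-quantile grid), the image
#' median, and the KS statistic against the positive reference pool:
#' 5 x (19 + 1 + 1) = 105 image-descriptive variables per margin.
#'
#' @param cohort List of [margin_image] objects with all five maps.
#' @param grid Optional [pooled_quantile_thresholds] grid (built from the
#'   cohort when `NULL`).
#' @param reference Optional [positive_reference] (built from the cohort when
#'   `NULL`).
#' @return A `feature_table` data frame: metadata columns (`margin_id`,
#'   `label`, `mbd`, `orientation`) plus 105 feature columns, with the grid
#'   and reference sizes attached as attributes `thresholds` and
#'   `reference_n`.
#' @export
reduce_cohort <- function(cohort, grid = NULL, reference = NULL) {
  if (length(cohort) == 0L) stop_ms("empty cohort")
  if (is.null(grid)) grid <- pooled_quantile_thresholds(cohort)
  if (is.null(reference)) reference <- positive_reference(cohort)
  qt <- quantile_tags()
  rows <- lapply(cohort, function(m) {
    vals <- numeric(0)
    for (p in MARGIN_PARAMETERS) {
      map <- m$maps[[p]]
      if (is.null(map)) stop_ms("margin ", m$margin_id, " lacks map '", p, "'")
      v <- finite_vals(map)
      if (length(v) == 0L) stop_ms("margin ", m$margin_id, " map '", p, "' all-NaN")
      fb <- vapply(grid[[p]], function(th) mean(v < th), numeric(1))
      ks <- ks_vs_positive_reference(map, reference, p)
      block <- c(fb, median(v), ks)
      names(block) <- paste0(p, "__", c(qt, "median", "ks_stat"))
      vals <- c(vals, block)
    }
    vals
  })
  feat <- as.data.frame(do.call(rbind, rows))
  meta <- data.frame(
    margin_id = vapply(cohort, `[[`, "", "margin_id"),
    label = vapply(cohort, `[[`, "", "label"),
    mbd = vapply(cohort, `[[`, 0L, "mbd"),
    orientation = vapply(cohort, function(m) as.character(m$orientation)[1], ""),
    stringsAsFactors = FALSE)
  out <- cbind(meta, feat)
  rownames(out) <- NULL
  attr(out, "thresholds") <- grid
  attr(out, "reference_n") <- vapply(reference, length, 0L)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature columns of a feature table
#' @param table A `feature_table` (or plain data frame using the same naming).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), feature_metadata_cols)
}

# binarized diagnosis: close + positive are lumped as positive
binarize_labels <- function(labels) labels %in% c("close", "positive")

#' Select the per-parameter optimal threshold (105 -> 15 variables)
#'
#' For each parameter, scans its 19 fraction-below columns with the Wilcoxon
#' rank-sum test of positive/close vs negative margins and keeps the column
#' with the smallest p-value (ties broken toward the lower quantile index).
#' The final table keeps, per parameter, that optimal-threshold fraction plus
#' the image median and the KS statistic: 5 x 3 = 15 variables. No
#' multiple-testing correction is applied to the scan - the minimum-p
#' threshold itself is the selection rule.
#'
#' @param full_table A `feature_table` from [reduce_cohort].
#' @param labels Optional label vector (defaults to the table's `label`
#'   column); close+positive are lumped as positive.
#' @return A `feature_table` with 15 feature columns and attribute
#'   `selected_thresholds`: a data frame with the chosen quantile, threshold
#'   value (parameter units) and Wilcoxon p per parameter.
#' @export
select_optimal_thresholds <- function(full_table, labels = NULL) {
  if (is.null(labels)) labels <- full_table$label
  pos <- binarize_labels(labels)
  if (all(pos) || !any(pos))
    stop_ms("both label classes are required for threshold selection")
  grid <- attr(full_table, "thresholds")
  qt <- quantile_tags()
  keep <- character(0)
  sel <- data.frame(parameter = character(0), quantile = numeric(0),
                    threshold_value = numeric(0), p_value = numeric(0))
  for (p in MARGIN_PARAMETERS) {
    cols <- paste0(p, "__", qt)
    if (!all(cols %in% names(full_table)))
      stop_ms("full table lacks threshold columns for '", p, "'")
    X <- as.matrix(full_table[cols])
    pvals <- wilcoxon_scan(X, pos)
    j <- which.min(pvals)               # which.min takes the first (lowest quantile) on ties
    keep <- c(keep, cols[j], paste0(p, "__median"), paste0(p, "__ks_stat"))
    sel <- rbind(sel, data.frame(
      parameter = p, quantile = QUANTILE_PROBS[j],
      threshold_value = if (!is.null(grid)) grid[[p]][j] else NA_real_,
      p_value = pvals[j]))
  }
  out <- full_table[c(intersect(feature_metadata_cols, names(full_table)), keep)]
  attr(out, "thresholds") <- grid
  attr(out, "selected_thresholds") <- sel
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV (+ JSON threshold sidecar)
#'
#' @param table A `feature_table`.
#' @param path CSV output path; the selected-threshold report (when present)
#'   goes to `<path>.thresholds.json`.
#' @return The CSV path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  sel <- attr(table, "selected_thresholds")
  grid <- attr(table, "thresholds")
  side <- list()
  if (!is.null(sel)) side$selected_thresholds <- sel
  if (!is.null(grid)) side$threshold_grid <- unclass(grid)
  if (length(side))
    jsonlite::write_json(side, paste0(path, ".thresholds.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".thresholds.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$threshold_grid))
      attr(out, "thresholds") <- structure(side$threshold_grid, class = "threshold_grid")
    if (!is.null(side$selected_thresholds))
      attr(out, "selected_thresholds") <- side$selected_thresholds
  }
  class(out) <- c("feature_table", "data.frame")
  out
}
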