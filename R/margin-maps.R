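#' Construct a margin image
#'
#' A `margin_image` bundles the co-registered 2-D optical parameter maps of one
#' excised-specimen margin with its metadata: the histopathologic label
#' (negative / close / positive), the mammographic breast density (MBD) score
#' 1-4, the pixel pitch (5 mm by default, the probe's sampling resolution), an
#' optional free-text orientation, and - for synthetic margins - the per-pixel
#' tissue-class ground truth.
#'
#' Maps are numeric matrices in physical units: `beta_carotene` and `total_hb`
#' in uM, `mus_prime` in 1/cm, and the derived ratios in uM.cm. All maps must
#' share one shape. Unmeasured pixels are encoded as `NA`/`NaN` and are
#' excluded from every downstream pixel pool; measured values must be strictly
#' positive and finite.
#'
#' @param margin_id Character scalar identifier.
#' @param maps Named list of numeric matrices; must contain at least
#'   `beta_carotene`, `total_hb` and `mus_prime`. Names must be a subset of
#'   [MARGIN_PARAMETERS].
#' @param label One of `"negative"`, `"close"`, `"positive"`.
#' @param mbd Integer MBD score in 1..4.
#' @param pixel_pitch_mm Sampling pitch in mm (default 5).
#' @param orientation Optional free-text margin orientation.
#' @param class_truth Optional character matrix of per-pixel tissue classes
#'   (synthetic margins only), same shape as the maps.
#' @return An object of class `margin_image`.
#' @export
margin_image <- function(margin_id, maps, label, mbd, pixel_pitch_mm = 5,
                         orientation = NA_character_, class_truth = NULL) {
  if (!is.character(margin_id) || length(margin_id) != 1L || is.na(margin_id))
    stop_ms("`margin_id` must be a single string")
  if (!is.list(maps) || is.null(names(maps)) || any(names(maps) == ""))
    stop_ms("`maps` must be a named list of matrices")
  unknown <- setdiff(names(maps), MARGIN_PARAMETERS)
  if (length(unknown))
    stop_ms("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(BASE_PARAMETERS, names(maps))
  if (length(missing))
    stop_ms("missing required parameter map(s): ", paste(missing, collapse = ", "))
  if (!all(vapply(maps, is.matrix, logical(1))))
    stop_ms("all maps must be matrices")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_ms("all maps must share the same shape")
  for (p in names(maps)) {
    v <- maps[[p]]
    bad <- is.finite(v) & v <= 0
    if (any(bad))
      stop_ms("map '", p, "' contains non-positive measured values")
    if (any(is.infinite(v)))
      stop_ms("map '", p, "' contains infinite values")
  }
  label <- match.arg(label, MARGIN_LABELS)
  if (!is_count(mbd) || mbd < 1 || mbd > 4)
    stop_ms("`mbd` must be an integer in 1..4")
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop_ms("`pixel_pitch_mm` must be positive")
  if (!is.null(class_truth)) {
    if (!is.matrix(class_truth) ||
        !identical(dim(class_truth), dim(maps[[1L]])))
      stop_ms("`class_truth` must be a matrix matching the map shape")
  }
  structure(
    list(margin_id = margin_id, maps = maps, label = label,
         mbd = as.integer(mbd), pixel_pitch_mm = pixel_pitch_mm,
         orientation = as.character(orientation), class_truth = class_truth),
    class = "margin_image")
}

#' @export
print.margin_image <- function(x, ...) {
  d <- dim(x$maps[[1L]])
  cat(sprintf("<margin_image> %s: %dx%d px @ %g mm, label=%s, MBD=%d\n",
              x$margin_id, d[1], d[2], x$pixel_pitch_mm, x$label, x$mbd))
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Add the derived ratio maps to a margin image
#'
#' Computes, pixelwise, `bc_over_mus = beta_carotene / mus_prime` and
#' `thb_over_mus = total_hb / mus_prime` (both in uM.cm). The ratio of
#' beta-carotene (a fat-stored absorber) to reduced scattering (a
#' collagen/glandular-density proxy) reports the relative fat-to-fibroglandular
#' composition at the tissue surface and is the pipeline's primary
#' discriminator of positive margins. The original maps are untouched.
#'
#' @param margin A [margin_image].
#' @return The margin with `bc_over_mus` and `thb_over_mus` maps added
#'   (replaced if already present).
#' @export
compute_ratio_maps <- function(margin) {
  if (!inherits(margin, "margin_image")) stop_ms("`margin` must be a margin_image")
  mus <- margin$maps$mus_prime
  if (any(is.finite(mus) & mus <= 0))
    stop_ms("mus_prime must be strictly positive at every measured pixel")
  margin$maps$bc_over_mus <- margin$maps$beta_carotene / mus
  margin$maps$thb_over_mus <- margin$maps$total_hb / mus
  margin
}

#' Write / read one margin in the long-form CSV dialect
#'
#' A margin is stored as two files in `dir`: `<margin_id>_maps.csv` with
#' columns `margin_id,row,col,parameter,value` (0-based row/col, row-major;
#' `NA` value for unmeasured pixels), and `<margin_id>_meta.json` carrying the
#' label, MBD, pixel pitch, orientation, map shape and - when present - the
#' tissue-class ground truth. A write -> read round trip preserves metadata
#' exactly and map values to full double precision.
#'
#' @param margin A [margin_image].
#' @param dir Directory (created if needed).
#' @return `write_margin` returns the two file paths invisibly; `read_margin`
#'   returns the reconstructed [margin_image].
#' @export
write_margin <- function(margin, dir) {
  if (!inherits(margin, "margin_image")) stop_ms("`margin` must be a margin_image")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(margin$maps[[1L]])
  long <- do.call(rbind, lapply(names(margin$maps), function(p) {
    data.frame(margin_id = margin$margin_id,
               row = rep(seq_len(d[1]) - 1L, times = d[2]),
               col = rep(seq_len(d[2]) - 1L, each = d[1]),
               parameter = p,
               value = as.vector(margin$maps[[p]]))
  }))
  maps_path <- file.path(dir, paste0(margin$margin_id, "_maps.csv"))
  meta_path <- file.path(dir, paste0(margin$margin_id, "_meta.json"))
  write.csv(long, maps_path, row.names = FALSE)
  meta <- list(margin_id = margin$margin_id, label = margin$label,
               mbd = margin$mbd, pixel_pitch_mm = margin$pixel_pitch_mm,
               orientation = margin$orientation, shape = d)
  if (!is.null(margin$class_truth))
    meta$class_truth <- margin$class_truth
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(maps = maps_path, meta = meta_path))
}

#' @param path Either the directory containing the pair of files plus
#'   `margin_id`, or the `_maps.csv` path itself.
#' @param margin_id Margin identifier (when `path` is a directory).
#' @rdname write_margin
#' @export
read_margin <- function(path, margin_id = NULL) {
  if (dir.exists(path)) {
    if (is.null(margin_id)) stop_ms("`margin_id` required when `path` is a directory")
    maps_path <- file.path(path, paste0(margin_id, "_maps.csv"))
    meta_path <- file.path(path, paste0(margin_id, "_meta.json"))
  } else {
    maps_path <- path
    meta_path <- sub("_maps\\.csv$", "_meta.json", path)
  }
  if (!file.exists(maps_path) || !file.exists(meta_path))
    stop_ms("margin files not found: ", maps_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  long <- read.csv(maps_path, stringsAsFactors = FALSE)
  need <- c("margin_id", "row", "col", "parameter", "value")
  if (!all(need %in% names(long))) stop_ms("malformed maps CSV: ", maps_path)
  shape <- as.integer(meta$shape)
  params <- unique(long$parameter)
  unknown <- setdiff(params, MARGIN_PARAMETERS)
  if (length(unknown))
    stop_ms("unknown parameter name(s) in ", maps_path, ": ",
            paste(unknown, collapse = ", "))
  maps <- lapply(params, function(p) {
    sub <- long[long$parameter == p, , drop = FALSE]
    if (nrow(sub) != prod(shape))
      stop_ms("parameter '", p, "' has ", nrow(sub),
              " pixels but metadata shape implies ", prod(shape))
    m <- matrix(NA_real_, shape[1], shape[2])
    m[cbind(sub$row + 1L, sub$col + 1L)] <- sub$value
    m
  })
  names(maps) <- params
  ct <- NULL
  if (!is.null(meta$class_truth)) {
    ct <- meta$class_truth
    if (!is.matrix(ct)) ct <- matrix(unlist(ct), shape[1], shape[2], byrow = TRUE)
  }
  margin_image(meta$margin_id, maps, meta$label, meta$mbd,
               pixel_pitch_mm = meta$pixel_pitch_mm,
               orientation = meta$orientation, class_truth = ct)
}

#' Write / read a full cohort directory
#'
#' Writes every margin with [write_margin] plus a `cohort.json` index listing
#' margin ids, labels, MBD scores and (when the cohort came from
#' [generate_cohort]) the configuration echo and per-margin seeds.
#'
#' @param cohort List of [margin_image] objects (optionally with a `config`
#'   attribute from [generate_cohort]).
#' @param dir Output directory.
#' @return Invisibly, the path to `cohort.json`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort) write_margin(m, dir)
  idx <- list(
    margin_ids = vapply(cohort, `[[`, "", "margin_id"),
    labels = vapply(cohort, `[[`, "", "label"),
    mbd = vapply(cohort, `[[`, 0L, "mbd"))
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) idx$config <- config_to_list(cfg)
  seeds <- attr(cohort, "margin_seeds")
  if (!is.null(seeds)) idx$margin_seeds <- seeds
  p <- file.path(dir, "cohort.json")
  jsonlite::write_json(idx, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- file.path(dir, "cohort.json")
  if (!file.exists(p)) stop_ms("no cohort.json in ", dir)
  idx <- jsonlite::read_json(p, simplifyVector = TRUE)
  cohort <- lapply(idx$margin_ids, function(id) read_margin(dir, id))
  if (!is.null(idx$config))
    attr(cohort, "config") <- config_from_list(idx$config)
  if (!is.null(idx$margin_seeds)) attr(cohort, "margin_seeds") <- idx$margin_seeds
  cohort
}
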