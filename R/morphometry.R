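#' Configure adipocyte morphometry
#'
#' Defaults follow the acquisition and gating of the histology analysis this
#' package reproduces: 1.1 um/pixel imagery and empirical cell-area gates of
#' 129.3 and 22,569 um2 (about 106.9 and 18,652 px2 at 1.1 um/px) that limit
#' counted regions to plausible adipocytes. Filter and edge parameters are
#' exposed because no canonical values exist: bilateral spatial sigma 3 px and
#' range sigma 0.1 of the image dynamic range; Canny Gaussian sigma 1.5 px
#' with hysteresis thresholds at 0.1 / 0.2 of the gradient maximum.
#'
#' @param pixel_size_um Pixel size (um/pixel).
#' @param area_gate_um2 `(low, high)` cell-area gate in um2.
#' @param bilateral_sigma_spatial Spatial sigma of the bilateral filter (px).
#' @param bilateral_sigma_range Range sigma as a fraction of dynamic range.
#' @param canny_sigma Gaussian smoothing sigma before edge detection (px).
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   gradient-magnitude maximum.
#' @param closing_size Brush width (px) of the morphological closing that
#'   seals contour gaps and merges a membrane's double Canny contour (inner
#'   and outer transition) into one solid band before filling; default 5
#'   (seals ring contours up to 4 px apart, i.e. membranes up to ~4 px wide).
#' @param exclude_border Drop regions touching the image border (default
#'   FALSE: border cells are counted).
#' @return A `morphometry_config`.
#' @export
morphometry_config <- function(pixel_size_um = 1.1,
                               area_gate_um2 = c(129.3, 22569),
                               bilateral_sigma_spatial = 3,
                               bilateral_sigma_range = 0.1,
                               canny_sigma = 1.5,
                               canny_low = 0.1,
                               canny_high = 0.2,
                               closing_size = 5L,
                               exclude_border = FALSE) {
  if (pixel_size_um <= 0) stop_ms("`pixel_size_um` must be positive")
  if (length(area_gate_um2) != 2L || area_gate_um2[1] <= 0 ||
      area_gate_um2[1] >= area_gate_um2[2])
    stop_ms("`area_gate_um2` must satisfy 0 < low < high")
  if (canny_low >= canny_high) stop_ms("`canny_low` must be below `canny_high`")
  structure(list(pixel_size_um = pixel_size_um, area_gate_um2 = area_gate_um2,
                 bilateral_sigma_spatial = bilateral_sigma_spatial,
                 bilateral_sigma_range = bilateral_sigma_range,
                 canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high, closing_size = as.integer(closing_size),
                 exclude_border = isTRUE(exclude_border)),
            class = "morphometry_config")
}

# replicate-edge shift of a matrix by (dr, dc)
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Edge-preserving bilateral filter
#'
#' Classic bilateral smoothing: each output pixel is a normalized average of
#' its neighborhood weighted by both spatial distance (Gaussian, `sigma_s`)
#' and intensity difference (Gaussian, `sigma_r`), so homogeneous regions are
#' smoothed while intensity edges are preserved. Window radius is
#' `ceiling(2 * sigma_s)`; borders use replicate padding.
#'
#' @param im Numeric matrix (single channel).
#' @param sigma_s Spatial standard deviation (pixels).
#' @param sigma_r Range standard deviation (intensity units).
#' @return Filtered matrix, same shape.
#' @export
bilateral_filter <- function(im, sigma_s = 3, sigma_r = 0.1) {
  if (!is.matrix(im)) stop_ms("`im` must be a matrix")
  if (sigma_r <= 0) return(im)
  rad <- max(1L, ceiling(2 * sigma_s))
  acc <- im * 0
  norm <- acc
  inv2ss <- 1 / (2 * sigma_s^2)
  inv2sr <- 1 / (2 * sigma_r^2)
  for (dr in (-rad):rad) for (dc in (-rad):rad) {
    ws <- exp(-(dr * dr + dc * dc) * inv2ss)
    sh <- shift_pad(im, dr, dc)
    w <- ws * exp(-(sh - im)^2 * inv2sr)
    acc <- acc + w * sh
    norm <- norm + w
  }
  acc / norm
}

# separable Gaussian blur, replicate padding
gaussian_blur <- function(im, sigma) {
  if (sigma <= 0) return(im)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- im
  tmp <- im * 0
  for (d in (-rad):rad) tmp <- tmp + k[d + rad + 1L] * shift_pad(out, d, 0L)
  out <- tmp
  tmp <- im * 0
  for (d in (-rad):rad) tmp <- tmp + k[d + rad + 1L] * shift_pad(out, 0L, d)
  tmp
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding: weak-edge pixels
#' survive only in connected components that contain at least one strong
#' pixel. Thresholds are fractions of the gradient-magnitude maximum.
#'
#' @param im Numeric matrix.
#' @param sigma Gaussian smoothing sigma (px).
#' @param low,high Hysteresis fractions of the gradient maximum.
#' @return Logical edge matrix.
#' @export
canny_edges <- function(im, sigma = 1.5, low = 0.1, high = 0.2) {
  if (!is.matrix(im)) stop_ms("`im` must be a matrix")
  g <- gaussian_blur(im, sigma)
  # Sobel
  sx <- (shift_pad(g, -1, -1) + 2 * shift_pad(g, 0, -1) + shift_pad(g, 1, -1)) -
        (shift_pad(g, -1,  1) + 2 * shift_pad(g, 0,  1) + shift_pad(g, 1,  1))
  sy <- (shift_pad(g, -1, -1) + 2 * shift_pad(g, -1, 0) + shift_pad(g, -1, 1)) -
        (shift_pad(g,  1, -1) + 2 * shift_pad(g,  1, 0) + shift_pad(g,  1, 1))
  mag <- sqrt(sx^2 + sy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(im), ncol(im)))
  ang <- atan2(sy, sx)                      # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)    # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  n1 <- mag; n2 <- mag
  pick <- function(s, dr1, dc1) {
    sel <- sector == s
    n1[sel] <<- shift_pad(mag, dr1, dc1)[sel]
    n2[sel] <<- shift_pad(mag, -dr1, -dc1)[sel]
  }
  pick(0, 0L, 1L)    # gradient ~ horizontal -> compare left/right
  pick(1, 1L, 1L)
  pick(2, 1L, 0L)
  pick(3, 1L, -1L)
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0
  strong <- nms >= high * mx
  weak <- nms >= low * mx
  if (!any(strong)) return(matrix(FALSE, nrow(im), ncol(im)))
  lbl <- EBImage::bwlabel(weak * 1)
  keep <- sort(unique(lbl[strong]))
  keep <- keep[keep > 0]
  matrix(lbl %in% keep, nrow(im), ncol(im))
}

#' Segment adipocytes and measure morphometry
#'
#' Pipeline: green channel (membrane stain contrast) -> edge-preserving
#' bilateral filter -> Canny edges -> morphological closing (seals contour
#' gaps and merges each membrane's double contour into a solid band) -> fill
#' enclosed regions -> erosion by the closing brush (undoing its outward
#' dilation, so a cell's region sits at its outer membrane contour) ->
#' connected-component labeling -> pixel areas converted to um2 via
#' `pixel_size_um^2` -> regions outside the area gate discarded. Returns
#' count, density (cells/mm2 of imaged area) and per-cell areas.
#'
#' @param rgb_image H x W x 3 numeric array (or a `list(image=..., ...)` as
#'   returned by [generate_adipocyte_image]).
#' @param config A [morphometry_config].
#' @return A `morphometry_result`: `cell_count`, `cell_density_mm2`,
#'   `areas_um2`, `mean_area_um2`, `imaged_area_mm2`.
#' @export
segment_adipocytes <- function(rgb_image, config = morphometry_config()) {
  if (is.list(rgb_image) && !is.null(rgb_image$image)) rgb_image <- rgb_image$image
  if (!(is.array(rgb_image) && length(dim(rgb_image)) == 3L &&
        dim(rgb_image)[3] >= 3L))
    stop_ms("`rgb_image` must be an H x W x 3 array")
  if (!inherits(config, "morphometry_config"))
    stop_ms("`config` must be a morphometry_config")
  g <- rgb_image[, , 2L]
  dyn <- diff(range(g))
  result0 <- function() {
    area_mm2 <- prod(dim(g)) * config$pixel_size_um^2 / 1e6
    structure(list(cell_count = 0L, cell_density_mm2 = 0,
                   areas_um2 = numeric(0), mean_area_um2 = NA_real_,
                   imaged_area_mm2 = area_mm2, config = config),
              class = "morphometry_result")
  }
  if (dyn == 0) return(result0())
  f <- bilateral_filter(g, config$bilateral_sigma_spatial,
                        config$bilateral_sigma_range * dyn)
  edges <- canny_edges(f, config$canny_sigma, config$canny_low, config$canny_high)
  if (!any(edges)) return(result0())
  brush <- EBImage::makeBrush(config$closing_size, shape = "disc")
  closed <- EBImage::closing(edges * 1, brush)
  filled <- EBImage::fillHull(closed)
  regions <- EBImage::erode(filled, brush)
  lbl <- EBImage::bwlabel(regions)
  if (max(lbl) == 0) return(result0())
  if (config$exclude_border) {
    border_labels <- unique(c(lbl[1, ], lbl[nrow(lbl), ], lbl[, 1], lbl[, ncol(lbl)]))
    lbl[lbl %in% border_labels[border_labels > 0]] <- 0L
  }
  px_areas <- tabulate(lbl[lbl > 0])
  areas_um2 <- px_areas[px_areas > 0] * config$pixel_size_um^2
  gate <- config$area_gate_um2
  areas_um2 <- areas_um2[areas_um2 >= gate[1] & areas_um2 <= gate[2]]
  area_mm2 <- prod(dim(g)) * config$pixel_size_um^2 / 1e6
  structure(list(
    cell_count = length(areas_um2),
    cell_density_mm2 = length(areas_um2) / area_mm2,
    areas_um2 = areas_um2,
    mean_area_um2 = if (length(areas_um2)) mean(areas_um2) else NA_real_,
    imaged_area_mm2 = area_mm2, config = config),
    class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> %d cells, %.1f cells/mm2, mean area %.0f um2\n",
              x$cell_count, x$cell_density_mm2,
              ifelse(is.na(x$mean_area_um2), NaN, x$mean_area_um2)))
  invisible(x)
}

#' Compare adipocyte morphometry between density groups
#'
#' Wilcoxon rank-sum tests of per-image cell density and per-image mean cell
#' area between two groups of [segment_adipocytes] results (e.g. low- vs
#' high-MBD breasts).
#'
#' @param results_low,results_high Lists of `morphometry_result` objects, at
#'   least 2 per group.
#' @return List with `p_density`, `p_area`, and the group medians of each
#'   quantity.
#' @export
compare_density_groups <- function(results_low, results_high) {
  if (length(results_low) < 2L || length(results_high) < 2L)
    stop_ms("need at least 2 results per group")
  dens <- function(rs) vapply(rs, `[[`, numeric(1), "cell_density_mm2")
  area <- function(rs) vapply(rs, `[[`, numeric(1), "mean_area_um2")
  d_lo <- dens(results_low); d_hi <- dens(results_high)
  a_lo <- area(results_low); a_hi <- area(results_high)
  list(p_density = wilcoxon_rank_sum(d_lo, d_hi)$p,
       p_area = wilcoxon_rank_sum(a_lo, a_hi)$p,
       median_density = c(low = median(d_lo), high = median(d_hi)),
       median_area = c(low = median(a_lo, na.rm = TRUE),
                       high = median(a_hi, na.rm = TRUE)))
}
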