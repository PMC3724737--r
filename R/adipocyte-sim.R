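#' Generate a synthetic packed-adipocyte histology image
#'
#' Emulates an H&E micrograph of adipose tissue: adipocytes are rendered as
#' non-overlapping disks placed by random sequential adsorption (RSA) on a
#' pink stromal background, with near-white interiors (dissolved fat) and a
#' darker pink/blue membrane ring so the green channel carries the membrane
#' contrast that the segmentation pipeline relies on. Mean cell radius depends
#' on the mammographic-density group when not given explicitly: adipocytes of
#' high-density breasts are smaller (default means 32 um low / 22 um high).
#'
#' The default field of view is 1 mm x 1.3 mm at 1.1 um/pixel, the acquisition
#' geometry of the histology arm of the study design this emulates; smaller
#' fields can be requested for fast fixtures. Cells are placed fully inside
#' the field with a minimum inter-cell gap so adjacent membranes never merge.
#'
#' @param mean_radius_um Mean cell radius (um). If `NULL`, chosen from
#'   `mbd_group` (32 low / 22 high).
#' @param mbd_group `"low"` or `"high"` mammographic breast density.
#' @param seed Integer RNG seed.
#' @param n_cells Number of cells to attempt to place (0 gives a blank image
#'   and empty ground truth).
#' @param fov_um Field of view `(height, width)` in um.
#' @param pixel_size_um Pixel size (um/pixel), default 1.1.
#' @param radius_cv Coefficient of variation of the lognormal radius
#'   distribution (0 for identical radii).
#' @param min_gap_um Minimum clearance between cell boundaries (um).
#' @param membrane_width_um Rendered membrane ring width (um).
#' @param max_attempts RSA placement attempts before giving up.
#' @return List with `image` (H x W x 3 array in \[0,1\]) and `truth`, an
#'   `adipocyte_truth` object carrying `centers_um` (n x 2, x/y), `radii_um`,
#'   `areas_um2` (pi r^2), `pixel_size_um` and `fov_um`.
#' @export
generate_adipocyte_image <- function(mean_radius_um = NULL,
                                     mbd_group = c("low", "high"),
                                     seed = 1L,
                                     n_cells = 150L,
                                     fov_um = c(1000, 1300),
                                     pixel_size_um = 1.1,
                                     radius_cv = 0.15,
                                     min_gap_um = 8.8,
                                     membrane_width_um = 2.2,
                                     max_attempts = 20000L) {
  mbd_group <- match.arg(mbd_group)
  if (is.null(mean_radius_um))
    mean_radius_um <- if (mbd_group == "high") 22 else 32
  if (mean_radius_um <= 0) stop_ms("`mean_radius_um` must be positive")
  if (!is_count(n_cells)) stop_ms("`n_cells` must be a non-negative count")
  H <- as.integer(round(fov_um[1] / pixel_size_um))
  W <- as.integer(round(fov_um[2] / pixel_size_um))
  bg <- c(0.85, 0.60, 0.70)       # stroma (pink)
  interior <- c(0.97, 0.95, 0.96) # dissolved fat (near white)
  membrane <- c(0.75, 0.35, 0.55) # darker pink/blue ring
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3L))
  empty_truth <- structure(
    list(centers_um = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("x", "y"))),
         radii_um = numeric(0), areas_um2 = numeric(0),
         pixel_size_um = pixel_size_um, fov_um = fov_um),
    class = "adipocyte_truth")
  if (n_cells == 0L) return(list(image = img, truth = empty_truth))

  placed <- with_seed(seed, {
    sdlog <- sqrt(log(1 + radius_cv^2))
    meanlog <- log(mean_radius_um) - sdlog^2 / 2
    cx <- cy <- rr <- numeric(0)
    attempts <- 0L
    while (length(rr) < n_cells && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- if (radius_cv > 0) rlnorm(1, meanlog, sdlog) else mean_radius_um
      pad <- r + min_gap_um
      if (2 * pad >= min(fov_um)) next
      x <- runif(1, pad, fov_um[2] - pad)
      y <- runif(1, pad, fov_um[1] - pad)
      if (length(rr) == 0L ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= rr + r + min_gap_um)) {
        cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
      }
    }
    list(x = cx, y = cy, r = rr)
  })
  if (length(placed$r) == 0L)
    stop_ms("placement failure: mean radius too large for the field of view")

  # render each cell inside its bounding box (distances in um)
  px <- pixel_size_um
  for (i in seq_along(placed$r)) {
    r <- placed$r[i]; x0 <- placed$x[i]; y0 <- placed$y[i]
    rows <- max(1L, floor((y0 - r) / px)):min(H, ceiling((y0 + r) / px) + 1L)
    cols <- max(1L, floor((x0 - r) / px)):min(W, ceiling((x0 + r) / px) + 1L)
    yy <- (rows - 0.5) * px; xx <- (cols - 0.5) * px
    d <- sqrt(outer((yy - y0)^2, (xx - x0)^2, "+"))
    in_cell <- d <= r
    in_ring <- in_cell & d > (r - membrane_width_um)
    for (ch in 1:3) {
      plane <- img[rows, cols, ch]
      plane[in_cell] <- interior[ch]
      plane[in_ring] <- membrane[ch]
      img[rows, cols, ch] <- plane
    }
  }
  truth <- structure(
    list(centers_um = cbind(x = placed$x, y = placed$y),
         radii_um = placed$r, areas_um2 = pi * placed$r^2,
         pixel_size_um = pixel_size_um, fov_um = fov_um),
    class = "adipocyte_truth")
  list(image = img, truth = truth)
}

#' Write an RGB image array as PNG
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read an RGB PNG into an array
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array in \[0,1\].
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop_ms("expected an RGB image, got grayscale")
  img[, , 1:3, drop = FALSE]
}
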