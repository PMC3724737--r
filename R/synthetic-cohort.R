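#' Default per-class optical parameter distributions
#'
#' Pixel values are drawn from lognormal distributions (right-skewed, strictly
#' positive) whose medians encode the tissue-class orderings seen in breast
#' optical spectroscopy: beta-carotene (fat-stored) is highest in adipose
#' tissue (~4x fibroglandular) and lowest in malignant tissue, while the
#' reduced scattering coefficient (collagen/glandular density proxy) runs the
#' opposite way. The medians are simulation defaults, not measured claims; no
#' calibrated per-class values exist for the study cohort.
#'
#' @return List with `medians` (parameter x tissue-class matrix; uM for the
#'   absorbers, 1/cm for scattering) and `sdlog` (lognormal shape per
#'   parameter).
#' @export
default_class_params <- function() {
  medians <- rbind(
    beta_carotene = c(adipose = 12,  fibroadipose = 7,  fibroglandular = 3,  malignant = 1.5),
    total_hb      = c(adipose = 12,  fibroadipose = 15, fibroglandular = 18, malignant = 25),
    mus_prime     = c(adipose = 7,   fibroadipose = 10, fibroglandular = 14, malignant = 17))
  list(medians = medians,
       sdlog = c(beta_carotene = 0.35, total_hb = 0.30, mus_prime = 0.25))
}

#' Configure a synthetic margin cohort
#'
#' Bundles every knob of the cohort generator. Defaults emulate the structure
#' of an 88-margin lumpectomy cohort: 52% close-or-positive margins, 45% of
#' margins from high mammographic breast density (MBD 3-4) breasts, 8x12 pixel
#' maps at 5 mm pitch (24 cm2, within the 20-40 cm2 margin range), spatially
#' clustered tissue classes with ~2-pixel correlation length, and a contiguous
#' malignant patch occupying 15-45% of a positive margin's surface.
#'
#' High-MBD margins get elevated beta-carotene baselines in the fat-bearing
#' classes (x1.6 in adipose and fibroadipose) and a global x1.3 scattering
#' baseline, plus a mild composition shift toward fibroglandular tissue; these
#' reproduce the direction of the density effects the analysis is built to
#' exploit. "Close" margins reuse the positive-margin landscape with the
#' malignant patch attenuated toward fibroglandular values (sub-surface
#' disease viewed through overlying benign tissue).
#'
#' @param n_margins Number of margins.
#' @param fraction_positive Fraction of margins labeled close or positive
#'   (lumped "positive" downstream).
#' @param fraction_high_mbd Fraction of margins from high-MBD (3-4) breasts.
#' @param map_shape `(rows, cols)` of each parameter map, pixels at 5 mm pitch.
#' @param spatial_correlation_length Gaussian smoothing sd (pixels) of the
#'   tissue-class random field.
#' @param malignant_patch_fraction_range Interval (proportions in (0,1)) from
#'   which a positive/close margin's malignant surface fraction is drawn.
#' @param close_fraction Fraction of the positive-type margins labeled "close".
#' @param close_attenuation Weight in \[0,1\] pulling close-margin malignant
#'   pixels from fibroglandular (0) toward full malignant (1) parameter values
#'   on the log scale.
#' @param margin_sdlog_shared Between-margin lognormal variability shared by
#'   all three measured parameters (inter-patient baseline and probe-coupling
#'   scale differences). A shared multiplicative factor cancels in the ratio
#'   maps, which is why ratiometric parameters are the robust discriminators.
#' @param margin_sdlog_param Additional independent per-parameter
#'   between-margin variability (does not cancel in ratios).
#' @param class_params Per-class distributions, see [default_class_params].
#' @param mbd_bc_multiplier Named per-class beta-carotene multipliers applied
#'   in high-MBD margins.
#' @param mbd_mus_multiplier Global scattering multiplier in high-MBD margins.
#' @param class_proportions Benign tissue-class mixes per MBD group (named
#'   lists `low`/`high`, each summing to 1 over adipose / fibroadipose /
#'   fibroglandular).
#' @param pixel_pitch_mm Sampling pitch in mm.
#' @param seed Integer master seed; all per-margin seeds derive from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_margins = 88L,
                          fraction_positive = 0.52,
                          fraction_high_mbd = 0.45,
                          map_shape = c(8L, 12L),
                          spatial_correlation_length = 2,
                          malignant_patch_fraction_range = c(0.15, 0.45),
                          close_fraction = 0.5,
                          close_attenuation = 0.6,
                          margin_sdlog_shared = 0.20,
                          margin_sdlog_param = 0.08,
                          class_params = default_class_params(),
                          mbd_bc_multiplier = c(adipose = 1.6, fibroadipose = 1.6,
                                                fibroglandular = 1, malignant = 1),
                          mbd_mus_multiplier = 1.3,
                          class_proportions = list(
                            low  = c(adipose = 0.50, fibroadipose = 0.30, fibroglandular = 0.20),
                            high = c(adipose = 0.45, fibroadipose = 0.30, fibroglandular = 0.25)),
                          pixel_pitch_mm = 5,
                          seed = 1L) {
  if (!is_count(n_margins)) stop_ms("`n_margins` must be a non-negative count")
  for (f in c(fraction_positive, fraction_high_mbd, close_fraction))
    if (!is.numeric(f) || f < 0 || f > 1) stop_ms("fractions must lie in [0,1]")
  map_shape <- as.integer(map_shape)
  if (length(map_shape) != 2L || any(map_shape < 2L))
    stop_ms("`map_shape` must be two dims, each >= 2")
  r <- malignant_patch_fraction_range
  if (length(r) != 2L || any(r <= 0) || any(r >= 1) || r[1] > r[2])
    stop_ms("`malignant_patch_fraction_range` must be within (0,1), low <= high")
  if (any(class_params$medians <= 0)) stop_ms("location parameters must be positive")
  for (g in c("low", "high")) {
    pr <- class_proportions[[g]]
    if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0))
      stop_ms("class_proportions$", g, " must be non-negative and sum to 1")
  }
  structure(list(
    n_margins = as.integer(n_margins), fraction_positive = fraction_positive,
    fraction_high_mbd = fraction_high_mbd, map_shape = map_shape,
    spatial_correlation_length = spatial_correlation_length,
    malignant_patch_fraction_range = r, close_fraction = close_fraction,
    close_attenuation = close_attenuation,
    margin_sdlog_shared = margin_sdlog_shared,
    margin_sdlog_param = margin_sdlog_param,
    class_params = class_params, mbd_bc_multiplier = mbd_bc_multiplier,
    mbd_mus_multiplier = mbd_mus_multiplier,
    class_proportions = class_proportions,
    pixel_pitch_mm = pixel_pitch_mm, seed = as.integer(seed)),
    class = "cohort_config")
}

# Gaussian-smoothed white noise field (replicate-padded separable kernel)
smooth_noise_field <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  rad <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    idx <- function(i, n) pmin(pmax(i, 1L), n)
    out <- m * 0
    for (d in (-rad):rad) {
      w <- k[d + rad + 1L]
      if (along_rows) out <- out + w * m[idx(seq_len(nr) + d, nr), , drop = FALSE]
      else out <- out + w * m[, idx(seq_len(nc) + d, nc), drop = FALSE]
    }
    out
  }
  conv1(conv1(z, TRUE), FALSE)
}

# assign spatially clustered classes by ranking the smoothed field and cutting
# at counts proportional to the requested mix (exact up to rounding)
classify_field <- function(field, proportions) {
  npix <- length(field)
  counts <- floor(npix * cumsum(proportions) + 0.5)
  counts <- diff(c(0L, counts))
  counts[length(counts)] <- npix - sum(counts[-length(counts)])
  cls <- rep(names(proportions), times = counts)
  m <- matrix(NA_character_, nrow(field), ncol(field))
  m[order(field)] <- cls
  m
}

# contiguous malignant patch: the n nearest pixels to a random center under a
# randomly stretched metric (elongated, blob-like lesions)
plant_patch <- function(class_mat, n_mal) {
  nr <- nrow(class_mat); nc <- ncol(class_mat)
  cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
  theta <- runif(1, 0, pi); stretch <- runif(1, 1, 2.5)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  d2 <- (u / stretch)^2 + (v * stretch)^2
  sel <- order(d2)[seq_len(n_mal)]
  class_mat[sel] <- "malignant"
  class_mat
}

#' Generate one synthetic margin image
#'
#' Draws a spatially correlated tissue-class landscape (Gaussian-smoothed
#' noise cut at class-proportion quantiles), overlays a contiguous malignant
#' patch for positive/close margins, and fills each measured parameter map
#' with per-class lognormal draws modulated by a margin-level baseline effect
#' and, for high-MBD margins, the density multipliers of the configuration.
#' Ratio maps are added and the tissue-class ground truth is recorded.
#'
#' @param label Margin label: `"negative"`, `"close"` or `"positive"`.
#' @param mbd MBD score 1-4 (1-2 low density, 3-4 high).
#' @param config A [cohort_config].
#' @param seed Integer seed; identical arguments give bit-identical margins.
#' @param margin_id Identifier (default derived from the seed).
#' @param orientation Optional orientation string.
#' @return A [margin_image] with `class_truth` filled in.
#' @export
generate_margin <- function(label, mbd, config = cohort_config(), seed,
                            margin_id = sprintf("margin_%08d", seed %% 1e8),
                            orientation = NA_character_) {
  label <- match.arg(label, MARGIN_LABELS)
  if (!is_count(mbd) || mbd < 1 || mbd > 4) stop_ms("`mbd` must be in 1..4")
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  nr <- config$map_shape[1]; nc <- config$map_shape[2]
  npix <- nr * nc
  group <- if (mbd >= 3) "high" else "low"
  with_seed(seed, {
    field <- smooth_noise_field(nr, nc, config$spatial_correlation_length)
    cls <- classify_field(field, config$class_proportions[[group]])
    if (label != "negative") {
      f <- runif(1, config$malignant_patch_fraction_range[1],
                 config$malignant_patch_fraction_range[2])
      cls <- plant_patch(cls, max(1L, as.integer(round(f * npix))))
    }
    cp <- config$class_params
    shared_fx <- rnorm(1, 0, config$margin_sdlog_shared)
    margin_fx <- exp(shared_fx +
                       rnorm(length(BASE_PARAMETERS), 0, config$margin_sdlog_param))
    names(margin_fx) <- BASE_PARAMETERS
    maps <- list()
    for (p in BASE_PARAMETERS) {
      med <- cp$medians[p, ][cls]          # per-pixel class median
      if (group == "high") {
        if (p == "beta_carotene") med <- med * config$mbd_bc_multiplier[cls]
        if (p == "mus_prime") med <- med * config$mbd_mus_multiplier
      }
      meanlog <- log(med)
      if (label == "close") {
        # attenuate the malignant patch toward fibroglandular on the log scale
        mal <- cls == "malignant"
        fg_med <- cp$medians[p, "fibroglandular"]
        if (group == "high" && p == "mus_prime") fg_med <- fg_med * config$mbd_mus_multiplier
        if (group == "high" && p == "beta_carotene")
          fg_med <- fg_med * config$mbd_bc_multiplier[["fibroglandular"]]
        meanlog[mal] <- config$close_attenuation * meanlog[mal] +
          (1 - config$close_attenuation) * log(fg_med)
      }
      maps[[p]] <- matrix(
        rlnorm(npix, meanlog = meanlog, sdlog = cp$sdlog[p]) * margin_fx[p],
        nr, nc)
    }
    m <- margin_image(margin_id, maps, label, mbd,
                      pixel_pitch_mm = config$pixel_pitch_mm,
                      orientation = orientation, class_truth = cls)
    compute_ratio_maps(m)
  })
}

#' Generate a full synthetic cohort
#'
#' Label and MBD mixes follow the configured fractions with round-half-up
#' allocation (`floor(n * f + 0.5)`); per-margin seeds are derived
#' deterministically from `config$seed`, so the same configuration always
#' yields the identical cohort. Within the high-MBD group scores 3 and 4 are
#' drawn 0.78/0.22 and within low, 1 and 2 are drawn 0.3/0.7 (roughly the
#' typical clinical mix); orientations cycle through the six standard faces.
#'
#' @param config A [cohort_config].
#' @return List of [margin_image] objects with attributes `config` and
#'   `margin_seeds`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_margins
  if (n == 0L) stop_ms("empty cohort: n_margins is 0")
  n_pos_type <- alloc_count(n, config$fraction_positive)
  n_close <- alloc_count(n_pos_type, config$close_fraction)
  labels <- c(rep("close", n_close), rep("positive", n_pos_type - n_close),
              rep("negative", n - n_pos_type))
  n_high <- alloc_count(n, config$fraction_high_mbd)
  orient_pool <- c("anterior", "posterior", "medial", "lateral", "superior", "inferior")
  plan <- with_seed(config$seed, {
    lab <- sample(labels)
    hi <- sample(c(rep(TRUE, n_high), rep(FALSE, n - n_high)))
    mbd <- ifelse(hi, sample(3:4, n, replace = TRUE, prob = c(0.78, 0.22)),
                      sample(1:2, n, replace = TRUE, prob = c(0.30, 0.70)))
    list(lab = lab, mbd = mbd,
         orientation = orient_pool[(seq_len(n) - 1L) %% 6L + 1L],
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  cohort <- lapply(seq_len(n), function(i) {
    generate_margin(plan$lab[i], plan$mbd[i], config, seed = plan$seeds[i],
                    margin_id = sprintf("m%03d", i),
                    orientation = plan$orientation[i])
  })
  attr(cohort, "config") <- config
  attr(cohort, "margin_seeds") <- plan$seeds
  cohort
}
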