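test_that("pooled threshold grid has 19 linear-interpolation quantiles per parameter", {
  co <- small_cohort(n = 8, seed = 2)
  grid <- pooled_quantile_thresholds(co)
  for (p in MARGIN_PARAMETERS) {
    expect_length(grid[[p]], 19)
    expect_true(all(diff(grid[[p]]) >= 0))
  }
  # closed form of the type-7 rule on 1..20
  m <- make_margin("c1", "positive", 1, bc = matrix(1:20, 4, 5),
                   hb = 1, mus = 1)
  g1 <- pooled_quantile_thresholds(list(m))
  expect_equal(g1$beta_carotene[1], 1.95)
  expect_equal(g1$beta_carotene[10], 10.5)   # median quantile
  # constant pool collapses to a constant grid
  mc <- make_margin("c2", "positive", 1, bc = 7, hb = 1, mus = 1)
  expect_true(all(pooled_quantile_thresholds(list(mc))$beta_carotene == 7))
  expect_error(pooled_quantile_thresholds(list()), "empty")
})

test_that("fraction below uses strict inequality and is monotone in the threshold", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(fraction_below(m, 0.5), 0)
  expect_equal(fraction_below(m, 100), 1)
  expect_equal(fraction_below(m, 2.5), 0.5)
  expect_equal(fraction_below(m, 2), 0.25)   # strict: 2 itself not counted
  set.seed(31)
  v <- matrix(stats::rlnorm(50), 5, 10)
  th <- sort(stats::runif(10, 0, 5))
  expect_true(all(diff(vapply(th, function(t) fraction_below(v, t),
                              numeric(1))) >= 0))
  expect_error(fraction_below(matrix(NA_real_, 2, 2), 1), "finite")
})

test_that("image median averages the middle pair and ignores missing pixels", {
  expect_equal(image_median(matrix(c(1, 2, 3), 1)), 2)
  expect_equal(image_median(matrix(c(1, 2, 3, 4), 2)), 2.5)
  expect_equal(image_median(matrix(c(1, NA, 3), 1)), 2)
  set.seed(4)
  v <- stats::rnorm(101)
  expect_equal(image_median(matrix(v, 1)), sort(v)[51])  # sort-based oracle
})

test_that("positive reference pools only close and positive margins", {
  co <- small_cohort(n = 12, seed = 9)
  ref <- positive_reference(co)
  lab <- vapply(co, `[[`, "", "label")
  n_expected <- sum(lab %in% c("close", "positive")) * prod(attr(co, "config")$map_shape)
  expect_length(ref$beta_carotene, n_expected)
  # leave-one-out drops exactly one margin's pixels
  pos_id <- co[[which(lab != "negative")[1]]]$margin_id
  ref_loo <- positive_reference(co, exclude_margin_id = pos_id)
  expect_length(ref_loo$beta_carotene,
                n_expected - prod(attr(co, "config")$map_shape))
  only_neg <- Filter(function(m) m$label == "negative", co)
  expect_error(positive_reference(only_neg), "no close/positive")
})

test_that("KS against the positive reference delegates to the two-sample statistic", {
  co <- small_cohort(n = 10, seed = 14)
  ref <- positive_reference(co)
  lab <- vapply(co, `[[`, "", "label")
  # a margin whose pixels are the entire reference has D = 0
  pos <- co[lab != "negative"]
  combined <- do.call(rbind, lapply(pos, function(m) m$maps$mus_prime))
  expect_equal(ks_vs_positive_reference(combined, ref, "mus_prime"), 0)
  # disjoint support gives D = 1
  far <- matrix(1e6, 4, 4)
  expect_equal(ks_vs_positive_reference(far, ref, "mus_prime"), 1)
  # delegation identity on an arbitrary margin
  m <- co[[1]]
  expect_equal(ks_vs_positive_reference(m$maps$beta_carotene, ref, "beta_carotene"),
               ks_two_sample(as.vector(m$maps$beta_carotene), ref$beta_carotene))
})

test_that("cohort reduction yields exactly 105 ordered features per margin", {
  co <- small_cohort(n = 10, seed = 3)
  full <- reduce_cohort(co)
  expect_length(feature_columns(full), 105)
  expect_equal(nrow(full), 10)
  # stable order and determinism
  full2 <- reduce_cohort(small_cohort(n = 10, seed = 3))
  expect_identical(full, full2)
  # pixel-order invariance: permuting pixels within maps changes nothing
  co_perm <- lapply(co, function(m) {
    set.seed(1); o <- sample(length(m$maps[[1]]))
    m$maps <- lapply(m$maps, function(mp) matrix(mp[o], nrow(mp), ncol(mp)))
    m$class_truth <- NULL
    m
  })
  attr(co_perm, "config") <- attr(co, "config")
  full3 <- reduce_cohort(co_perm, grid = attr(full, "thresholds"),
                         reference = positive_reference(co))
  expect_equal(as.data.frame(full3)[feature_columns(full3)],
               as.data.frame(full)[feature_columns(full)])
})

test_that("a margin constant at the pooled median splits the threshold columns at q50", {
  # cohort: one margin spanning 1..100, one constant at the pooled median
  span <- make_margin("m1", "positive", 1, bc = matrix(1:100, 10, 10),
                      hb = 1, mus = 1, nr = 10, nc = 10)
  grid <- pooled_quantile_thresholds(list(span))
  const_val <- unname(stats::quantile(1:100, 0.5, type = 7))
  cm <- make_margin("m2", "negative", 1, bc = matrix(const_val, 10, 10),
                    hb = 1, mus = 1, nr = 10, nc = 10)
  full <- reduce_cohort(list(span, cm), grid = grid,
                        reference = positive_reference(list(span)))
  fb <- unlist(full[2, paste0("beta_carotene__below_q", sprintf("%02d", seq(5, 95, 5)))])
  expect_true(all(fb[1:9] == 0))    # thresholds below the constant
  expect_true(all(fb[11:19] == 1))  # thresholds above it
})

test_that("optimal-threshold selection keeps 15 columns and finds a planted threshold", {
  co <- small_cohort(n = 20, seed = 16)
  full <- reduce_cohort(co)
  final <- select_optimal_thresholds(full)
  expect_length(feature_columns(final), 15)
  sel <- attr(final, "selected_thresholds")
  expect_equal(nrow(sel), 5)
  expect_setequal(sel$parameter, MARGIN_PARAMETERS)
  # exhaustive Wilcoxon scan oracle: the kept column minimizes p per parameter
  pos <- full$label %in% c("close", "positive")
  for (p in MARGIN_PARAMETERS) {
    cols <- paste0(p, "__below_q", sprintf("%02d", seq(5, 95, 5)))
    pv <- vapply(cols, function(cn)
      wilcoxon_rank_sum(full[[cn]][pos], full[[cn]][!pos])$p, numeric(1))
    chosen <- sel$p_value[sel$parameter == p]
    expect_equal(chosen, min(pv))
    expect_equal(sel$quantile[sel$parameter == p],
                 seq(0.05, 0.95, 0.05)[which.min(pv)])  # tie -> lower quantile
  }
  expect_error(select_optimal_thresholds(full, labels = rep("negative", 20)),
               "both label classes")
})

test_that("a planted excess mass band drives threshold selection above that band", {
  # positives carry extra mass in a narrow band near the pooled 0.22 value of
  # beta-carotene; groups are identical below the band, so only thresholds
  # above it can separate them
  set.seed(30)
  mk <- function(id, label, shift) {
    v <- if (shift) c(stats::runif(80, 0.01, 1), stats::runif(20, 0.215, 0.235))
         else stats::runif(100, 0.01, 1)
    make_margin(id, label, 1, bc = matrix(v, 10, 10), hb = 1,
                mus = 1, nr = 10, nc = 10)
  }
  co <- c(lapply(1:8, function(i) mk(paste0("p", i), "positive", TRUE)),
          lapply(1:8, function(i) mk(paste0("n", i), "negative", FALSE)))
  full <- reduce_cohort(co)
  sel <- attr(select_optimal_thresholds(full), "selected_thresholds")
  bc <- sel[sel$parameter == "beta_carotene", ]
  expect_gt(bc$threshold_value, 0.235)   # must clear the planted band
  expect_lte(bc$quantile, 0.5)           # and not wander into the upper tail
  # strongly separating parameter, unlike the constant hemoglobin map
  expect_lt(bc$p_value, 0.001)
  expect_equal(sel$p_value[sel$parameter == "total_hb"], 1)
})

test_that("feature tables round-trip through CSV with their threshold sidecar", {
  dir <- withr::local_tempdir()
  co <- small_cohort(n = 8, seed = 21)
  full <- reduce_cohort(co)
  final <- select_optimal_thresholds(full)
  p <- file.path(dir, "final.csv")
  write_feature_table(final, p)
  back <- read_feature_table(p)
  expect_equal(as.data.frame(back)[feature_columns(final)],
               as.data.frame(final)[feature_columns(final)])
  expect_equal(attr(back, "selected_thresholds")$threshold_value,
               attr(final, "selected_thresholds")$threshold_value)
})
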