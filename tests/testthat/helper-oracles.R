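# Independent oracles and small fixture builders used across the suite.

# brute-force two-sample KS: evaluate |F_a - F_b| on the pooled support grid
ks_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# exhaustive two-sided Wilcoxon rank-sum p by enumerating all assignments of
# the observed midranks to the first group
wilcox_enum <- function(x, y) {
  r <- rank(c(x, y))
  n_x <- length(x)
  W <- sum(r[seq_len(n_x)])
  mu <- n_x * (length(r) + 1) / 2
  sums <- utils::combn(r, n_x, sum)
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# exhaustive blocked-permutation KS distribution: every assignment of the
# group labels to blocks (as an unordered relabeling)
blocked_enum <- function(values, block_id, block_label) {
  blocks <- unique(block_id)
  labs <- block_label[blocks]
  g1 <- sort(unique(labs))[1]
  n1 <- sum(labs == g1)
  ks_for <- function(assign_g1) {
    lab <- setNames(rep("other", length(blocks)), blocks)
    lab[assign_g1] <- g1
    in1 <- lab[block_id] == g1
    ks_brute(values[in1], values[!in1])
  }
  sets <- utils::combn(blocks, n1, simplify = FALSE)
  vapply(sets, ks_for, numeric(1))
}

# tiny hand-built margin (constant or supplied maps)
make_margin <- function(id, label, mbd, bc, hb, mus, nr = 4, nc = 5,
                        orientation = "anterior") {
  as_map <- function(v) if (is.matrix(v)) v else matrix(v, nr, nc)
  compute_ratio_maps(margin_image(
    id, list(beta_carotene = as_map(bc), total_hb = as_map(hb),
             mus_prime = as_map(mus)),
    label, mbd, orientation = orientation))
}

# small default-structure cohort for reduction / CIT tests
small_cohort <- function(n = 24, seed = 1, ...) {
  generate_cohort(cohort_config(n_margins = n, seed = seed, ...))
}

# pure-noise 105-column feature table with exchangeable labels
noise_feature_table <- function(n, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(stats::rlnorm(n * 105), n))
  names(X) <- paste0(rep(MARGIN_PARAMETERS, each = 21), "__",
                     c(sprintf("below_q%02d", seq(5, 95, 5)), "median", "ks_stat"))
  ft <- cbind(data.frame(margin_id = sprintf("m%02d", seq_len(n)),
                         label = sample(rep(c("negative", "positive"),
                                            length.out = n)),
                         mbd = sample(rep(1:4, length.out = n)),
                         orientation = "anterior",
                         stringsAsFactors = FALSE), X)
  class(ft) <- c("feature_table", "data.frame")
  ft
}
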