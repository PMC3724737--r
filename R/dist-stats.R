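#' Build an empirical cumulative distribution function
#'
#' Returns a step-function representation of the eCDF of a pixel-value sample:
#' F(x) = (number of values <= x) / n. The object stores the sorted unique
#' support and the cumulative step heights, and can be evaluated
#' ([ecdf_eval]) or inverted ([ecdf_quantile]).
#'
#' @param values Numeric vector; non-finite entries are dropped.
#' @return An object of class `margin_ecdf` with fields `x` (sorted unique
#'   support), `F` (step heights) and `n`.
#' @export
build_ecdf <- function(values) {
  v <- finite_vals(as.numeric(values))
  if (length(v) == 0L) stop_ms("empty sample: no finite values")
  s <- sort(v)
  x <- unique(s)
  Fx <- cumsum(tabulate(match(s, x), nbins = length(x))) / length(s)
  structure(list(x = x, F = Fx, n = length(s)), class = "margin_ecdf")
}

#' Evaluate an eCDF (right-continuous step function)
#'
#' @param e A `margin_ecdf` from [build_ecdf].
#' @param q Numeric vector of evaluation points.
#' @return F(q), with F = 0 left of the support and 1 at/after its maximum.
#' @export
ecdf_eval <- function(e, q) {
  stopifnot(inherits(e, "margin_ecdf"))
  idx <- findInterval(q, e$x)           # number of support points <= q
  c(0, e$F)[idx + 1L]
}

#' Invert an eCDF
#'
#' Generalized inverse: the smallest support value x with F(x) >= p.
#'
#' @param e A `margin_ecdf`.
#' @param p Probabilities in (0, 1].
#' @return Quantile values.
#' @export
ecdf_quantile <- function(e, p) {
  stopifnot(inherits(e, "margin_ecdf"), all(p > 0 & p <= 1))
  e$x[vapply(p, function(pp) which(e$F >= pp - 1e-12)[1L], integer(1))]
}

#' @export
print.margin_ecdf <- function(x, ...) {
  cat(sprintf("<margin_ecdf> n=%d, support [%g, %g]\n",
              x$n, x$x[1L], x$x[length(x$x)]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup over x of |F_a(x) - F_b(x)|, the maximum vertical distance between
#' the two empirical CDFs. Symmetric in its arguments and invariant under any
#' strictly monotone transform applied to both samples. Only the statistic is
#' returned; inference in this pipeline is by blocked permutation
#' ([blocked_permutation_pvalue]), not asymptotics.
#'
#' @param a,b Numeric samples (non-finite values dropped; must be non-empty
#'   after dropping).
#' @return D in \[0, 1\].
#' @export
ks_two_sample <- function(a, b) {
  a <- finite_vals(as.numeric(a)); b <- finite_vals(as.numeric(b))
  if (length(a) == 0L || length(b) == 0L) stop_ms("empty sample in KS statistic")
  # classic pooled-sort formulation: cumulative difference of normalized steps
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  o <- order(pooled)
  steps <- c(rep(1 / n_a, n_a), rep(-1 / n_b, n_b))[o]
  cum <- cumsum(steps)
  # at tied pooled values only the value after the full tie group counts
  z <- pooled[o]
  keep <- c(diff(z) != 0, TRUE)
  max(abs(cum[keep]))
}

#' Assemble a blocked pixel sample
#'
#' Pixels from the same margin are correlated; the margin is therefore the
#' exchangeable unit ("block") in permutation inference. A `blocked_sample`
#' carries pixel values, the block id of each value, and one group label per
#' block (e.g. positive / negative).
#'
#' @param values Numeric pixel values.
#' @param block_id Vector, same length as `values`; identifies each value's
#'   block (margin).
#' @param block_label Either a vector parallel to `values` (constant within
#'   block) or a named vector mapping block id to label. Exactly two distinct
#'   labels are required.
#' @return An object of class `blocked_sample`.
#' @export
blocked_sample <- function(values, block_id, block_label) {
  values <- as.numeric(values)
  if (length(block_id) != length(values))
    stop_ms("`block_id` must parallel `values`")
  block_id <- as.character(block_id)
  blocks <- unique(block_id)
  if (length(block_label) == length(values) && is.null(names(block_label))) {
    lab_by_block <- tapply(as.character(block_label), block_id, function(l) {
      u <- unique(l)
      if (length(u) != 1L) stop_ms("block has more than one label")
      u
    })
    lab <- lab_by_block[blocks]
  } else {
    if (is.null(names(block_label)) || !all(blocks %in% names(block_label)))
      stop_ms("`block_label` must be named by block id or parallel `values`")
    lab <- as.character(block_label[blocks])
  }
  names(lab) <- blocks
  if (length(unique(lab)) != 2L)
    stop_ms("exactly two group labels are required")
  keep <- is.finite(values)
  structure(list(values = values[keep], block_id = block_id[keep],
                 block_label = lab),
            class = "blocked_sample")
}

#' Blocked-permutation p-value for the two-sample KS statistic
#'
#' Computes the observed KS statistic between the two label groups' pooled
#' pixels, then permutes the group labels over whole blocks (margins) - pixels
#' travel with their block, preserving within-margin correlation - and reports
#' the add-one empirical p-value p = (1 + #\{D_perm >= D_obs\}) / (n_perm + 1).
#' The add-one estimator never returns 0 and is exactly valid for any finite
#' number of permutations; ties count against rejection (>=, conservative).
#'
#' @param sample A [blocked_sample] (or the arguments to build one).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return List with `D_obs`, `p`, `n_perm`, and `D_perm` (the permuted
#'   statistics).
#' @export
blocked_permutation_pvalue <- function(sample, n_perm = 1000L, seed = 1L) {
  if (!inherits(sample, "blocked_sample"))
    stop_ms("`sample` must be a blocked_sample")
  if (!is_count(n_perm) || n_perm < 1L) stop_ms("`n_perm` must be a positive count")
  lab <- sample$block_label
  groups <- sort(unique(lab))
  if (min(table(lab)) < 2L)
    stop_ms("degenerate design: need at least 2 blocks per group")
  blk <- sample$block_id
  val <- sample$values
  in_g1_block <- lab == groups[1L]
  pix_group1 <- in_g1_block[blk]        # named-lookup by block id
  D_obs <- ks_two_sample(val[pix_group1], val[!pix_group1])
  nb <- length(lab)
  D_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- lab[sample.int(nb)]
    names(perm) <- names(lab)
    g1 <- (perm == groups[1L])[blk]
    ks_two_sample(val[g1], val[!g1])
  }, numeric(1)))
  p <- (1 + sum(D_perm >= D_obs)) / (n_perm + 1)
  list(D_obs = D_obs, p = p, n_perm = as.integer(n_perm), D_perm = D_perm)
}

#' Difference of two eCDFs on a shared grid
#'
#' F_pos(x) - F_neg(x) evaluated per grid point. Negative values indicate the
#' "negative" distribution carries more mass at low values (i.e. the negative
#' margins have higher values at that point of the scale); the curve's
#' extremum magnitude equals the two-sample KS distance when the grid contains
#' the pooled support.
#'
#' @param ecdf_pos,ecdf_neg `margin_ecdf` objects.
#' @param grid Numeric evaluation grid (non-empty).
#' @return Data frame with columns `x` and `delta`.
#' @export
difference_ecdf <- function(ecdf_pos, ecdf_neg, grid) {
  if (length(grid) == 0L) stop_ms("empty evaluation grid")
  data.frame(x = as.numeric(grid),
             delta = ecdf_eval(ecdf_pos, grid) - ecdf_eval(ecdf_neg, grid))
}

# cache of exact rank-sum null distributions keyed by the midrank multiset and
# group size; with continuous data ranks are always 1..n so the cache hits
.wilcox_exact_cache <- new.env(parent = emptyenv())

exact_ranksum_tail <- function(ranks, n_x) {
  key <- paste0(n_x, "|", paste(signif(sort(ranks), 12), collapse = ","))
  dist <- .wilcox_exact_cache[[key]]
  if (is.null(dist)) {
    sums <- combn(ranks, n_x, sum)
    dist <- sums
    .wilcox_exact_cache[[key]] <- dist
  }
  dist
}

#' Wilcoxon rank-sum test (midranks; exact for small samples)
#'
#' Two-sided two-sample Wilcoxon/Mann-Whitney test with midranks for ties.
#' When the combined sample size is at most 12, the null distribution of the
#' rank sum is obtained by exact enumeration over all assignments of the
#' observed (mid)ranks to the first group; otherwise a normal approximation
#' with tie correction and a 0.5 continuity correction is used. If every value
#' is identical across both groups the test is vacuous and p = 1.
#'
#' @param x,y Numeric samples (non-finite dropped; non-empty after dropping).
#' @param exact_max Combined-size cutoff for the exact branch (default 12).
#' @return List with `statistic` (rank sum of `x`, midranks) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  x <- finite_vals(as.numeric(x)); y <- finite_vals(as.numeric(y))
  if (length(x) == 0L || length(y) == 0L) stop_ms("empty group in Wilcoxon test")
  wilcox_core(c(x, y), length(x), exact_max)
}

# hot path shared by the test, threshold selection and the CIT scan:
# v = c(first group, second group), all finite
wilcox_core <- function(v, n_x, exact_max = 12L) {
  n <- length(v)
  r <- rank(v)                             # midranks
  W <- sum(r[seq_len(n_x)])
  mu <- n_x * (n + 1) / 2
  # tie sizes from sorted ranks (avoids table())
  rs <- sort.int(r, method = "quick")
  starts <- which(c(TRUE, rs[-1L] != rs[-n]))
  tsz <- diff(c(starts, n + 1L))
  tie_term <- sum(tsz^3 - tsz)
  if (tie_term == n^3 - n)                 # every value identical
    return(list(statistic = W, p = 1))
  if (n <= exact_max) {
    dist <- exact_ranksum_tail(r, n_x)
    p <- mean(abs(dist - mu) >= abs(W - mu) - 1e-9)
  } else {
    sigma2 <- n_x * (n - n_x) / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- max((abs(W - mu) - 0.5) / sqrt(sigma2), 0)
    p <- min(1, 2 * pnorm(-z))
  }
  list(statistic = W, p = p)
}

# p-values of the Wilcoxon test of each column of X against logical grouping g
# (TRUE = first group)
wilcoxon_scan <- function(X, g) {
  n_x <- sum(g)
  ord <- c(which(g), which(!g))
  vapply(seq_len(ncol(X)), function(j) wilcox_core(X[ord, j], n_x)$p, numeric(1))
}
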