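test_that("eCDF construction, evaluation and inversion behave as step functions", {
  e <- build_ecdf(c(1, 2, 2, 3))
  expect_equal(ecdf_eval(e, 2), 0.75)
  expect_equal(ecdf_eval(e, 0), 0)       # below support
  expect_equal(ecdf_eval(e, 3), 1)       # at max
  expect_equal(ecdf_eval(e, 10), 1)

  dup <- build_ecdf(c(5, 5, 5))
  expect_equal(ecdf_eval(dup, 5), 1)
  expect_equal(ecdf_eval(dup, 4.999), 0)

  expect_equal(ecdf_quantile(e, c(0.25, 0.75, 1)), c(1, 2, 3))
  expect_error(build_ecdf(numeric(0)), "empty")
  expect_error(build_ecdf(c(NA, NaN)), "empty")
})

test_that("eCDF evaluated at its own sample points reproduces ranks/n", {
  set.seed(71)
  for (i in 1:20) {
    v <- round(stats::rnorm(30), sample(0:2, 1))  # force some ties
    e <- build_ecdf(v)
    expect_equal(ecdf_eval(e, v),
                 vapply(v, function(x) mean(v <= x), numeric(1)))
  }
})

test_that("two-sample KS statistic matches direct counting", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_two_sample(1:4, 2:5), 0.25)
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("KS agrees with brute-force grid oracle and stats::ks.test on random instances", {
  set.seed(42)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    # mix continuous and heavily tied integer samples
    a <- if (i %% 2) stats::rnorm(n1) else sample(0:4, n1, replace = TRUE)
    b <- if (i %% 2) stats::rnorm(n2, 0.5) else sample(0:4, n2, replace = TRUE)
    d <- ks_two_sample(a, b)
    expect_equal(d, ks_brute(a, b))
    expect_equal(d, ks_two_sample(b, a))  # symmetry
  }
  set.seed(43)
  for (i in 1:25) {
    a <- stats::rnorm(20); b <- stats::rnorm(15, 0.3)
    expect_equal(ks_two_sample(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  }
})

test_that("KS is invariant under strictly monotone transforms of both samples", {
  set.seed(7)
  a <- stats::rlnorm(25); b <- stats::rlnorm(20, 0.4)
  d <- ks_two_sample(a, b)
  expect_equal(ks_two_sample(log(a), log(b)), d)
  expect_equal(ks_two_sample(a^3, b^3), d)
})

test_that("difference eCDF is zero for identical inputs and peaks at the KS distance", {
  set.seed(5)
  a <- stats::rnorm(40); b <- stats::rnorm(35, 0.8)
  ea <- build_ecdf(a); eb <- build_ecdf(b)
  grid <- sort(c(a, b))
  same <- difference_ecdf(ea, ea, grid)
  expect_true(all(same$delta == 0))
  diffc <- difference_ecdf(ea, eb, grid)
  expect_equal(max(abs(diffc$delta)), ks_two_sample(a, b))
  # a sample shifted left has uniformly higher CDF
  expect_true(all(difference_ecdf(eb, build_ecdf(b + 2), sort(c(b, b + 2)))$delta >= 0))
  expect_error(difference_ecdf(ea, eb, numeric(0)), "empty")
})

test_that("Wilcoxon exact branch reproduces full enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                 # 2 of the 20 rank assignments
  expect_equal(r$statistic, 6)
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2))$p, 1)  # vacuous
  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)  # ties exercised
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_enum(x, y))
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  }
})

test_that("Wilcoxon exact branch matches stats::wilcox.test on tie-free samples", {
  set.seed(12)
  for (i in 1:25) {
    x <- stats::rnorm(sample(3:6, 1)); y <- stats::rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Wilcoxon exact and normal branches agree within 0.02 at combined n = 12", {
  set.seed(13)
  for (i in 1:50) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, 0.5)
    p_exact <- wilcoxon_rank_sum(x, y, exact_max = 12L)$p
    p_norm <- wilcoxon_rank_sum(x, y, exact_max = 0L)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("blocked samples validate their block structure", {
  expect_error(blocked_sample(1:4, c(1, 1, 2, 2), c("a", "b", "a", "b")),
               "more than one label")
  expect_error(blocked_sample(1:4, c(1, 1, 2, 2), c("a", "a", "a", "a")),
               "two group labels")
  bs <- blocked_sample(1:6, c(1, 1, 2, 2, 3, 3),
                       c("a", "a", "a", "a", "b", "b"))
  expect_s3_class(bs, "blocked_sample")
  expect_error(blocked_permutation_pvalue(bs, 10, 1), "degenerate")
})

test_that("blocked permutation matches exhaustive enumeration on tiny designs", {
  set.seed(3)
  vals <- c(stats::rnorm(5), stats::rnorm(5), stats::rnorm(5, 1), stats::rnorm(5, 1))
  bid <- rep(1:4, each = 5)
  lab <- rep(c("neg", "neg", "pos", "pos"), each = 5)
  bs <- blocked_sample(vals, bid, lab)
  res <- blocked_permutation_pvalue(bs, n_perm = 2000, seed = 9)
  # oracle: all C(4,2)=6 block relabelings
  dist <- blocked_enum(vals, as.character(bid),
                       setNames(c("neg", "neg", "pos", "pos"), 1:4))
  p_exhaustive <- mean(dist >= res$D_obs - 1e-12)
  # add-one MC estimate converges to the exhaustive value
  expect_lt(abs(res$p - p_exhaustive), 0.05)
  # the observed statistic matches the pooled-group KS
  expect_equal(res$D_obs, ks_brute(vals[lab == "neg"], vals[lab == "pos"]))
})

test_that("add-one estimator floors at 1/(n_perm+1) when D_obs beats every permutation", {
  # two well-separated groups of blocks: no relabeling can beat the truth
  vals <- c(rep(0, 10), rep(0.1, 10), rep(10, 10), rep(10.1, 10),
            rep(0.2, 10), rep(10.2, 10))
  bid <- rep(1:6, each = 10)
  lab <- rep(c("a", "a", "b", "b", "a", "b"), each = 10)
  res <- blocked_permutation_pvalue(blocked_sample(vals, bid, lab),
                                    n_perm = 99, seed = 2)
  expect_equal(res$D_obs, 1)
  # D_perm can tie D_obs only for relabelings equal to truth or its mirror
  expect_gte(res$p, 1 / 100)
  expect_lt(res$p, 0.25)
})

test_that("singleton blocks reduce blocked permutation to the unblocked test", {
  set.seed(21)
  vals <- c(stats::rnorm(6), stats::rnorm(6, 1.5))
  bid <- as.character(1:12)
  lab <- rep(c("x", "y"), each = 6)
  dist_blocked <- blocked_enum(vals, bid, setNames(lab, bid))
  # unblocked oracle: permute value-level labels directly
  sets <- utils::combn(1:12, 6, simplify = FALSE)
  dist_unblocked <- vapply(sets, function(s)
    ks_brute(vals[s], vals[-s]), numeric(1))
  expect_equal(sort(dist_blocked), sort(dist_unblocked))
})

test_that("blocked permutation p is calibrated under the null", {
  # all blocks from one distribution (block effects, no group effect)
  rej <- vapply(1:120, function(s) {
    set.seed(s + 500)
    nb <- 10; npx <- 20
    be <- stats::rnorm(nb, 0, 0.3)
    vals <- unlist(lapply(seq_len(nb), function(b) stats::rlnorm(npx, be[b], 0.4)))
    bid <- rep(seq_len(nb), each = npx)
    lab <- rep(c("A", "B"), each = nb / 2)
    bs <- blocked_sample(vals, bid, lab[bid])
    blocked_permutation_pvalue(bs, n_perm = 99, seed = s)$p <= 0.05
  }, logical(1))
  # binomial 95% envelope around 0.05 for 120 runs reaches ~0.09
  expect_lte(mean(rej), 0.09)
})
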