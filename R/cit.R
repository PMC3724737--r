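#' MBD group from the 1-4 density score
#'
#' Scores 1-2 are low density, 3-4 high density.
#'
#' @param mbd Integer vector of MBD scores.
#' @return Character vector `"low"` / `"high"`.
#' @export
mbd_group <- function(mbd) {
  if (any(!mbd %in% 1:4)) stop_ms("MBD scores must be in 1..4")
  ifelse(mbd >= 3, "high", "low")
}

# absolute standardized two-sample linear statistic of x against binary y,
# identity influence function: |sum_{y=1} x - n1 xbar| / permutation sd
identity_z <- function(x, y) {
  n <- length(y); n1 <- sum(y)
  vx <- var(x) * (n - 1) / n
  if (vx == 0 || n1 == 0 || n1 == n) return(0)
  sigma2 <- n1 * (n - n1) / (n - 1) * vx
  abs(sum(x[y == 1L]) - n1 * mean(x)) / sqrt(sigma2)
}

# standardized two-sample linear statistic for a cut of x at c against binary
# y: |sum_{x<=c} y - n_L ybar| / sd under the permutation null
best_cutpoint <- function(x, y, min_leaf) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (head(ux, -1L) + ux[-1L]) / 2
  n <- length(y); ybar <- mean(y); vy <- mean((y - ybar)^2)
  if (vy == 0) return(NULL)
  best <- NULL; best_z <- -Inf
  for (cc in cuts) {
    left <- x <= cc
    n_l <- sum(left)
    if (n_l < min_leaf || (n - n_l) < min_leaf) next
    sigma2 <- n_l * (n - n_l) / (n - 1) * vy
    z <- abs(sum(y[left]) - n_l * ybar) / sqrt(sigma2)
    if (z > best_z + 1e-12) { best_z <- z; best <- cc }
  }
  best
}

# recursive partitioning within one stratum
grow_node <- function(X, y, vars, alpha, min_leaf, depth, max_depth) {
  n <- length(y)
  leaf <- function() {
    n_pos <- sum(y)
    list(kind = "leaf",
         leaf_label = if (n_pos > n - n_pos) "positive" else "negative",
         leaf_counts = c(positive = n_pos, negative = n - n_pos))
  }
  if (n < 2L * min_leaf || length(unique(y)) < 2L || depth >= max_depth)
    return(leaf())
  pvals <- wilcoxon_scan(X, y == 1L)
  adj <- pmin(1, pvals * length(vars))    # Bonferroni across candidates
  # rank-test p-values hit a discreteness floor when several variables separate
  # the classes perfectly; break such ties by the standardized linear statistic
  # with identity scores (a continuous, scale-free effect size)
  tied <- which(adj <= min(adj) * (1 + 1e-9))
  j <- if (length(tied) == 1L) tied else tied[which.max(
    vapply(tied, function(k) identity_z(X[, k], y), numeric(1)))]
  if (adj[j] > alpha) return(leaf())
  cut <- best_cutpoint(X[, j], y, min_leaf)
  if (is.null(cut)) return(leaf())
  left <- X[, j] <= cut
  list(kind = "variable_split", variable = vars[j], cutpoint = cut,
       association_p = adj[j],
       children = list(
         left = grow_node(X[left, , drop = FALSE], y[left], vars,
                          alpha, min_leaf, depth + 1L, max_depth),
         right = grow_node(X[!left, , drop = FALSE], y[!left], vars,
                           alpha, min_leaf, depth + 1L, max_depth)))
}

#' Fit the MBD-stratified conditional inference tree
#'
#' The root node always splits on mammographic-density group (MBD 1-2 vs
#' 3-4); margins are classified into density strata before any data-driven
#' split, so baseline optical differences between density groups are absorbed
#' by design. Within each stratum the tree grows recursively: each candidate
#' variable's association with the binary diagnosis is tested with the
#' Wilcoxon rank-sum (the conditional-inference test for a numeric variable
#' against a binary response), p-values are Bonferroni-adjusted across the
#' candidates, growth stops when the smallest adjusted p exceeds `alpha`, and
#' otherwise the winning variable is split at the cutpoint maximizing the
#' standardized two-sample statistic over midpoints of its sorted unique
#' values, subject to `min_leaf` cases per side. Leaves carry majority labels
#' (ties resolve to negative).
#'
#' @param final_table A `feature_table` (typically the 15-variable table from
#'   [select_optimal_thresholds]); metadata columns are ignored as
#'   predictors.
#' @param labels Optional margin labels (default: table's `label` column);
#'   close+positive lumped as positive.
#' @param mbd Optional MBD scores (default: table's `mbd` column).
#' @param alpha Significance level for split admission (default 0.05).
#' @param min_leaf Minimum cases per child (default 7).
#' @param max_depth Maximum variable-split depth per stratum (default 5).
#' @return A `cit_model`: root stratum split with one subtree per density
#'   stratum, plus the fit settings.
#' @export
fit_cit <- function(final_table, labels = NULL, mbd = NULL,
                    alpha = 0.05, min_leaf = 7L, max_depth = 5L) {
  if (is.null(labels)) labels <- final_table$label
  if (is.null(mbd)) mbd <- final_table$mbd
  y <- as.integer(binarize_labels(labels))
  if (length(unique(y)) < 2L) stop_ms("both classes required to fit")
  vars <- feature_columns(final_table)
  X <- as.matrix(as.data.frame(final_table)[vars])
  if (!is.numeric(X)) stop_ms("feature columns must be numeric")
  grp <- mbd_group(mbd)
  strata <- list()
  warnings <- character(0)
  for (g in c("low", "high")) {
    idx <- grp == g
    if (!any(idx)) {
      maj <- if (mean(y) > 0.5) "positive" else "negative"
      strata[[g]] <- list(kind = "leaf", leaf_label = maj,
                          leaf_counts = c(positive = 0L, negative = 0L))
      warnings <- c(warnings, paste0("stratum '", g,
                                     "' is empty; emitted overall-majority leaf"))
      next
    }
    strata[[g]] <- grow_node(X[idx, , drop = FALSE], y[idx], vars,
                             alpha, min_leaf, 0L, max_depth)
  }
  structure(list(
    root = list(kind = "stratum_split", variable = "mbd_group",
                children = strata),
    alpha = alpha, min_leaf = as.integer(min_leaf),
    max_depth = as.integer(max_depth), feature_names = vars,
    warnings = warnings),
    class = "cit_model")
}

route_row <- function(node, row) {
  while (node$kind != "leaf") {
    v <- row[[node$variable]]
    if (is.null(v) || is.na(v)) stop_ms("missing feature '", node$variable, "'")
    node <- if (v <= node$cutpoint) node$children$left else node$children$right
  }
  node$leaf_label
}

#' Predict margin status with a fitted CIT
#'
#' Deterministically routes each margin through the density stratum and the
#' stratum's variable splits to a leaf.
#'
#' @param object A `cit_model`.
#' @param newdata A `feature_table` (or data frame) containing `mbd` and every
#'   variable the model uses.
#' @param ... Unused.
#' @return Character vector of `"positive"` / `"negative"` predictions.
#' @export
predict.cit_model <- function(object, newdata, ...) {
  missing <- setdiff(used_variables(object), names(newdata))
  if (length(missing))
    stop_ms("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
  if (!"mbd" %in% names(newdata)) stop_ms("newdata lacks `mbd`")
  grp <- mbd_group(newdata$mbd)
  vapply(seq_len(nrow(newdata)), function(i) {
    route_row(object$root$children[[grp[i]]], as.list(newdata[i, , drop = FALSE]))
  }, character(1))
}

# variables actually referenced by splits
used_variables <- function(model) {
  rec <- function(node) {
    if (node$kind == "leaf") return(character(0))
    if (node$kind == "stratum_split")
      return(unique(unlist(lapply(node$children, rec))))
    c(node$variable, rec(node$children$left), rec(node$children$right))
  }
  unique(rec(model$root))
}

#' Variables selected per density stratum
#'
#' @param model A `cit_model`.
#' @return Named list (`low`, `high`) of character vectors of split variables
#'   in order of selection depth.
#' @export
selected_variables <- function(model) {
  rec <- function(node) {
    if (node$kind == "leaf") return(character(0))
    c(node$variable, rec(node$children$left), rec(node$children$right))
  }
  lapply(model$root$children, rec)
}

#' @export
print.cit_model <- function(x, ...) {
  cat("<cit_model> root: stratum split on MBD group\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      cat(sprintf("%sleaf -> %s (pos=%d, neg=%d)\n", pad, node$leaf_label,
                  node$leaf_counts[["positive"]], node$leaf_counts[["negative"]]))
    } else {
      cat(sprintf("%s%s <= %.4g (adj p=%.3g)\n", pad, node$variable,
                  node$cutpoint, node$association_p))
      show(node$children$left, indent + 1L)
      show(node$children$right, indent + 1L)
    }
  }
  for (g in names(x$root$children)) {
    cat(" stratum:", g, "\n")
    show(x$root$children[[g]], 2L)
  }
  invisible(x)
}

#' Confusion-matrix performance summary
#'
#' Sensitivity, specificity, positive/negative predictive value, and accuracy
#' from predicted vs true binary margin status (close+positive lumped as
#' positive). Ratios with zero denominators are reported as `NA` (undefined),
#' never as 0.
#'
#' @param predicted Character/logical predictions (`"positive"`/`"negative"`
#'   or TRUE/FALSE).
#' @param truth True labels (any of negative/close/positive, or logical).
#' @return A `performance_summary` list: `counts` (TP, FP, TN, FN) and `Se`,
#'   `Sp`, `PPV`, `NPV`, `A`.
#' @export
confusion_metrics <- function(predicted, truth) {
  to_bin <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x > 0.5)
    binarize_labels(as.character(x))
  }
  p <- to_bin(predicted); t <- to_bin(truth)
  if (length(p) != length(t)) stop_ms("length mismatch")
  TP <- sum(p & t); FP <- sum(p & !t); TN <- sum(!p & !t); FN <- sum(!p & t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
    Se = ratio(TP, TP + FN), Sp = ratio(TN, TN + FP),
    PPV = ratio(TP, TP + FP), NPV = ratio(TN, TN + FN),
    A = ratio(TP + TN, length(p))),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Se=%.3f Sp=%.3f PPV=%.3f NPV=%.3f A=%.3f (TP=%d FP=%d TN=%d FN=%d)\n",
              x$Se, x$Sp, x$PPV, x$NPV, x$A,
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]]))
  invisible(x)
}

#' Model discrepancy statistic F
#'
#' F = (1 - sensitivity)^2 + (1 - specificity)^2; minimized by well-performing
#' models. Undefined Se or Sp counts as 0 performance (worst case) so F stays
#' computable for degenerate fits.
#'
#' @param se,sp Sensitivity and specificity (NA treated as 0).
#' @return Numeric F >= 0.
#' @export
model_f_statistic <- function(se, sp) {
  if (is.na(se)) se <- 0
  if (is.na(sp)) sp <- 0
  (1 - se)^2 + (1 - sp)^2
}

# full model-building chain on one label assignment: threshold selection ->
# CIT fit -> resubstitution predictions
fit_full_chain <- function(full_table, labels, alpha, min_leaf) {
  final <- select_optimal_thresholds(full_table, labels = labels)
  model <- fit_cit(final, labels = labels, mbd = final$mbd,
                   alpha = alpha, min_leaf = min_leaf)
  pred <- predict(model, final)
  perf <- confusion_metrics(pred, labels)
  list(model = model, final = final, perf = perf,
       F = model_f_statistic(perf$Se, perf$Sp))
}

#' Permutation significance of the full classification model
#'
#' Rebuilds the entire model - optimal-threshold selection, variable
#' selection, tree growth - on label vectors permuted without replacement,
#' and compares the resubstitution discrepancy F = (1-Se)^2 + (1-Sp)^2 of the
#' observed model against the permuted models. Permuting before selection
#' charges the significance estimate for the whole model-building procedure,
#' not just the final tree.
#'
#' Two estimates are returned. `p` is the add-one, tie-inclusive estimator
#' (1 + #\{F_perm <= F_obs\}) / (n_perm + 1), which is a valid p-value for any
#' finite number of permutations: because F takes few distinct values under
#' resubstitution (every confusion table maps to one of finitely many F
#' atoms), an estimator that excludes ties is anti-conservative, so `p` is
#' what the package treats as the model's significance. `p_strict` is the
#' plain fraction #\{F_perm < F_obs\} / n_perm - the probability that a model
#' built on shuffled diagnoses strictly outperforms the observed one -
#' reported for comparability with the classical description of this
#' procedure.
#'
#' @param full_table The 105-variable `feature_table` from [reduce_cohort]
#'   (with `label` and `mbd` columns).
#' @param labels Optional label vector (default: table's `label`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alpha,min_leaf Passed to [fit_cit].
#' @return List with `F_obs`, `p` (add-one, tie-inclusive), `p_strict` (plain
#'   strictly-better fraction), `n_perm`, `perf_obs` (observed
#'   [confusion_metrics]), `model_obs` and `F_perm`.
#' @export
model_significance <- function(full_table, labels = NULL, n_perm = 1000L,
                               seed = 1L, alpha = 0.05, min_leaf = 7L) {
  if (is.null(labels)) labels <- full_table$label
  if (!is_count(n_perm) || n_perm < 1L) stop_ms("`n_perm` must be >= 1")
  obs <- fit_full_chain(full_table, labels, alpha, min_leaf)
  n <- length(labels)
  F_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm_labels <- labels[sample.int(n)]
    fit_full_chain(full_table, perm_labels, alpha, min_leaf)$F
  }, numeric(1)))
  list(F_obs = obs$F,
       p = (1 + sum(F_perm <= obs$F)) / (n_perm + 1),
       p_strict = sum(F_perm < obs$F) / n_perm,
       n_perm = as.integer(n_perm), perf_obs = obs$perf,
       model_obs = obs$model, F_perm = F_perm)
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore a CIT model as JSON
#'
#' @param model A `cit_model`.
#' @param path JSON file path.
#' @return `write_cit_model` returns `path` invisibly; `read_cit_model`
#'   returns the restored `cit_model`.
#' @export
write_cit_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cit_model
#' @export
read_cit_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(node) {
    if (!is.null(node$leaf_counts)) node$leaf_counts <- unlist(node$leaf_counts)
    if (!is.null(node$children)) node$children <- lapply(node$children, fix)
    node
  }
  m$root <- fix(m$root)
  m$feature_names <- unlist(m$feature_names)
  structure(m, class = "cit_model")
}

#' Table-3-style performance report
#'
#' Confusion metrics overall, by MBD density group, and (when orientation
#' metadata is present) by anterior/posterior vs other orientation.
#'
#' @param predicted,truth As in [confusion_metrics].
#' @param mbd MBD scores per margin.
#' @param orientation Optional orientation strings.
#' @return Data frame with one row per subgroup and columns `group`, `n`,
#'   `Se`, `Sp`, `PPV`, `NPV`, `A`.
#' @export
performance_report <- function(predicted, truth, mbd, orientation = NULL) {
  row_for <- function(name, idx) {
    cm <- confusion_metrics(predicted[idx], truth[idx])
    data.frame(group = name, n = sum(idx), Se = cm$Se, Sp = cm$Sp,
               PPV = cm$PPV, NPV = cm$NPV, A = cm$A)
  }
  out <- rbind(row_for("all", rep(TRUE, length(predicted))),
               row_for("mbd_low", mbd_group(mbd) == "low"),
               row_for("mbd_high", mbd_group(mbd) == "high"))
  if (!is.null(orientation) && !all(is.na(orientation))) {
    ap <- orientation %in% c("anterior", "posterior")
    out <- rbind(out, row_for("anterior_posterior", ap),
                 row_for("other_orientation", !ap))
  }
  rownames(out) <- NULL
  out
}
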