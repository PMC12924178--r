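# Explainability stage: exact Shapley values by coalition enumeration, a
# fast interventional tree-ensemble pass (Rcpp), physical feature grouping,
# and global / per-interval importance summaries.
#
# Both paths use the same interventional value function: f(S) is the mean
# model output over the background rows of the hybrid input that takes the
# features in S from the explained instance and the rest from the
# background row. With that convention the additive decomposition
# phi_0 + sum(phi_i) = prediction holds exactly, with phi_0 the mean model
# output over the background.

#' Exact Shapley values by brute-force coalition enumeration
#'
#' For every feature i,
#' \deqn{\phi_i = \sum_{S \subseteq N \setminus \{i\}}
#'   \frac{|S|!\,(|N|-|S|-1)!}{|N|!}\,(f(S \cup \{i\}) - f(S))}
#' with the interventional value function described above. All \eqn{2^{|N|}}
#' coalitions are enumerated, so the feature set is capped at 15.
#'
#' @param predict_fn Function taking a numeric matrix (rows = inputs,
#'   columns = features) and returning a numeric vector of model outputs.
#' @param instance Named numeric vector (or one-row data frame) to explain.
#' @param background Matrix or data frame of background rows (same columns).
#' @param feature_names Features to attribute over; defaults to the
#'   background columns.
#' @return Object of class `shapley_attribution`: list with `phi` (named
#'   vector), `base_value` (mean background prediction) and `prediction`
#'   (model output for the instance).
#' @export
exact_shapley <- function(predict_fn, instance, background,
                          feature_names = NULL) {
  bg <- as.matrix(background)
  if (is.data.frame(instance)) instance <- unlist(instance[1, , drop = TRUE])
  if (is.null(feature_names)) feature_names <- colnames(bg)
  stopifnot(!is.null(feature_names), all(feature_names %in% names(instance)),
            all(feature_names %in% colnames(bg)), nrow(bg) >= 1)
  n <- length(feature_names)
  if (n > 15) stop("exact enumeration capped at 15 features (2^n coalitions)")
  x <- as.numeric(instance[feature_names])
  bg <- bg[, feature_names, drop = FALSE]
  m <- nrow(bg)
  n_masks <- bitwShiftL(1L, n)

  # hybrid inputs for every coalition, one predict call
  H <- bg[rep(seq_len(m), n_masks), , drop = FALSE]
  mask_of_row <- rep(seq_len(n_masks) - 1L, each = m)
  for (j in seq_len(n)) {
    sel <- bitwAnd(mask_of_row, bitwShiftL(1L, j - 1L)) != 0L
    H[sel, j] <- x[j]
  }
  v <- vapply(split(predict_fn(H), mask_of_row), mean, numeric(1))
  v <- unname(v[order(as.integer(names(v)))])

  popcount <- vapply(0:(n_masks - 1L), function(mm) sum(
    bitwAnd(mm, bitwShiftL(1L, 0:(n - 1L))) != 0L), numeric(1))
  w <- factorial(0:(n - 1)) * factorial(n - (0:(n - 1)) - 1) / factorial(n)
  phi <- vapply(seq_len(n), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    no_i <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L)
    sum(w[popcount[no_i] + 1] * (v[no_i + bit] - v[no_i]))
  }, numeric(1))
  structure(list(phi = stats::setNames(phi, feature_names),
                 base_value = v[1], prediction = v[n_masks]),
            class = "shapley_attribution")
}

# flatten a ranger forest into the plain arrays the C++ pass consumes
.extract_forest <- function(forest) {
  stopifnot(inherits(forest, "ranger"))
  if (forest$treetype != "Regression")
    stop("only regression forests are supported")
  ivn <- forest$forest$independent.variable.names
  lapply(seq_len(forest$num.trees), function(t) {
    ti <- ranger::treeInfo(forest, t)
    feat <- match(ti$splitvarName, ivn) - 1L
    feat[is.na(feat)] <- -1L
    list(left = ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild)),
         right = ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild)),
         feat = feat,
         split = ifelse(is.na(ti$splitval), 0, as.numeric(ti$splitval)),
         value = ifelse(is.na(ti$prediction), 0, as.numeric(ti$prediction)))
  })
}

#' Interventional Shapley values for a tree ensemble
#'
#' Computes, for every instance, the exact Shapley attribution of a
#' regression forest under the interventional value function, exploiting
#' the tree structure: the recursion only branches where the instance and
#' the background row diverge, so the cost per (instance, background row,
#' tree) is bounded by the tree size rather than by \eqn{2^{|N|}}. On small
#' feature sets this agrees with [exact_shapley()] to within floating
#' accumulation (the package's central correctness test).
#'
#' @param model A `bdt_model` (from [tune_and_train()]) or a bare
#'   `ranger` regression forest.
#' @param instances Feature rows to explain: a feature table for a
#'   `bdt_model`, or a numeric matrix/data frame matching the forest's
#'   variables for a bare ranger model.
#' @param background Background rows (same layout as `instances`).
#' @return Object of class `shap_values`: list with `phi` (instances x
#'   features matrix), `base_value` (scalar), `prediction` (per-instance
#'   model output), `feature_names`.
#' @export
tree_shap <- function(model, instances, background) {
  if (inherits(model, "bdt_model")) {
    X <- as.matrix(.model_matrix(model, instances))
    B <- as.matrix(.model_matrix(model, background))
    forest <- model$forest
  } else if (inherits(model, "ranger")) {
    ivn <- model$forest$independent.variable.names
    X <- as.matrix(as.data.frame(instances)[, ivn, drop = FALSE])
    B <- as.matrix(as.data.frame(background)[, ivn, drop = FALSE])
    forest <- model
  } else stop("unsupported model type; need bdt_model or ranger")
  trees <- .extract_forest(forest)
  phi <- .forest_interventional_shap(trees, X, B)
  colnames(phi) <- colnames(X)
  base <- mean(.forest_predict_cpp(trees, B))
  pred <- .forest_predict_cpp(trees, X)
  structure(list(phi = phi, base_value = base, prediction = pred,
                 feature_names = colnames(X)),
            class = "shap_values")
}

#' Default physical feature grouping
#'
#' Partitions the model features by physical subsystem: adaptive aperture,
#' spot position, pulse charge, energy selection, and the boolean
#' transition flags. User-overridable: any named list partitioning the
#' feature set is accepted by [group_attributions()].
#'
#' @return Named list mapping group name to member feature names.
#' @export
default_feature_groups <- function() {
  list(AA = "log_daa",
       spot = "log_ds",
       charge = c("charge", "delta_charge"),
       energy = c("delta_e", "log_de"),
       boolean = c("is_first_pulse", "is_tx_pulse"))
}

#' Sum per-feature attributions into feature groups
#'
#' Group attributions are the sums of their members' Shapley values, so the
#' additive decomposition phi_0 + sum(group phi) = prediction is preserved.
#'
#' @param shap A `shap_values` object from [tree_shap()].
#' @param grouping Named list partitioning the feature names (default
#'   [default_feature_groups()]).
#' @return A `shap_values` object whose `phi` columns are the groups.
#' @export
group_attributions <- function(shap, grouping = default_feature_groups()) {
  stopifnot(inherits(shap, "shap_values"))
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members))
    stop("grouping assigns a feature to more than one group")
  missing <- setdiff(shap$feature_names, members)
  if (length(missing))
    stop("feature(s) missing from grouping: ", paste(missing, collapse = ", "))
  extra <- setdiff(members, shap$feature_names)
  if (length(extra))
    stop("grouping names unknown feature(s): ", paste(extra, collapse = ", "))
  gphi <- vapply(grouping, function(m)
    rowSums(shap$phi[, m, drop = FALSE]), numeric(nrow(shap$phi)))
  if (is.null(dim(gphi))) gphi <- matrix(gphi, nrow = 1,
                                         dimnames = list(NULL, names(grouping)))
  structure(list(phi = gphi, base_value = shap$base_value,
                 prediction = shap$prediction,
                 feature_names = names(grouping)),
            class = "shap_values")
}

#' Global and per-interval importance summaries
#'
#' Global importance is the mean absolute attribution per group over all
#' explained instances. Per-interval importance bins instances by their
#' predicted inter-pulse time and reports the maximum absolute attribution
#' per group within each bin (which exposes regime-dependent feature
#' relevance: which subsystem can move a prediction the most in each
#' timing regime).
#'
#' @param shap A `shap_values` object (typically grouped).
#' @param predicted_dt_ms Predicted inter-pulse time (ms) per instance.
#' @param breaks Interval edges, as in [interval_metrics()].
#' @return List of data frames `global` (`group`, `mean_abs`) and
#'   `per_interval` (`bin_lo`, `bin_hi`, `group`, `max_abs`, `n`).
#' @export
importance_summary <- function(shap, predicted_dt_ms,
                               breaks = c(0, 50, 500, 1000, Inf)) {
  stopifnot(inherits(shap, "shap_values"),
            length(predicted_dt_ms) == nrow(shap$phi), nrow(shap$phi) >= 1)
  ab <- abs(shap$phi)
  global <- data.frame(group = colnames(ab), mean_abs = colMeans(ab),
                       row.names = NULL)
  bin <- findInterval(predicted_dt_ms, breaks)
  nb <- length(breaks) - 1
  per <- do.call(rbind, lapply(seq_len(nb), function(k) {
    sel <- bin == k
    data.frame(bin_lo = breaks[k], bin_hi = breaks[k + 1],
               group = colnames(ab),
               max_abs = if (any(sel))
                 apply(ab[sel, , drop = FALSE], 2, max) else NA_real_,
               n = sum(sel), row.names = NULL)
  }))
  list(global = global, per_interval = per)
}

#' Draw a target-stratified explanation sample
#'
#' Shapley explanation is computed on a subset of the test set; to cover
#' the whole inter-pulse time range the draw is stratified over quantile
#' bins of the target (equal draws per bin, which for quantile bins is
#' proportional allocation).
#'
#' @param table A feature table (test subset).
#' @param n Number of instances to draw (default 100).
#' @param seed Integer seed.
#' @param n_bins Number of target quantile bins.
#' @return The sampled rows of `table` (all rows, with a warning, when
#'   `table` has at most `n` rows).
#' @export
sample_for_explanation <- function(table, n = 100, seed = 1, n_bins = 10) {
  if (nrow(table) <= n) {
    if (nrow(table) < n) warning("table has fewer than n rows; returning all")
    return(table)
  }
  y <- table$log_delta_t
  edges <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  bin <- if (length(edges) < 3) rep(1L, length(y))
         else cut(y, breaks = edges, include.lowest = TRUE, labels = FALSE)
  idx <- withr::with_seed(seed, {
    per_bin <- split(seq_len(nrow(table)), bin)
    quota <- diff(round(seq(0, n, length.out = length(per_bin) + 1)))
    unlist(mapply(function(ix, k) sample(ix, min(k, length(ix))),
                  per_bin, quota, SIMPLIFY = FALSE), use.names = FALSE)
  })
  # top up (some bins may hold fewer rows than their quota)
  if (length(idx) < n) {
    rest <- setdiff(seq_len(nrow(table)), idx)
    idx <- c(idx, withr::with_seed(seed + 1, sample(rest, n - length(idx))))
  }
  table[sort(idx), , drop = FALSE]
}
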