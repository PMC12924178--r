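# Training / evaluation stage: robust scaling of numeric features with
# boolean passthrough, random-forest regression of the log-transformed
# inter-pulse time with cross-validated randomized hyperparameter search,
# and interval-stratified error analysis.

#' Fit a robust scaler (median / inter-quartile range)
#'
#' Centers each numeric feature on its median and scales by the range
#' between the 1st and 3rd quartile (linear-interpolation quantiles).
#' Constant columns fall back to scale 1 so the transform stays defined.
#' Boolean features are not scaled (passthrough).
#'
#' @param data A data frame containing the columns to scale.
#' @param columns Character vector of numeric feature names.
#' @return An object of class `bdt_scaler` with `center` and `scale`
#'   vectors.
#' @export
fit_scaler <- function(data, columns = .numeric_features) {
  if (nrow(data) < 2) stop("need at least 2 rows to fit a scaler")
  stopifnot(all(columns %in% names(data)))
  center <- vapply(data[columns], stats::median, numeric(1))
  q1 <- vapply(data[columns], stats::quantile, numeric(1), probs = 0.25,
               names = FALSE, type = 7)
  q3 <- vapply(data[columns], stats::quantile, numeric(1), probs = 0.75,
               names = FALSE, type = 7)
  scl <- q3 - q1
  scl[scl <= 0] <- 1
  structure(list(center = center, scale = scl, columns = columns),
            class = "bdt_scaler")
}

#' Apply (or invert) a fitted robust scaler
#'
#' @param scaler A `bdt_scaler` from [fit_scaler()].
#' @param data Data frame with the scaler's columns.
#' @param inverse Undo the transform instead of applying it.
#' @return `data` with the scaler's columns transformed.
#' @export
apply_scaler <- function(scaler, data, inverse = FALSE) {
  stopifnot(inherits(scaler, "bdt_scaler"),
            all(scaler$columns %in% names(data)))
  for (cn in scaler$columns) {
    data[[cn]] <- if (inverse) data[[cn]] * scaler$scale[[cn]] + scaler$center[[cn]]
                  else (data[[cn]] - scaler$center[[cn]]) / scaler$scale[[cn]]
  }
  data
}

#' Default randomized hyperparameter search space
#'
#' Tree count 100--500, unlimited or capped depth, minimum leaf size, and
#' the fraction of features tried at each split.
#'
#' @return A list of candidate-value vectors sampled by [tune_and_train()].
#' @export
default_search_space <- function() {
  list(num_trees = seq(100, 500, by = 50),
       max_depth = c(0, 10, 15, 20, 25),       # 0 = unlimited
       min_node_size = c(1, 2, 5, 10, 20),
       mtry_frac = c(0.3, 0.5, 0.7, 1.0))
}

.model_matrix <- function(model, rows) {
  missing <- setdiff(model$feature_names, names(rows))
  if (length(missing))
    stop("rows lack model feature column(s): ", paste(missing, collapse = ", "))
  x <- apply_scaler(model$scaler, rows[, model$feature_names, drop = FALSE])
  for (b in model$bool_features) x[[b]] <- as.numeric(x[[b]])
  x
}

#' Tune and train the inter-pulse time random forest
#'
#' Randomized search over [default_search_space()]: `n_candidates`
#' hyperparameter draws are scored by `cv_folds`-fold cross-validated mean
#' absolute error on the log-transformed target, and the best candidate is
#' refit on the whole training table. Numeric features are robust-scaled
#' (the scaler is stored with the model); boolean features pass through.
#' Fully seeded: the same seed and data give the same selected
#' hyperparameters and forest.
#'
#' @param train A feature table (training subset).
#' @param seed Integer seed.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param n_candidates Number of random hyperparameter draws.
#' @param search_space Candidate-value list, see [default_search_space()].
#' @param num_threads Threads passed to ranger (1 keeps runs deterministic).
#' @return An object of class `bdt_model`: scaler, fitted forest, selected
#'   hyperparameters, per-candidate CV summary, seed, feature layout and
#'   the record identifiers the model was trained on.
#' @export
tune_and_train <- function(train, seed = 1, cv_folds = 5, n_candidates = 8,
                           search_space = default_search_space(),
                           num_threads = 1) {
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  if (nrow(train) < cv_folds) stop("fewer training rows than folds")
  feature_names <- c(.numeric_features, .bool_features)
  stopifnot(all(feature_names %in% names(train)),
            "log_delta_t" %in% names(train))
  scaler <- fit_scaler(train, .numeric_features)
  stub <- list(scaler = scaler, feature_names = feature_names,
               bool_features = .bool_features)
  x <- .model_matrix(stub, train)
  y <- train$log_delta_t
  p <- length(feature_names)

  cands <- withr::with_seed(seed, {
    lapply(seq_len(n_candidates), function(i) {
      list(num_trees = sample(search_space$num_trees, 1),
           max_depth = sample(search_space$max_depth, 1),
           min_node_size = sample(search_space$min_node_size, 1),
           mtry = max(1L, round(sample(search_space$mtry_frac, 1) * p)))
    })
  })
  fold <- withr::with_seed(seed + 1,
    sample(rep_len(seq_len(cv_folds), nrow(train))))

  cv <- vapply(seq_along(cands), function(ci) {
    h <- cands[[ci]]
    mean(vapply(seq_len(cv_folds), function(k) {
      tr <- fold != k
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = h$num_trees, mtry = h$mtry,
                            min.node.size = h$min_node_size,
                            max.depth = h$max_depth,
                            seed = seed + 100 * ci + k,
                            num.threads = num_threads, verbose = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE],
                      num.threads = num_threads)$predictions
      mean(abs(pred - y[!tr]))
    }, numeric(1)))
  }, numeric(1))

  best <- cands[[which.min(cv)]]
  forest <- ranger::ranger(x = x, y = y, num.trees = best$num_trees,
                           mtry = best$mtry,
                           min.node.size = best$min_node_size,
                           max.depth = best$max_depth, seed = seed,
                           num.threads = num_threads, verbose = FALSE)
  cv_summary <- cbind(do.call(rbind, lapply(cands, as.data.frame)),
                      cv_mae_log = cv)
  trained_on <- if (all(c("fraction_id", "beam_id") %in% names(train)))
    unique(paste(train$fraction_id, train$beam_id, sep = "/")) else character(0)
  structure(list(scaler = scaler, forest = forest,
                 best_hyperparameters = best, cv_summary = cv_summary,
                 cv_folds = cv_folds, seed = seed,
                 feature_names = feature_names,
                 numeric_features = .numeric_features,
                 bool_features = .bool_features,
                 trained_on = trained_on),
            class = "bdt_model")
}

#' @export
print.bdt_model <- function(x, ...) {
  cat("<bdt_model> random forest on log1p(delta_t)\n")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  h <- x$best_hyperparameters
  cat(sprintf("  best: %d trees, max depth %s, min node %d, mtry %d (CV MAE %.4f)\n",
              h$num_trees, if (h$max_depth == 0) "none" else h$max_depth,
              h$min_node_size, h$mtry, min(x$cv_summary$cv_mae_log)))
  invisible(x)
}

#' Predict inter-pulse times in milliseconds
#'
#' The forest predicts in log space; predictions are mapped back through
#' `expm1` and clamped at zero.
#'
#' @param model A `bdt_model`.
#' @param rows Feature rows (columns per the model's feature layout).
#' @param log_space Return the raw log-space forest output instead.
#' @return Numeric vector of predicted inter-pulse times (ms), one per row.
#' @export
predict_delta_t <- function(model, rows, log_space = FALSE) {
  stopifnot(inherits(model, "bdt_model"))
  x <- .model_matrix(model, rows)
  p <- predict(model$forest, x, num.threads = 1)$predictions
  if (log_space) p else pmax(inv_log1p_target(p), 0)
}

#' Interval-stratified error metrics
#'
#' Transitions are binned by the reference inter-pulse time into half-open
#' intervals (default 0-50, 50-500, 500-1000, >1000 ms) and per-bin MAE
#' (mean |reference - predicted|, ms) and MAPE
#' (100 x mean |reference - predicted| / reference, %) are reported.
#'
#' @param reference,predicted Equal-length vectors of inter-pulse times, ms;
#'   references must be positive.
#' @param breaks Increasing bin edges; the last bin is unbounded when the
#'   final edge is `Inf`.
#' @return A data frame with columns `bin_lo`, `bin_hi`, `n`, `mae_ms`,
#'   `mape_pct` (NA metrics for empty bins); bin counts sum to the number
#'   of evaluated transitions.
#' @export
interval_metrics <- function(reference, predicted,
                             breaks = c(0, 50, 500, 1000, Inf)) {
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ")
  if (any(reference <= 0)) stop("reference inter-pulse times must be positive")
  bin <- findInterval(reference, breaks)
  err <- abs(reference - predicted)
  nb <- length(breaks) - 1
  out <- data.frame(bin_lo = breaks[seq_len(nb)], bin_hi = breaks[-1],
                    n = 0L, mae_ms = NA_real_, mape_pct = NA_real_)
  for (k in seq_len(nb)) {
    sel <- bin == k
    out$n[k] <- sum(sel)
    if (any(sel)) {
      out$mae_ms[k] <- mean(err[sel])
      out$mape_pct[k] <- 100 * mean(err[sel] / reference[sel])
    }
  }
  out
}

#' Inter-fraction delivery-time variability of a simulated course
#'
#' Uses the first fraction as the reference and compares every later
#' fraction's inter-pulse times against it, transition by transition
#' (matched on beam and pulse index). This quantifies the intrinsic
#' reproducibility of the delivery, the natural yardstick for the
#' regression model's own error.
#'
#' @param course A multi-fraction pulse log (see [simulate_course()]).
#' @param band_ms Half-width of the residual band reported (default 500 ms).
#' @param breaks Interval edges passed to [interval_metrics()].
#' @return A list: `residuals` (per-transition data frame with reference and
#'   fraction inter-pulse times and their difference), `metrics` (per-bin
#'   MAE/MAPE of fraction vs reference, binned by the reference time) and
#'   `within_band` (share of residuals within `+/- band_ms`).
#' @export
interfraction_variability <- function(course, band_ms = 500,
                                      breaks = c(0, 50, 500, 1000, Inf)) {
  fr <- sort(unique(course$fraction_id))
  if (length(fr) < 2) stop("need at least 2 fractions")
  dts <- lapply(fr, function(f) {
    d <- course[course$fraction_id == f, , drop = FALSE]
    parts <- lapply(split(d, d$beam_id), function(b) {
      b <- b[order(b$pulse_index), , drop = FALSE]
      data.frame(beam_id = b$beam_id[1], pulse_index = b$pulse_index[-1],
                 dt = diff(b$timestamp_ms))
    })
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
  ref <- dts[[1]]
  res <- lapply(seq_along(fr)[-1], function(i) {
    m <- merge(ref, dts[[i]], by = c("beam_id", "pulse_index"),
               suffixes = c("_ref", "_frac"))
    if (nrow(m) != nrow(ref))
      stop("fraction ", fr[i], " does not match the reference pulse sequence")
    m$fraction_id <- fr[i]
    m$residual <- m$dt_ref - m$dt_frac
    m
  })
  res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  list(residuals = res,
       metrics = interval_metrics(res$dt_ref, res$dt_frac, breaks),
       within_band = mean(abs(res$residual) <= band_ms))
}
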