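# Feature-engineering stage: per-transition deltas, the summed-leaf-travel
# aggregate, boolean flags, the log1p target transform, and the
# quantile-stratified train/test split.

#' Summed adaptive-aperture leaf travel between two pulses
#'
#' \deqn{\Delta AA = \sum_{l} \sqrt{\Delta X_l^2 + \Delta Y_l^2}}
#' where the sum runs over the collimator leaves matched by index. The
#' aggregate is non-negative, zero only when every leaf is unchanged, and
#' invariant to a common translation of all coordinates.
#'
#' @param prev_leaves,next_leaves Numeric matrices (n_leaves x 2, columns
#'   X and Y, mm) or vectors interleaved as x1, y1, x2, y2, ...
#' @return Total leaf travel, mm.
#' @examples
#' a <- matrix(0, 14, 2); b <- a; b[1, ] <- c(3, 4)
#' delta_aa(a, b)  # 5
#' @export
delta_aa <- function(prev_leaves, next_leaves) {
  as_m <- function(x) {
    if (is.matrix(x)) x
    else matrix(as.numeric(x), ncol = 2, byrow = TRUE)
  }
  a <- as_m(prev_leaves); b <- as_m(next_leaves)
  if (!all(dim(a) == dim(b)))
    stop("leaf sets have mismatched dimensions")
  d <- b - a
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Euclidean spot shift between two pulses
#'
#' @param prev_xy,next_xy Length-2 numeric vectors (x, y) in mm.
#' @return Distance in mm.
#' @export
delta_s <- function(prev_xy, next_xy) {
  stopifnot(length(prev_xy) == 2, length(next_xy) == 2,
            all(is.finite(c(prev_xy, next_xy))))
  sqrt(sum((as.numeric(next_xy) - as.numeric(prev_xy))^2))
}

#' Log target transform and its inverse
#'
#' The inter-pulse time spans several orders of magnitude; the model is
#' trained on \eqn{y_{log} = \log(1 + y)} to reduce skewness.
#'
#' @param y Inter-pulse time(s), ms, non-negative.
#' @return `log1p_target`: transformed value(s); `inv_log1p_target`: times
#'   in ms recovered from transformed values.
#' @export
log1p_target <- function(y) {
  if (any(y < 0)) stop("target must be non-negative")
  log1p(y)
}

#' @rdname log1p_target
#' @param y_log Transformed value(s).
#' @export
inv_log1p_target <- function(y_log) expm1(y_log)

# model feature layout
.numeric_features <- c("log_daa", "log_ds", "delta_e", "log_de",
                       "charge", "delta_charge")
.bool_features <- c("is_first_pulse", "is_tx_pulse")

#' Build the per-transition feature table from a pulse log
#'
#' One row per pulse transition (pulse n-1 to n) within each
#' (fraction, beam) record, so a record of N pulses yields N-1 rows.
#' Features: `log_daa` and `log_ds` (log1p of the summed leaf travel and of
#' the spot shift, mm), `delta_e` (signed energy-level difference, level
#' units) and `log_de` (log1p of its magnitude), `charge` (destination-pulse
#' target charge, pC), `delta_charge` (signed charge difference, pC),
#' `is_first_pulse` (the transition out of a record's first pulse) and
#' `is_tx_pulse` (the transition from the last low-charge pulse to the
#' first treatment pulse). The target `delta_t` is the timestamp difference
#' in ms, with `log_delta_t = log1p(delta_t)`.
#'
#' @param records A pulse-log data frame.
#' @param config A [machine_config()].
#' @return A feature data frame; `fraction_id` and `beam_id` are carried
#'   along as bookkeeping columns (not model features).
#' @export
build_feature_table <- function(records, config = machine_config()) {
  groups <- split(seq_len(nrow(records)),
                  paste(records$fraction_id, records$beam_id, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    r <- records[idx, , drop = FALSE]
    r <- r[order(r$pulse_index), , drop = FALSE]
    if (nrow(r) < 2) {
      warning(sprintf("record %s/%s has a single pulse; no transitions",
                      r$fraction_id[1], r$beam_id[1]))
      return(NULL)
    }
    g <- .transition_geometry(r, config)
    dt <- diff(r$timestamp_ms)
    data.frame(fraction_id = r$fraction_id[1], beam_id = r$beam_id[1],
               pulse_index = r$pulse_index[-1],
               log_daa = log1p(g$daa), log_ds = log1p(g$ds),
               delta_e = g$de, log_de = log1p(abs(g$de)),
               charge = g$charge, delta_charge = g$dq,
               is_first_pulse = g$is_first, is_tx_pulse = g$is_tx,
               delta_t = dt, log_delta_t = log1p(dt),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(fraction_id = character(0), beam_id = character(0),
                      pulse_index = integer(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratified train/test split on the log-transformed target
#'
#' Quantile-based binning of `log_delta_t` preserves the heavily skewed
#' target distribution in both subsets: within each quantile bin a seeded
#' `train_frac` share of rows (rounded to the nearest row) is assigned to
#' the training set.
#'
#' @param table A feature table from [build_feature_table()].
#' @param train_frac Training share (default 0.7 for a 70/30 split).
#' @param n_bins Number of quantile bins of the target (collapsed with a
#'   warning when the target has too few distinct values).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return A list with elements `train` and `test`: disjoint, exhaustive
#'   subsets of `table`.
#' @export
stratified_split <- function(table, train_frac = 0.7, n_bins = 10, seed = 1) {
  stopifnot(nrow(table) >= n_bins, train_frac > 0, train_frac < 1)
  y <- table$log_delta_t
  edges <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < n_bins + 1)
    warning("duplicate quantile edges; bins collapsed to ",
            max(length(edges) - 1, 1))
  bin <- if (length(edges) < 3) rep(1L, length(y))
         else cut(y, breaks = edges, include.lowest = TRUE, labels = FALSE)
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), bin), function(idx) {
      k <- round(length(idx) * train_frac)
      sample(idx, k)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}
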