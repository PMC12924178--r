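# Application stage: cumulative delivery-time reconstruction (volumetric
# repainting use case) and pulse-to-breathing-phase mapping for interplay
# evaluation.

#' Cumulative beam delivery time
#'
#' Running sum of the inter-pulse times in delivery order; the final value
#' is the total delivery time of the sequence.
#'
#' @param delta_ts Positive inter-pulse times (ms) in delivery order.
#' @param pulse_index Optional index labels (defaults to transition order).
#' @param energy_level Optional per-transition energy level, carried along
#'   for plots of cumulative time against energy.
#' @return Data frame with `pulse_index`, optional `energy_level`,
#'   `delta_t_ms`, `cumulative_ms`.
#' @export
cumulative_bdt <- function(delta_ts, pulse_index = NULL, energy_level = NULL) {
  if (any(!is.finite(delta_ts)) || any(delta_ts <= 0))
    stop("inter-pulse times must be positive and finite")
  out <- data.frame(
    pulse_index = if (is.null(pulse_index)) seq_along(delta_ts) else pulse_index,
    delta_t_ms = delta_ts, cumulative_ms = cumsum(delta_ts))
  if (!is.null(energy_level)) out$energy_level <- energy_level
  out
}

#' Compare two timing sources over the same pulse sequence
#'
#' Typically reference = machine-log inter-pulse times, predicted = model
#' output for the same transitions. The headline number is the relative
#' deviation of the total delivery time, signed as predicted minus
#' reference (negative = the model underestimates the delivery time).
#'
#' @param reference,predicted Equal-length positive inter-pulse times, ms.
#' @return List: `total_reference_ms`, `total_predicted_ms`,
#'   `relative_deviation` ((predicted - reference) / reference),
#'   `series` (per-transition cumulative data frame for both sources and
#'   the running relative difference).
#' @export
compare_timing_sources <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted transition counts differ")
  ref <- cumsum(reference)
  pre <- cumsum(predicted)
  list(total_reference_ms = ref[length(ref)],
       total_predicted_ms = pre[length(pre)],
       relative_deviation = (pre[length(pre)] - ref[length(ref)]) / ref[length(ref)],
       series = data.frame(pulse_index = seq_along(ref),
                           cumulative_reference_ms = ref,
                           cumulative_predicted_ms = pre,
                           relative_difference = (pre - ref) / ref))
}

#' Sinusoidal breathing trace
#'
#' @param period Breathing period, s.
#' @param amplitude Peak displacement (arbitrary units; metadata for
#'   downstream displacement use, never used by the phase binning).
#' @param phase_offset Starting phase, radians.
#' @param n_phases Number of respiratory bins (typical 4DCT binning is 10).
#' @return Object of class `breathing_trace`.
#' @export
breathing_trace <- function(period, amplitude = 10, phase_offset = 0,
                            n_phases = 10) {
  stopifnot(period > 0, n_phases >= 1)
  structure(list(period = period, amplitude = amplitude,
                 phase_offset = phase_offset, n_phases = n_phases),
            class = "breathing_trace")
}

#' Respiratory phase index at a time point
#'
#' Uniform-in-time phase binning of the breathing cycle:
#' `floor(n_phases * frac(t / period + offset / 2 pi))`. Periodic in
#' `period` and independent of the trace amplitude.
#'
#' @param t Time(s) in seconds, non-negative.
#' @param trace A [breathing_trace()].
#' @return Integer phase indices in `[0, n_phases)`.
#' @export
breathing_phase <- function(t, trace) {
  stopifnot(inherits(trace, "breathing_trace"), all(t >= 0))
  u <- t / trace$period + trace$phase_offset / (2 * pi)
  ph <- floor(trace$n_phases * (u - floor(u)))
  # guard the representable edge (u - floor(u) can round to 1)
  as.integer(pmin(ph, trace$n_phases - 1L))
}

#' Map pulses to respiratory phases
#'
#' Labels every pulse with the breathing phase of its timestamp and
#' accumulates the delivered charge per phase. Charge is conserved exactly:
#' the per-phase charges sum to the total delivered charge.
#'
#' @param timestamps_ms Monotone non-decreasing pulse timestamps, ms.
#' @param charges Positive pulse charges, pC.
#' @param trace A [breathing_trace()].
#' @return Object of class `phase_map`: list with `phase_charge` (named
#'   vector, one entry per phase), `labels` (per-pulse phase indices),
#'   `period`, `n_phases`.
#' @export
map_pulses_to_phases <- function(timestamps_ms, charges, trace) {
  if (length(timestamps_ms) != length(charges))
    stop("timestamps and charges lengths differ")
  if (any(diff(timestamps_ms) < 0)) stop("timestamps must be monotone")
  if (any(charges <= 0)) stop("charges must be positive")
  labels <- breathing_phase(timestamps_ms / 1000, trace)
  pc <- vapply(0:(trace$n_phases - 1L),
               function(p) sum(charges[labels == p]), numeric(1))
  structure(list(phase_charge = stats::setNames(pc, 0:(trace$n_phases - 1L)),
                 labels = labels, period = trace$period,
                 n_phases = trace$n_phases),
            class = "phase_map")
}

#' Compare two phase maps
#'
#' @param map_a,map_b `phase_map` objects over the same pulse sequence and
#'   phase count.
#' @return List: `agreement` (fraction of pulses with identical phase
#'   labels) and `tv_distance` (total-variation distance, half the L1
#'   distance between the normalized per-phase charge distributions); both
#'   in `[0, 1]`.
#' @export
compare_phase_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "phase_map"), inherits(map_b, "phase_map"))
  if (map_a$n_phases != map_b$n_phases ||
      length(map_a$labels) != length(map_b$labels))
    stop("phase maps have mismatched structure")
  pa <- map_a$phase_charge / sum(map_a$phase_charge)
  pb <- map_b$phase_charge / sum(map_b$phase_charge)
  list(agreement = mean(map_a$labels == map_b$labels),
       tv_distance = 0.5 * sum(abs(pa - pb)))
}

#' Build a volumetric-repainting variant of a plan
#'
#' Repeats the treatment (post-prelude) layer sequence `k` times; the
#' low-charge verification layer is kept once at the start. Each repaint
#' boundary induces a fresh aperture and energy transition (lowest energy
#' back to the highest), mirroring how a repainted delivery restarts the
#' layer sequence.
#'
#' @param plan A plan from [generate_plan()].
#' @param k Number of paintings (default 5).
#' @return A plan data frame with `k` copies of every treatment layer.
#' @export
make_repainted_plan <- function(plan, k = 5) {
  stopifnot(k >= 1)
  parts <- lapply(split(plan, factor(plan$beam_id, unique(plan$beam_id))),
                  function(b) {
    prelude <- b[b$layer_index == 0, , drop = FALSE]
    tx <- b[b$layer_index > 0, , drop = FALSE]
    n_layers <- max(tx$layer_index)
    reps <- do.call(rbind, lapply(seq_len(k), function(r) {
      out <- tx
      out$layer_index <- out$layer_index + (r - 1) * n_layers
      out
    }))
    rbind(prelude, reps)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  row.names(out) <- NULL
  out
}

# phase map of one fraction of a pulse log: per-beam timelines start at 0
.fraction_phase_map <- function(log_one_fraction, trace) {
  beams <- split(log_one_fraction,
                 factor(log_one_fraction$beam_id,
                        unique(log_one_fraction$beam_id)))
  labels <- unlist(lapply(beams, function(b) {
    b <- b[order(b$pulse_index), , drop = FALSE]
    breathing_phase(b$timestamp_ms / 1000, trace)
  }), use.names = FALSE)
  charges <- unlist(lapply(beams, function(b)
    b[order(b$pulse_index), "target_charge_pC"]), use.names = FALSE)
  pc <- vapply(0:(trace$n_phases - 1L),
               function(p) sum(charges[labels == p]), numeric(1))
  structure(list(phase_charge = stats::setNames(pc, 0:(trace$n_phases - 1L)),
                 labels = labels, period = trace$period,
                 n_phases = trace$n_phases),
            class = "phase_map")
}

#' Predict the pulse timeline of a plan with the trained model
#'
#' Expands the plan into its noise-free pulse sequence, evaluates the
#' model on the per-transition features and reconstructs per-beam
#' timestamps from the predicted inter-pulse times.
#'
#' @param plan A plan from [generate_plan()].
#' @param model A `bdt_model`.
#' @param config A [machine_config()].
#' @return A pulse-log data frame whose timestamps are model-predicted.
#' @export
predict_plan_timeline <- function(plan, model, config = machine_config()) {
  zero_noise <- config
  zero_noise$noise <- noise_params(sigma_floor = 0, sigma_rel = 0,
                                   outlier_prob = 0)
  log0 <- simulate_fraction(plan, seed = 0, config = zero_noise,
                            fraction_id = "MODEL")
  ft <- build_feature_table(log0, config)
  pred <- predict_delta_t(model, ft)
  parts <- lapply(split(seq_len(nrow(log0)),
                        factor(log0$beam_id, unique(log0$beam_id))),
                  function(idx) {
    b <- log0[idx, , drop = FALSE]
    sel <- ft$beam_id == b$beam_id[1]
    b$timestamp_ms <- c(0, cumsum(pred[sel]))
    b
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Interplay experiment: model timing vs intrinsic delivery variability
#'
#' For each breathing period, the per-phase charge map obtained from
#' model-predicted pulse timings is compared with the maps obtained from
#' every simulated reference fraction of the same plan. The model passes
#' when its mean total-variation distance to the reference fractions does
#' not exceed the largest fraction-to-fraction (intrinsic) distance, i.e.
#' the model's timing uncertainty stays within the machine's own delivery
#' variability.
#'
#' @param plan The evaluation plan (must not appear in the model's
#'   training records; checked by record identifiers).
#' @param model A `bdt_model`.
#' @param reference_course A multi-fraction pulse log of `plan` from
#'   [simulate_course()].
#' @param periods Breathing periods to evaluate, s.
#' @param config A [machine_config()].
#' @param n_phases,phase_offset Trace binning parameters.
#' @return List: `summary` (per-period model TV vs intrinsic TV range and
#'   the `within_intrinsic` flag), `detail` (every pairwise comparison),
#'   and `charge_conserved` (exact per-map charge conservation check).
#' @export
interplay_experiment <- function(plan, model, reference_course,
                                 periods = c(2, 4, 5),
                                 config = machine_config(),
                                 n_phases = 10, phase_offset = 0) {
  beams <- unique(plan$beam_id)
  trained_beams <- unique(sub("^[^/]*/", "", model$trained_on))
  if (length(intersect(beams, trained_beams)))
    stop("leakage: evaluation plan beams appear in the model training records")
  model_log <- predict_plan_timeline(plan, model, config)
  fractions <- sort(unique(reference_course$fraction_id))
  total_charge <- NULL
  detail <- list()
  summary <- lapply(periods, function(per) {
    trace <- breathing_trace(per, n_phases = n_phases,
                             phase_offset = phase_offset)
    m_map <- .fraction_phase_map(model_log, trace)
    f_maps <- lapply(fractions, function(f)
      .fraction_phase_map(
        reference_course[reference_course$fraction_id == f, , drop = FALSE],
        trace))
    total_charge <<- c(total_charge,
                       vapply(c(list(m_map), f_maps),
                              function(mp) sum(mp$phase_charge), numeric(1)))
    mv <- vapply(f_maps, function(fm)
      compare_phase_maps(m_map, fm)$tv_distance, numeric(1))
    ma <- vapply(f_maps, function(fm)
      compare_phase_maps(m_map, fm)$agreement, numeric(1))
    pairs <- utils::combn(seq_along(f_maps), 2)
    iv <- apply(pairs, 2, function(p)
      compare_phase_maps(f_maps[[p[1]]], f_maps[[p[2]]])$tv_distance)
    detail[[as.character(per)]] <<- data.frame(
      period_s = per,
      comparison = c(paste0("model_vs_", fractions),
                     paste0(fractions[pairs[1, ]], "_vs_",
                            fractions[pairs[2, ]])),
      tv_distance = c(mv, iv),
      agreement = c(ma, rep(NA_real_, length(iv))))
    data.frame(period_s = per, model_tv_mean = mean(mv),
               model_tv_max = max(mv), model_agreement_mean = mean(ma),
               intrinsic_tv_min = min(iv), intrinsic_tv_mean = mean(iv),
               intrinsic_tv_max = max(iv),
               within_intrinsic = mean(mv) <= max(iv))
  })
  # every map is over the same pulse expansion of the plan, so each must
  # hold exactly the plan's total delivered charge
  expected <- sum(model_log$target_charge_pC)
  list(summary = do.call(rbind, summary),
       detail = do.call(rbind, c(detail, list(make.row.names = FALSE))),
       charge_conserved = all(abs(total_charge - expected) < 1e-6))
}
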