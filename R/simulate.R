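#' @useDynLib bdtmodel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ranger ranger treeInfo
#' @importFrom stats median quantile rnorm runif predict setNames
#' @importFrom utils read.csv write.csv head
NULL

# column names holding the adaptive-aperture leaf coordinates
leaf_columns <- function(n_leaves) {
  as.vector(t(outer(seq_len(n_leaves), c("x", "y"),
                    function(l, ax) sprintf("leaf%02d_%s_mm", l, ax))))
}

.leaf_ring <- function(cx, cy, config) {
  ang <- 2 * pi * (seq_len(config$n_leaves) - 0.5) / config$n_leaves
  cbind(cx + config$leaf_margin * cos(ang),
        cy + config$leaf_margin * sin(ang))
}

#' Generate a synthetic pulse-scanned treatment plan
#'
#' Builds an ordered spot list emulating a delivery-ordered plan: each beam
#' opens with a low-charge verification layer (a copy of its first energy
#' layer delivered at the configured low charge per pulse), followed by the
#' treatment layers in descending energy order. Spots within a layer follow
#' a serpentine raster with small positional jitter; the adaptive aperture
#' follows the spot sequence with a dead band, so the leaf ring re-centers
#' only on spot moves larger than `aa_deadband` mm (or occasional drift
#' corrections), which reproduces the observed mix of aperture-static and
#' aperture-moving transitions.
#'
#' @param seed Integer seed; the same seed reproduces the plan exactly.
#' @param n_beams,n_layers_per_beam,spots_per_layer Plan dimensions.
#' @param config A [machine_config()].
#' @param plan_id Identifier prefix for beam names (keeps plans distinguishable
#'   so that train/application leakage can be detected).
#' @param charge_range Range (pC) from which spot charges are drawn uniformly;
#'   spots above the pulse cap are later split into several pulses.
#' @param spot_spacing In-row spot spacing, mm.
#' @return A data frame of spots: `beam_id`, `layer_index` (0 = low-charge
#'   layer), `energy_level`, `x_mm`, `y_mm`, `charge_pC`, `is_low_charge`,
#'   and one `leafNN_{x,y}_mm` column pair per aperture leaf.
#' @export
generate_plan <- function(seed, n_beams = 2, n_layers_per_beam = 10,
                          spots_per_layer = 30, config = machine_config(),
                          plan_id = "P", charge_range = c(2, 30),
                          spot_spacing = 2.5) {
  stopifnot(n_beams >= 1, n_layers_per_beam >= 1, spots_per_layer >= 1,
            inherits(config, "machine_config"),
            charge_range[1] > 0, charge_range[2] >= charge_range[1])
  withr::with_seed(seed, {
    beams <- lapply(seq_len(n_beams), function(b) {
      .generate_beam(sprintf("%s_B%d", plan_id, b), n_layers_per_beam,
                     spots_per_layer, config, charge_range, spot_spacing)
    })
    do.call(rbind, beams)
  })
}

.generate_beam <- function(beam_id, n_layers, n_spots, config,
                           charge_range, spot_spacing) {
  max_step <- 3L
  total <- max_step * max(n_layers - 1, 1)
  lo <- min(total, config$n_energy_levels - 1)
  start <- sample(seq(lo, config$n_energy_levels - 1), 1)
  steps <- if (n_layers > 1) sample(seq_len(max_step), n_layers - 1, TRUE) else integer(0)
  levels <- pmax(start - cumsum(c(0L, steps)), 0L)

  layer_geom <- function() {
    ncol_ <- sample(8:14, 1)
    dy <- runif(1, 4, 16)
    nrow_ <- ceiling(n_spots / ncol_)
    off <- runif(2, -5, 5)
    idx <- seq_len(n_spots) - 1L
    row <- idx %/% ncol_
    col <- idx %% ncol_
    col <- ifelse(row %% 2 == 1, ncol_ - 1L - col, col)  # serpentine
    half <- config$field_half_extent * 10
    x <- (col - (ncol_ - 1) / 2) * spot_spacing + off[1] + runif(n_spots, -1, 1)
    y <- (row - (nrow_ - 1) / 2) * dy + off[2] + runif(n_spots, -1, 1)
    lim <- half - config$leaf_margin
    cbind(pmin(pmax(x, -lim), lim), pmin(pmax(y, -lim), lim))
  }

  geoms <- lapply(seq_len(n_layers), function(j) layer_geom())
  charges <- lapply(seq_len(n_layers), function(j)
    runif(n_spots, charge_range[1], charge_range[2]))

  # prelude (low-charge) layer: first layer's geometry at the low charge
  xy <- rbind(geoms[[1]], do.call(rbind, geoms))
  layer_index <- rep(0:n_layers, each = n_spots)
  energy_level <- rep(c(levels[1], levels), each = n_spots)
  charge <- c(rep(config$low_charge, n_spots), unlist(charges))
  is_low <- layer_index == 0L

  # adaptive aperture follows the spot sequence with a dead band
  n_tot <- nrow(xy)
  leaves <- matrix(NA_real_, n_tot, 2 * config$n_leaves)
  center <- c(Inf, Inf)
  cur <- NULL
  for (i in seq_len(n_tot)) {
    d <- sqrt(sum((xy[i, ] - center)^2))
    if (!is.finite(d) || d > config$aa_deadband ||
        runif(1) < config$aa_reposition_prob) {
      center <- xy[i, ]
      ring <- .leaf_ring(center[1], center[2], config)
      cur <- as.vector(t(ring))  # x1,y1,x2,y2,...
    }
    leaves[i, ] <- cur
  }

  out <- data.frame(beam_id = beam_id, layer_index = layer_index,
                    energy_level = as.integer(energy_level),
                    x_mm = round(xy[, 1], 3), y_mm = round(xy[, 2], 3),
                    charge_pC = round(charge, 3), is_low_charge = is_low,
                    stringsAsFactors = FALSE)
  lc <- leaf_columns(config$n_leaves)
  # leaves already interleaved leaf01_x, leaf01_y, leaf02_x, ...
  out[lc] <- round(leaves, 3)
  out
}

#' Split a spot's charge into machine pulses
#'
#' A spot whose prescribed charge exceeds the per-pulse cap is delivered as
#' several pulses, filled to the cap with a final remainder pulse.
#'
#' @param spot Either a numeric charge (pC) or a one-row plan data frame
#'   with a `charge_pC` column.
#' @param config A [machine_config()].
#' @return Numeric vector of pulse charges (pC); sums to the spot charge,
#'   each element at most `max_pulse_charge`.
#' @examples
#' split_spot_to_pulses(20)  # 8, 8, 4
#' @export
split_spot_to_pulses <- function(spot, config = machine_config()) {
  q <- if (is.numeric(spot)) spot else spot$charge_pC
  stopifnot(length(q) == 1)
  if (!is.finite(q) || q <= 0) stop("spot charge must be positive")
  cap <- config$max_pulse_charge
  k <- ceiling(q / cap)
  out <- c(rep(cap, k - 1), q - (k - 1) * cap)
  out
}

# deterministic inter-pulse time from pre-computed transition geometry
.det_dt <- function(daa, ds, dq_abs, energy_changed, plates, is_tx, is_first,
                    tp) {
  tp$t_base +
    tp$t_spot_per_mm * ds +
    tp$t_charge_per_pc * dq_abs +
    ifelse(daa > 0, tp$t_aa_latency + tp$t_aa_per_mm * daa, 0) +
    ifelse(energy_changed, tp$t_energy_latency + tp$t_plate * plates, 0) +
    tp$t_tx_extra * is_tx +
    tp$t_first_extra * is_first
}

#' Deterministic inter-pulse time between two pulse records
#'
#' Evaluates the additive latency model documented in [timing_params()] for
#' one transition. The low-charge-to-treatment flag is inferred from the
#' `is_low_charge` fields, and the first-transition flag from
#' `prev$pulse_index == 1` when a `pulse_index` field is present.
#'
#' @param prev,next_ One-row data frames (or named lists) with fields
#'   `x_mm`, `y_mm`, `energy_level`, `target_charge_pC` (or `charge_pC`),
#'   `is_low_charge`, and the leaf coordinate columns.
#' @param config A [machine_config()].
#' @return Inter-pulse time in ms (strictly positive).
#' @export
deterministic_delta_t <- function(prev, next_, config = machine_config()) {
  lc <- leaf_columns(config$n_leaves)
  if (!all(lc %in% names(prev)) || !all(lc %in% names(next_)))
    stop("pulse records lack the expected leaf coordinate columns")
  qname <- if ("target_charge_pC" %in% names(prev)) "target_charge_pC" else "charge_pC"
  lx <- seq(1, 2 * config$n_leaves, 2)
  dl <- unlist(next_[lc]) - unlist(prev[lc])
  daa <- sum(sqrt(dl[lx]^2 + dl[lx + 1]^2))
  ds <- sqrt((next_$x_mm - prev$x_mm)^2 + (next_$y_mm - prev$y_mm)^2)
  dq <- abs(next_[[qname]] - prev[[qname]])
  ech <- next_$energy_level != prev$energy_level
  pl <- if (ech) plates_moved(prev$energy_level, next_$energy_level, config) else 0L
  tx <- isTRUE(prev$is_low_charge) && !isTRUE(next_$is_low_charge)
  first <- !is.null(prev$pulse_index) && isTRUE(prev$pulse_index == 1)
  .det_dt(daa, ds, dq, ech, pl, tx, first, config$timing)
}

# per-transition geometry for one beam-fraction, rows sorted by pulse_index
.transition_geometry <- function(p, config) {
  n <- nrow(p)
  if (n < 2) return(NULL)
  lc <- leaf_columns(config$n_leaves)
  lm <- as.matrix(p[, lc, drop = FALSE])
  dlm <- diff(lm)
  ix <- seq(1, ncol(lm), 2)
  daa <- rowSums(sqrt(dlm[, ix, drop = FALSE]^2 + dlm[, ix + 1, drop = FALSE]^2))
  qname <- if ("target_charge_pC" %in% names(p)) "target_charge_pC" else "charge_pC"
  lev <- p$energy_level
  de <- diff(lev)
  plates <- integer(n - 1)
  ch <- de != 0
  if (any(ch)) plates[ch] <- plates_moved(lev[-n][ch], lev[-1][ch], config)
  low <- p$is_low_charge
  data.frame(
    daa = daa,
    ds = sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2),
    de = de,
    plates = plates,
    charge = p[[qname]][-1],
    dq = diff(p[[qname]]),
    is_first = c(TRUE, rep(FALSE, n - 2)),
    is_tx = low[-n] & !low[-1]
  )
}

#' Simulate one treatment fraction of a plan
#'
#' Expands every spot into its pulses, evaluates the deterministic timing
#' model along the delivery sequence, and adds seeded heteroscedastic noise
#' (see [noise_params()]). Timestamps are cumulative within each beam,
#' starting at 0 for the beam's first pulse, truncated so that every
#' inter-pulse time stays positive, and rounded to 0.001 ms so that log
#' files round-trip exactly through [write_pulse_log()] / [read_pulse_log()].
#'
#' @param plan A plan from [generate_plan()].
#' @param seed Integer seed for the noise draws.
#' @param config A [machine_config()].
#' @param fraction_id Identifier recorded on every pulse.
#' @return A pulse-log data frame with columns `fraction_id`, `beam_id`,
#'   `pulse_index`, `timestamp_ms`, `target_charge_pC`, `energy_level`,
#'   `x_mm`, `y_mm`, `is_low_charge` and the leaf columns.
#' @export
simulate_fraction <- function(plan, seed, config = machine_config(),
                              fraction_id = "F01") {
  stopifnot(nrow(plan) > 0)
  lc <- leaf_columns(config$n_leaves)
  pulses_per_spot <- lapply(plan$charge_pC, split_spot_to_pulses, config = config)
  reps <- lengths(pulses_per_spot)
  pl <- plan[rep(seq_len(nrow(plan)), reps), , drop = FALSE]
  pl$target_charge_pC <- round(unlist(pulses_per_spot), 3)
  withr::with_seed(seed, {
    out <- lapply(split(seq_len(nrow(pl)), factor(pl$beam_id, unique(pl$beam_id))),
                  function(idx) {
      b <- pl[idx, , drop = FALSE]
      n <- nrow(b)
      b$pulse_index <- seq_len(n)
      g <- .transition_geometry(b, config)
      ts <- 0
      if (!is.null(g)) {
        dt_det <- .det_dt(g$daa, g$ds, abs(g$dq), g$de != 0, g$plates,
                          g$is_tx, g$is_first, config$timing)
        np <- config$noise
        eps <- rnorm(n - 1, 0, np$sigma_floor + np$sigma_rel * dt_det)
        out_mask <- runif(n - 1) < np$outlier_prob
        if (any(out_mask))
          eps[out_mask] <- eps[out_mask] +
            abs(rnorm(sum(out_mask), 0, np$outlier_scale))
        ts <- c(0, cumsum(pmax(dt_det + eps, 0.1)))
      }
      data.frame(fraction_id = fraction_id, beam_id = b$beam_id,
                 pulse_index = b$pulse_index,
                 timestamp_ms = round(ts, 3),
                 target_charge_pC = b$target_charge_pC,
                 energy_level = b$energy_level,
                 x_mm = b$x_mm, y_mm = b$y_mm,
                 is_low_charge = b$is_low_charge,
                 b[, lc, drop = FALSE],
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate a multi-fraction treatment course
#'
#' Delivers the same plan `n_fractions` times: the pulse sequence is
#' identical in every fraction, while the timing noise is drawn
#' independently per fraction (sub-seed = `seed + fraction number`), which
#' emulates inter-fractional delivery variability.
#'
#' @param plan A plan from [generate_plan()].
#' @param n_fractions Number of fractions to simulate.
#' @param seed Integer master seed.
#' @param config A [machine_config()].
#' @return A pulse-log data frame covering all fractions, with `fraction_id`
#'   values `"F01"`, `"F02"`, ...
#' @export
simulate_course <- function(plan, n_fractions, seed,
                            config = machine_config()) {
  stopifnot(n_fractions >= 1)
  logs <- lapply(seq_len(n_fractions), function(f)
    simulate_fraction(plan, seed = seed + f, config = config,
                      fraction_id = sprintf("F%02d", f)))
  do.call(rbind, c(logs, list(make.row.names = FALSE)))
}
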