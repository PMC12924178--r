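#' Timing parameters of the deterministic inter-pulse time model
#'
#' The deterministic inter-pulse time between two consecutive pulses is an
#' additive sum of latencies:
#'
#' \deqn{\Delta T = t_{base} + t_{spot} \Delta S + t_{charge} |\Delta q|
#'   + [\Delta AA > 0](t_{aa,lat} + t_{aa} \Delta AA)
#'   + [\Delta E \neq 0](t_{E,lat} + t_{plate} \cdot n_{plates\,moved})
#'   + t_{tx}[\mathrm{tx}] + t_{first}[\mathrm{first}]}
#'
#' The defaults place transitions in the three regimes observed on
#' synchrocyclotron pulse-scanned systems: a few milliseconds for same-layer
#' pulses with no aperture motion, 50--1000 ms when the adaptive aperture
#' moves, and more than 1000 ms whenever the energy (range-modulator plate
#' configuration) changes.
#'
#' @param t_base Fixed pulse repetition interval, ms.
#' @param t_aa_latency Fixed cost of any adaptive-aperture move, ms.
#' @param t_aa_per_mm Cost per mm of summed leaf travel (Delta-AA), ms/mm.
#' @param t_energy_latency Fixed cost of any energy-level change, ms.
#' @param t_plate Cost per range-modulator plate repositioned, ms.
#' @param t_tx_extra Extra latency on the low-charge-to-treatment transition,
#'   ms (position-verification overhead).
#' @param t_first_extra Extra latency on a beam's first transition, ms.
#' @param t_spot_per_mm Cost per mm of spot travel (scanning/steering), ms/mm.
#' @param t_charge_per_pc Cost per pC of pulse-to-pulse target-charge change
#'   (extraction regulation), ms/pC.
#' @return An object of class `timing_params`.
#' @export
timing_params <- function(t_base = 7, t_aa_latency = 50, t_aa_per_mm = 2,
                          t_energy_latency = 900, t_plate = 120,
                          t_tx_extra = 400, t_first_extra = 200,
                          t_spot_per_mm = 2, t_charge_per_pc = 1) {
  p <- list(t_base = t_base, t_aa_latency = t_aa_latency,
            t_aa_per_mm = t_aa_per_mm, t_energy_latency = t_energy_latency,
            t_plate = t_plate, t_tx_extra = t_tx_extra,
            t_first_extra = t_first_extra, t_spot_per_mm = t_spot_per_mm,
            t_charge_per_pc = t_charge_per_pc)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1))))
    stop("all timing parameters must be single non-negative numbers")
  structure(p, class = "timing_params")
}

#' Inter-fraction timing noise parameters
#'
#' Fraction-to-fraction variability of the delivered inter-pulse times is
#' modelled as zero-mean Gaussian noise whose standard deviation grows
#' linearly with the deterministic interval (heteroscedastic), plus a rare
#' positive outlier component representing sporadic machine stalls.
#'
#' @param sigma_floor Baseline noise standard deviation, ms.
#' @param sigma_rel Relative noise: sd grows by this fraction of the
#'   deterministic inter-pulse time.
#' @param outlier_prob Probability that a transition receives an extra
#'   positive delay.
#' @param outlier_scale Scale (sd of the half-normal) of outlier delays, ms.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_floor = 0.5, sigma_rel = 0.08,
                         outlier_prob = 0.001, outlier_scale = 300) {
  stopifnot(sigma_floor >= 0, sigma_rel >= 0,
            outlier_prob >= 0, outlier_prob <= 1, outlier_scale >= 0)
  structure(list(sigma_floor = sigma_floor, sigma_rel = sigma_rel,
                 outlier_prob = outlier_prob, outlier_scale = outlier_scale),
            class = "noise_params")
}

#' Machine configuration for the synthetic delivery simulator
#'
#' Encodes the physics constants of a Hyperscan-type pulse-scanned proton
#' system: a nozzle-mounted range modulator of `n_plates` degrader plates
#' generating `n_energy_levels` energy levels spaced `wet_spacing` mm in
#' water-equivalent thickness, a synchrocyclotron extracting discrete pulses
#' capped at `max_pulse_charge` pC, a low-charge verification layer delivered
#' at `low_charge` pC per pulse, and an adaptive aperture of `n_leaves`
#' collimator leaves trimming each spot within a square field of half-extent
#' `field_half_extent` cm.
#'
#' Plate thicknesses are binary-weighted (1, 2, 4, ... in `wet_spacing`
#' units) on the first `ceiling(log2(n_energy_levels))` plates; remaining
#' plates are held as spares. This is the minimal scheme reproducing the
#' level count and constant spacing, and gives "number of plates moved" a
#' concrete meaning.
#'
#' @param n_plates Number of range-modulator plates.
#' @param n_energy_levels Number of distinct energy levels.
#' @param wet_spacing Water-equivalent spacing between adjacent levels, mm.
#' @param max_pulse_charge Maximum charge a single pulse can carry, pC.
#' @param low_charge Fixed per-pulse charge of the verification layer, pC.
#' @param n_leaves Number of adaptive-aperture leaves entering the
#'   summed-leaf-travel aggregate.
#' @param field_half_extent Half-extent of the scanned field at isocenter, cm.
#' @param leaf_margin Radius of the leaf ring around each trimmed spot, mm.
#' @param aa_deadband Spot displacement (mm) below which the aperture does
#'   not follow the spot.
#' @param aa_reposition_prob Probability of an unforced aperture re-centering
#'   on a within-deadband spot move (drift correction).
#' @param timing A [timing_params()] object.
#' @param noise A [noise_params()] object.
#' @return An object of class `machine_config`.
#' @examples
#' cfg <- machine_config()
#' length(energy_table(cfg))
#' @export
machine_config <- function(n_plates = 18, n_energy_levels = 161,
                           wet_spacing = 2.1, max_pulse_charge = 8,
                           low_charge = 5, n_leaves = 14,
                           field_half_extent = 10,
                           leaf_margin = 8, aa_deadband = 12,
                           aa_reposition_prob = 0.05,
                           timing = timing_params(),
                           noise = noise_params()) {
  stopifnot(n_energy_levels >= 1, wet_spacing > 0, n_leaves >= 1,
            n_plates >= 1, low_charge > 0, max_pulse_charge > low_charge,
            field_half_extent > 0, leaf_margin >= 0, aa_deadband >= 0,
            aa_reposition_prob >= 0, aa_reposition_prob <= 1)
  n_active <- ceiling(log2(max(n_energy_levels, 2)))
  if (n_active > n_plates)
    stop("n_plates too small to realize n_energy_levels with binary weights")
  plate_weights <- c(2^(0:(n_active - 1)), rep(0, n_plates - n_active))
  if (!inherits(timing, "timing_params")) stop("timing must be timing_params()")
  if (!inherits(noise, "noise_params")) stop("noise must be noise_params()")
  structure(list(n_plates = n_plates, n_energy_levels = n_energy_levels,
                 wet_spacing = wet_spacing,
                 max_pulse_charge = max_pulse_charge, low_charge = low_charge,
                 n_leaves = n_leaves, field_half_extent = field_half_extent,
                 leaf_margin = leaf_margin, aa_deadband = aa_deadband,
                 aa_reposition_prob = aa_reposition_prob,
                 plate_weights = plate_weights,
                 timing = timing, noise = noise),
            class = "machine_config")
}

#' @export
print.machine_config <- function(x, ...) {
  cat("<machine_config>\n")
  cat(sprintf("  %d energy levels x %.1f mm WET, %d plates (%d active)\n",
              x$n_energy_levels, x$wet_spacing, x$n_plates,
              sum(x$plate_weights > 0)))
  cat(sprintf("  pulse cap %.1f pC, low-charge layer %.1f pC, %d AA leaves\n",
              x$max_pulse_charge, x$low_charge, x$n_leaves))
  cat(sprintf("  field %.0f x %.0f cm\n",
              2 * x$field_half_extent, 2 * x$field_half_extent))
  invisible(x)
}

#' Water-equivalent thickness of every energy level
#'
#' @param config A [machine_config()].
#' @return Numeric vector of length `n_energy_levels`: the water-equivalent
#'   thickness (mm) inserted by the range modulator at each level, level 0
#'   first. Adjacent values differ by exactly `wet_spacing`.
#' @export
energy_table <- function(config = machine_config()) {
  stopifnot(inherits(config, "machine_config"))
  (seq_len(config$n_energy_levels) - 1) * config$wet_spacing
}

#' Range-modulator plate occupancy for an energy level
#'
#' Decomposes a level index into the binary-weighted plate set whose summed
#' thickness (in `wet_spacing` units) equals the level. The mapping is
#' deterministic and injective: distinct levels always give distinct
#' occupancy vectors.
#'
#' @param level Integer level index (0-based), scalar or vector.
#' @param config A [machine_config()].
#' @return For scalar `level`, a logical vector of length `n_plates`
#'   (`TRUE` = plate inserted); for vector input, a logical matrix with one
#'   row per level.
#' @export
plate_configuration <- function(level, config = machine_config()) {
  stopifnot(inherits(config, "machine_config"))
  if (any(level < 0 | level >= config$n_energy_levels | level != floor(level)))
    stop("level out of range [0, n_energy_levels)")
  w <- config$plate_weights
  occ <- t(vapply(level, function(l) {
    ins <- rep(FALSE, length(w))
    for (j in order(w, decreasing = TRUE)) {
      if (w[j] > 0 && w[j] <= l) { ins[j] <- TRUE; l <- l - w[j] }
    }
    ins
  }, logical(length(w))))
  if (length(level) == 1L) occ[1, ] else occ
}

#' Number of plates repositioned between two energy levels
#'
#' Hamming distance between the plate occupancy vectors of the two levels:
#' larger energy steps generally require repositioning more range-shifter
#' plates, but the count also depends on the binary structure of the level
#' indices (a one-level step can flip several plates).
#'
#' @param level_a,level_b Integer level indices (vectors recycle).
#' @param config A [machine_config()].
#' @return Integer vector of plate move counts; zero iff the levels match.
#' @export
plates_moved <- function(level_a, level_b, config = machine_config()) {
  stopifnot(inherits(config, "machine_config"))
  if (any(c(level_a, level_b) < 0) ||
      any(c(level_a, level_b) >= config$n_energy_levels) ||
      any(c(level_a, level_b) != floor(c(level_a, level_b))))
    stop("level out of range [0, n_energy_levels)")
  .popcount(bitwXor(as.integer(level_a), as.integer(level_b)))
}

# popcount for non-negative integers below 2^16
.popcount <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      t8 <- integer(256)
      for (i in 1:255) t8[i + 1] <- t8[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
      tab <<- t8
    }
    tab[bitwAnd(x, 255L) + 1L] + tab[bitwShiftR(x, 8L) + 1L]
  }
})
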