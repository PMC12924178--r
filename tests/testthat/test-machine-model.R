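test_that("energy table has the configured level count and constant spacing", {
  cfg <- machine_config()
  tab <- energy_table(cfg)
  expect_length(tab, 161)
  expect_identical(tab[1], 0)
  expect_equal(tab[161], 336.0)
  expect_equal(unique(round(diff(tab), 9)), 2.1)

  small <- machine_config(n_energy_levels = 9, wet_spacing = 0.5)
  expect_equal(energy_table(small), seq(0, 4, by = 0.5))
})

test_that("plate configuration is a bijection realizing every level", {
  cfg <- machine_config()
  occ <- plate_configuration(0:160, cfg)
  expect_equal(nrow(occ), 161)
  # summed inserted thickness equals the level, for every level
  expect_equal(as.vector(occ %*% cfg$plate_weights), 0:160)
  expect_equal(nrow(unique(occ)), 161)  # injective
  expect_false(any(plate_configuration(0, cfg)))
  expect_equal(which(plate_configuration(5, cfg)), c(1, 3))  # weights 1 + 4
  expect_error(plate_configuration(161, cfg), "range")
  expect_error(plate_configuration(-1, cfg), "range")
})

test_that("plates_moved is the symmetric occupancy Hamming distance", {
  cfg <- machine_config()
  expect_identical(plates_moved(7, 7, cfg), 0L)
  expect_identical(plates_moved(0, 1, cfg), 1L)
  expect_identical(plates_moved(3, 4, cfg), 3L)  # {1,2} vs {4}
  lv <- expand.grid(a = c(0, 1, 5, 63, 64, 160), b = c(0, 2, 31, 32, 100))
  expect_equal(plates_moved(lv$a, lv$b, cfg), plates_moved(lv$b, lv$a, cfg))
  expect_true(all(plates_moved(lv$a, lv$b, cfg)[lv$a != lv$b] > 0))
})

test_that("spot-to-pulse splitting fills to the cap with a remainder", {
  expect_identical(split_spot_to_pulses(5), 5)
  expect_identical(split_spot_to_pulses(8), 8)
  expect_identical(split_spot_to_pulses(20), c(8, 8, 4))
  expect_error(split_spot_to_pulses(0), "positive")
  for (q in c(0.3, 7.99, 8.01, 16, 29.5)) {
    p <- split_spot_to_pulses(q)
    expect_equal(sum(p), q)
    expect_length(p, ceiling(q / 8))
    expect_true(all(p <= 8 + 1e-12))
  }
})

test_that("deterministic inter-pulse time reproduces the additive latencies", {
  cfg <- machine_config()
  a <- two_pulse_record(config = cfg)[1, ]
  a$pulse_index <- 5L  # mid-sequence: no first-transition extra
  b <- a
  # identical pulses: base interval only
  expect_equal(deterministic_delta_t(a, b, cfg), 7)
  # one leaf moved 100 mm, same energy/position/charge: aperture regime
  b2 <- a; b2$leaf01_x_mm <- a$leaf01_x_mm + 100
  expect_equal(deterministic_delta_t(a, b2, cfg), 7 + 50 + 200)
  # energy change moving 3 plates (levels 3 -> 4), nothing else
  a3 <- a; a3$energy_level <- 3L
  b3 <- a; b3$energy_level <- 4L
  expect_equal(deterministic_delta_t(a3, b3, cfg), 7 + 900 + 3 * 120)
  # monotone in leaf travel
  b4 <- a; b4$leaf01_x_mm <- a$leaf01_x_mm + 200
  expect_gt(deterministic_delta_t(a, b4, cfg),
            deterministic_delta_t(a, b2, cfg))
})

test_that("generated plans respect structure, field bounds and determinism", {
  cfg <- machine_config()
  p1 <- generate_plan(5, 1, 1, 1, cfg)
  expect_setequal(unique(p1$layer_index), c(0, 1))  # prelude + treatment
  expect_true(all(p1$charge_pC[p1$layer_index == 0] == cfg$low_charge))

  p <- tiny_plan(7, 2, 3, 10)
  expect_true(all(abs(p$x_mm) <= 100 & abs(p$y_mm) <= 100))
  expect_identical(p, tiny_plan(7, 2, 3, 10))
  expect_false(identical(p, tiny_plan(8, 2, 3, 10)))
  # treatment layers in descending energy within each beam
  for (b in unique(p$beam_id)) {
    tx <- p[p$beam_id == b & p$layer_index > 0, ]
    lev <- tapply(tx$energy_level, tx$layer_index, unique)
    expect_true(all(diff(lev) < 0))
  }
})

test_that("simulated fractions obey the timing regimes and pulse invariants", {
  cfg <- quiet_cfg()
  plan <- tiny_plan(31, 1, 4, 12, cfg)
  log0 <- simulate_fraction(plan, 32, cfg)
  expect_true(all(log0$target_charge_pC <= cfg$max_pulse_charge + 1e-9))
  expect_true(all(log0$target_charge_pC[log0$is_low_charge] == cfg$low_charge))
  expect_equal(nrow(validate_pulse_log(log0, cfg)), 0)

  ft <- build_feature_table(log0, cfg)
  plain <- !ft$is_first_pulse & !ft$is_tx_pulse
  same <- plain & ft$log_daa == 0 & ft$log_de == 0
  aa_only <- plain & ft$log_daa > 0 & ft$log_de == 0
  energy <- ft$log_de > 0
  expect_gt(sum(same), 0)
  expect_gt(sum(aa_only), 0)
  expect_gt(sum(energy), 0)
  expect_true(all(ft$delta_t[same] < 50))
  expect_true(all(ft$delta_t[aa_only] >= 50 & ft$delta_t[aa_only] <= 1000))
  expect_true(all(ft$delta_t[energy] > 1000))
})

test_that("noise only perturbs timestamps, reproducibly, with zero-noise cumsum", {
  cfgq <- quiet_cfg()
  cfg <- machine_config()
  plan <- tiny_plan(41, 1, 2, 8)
  l_quiet <- simulate_fraction(plan, 42, cfgq)
  ftq <- build_feature_table(l_quiet, cfgq)
  # zero noise: timestamp differences are exactly the deterministic model
  g <- l_quiet[l_quiet$pulse_index <= 2, ]
  expect_equal(ftq$delta_t[1],
               round(deterministic_delta_t(g[1, ], g[2, ], cfgq), 3))

  l1 <- simulate_fraction(plan, 42, cfg)
  l2 <- simulate_fraction(plan, 42, cfg)
  l3 <- simulate_fraction(plan, 43, cfg)
  expect_identical(l1, l2)
  expect_identical(l1[, setdiff(names(l1), "timestamp_ms")],
                   l3[, setdiff(names(l3), "timestamp_ms")])
  expect_false(identical(l1$timestamp_ms, l3$timestamp_ms))
})

test_that("courses share the pulse sequence with independent zero-mean noise", {
  # gaussian component only: the outlier mixture is positive by design and
  # would need far more fractions to average out
  cfg <- machine_config(noise = noise_params(outlier_prob = 0))
  plan <- tiny_plan(51, 1, 3, 8, cfg)
  course <- simulate_course(plan, 6, 51, cfg)
  counts <- table(course$fraction_id)
  expect_length(counts, 6)
  expect_equal(length(unique(counts)), 1)
  iv <- interfraction_variability(course)
  res <- iv$residuals$residual
  # zero-mean noise: the mean residual is within 4 standard errors of zero
  expect_lt(abs(mean(res)), 4 * stats::sd(res) / sqrt(length(res)))
})
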