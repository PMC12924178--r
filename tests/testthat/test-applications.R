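test_that("cumulative delivery time is the running sum", {
  one <- cumulative_bdt(100)
  expect_equal(one$cumulative_ms, 100)
  s <- cumulative_bdt(c(1, 2, 3))
  expect_equal(s$cumulative_ms, c(1, 3, 6))
  # the total is permutation invariant
  p <- cumulative_bdt(c(3, 1, 2))
  expect_equal(max(p$cumulative_ms), max(s$cumulative_ms))
  expect_error(cumulative_bdt(c(5, 0, 2)), "positive")
})

test_that("timing-source comparison reports the signed relative deviation", {
  ref <- c(10, 200, 1500, 30)
  same <- compare_timing_sources(ref, ref)
  expect_equal(same$relative_deviation, 0)
  up <- compare_timing_sources(ref, 1.01 * ref)
  expect_equal(up$relative_deviation, 0.01, tolerance = 1e-12)
  # predicted smaller than reference: negative sign (predicted minus actual)
  dn <- compare_timing_sources(ref, 0.95 * ref)
  expect_lt(dn$relative_deviation, 0)
  expect_equal(nrow(up$series), 4)
  expect_error(compare_timing_sources(ref, ref[-1]), "counts differ")
})

test_that("breathing phase is periodic, uniform in time, amplitude-free", {
  tr <- breathing_trace(4, n_phases = 4)
  expect_equal(breathing_phase(0, tr), 0L)
  expect_equal(breathing_phase(4, tr), 0L)   # one full period
  expect_equal(breathing_phase(2, tr), 2L)   # half period
  t <- seq(0, 20, by = 0.01)
  expect_equal(breathing_phase(t, tr), breathing_phase(t + 4, tr))
  tr2 <- breathing_trace(4, amplitude = 99, n_phases = 4)
  expect_equal(breathing_phase(t, tr), breathing_phase(t, tr2))
  # offset of half a cycle shifts the label by half the phases
  tr3 <- breathing_trace(4, phase_offset = pi, n_phases = 4)
  expect_equal(breathing_phase(0, tr3), 2L)
})

test_that("phase maps conserve charge exactly and equidistribute", {
  tr <- breathing_trace(2, n_phases = 10)
  # all pulses inside the first phase slice
  m0 <- map_pulses_to_phases(c(0, 50, 100, 150), rep(2, 4), tr)
  expect_equal(unname(m0$phase_charge["0"]), 8)
  expect_equal(sum(m0$phase_charge), 8)
  # charge conservation on an arbitrary spread
  ts <- cumsum(runif(500, 10, 900))
  ch <- runif(500, 1, 8)
  m1 <- map_pulses_to_phases(ts, ch, tr)
  expect_equal(sum(m1$phase_charge), sum(ch))
  # constant spacing incommensurate with the period: near-uniform shares
  m2 <- map_pulses_to_phases(cumsum(rep(337, 5000)), rep(1, 5000), tr)
  shares <- m2$phase_charge / sum(m2$phase_charge)
  expect_true(all(shares >= 0.08 & shares <= 0.12))
  expect_error(map_pulses_to_phases(c(10, 5), c(1, 1), tr), "monotone")
  expect_error(map_pulses_to_phases(c(5, 10), c(1, -1), tr), "positive")
})

test_that("phase-map comparison matches hand-computed agreement and TV", {
  tr <- breathing_trace(2, n_phases = 2)
  a <- map_pulses_to_phases(c(0, 100, 200, 1000), rep(1, 4), tr)  # {3, 1}
  b <- map_pulses_to_phases(c(0, 1000, 1100, 1200), rep(1, 4), tr)  # {1, 3}
  expect_equal(unname(a$phase_charge), c(3, 1))
  expect_equal(unname(b$phase_charge), c(1, 3))
  same <- compare_phase_maps(a, a)
  expect_equal(same$agreement, 1)
  expect_equal(same$tv_distance, 0)
  ab <- compare_phase_maps(a, b)
  expect_equal(ab$tv_distance, 0.5)
  expect_equal(ab$agreement, 0.5)
  # disjoint single-phase maps: extremes
  c1 <- map_pulses_to_phases(c(0, 100), c(1, 1), tr)
  c2 <- map_pulses_to_phases(c(1000, 1100), c(1, 1), tr)
  cc <- compare_phase_maps(c1, c2)
  expect_equal(cc$agreement, 0)
  expect_equal(cc$tv_distance, 1)
  expect_error(compare_phase_maps(a, map_pulses_to_phases(0, 1, tr)),
               "mismatched")
})

test_that("repainted plans repeat the treatment layers, prelude kept once", {
  plan <- tiny_plan(91, 1, 3, 6)
  rp <- make_repainted_plan(plan, k = 4)
  expect_equal(sum(rp$layer_index == 0), sum(plan$layer_index == 0))
  expect_equal(nrow(rp), sum(plan$layer_index == 0) +
                 4 * sum(plan$layer_index > 0))
  expect_equal(sort(unique(rp$layer_index)), 0:12)
  # every repaint repeats the same energy sequence
  lev <- tapply(rp$energy_level, rp$layer_index, unique)[-1]
  expect_equal(unname(lev[1:3]), unname(lev[4:6]))
})

test_that("zero-noise fractions produce identical phase maps", {
  cfgq <- quiet_cfg()
  plan <- tiny_plan(93, 1, 2, 8, cfgq)
  course <- simulate_course(plan, 2, 93, cfgq)
  tr <- breathing_trace(2, n_phases = 10)
  maps <- lapply(split(course, course$fraction_id), function(f)
    map_pulses_to_phases(f$timestamp_ms[order(f$pulse_index)],
                         f$target_charge_pC[order(f$pulse_index)], tr))
  cmp <- compare_phase_maps(maps[[1]], maps[[2]])
  expect_equal(cmp$tv_distance, 0)
  expect_equal(cmp$agreement, 1)
})

test_that("model-predicted timelines are monotone and leakage is refused", {
  qm <- quick_model()
  app_plan <- generate_plan(95, 1, 2, 8, machine_config(), plan_id = "APPU")
  tl <- predict_plan_timeline(app_plan, qm$m)
  expect_true(all(diff(tl$timestamp_ms) > 0))
  expect_equal(tl$timestamp_ms[1], 0)
  # reusing the training plan must raise a leakage error
  course <- simulate_course(qm$plan, 2, 96)
  expect_error(interplay_experiment(qm$plan, qm$m, course), "leakage")
})

test_that("interplay summary reports one row per period with exact charge", {
  qm <- quick_model()
  cfg <- machine_config()
  app_plan <- generate_plan(97, 1, 2, 8, cfg, plan_id = "APPI")
  course <- simulate_course(app_plan, 3, 97, cfg)
  res <- interplay_experiment(app_plan, qm$m, course, periods = c(2, 4, 5),
                              config = cfg)
  expect_equal(res$summary$period_s, c(2, 4, 5))
  expect_true(res$charge_conserved)
  expect_true(all(res$summary$intrinsic_tv_max >= 0))
  expect_true(all(res$summary$model_tv_mean >= 0 &
                    res$summary$model_tv_mean <= 1))
  # intrinsic spread is nonzero when fraction noise is nonzero
  expect_true(any(res$summary$intrinsic_tv_max > 0))
})
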