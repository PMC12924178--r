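# shared fixtures, built in code at test time

quiet_cfg <- function(...) {
  machine_config(noise = noise_params(sigma_floor = 0, sigma_rel = 0,
                                      outlier_prob = 0), ...)
}

# a small two-layer, two-beam plan and its noise-free fraction
tiny_plan <- function(seed = 11, n_beams = 2, n_layers = 2, spots = 6,
                      config = machine_config()) {
  generate_plan(seed, n_beams, n_layers, spots, config, plan_id = "T")
}

# minimal hand-built pulse log: two identical pulses at given leaf layout
two_pulse_record <- function(dt = 10, config = machine_config()) {
  lc <- leaf_columns(config$n_leaves)
  r <- data.frame(fraction_id = "F01", beam_id = "B1", pulse_index = 1:2,
                  timestamp_ms = c(0, dt), target_charge_pC = 8,
                  energy_level = 42L, x_mm = 1, y_mm = 2,
                  is_low_charge = FALSE)
  r[lc] <- 0
  r
}

# a quickly trained model on a small synthetic course (cached per session)
quick_model_env <- new.env()
quick_model <- function() {
  if (is.null(quick_model_env$m)) {
    cfg <- machine_config()
    plan <- generate_plan(21, 1, 4, 12, cfg, plan_id = "QM")
    course <- simulate_course(plan, 2, 21, cfg)
    ft <- build_feature_table(course, cfg)
    sp <- stratified_split(ft, seed = 22)
    quick_model_env$m <- tune_and_train(sp$train, seed = 23, cv_folds = 2,
                                        n_candidates = 1)
    quick_model_env$split <- sp
    quick_model_env$plan <- plan
    quick_model_env$course <- course
  }
  quick_model_env
}
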