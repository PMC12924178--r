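# Orchestration: configuration, per-stage sub-seeding, and an end-to-end
# reproduction run chaining every stage on synthetic data.

#' Default end-to-end run configuration
#'
#' Per-stage sub-seeds are derived from the master seed with fixed offsets
#' (simulation +10, split +20, training +30, explanation +40, application
#' plan +50), so any stage can be rerun in isolation reproducibly.
#'
#' @param seed Master seed.
#' @param n_beams,n_layers_per_beam,spots_per_layer,n_fractions Study size.
#' @param train_frac,n_bins Split settings.
#' @param cv_folds,n_candidates Hyperparameter search settings.
#' @param n_explain Explanation sample size.
#' @param explain_background Background rows used for the Shapley pass.
#' @param repaint_k Number of paintings of the held-out repainting plan.
#' @param periods Breathing periods (s) for the interplay stage.
#' @return A named list understood by [run_end_to_end()].
#' @export
default_run_config <- function(seed = 1, n_beams = 2, n_layers_per_beam = 8,
                               spots_per_layer = 25, n_fractions = 5,
                               train_frac = 0.7, n_bins = 10, cv_folds = 5,
                               n_candidates = 8, n_explain = 100,
                               explain_background = 100, repaint_k = 5,
                               periods = c(2, 4, 5)) {
  list(seed = seed, n_beams = n_beams,
       n_layers_per_beam = n_layers_per_beam,
       spots_per_layer = spots_per_layer, n_fractions = n_fractions,
       train_frac = train_frac, n_bins = n_bins, cv_folds = cv_folds,
       n_candidates = n_candidates, n_explain = n_explain,
       explain_background = explain_background, repaint_k = repaint_k,
       periods = periods)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return A run-configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  base
}

#' Run the full pipeline end to end on synthetic data
#'
#' simulate -> features -> split -> train -> evaluate -> inter-fraction
#' variability -> explain -> repainting cumulative comparison -> interplay.
#' Fully reproducible from (config, seed).
#'
#' @param config A run-configuration list (see [default_run_config()]).
#' @param machine A [machine_config()].
#' @param out_json Optional path: write the report as JSON.
#' @return The report: a named list with per-bin model and intrinsic
#'   metrics, grouped importance summaries, the repainting cumulative-time
#'   deviation, and the interplay summary table.
#' @export
run_end_to_end <- function(config = default_run_config(),
                           machine = machine_config(), out_json = NULL) {
  seed <- config$seed
  plan <- generate_plan(seed + 10, config$n_beams, config$n_layers_per_beam,
                        config$spots_per_layer, machine, plan_id = "TRAIN")
  course <- simulate_course(plan, config$n_fractions, seed + 10, machine)
  features <- build_feature_table(course, machine)
  split <- stratified_split(features, config$train_frac, config$n_bins,
                            seed + 20)
  model <- tune_and_train(split$train, seed = seed + 30,
                          cv_folds = config$cv_folds,
                          n_candidates = config$n_candidates)
  pred_test <- predict_delta_t(model, split$test)
  metrics <- interval_metrics(split$test$delta_t, pred_test)
  intrinsic <- interfraction_variability(course)

  expl_rows <- sample_for_explanation(split$test, config$n_explain, seed + 40)
  bg <- split$train[withr::with_seed(seed + 41,
    sample(nrow(split$train), min(config$explain_background,
                                  nrow(split$train)))), , drop = FALSE]
  shap <- tree_shap(model, expl_rows, bg)
  grouped <- group_attributions(shap)
  importance <- importance_summary(grouped, predict_delta_t(model, expl_rows))

  app_plan <- generate_plan(seed + 50, 1, config$n_layers_per_beam,
                            config$spots_per_layer, machine, plan_id = "APP")
  repaint <- make_repainted_plan(app_plan, config$repaint_k)
  repaint_log <- simulate_fraction(repaint, seed + 51, machine, "R01")
  repaint_ft <- build_feature_table(repaint_log, machine)
  cmp <- compare_timing_sources(repaint_ft$delta_t,
                                predict_delta_t(model, repaint_ft))
  app_course <- simulate_course(app_plan, config$n_fractions, seed + 52,
                                machine)
  interplay <- interplay_experiment(app_plan, model, app_course,
                                    config$periods, machine)

  report <- list(
    config = config,
    n_pulses = nrow(course), n_transitions = nrow(features),
    n_train = nrow(split$train), n_test = nrow(split$test),
    best_hyperparameters = model$best_hyperparameters,
    model_metrics = metrics,
    intrinsic_metrics = intrinsic$metrics,
    intrinsic_within_band = intrinsic$within_band,
    importance_global = importance$global,
    importance_per_interval = importance$per_interval,
    repaint_relative_deviation = cmp$relative_deviation,
    interplay_summary = interplay$summary,
    interplay_charge_conserved = interplay$charge_conserved)
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
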