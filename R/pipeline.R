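#' @title Simulation pipeline
#' @description Stage composition from subject descriptors to the
#'   per-configuration feature vector
#'   x = (Emax, Eint, Eavg, Vpeak, Tpeak, Height, Weight, Age, sex)
#'   and its PCS label. A single central electrode is driven at the default
#'   stimulation amplitude for feature extraction; the biphasic waveform and
#'   all constants come from the run configuration.
#' @name pipeline
NULL

FEATURE_NAMES <- c("e_max", "e_int", "e_avg", "v_peak", "t_peak",
                   "height", "weight", "age", "sex")

# electrode driven during feature extraction: a central one (index 3 is the
# middle-row left disc, nearest the array centroid)
.CENTRAL_ELECTRODE <- 3L

#' Simulate features and PCS for one subject-configuration pair
#'
#' Runs the full physics chain: personalized tissue model, voxel grid,
#' quasi-static solve with one central active disc, field features over the
#' innervated region, extracellular drive of the dermal fiber, passive cable
#' integration, neural peak features, and PCS.
#'
#' @param subject a `subject_descriptors`
#' @param config an `electrode_config`
#' @param run_config run configuration (see [default_run_config()])
#' @return one-row data.frame: `subject_id`, `config_label`, the 9 features
#'   (in fixed order), the PCS components and `pcs_calc`
#' @export
simulate_features <- function(subject, config,
                              run_config = default_run_config()) {
  model <- fingertip_model(subject, run_config)
  grid <- build_grid(model, config, run_config$solver)
  pot <- solve_potential(grid, active = .CENTRAL_ELECTRODE,
                         current_mA = run_config$solver$drive_current_ma,
                         tol = run_config$solver$tol)
  fld <- electric_field(pot)
  ff <- extract_field_features(fld, grid,
                               region = if (identical(run_config$solver$region,
                                                      "all")) "all"
                                        else "below_stratum_corneum")
  fib <- fiber_geometry(
    diameter_um = run_config$fiber$diameter_um,
    internode_mm = run_config$fiber$internode_mm,
    n_nodes = run_config$fiber$n_nodes,
    depth_mm = run_config$fiber$depth_mm,
    nodal_gap_um = run_config$fiber$nodal_gap_um)
  cp <- derive_cable_params(fib, run_config)
  wf <- biphasic_waveform(run_config$waveform$phase_width_us,
                          run_config$waveform$amplitude_ma,
                          run_config$waveform$polarity,
                          run_config$waveform$window_us)
  dt <- 0.05 * cp$c_m / (cp$g_m + 2 * cp$g_a)
  drv <- extracellular_drive(pot, node_positions(fib, grid$layout), wf,
                             dt = dt)
  traj <- integrate_cable(cp, drv)
  nf <- neural_features(traj, cp)
  comp <- pcs_score(ff, nf, v_th = cp$v_th, k = cp$k_slope,
                    epsilon = run_config$scoring$epsilon)
  data.frame(
    subject_id = if (is.null(subject$id)) NA_character_ else subject$id,
    config_label = config_label(config),
    e_max = ff$e_max, e_int = ff$e_int, e_avg = ff$e_avg,
    v_peak = nf$v_peak_mv, t_peak = nf$t_peak_s,
    height = subject$height, weight = subject$weight, age = subject$age,
    sex = subject$sex,
    e_focus = comp$e_focus, w_neuro = comp$w_neuro,
    u_pattern = comp$u_pattern, spread = comp$spread,
    pcs_calc = comp$pcs,
    stringsAsFactors = FALSE)
}

#' Feature pipeline closure for a run configuration
#'
#' @param run_config run configuration
#' @return function(subject, config) returning the [simulate_features()] row
#' @export
feature_pipeline <- function(run_config = default_run_config()) {
  force(run_config)
  function(subject, config) simulate_features(subject, config, run_config)
}

#' Simulate the full 36-configuration feature table for one subject
#'
#' @param subject a `subject_descriptors`
#' @param pipeline a pipeline callable as from [feature_pipeline()]
#' @param verbose print per-configuration progress
#' @return 36-row data.frame in enumeration order
#' @export
subject_feature_table <- function(subject,
                                  pipeline = feature_pipeline(),
                                  verbose = FALSE) {
  cfgs <- enumerate_configs()
  rows <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    rows[[i]] <- tryCatch(pipeline(subject, cfgs[[i]]),
      error = function(e) stop(sprintf(
        "pipeline failed for subject %s, configuration %s: %s",
        subject$id, config_label(cfgs[[i]]), conditionMessage(e))))
    if (verbose)
      message(sprintf("  %s: PCS = %.4f", rows[[i]]$config_label,
                      rows[[i]]$pcs_calc))
  }
  do.call(rbind, rows)
}

#' Run the end-to-end predict-then-verify workflow
#'
#' Stages: per-subject simulation features -> PCS labels -> cross-validated
#' model selection -> final fit -> per-subject rankings; if behavioral
#' records are supplied (or synthesized), the evaluation report is added.
#' Outputs are deterministic for fixed configuration and seed. When
#' `out_dir` is given, stage artifacts (CSV/JSON with provenance) are
#' written there.
#'
#' @param train_subjects list of `subject_descriptors` used to build the
#'   PCS-labeled training set
#' @param test_subjects list of `subject_descriptors` to rank for
#' @param run_config run configuration
#' @param seed integer seed for model selection and fitting
#' @param behavior optional behavioral records data.frame (see
#'   [evaluate_recommendations()]); if `NULL` and `synth_behavior = TRUE`,
#'   records are synthesized from each test subject's computed PCS
#' @param synth_behavior synthesize behavior when none is supplied
#' @param out_dir optional output directory for stage artifacts
#' @param verbose stage-level logging
#' @return list with `samples`, `cv_report`, `model`, `features_test`,
#'   `recommendations`, `behavior`, `evaluation`, `provenance`
#' @export
run_pipeline <- function(train_subjects, test_subjects,
                         run_config = default_run_config(),
                         seed = 7, behavior = NULL, synth_behavior = TRUE,
                         out_dir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  pipe <- feature_pipeline(run_config)
  log_stage <- function(fmt, ...) if (verbose)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, "secs")),
            sprintf(fmt, ...))

  log_stage("building PCS-labeled training set (%d subjects x 36 configs)",
            length(train_subjects))
  samples <- build_training_set(train_subjects, pipe)

  log_stage("cross-validating %d model candidates", 10)
  cv <- cross_validate_models(samples, seed = seed,
                              folds = run_config$model_selection$folds)
  log_stage("selected %s (CV MAE %.4g)", cv$chosen,
            min(cv$summary$mean_mae))
  model <- fit_final_model(samples, cv$chosen, seed = seed)

  log_stage("ranking 36 configurations for %d test subjects",
            length(test_subjects))
  feats <- lapply(test_subjects, subject_feature_table, pipeline = pipe)
  names(feats) <- vapply(test_subjects, function(s) s$id, character(1))
  recs <- lapply(feats, function(f) recommend_from_features(f, model))

  if (is.null(behavior) && synth_behavior) {
    log_stage("synthesizing behavioral records")
    behavior <- do.call(rbind, lapply(names(feats), function(sid)
      simulate_recognition_experiment(sid, feats[[sid]]$pcs_calc,
        spec = behavior_gen_spec(run_config$behavior),
        seed = seed + match(sid, names(feats)))))
  }
  evaluation <- if (!is.null(behavior)) {
    log_stage("evaluating recommendations against behavior")
    evaluate_recommendations(recs, behavior)
  }

  prov <- list(config_hash = config_hash(run_config), seed = seed,
               schema_version = run_config$schema_version,
               package_version = as.character(utils::packageVersion("pcsrank")),
               timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  res <- list(samples = samples, cv_report = cv, model = model,
              features_test = feats, recommendations = recs,
              behavior = behavior, evaluation = evaluation,
              provenance = prov)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' Write pipeline stage artifacts
#'
#' CSV for tabular stages, JSON for the CV report, rankings, evaluation and
#' provenance. Every file set carries the provenance record.
#'
#' @param res result of [run_pipeline()]
#' @param out_dir directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    f <<- c(f, p)
  }
  wjson <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f <<- c(f, p)
  }
  wcsv(res$samples, "training_samples.csv")
  wjson(list(summary = res$cv_report$summary, chosen = res$cv_report$chosen,
             seed = res$cv_report$seed), "cv_report.json")
  wjson(lapply(res$recommendations, function(r)
    list(subject_id = r$subject_id, ranking = r$ranking,
         top1 = r$top1, top5 = r$top5)), "recommendations.json")
  if (!is.null(res$behavior)) wcsv(res$behavior, "behavior.csv")
  if (!is.null(res$evaluation)) {
    ev <- unclass(res$evaluation)
    ev$subject_ranks <- as.list(ev$subject_ranks)
    wjson(ev, "evaluation.json")
  }
  wjson(res$provenance, "provenance.json")
  invisible(f)
}
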