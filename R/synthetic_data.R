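#' @title Synthetic cohorts and psychophysics
#' @description Generates subject cohorts with realistic descriptor ranges
#'   and simulates the 5-alternative pattern-recognition experiment (15
#'   trials per configuration, chance rate 0.2) with recognition accuracy
#'   stochastically linked to PCS through a clipped logistic, so the full
#'   predict-then-verify workflow is testable without human data.
#' @name synthetic_data
NULL

#' Behavior-generator specification
#'
#' Success probability per configuration:
#' p = clip(chance + (1 - chance) * logistic(beta0 + beta1 * z), chance,
#' cap), where z is the cohort-standardized PCS; the number of correct
#' responses is binomial with `n_trials_per_config` trials.
#'
#' @param config optional `behavior` section of a run configuration
#' @param chance_rate 5-AFC chance rate (1 / number of patterns)
#' @param n_trials_per_config trials per configuration (5 patterns x 3
#'   repeats)
#' @param beta0 link intercept (sets the group accuracy level)
#' @param beta1 link slope (strength of the PCS-accuracy association)
#' @param cap accuracy ceiling
#' @return a `behavior_gen_spec`
#' @export
behavior_gen_spec <- function(config = NULL, chance_rate = 0.2,
                              n_trials_per_config = 15, beta0 = 0.3,
                              beta1 = 1.0, cap = 0.95) {
  if (!is.null(config)) {
    chance_rate <- config$chance_rate
    n_trials_per_config <- config$n_trials_per_config
    beta0 <- config$beta0; beta1 <- config$beta1; cap <- config$cap
  }
  stopifnot(chance_rate > 0, chance_rate < 1, cap > chance_rate, cap <= 1,
            n_trials_per_config >= 1)
  structure(list(chance_rate = chance_rate,
                 n_trials_per_config = as.integer(n_trials_per_config),
                 beta0 = beta0, beta1 = beta1, cap = cap),
            class = "behavior_gen_spec")
}

#' Sample a synthetic subject cohort
#'
#' Descriptors are drawn uniformly from ranges matching the study
#' population: age 22-27 y, height 165-180 cm, weight 50-82 kg, sex
#' Bernoulli(0.5). Deterministic under the seed.
#'
#' @param n cohort size
#' @param seed integer seed
#' @param prefix id prefix (ids are `prefix1` ... `prefixn`)
#' @return list of `subject_descriptors`
#' @export
sample_subjects <- function(n, seed = 1, prefix = "P") {
  stopifnot(n >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    subject_descriptors(
      sex = stats::rbinom(1, 1, 0.5),
      age = stats::runif(1, 22, 27),
      height = stats::runif(1, 165, 180),
      weight = stats::runif(1, 50, 82),
      id = paste0(prefix, i)))
}

#' Simulate a recognition experiment for one subject
#'
#' For each of the 36 configurations, draws the number of correct responses
#' from a binomial whose success probability increases with the
#' configuration's (standardized) PCS through the clipped logistic link.
#'
#' @param subject_id subject identifier
#' @param pcs_values numeric vector of 36 per-configuration PCS values in
#'   enumeration order
#' @param spec a `behavior_gen_spec`
#' @param seed integer seed
#' @return data.frame of behavioral records: `subject_id`, `config_label`,
#'   `n_trials`, `n_correct`, `accuracy`, `p_true`
#' @export
simulate_recognition_experiment <- function(subject_id, pcs_values,
                                            spec = behavior_gen_spec(),
                                            seed = 1) {
  stopifnot(length(pcs_values) == 36,
            inherits(spec, "behavior_gen_spec"))
  z <- if (stats::sd(pcs_values) == 0) rep(0, 36)
       else (pcs_values - mean(pcs_values)) / stats::sd(pcs_values)
  p <- spec$chance_rate + (1 - spec$chance_rate) *
       stats::plogis(spec$beta0 + spec$beta1 * z)
  p <- pmin(pmax(p, spec$chance_rate), spec$cap)
  set.seed(seed)
  k <- stats::rbinom(36, spec$n_trials_per_config, p)
  data.frame(subject_id = subject_id,
             config_label = config_table()$label,
             n_trials = spec$n_trials_per_config,
             n_correct = k,
             accuracy = k / spec$n_trials_per_config,
             p_true = p,
             stringsAsFactors = FALSE)
}

#' The five spatial stimulation patterns
#'
#' Canonical electrode subsets on the 3 x 2 array (row-major numbering:
#' row 1 = electrodes 1-2, row 2 = 3-4, row 3 = 5-6): single point (1
#' electrode), horizontal line (a row pair, 2), vertical line (a column, 3),
#' small area (2 x 2 block, 4), large area (all 6). The exact subsets are a
#' fixture convention; PCS itself is pattern-agnostic.
#'
#' @return list of `stimulus_pattern`s (`name`, `active_electrodes`)
#' @export
pattern_set <- function() {
  mk <- function(name, el) structure(
    list(name = name, active_electrodes = as.integer(el)),
    class = "stimulus_pattern")
  list(mk("single_point", 3),
       mk("horizontal_line", c(3, 4)),
       mk("vertical_line", c(1, 3, 5)),
       mk("small_area", c(1, 2, 3, 4)),
       mk("large_area", 1:6))
}

#' Write a behavioral CSV fixture
#'
#' @param records behavioral records data.frame
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_behavior_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
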