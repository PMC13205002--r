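#' @title Evaluation against behavioral accuracy
#' @description Quantifies how well a predicted PCS ranking agrees with
#'   measured pattern-recognition accuracy: Pearson trend consistency
#'   across the 36 configurations, per-subject Top-k rank of the measured
#'   optimum, threshold-based exclusion pruning, and configuration-time
#'   savings of the predict-then-verify workflow.
#' @name evaluation
NULL

#' Normalize behavioral records to per-subject-configuration accuracies
#'
#' Accepts aggregate records (`subject_id`, `config_label` or `config`,
#' `n_trials`, `n_correct`) or trial-level records (`subject_id`, `config`,
#' `trial_index`, `pattern_true`, `pattern_reported`).
#'
#' @param records data.frame of behavioral records
#' @return data.frame with `subject_id`, `config_label`, `n_trials`,
#'   `n_correct`, `accuracy`
#' @export
normalize_behavior <- function(records) {
  nm <- names(records)
  if ("config" %in% nm && !"config_label" %in% nm)
    names(records)[nm == "config"] <- "config_label"
  if (all(c("pattern_true", "pattern_reported") %in% names(records))) {
    agg <- stats::aggregate(
      correct ~ subject_id + config_label,
      data = transform(records,
                       correct = records$pattern_true ==
                                 records$pattern_reported),
      FUN = function(x) c(n = length(x), k = sum(x)))
    out <- data.frame(subject_id = agg$subject_id,
                      config_label = agg$config_label,
                      n_trials = agg$correct[, "n"],
                      n_correct = agg$correct[, "k"],
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("subject_id", "config_label", "n_trials",
                    "n_correct") %in% names(records)))
    out <- records[, c("subject_id", "config_label", "n_trials",
                       "n_correct")]
  }
  if (any(out$n_correct < 0 | out$n_correct > out$n_trials))
    stop("n_correct must lie in [0, n_trials]")
  out$accuracy <- out$n_correct / out$n_trials
  out
}

#' Pearson trend-consistency coefficient
#'
#' Standard product-moment correlation between predicted PCS and measured
#' mean accuracy across configurations.
#'
#' @param pcs_pred per-configuration predicted PCS (length >= 3)
#' @param acc per-configuration mean accuracies, same length
#' @return correlation coefficient in \[-1, 1\]
#' @export
pearson_r <- function(pcs_pred, acc) {
  if (length(pcs_pred) != length(acc) || length(acc) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::sd(pcs_pred) == 0 || stats::sd(acc) == 0)
    stop("Pearson r undefined: zero variance")
  stats::cor(pcs_pred, acc)
}

#' Pearson r with its t-transform p-value
#'
#' @inheritParams pearson_r
#' @return list with `r` and `p` (reported, never used as a gate)
#' @export
pearson_test <- function(pcs_pred, acc) {
  r <- pearson_r(pcs_pred, acc)
  ct <- stats::cor.test(pcs_pred, acc)
  list(r = r, p = ct$p.value)
}

#' Rank of the measured-best configuration in a prediction
#'
#' @param recommendation a `ranked_recommendation`
#' @param measured_best configuration label of the experimental optimum
#' @return 1-based position in the predicted ranking
#' @export
topk_rank <- function(recommendation, measured_best) {
  stopifnot(inherits(recommendation, "ranked_recommendation"))
  pos <- match(measured_best, recommendation$ranking$config_label)
  if (is.na(pos)) stop("unknown configuration label: ", measured_best)
  pos
}

#' Threshold-based exclusion pruning
#'
#' Excludes configurations whose group mean accuracy falls below
#' `mean_thresh` AND whose maximum per-subject accuracy falls below
#' `max_thresh` (both conditions must hold).
#'
#' @param records behavioral records (any form accepted by
#'   [normalize_behavior()])
#' @param mean_thresh group-mean accuracy threshold (default 0.615)
#' @param max_thresh maximum per-subject accuracy threshold (default 0.80)
#' @return character vector of excluded configuration labels
#' @export
exclusion_filter <- function(records, mean_thresh = 0.615,
                             max_thresh = 0.80) {
  b <- normalize_behavior(records)
  agg <- stats::aggregate(accuracy ~ config_label, data = b,
                          FUN = function(x) c(mean = mean(x), max = max(x)))
  excl <- agg$config_label[agg$accuracy[, "mean"] < mean_thresh &
                           agg$accuracy[, "max"] < max_thresh]
  as.character(excl)
}

# round half-up to one decimal (presentation convention)
.round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Configuration-time saving percentage
#'
#' 100 x (1 - t_recommended / t_exhaustive), rounded half-up to one decimal
#' for reporting.
#'
#' @param t_exhaustive_min exhaustive-calibration duration in minutes
#' @param t_recommended_min predict-then-verify duration in minutes
#' @return percentage saving (one decimal)
#' @export
time_saving_pct <- function(t_exhaustive_min, t_recommended_min) {
  if (t_exhaustive_min <= 0 || t_recommended_min <= 0)
    stop("durations must be positive")
  .round1_half_up(100 * (1 - t_recommended_min / t_exhaustive_min))
}

#' Evaluate recommendations against behavioral records
#'
#' @param recommendations named list of `ranked_recommendation` (one per
#'   subject), or a single one
#' @param records behavioral records covering the same subjects
#' @return an `evaluation_report` list: `pearson` (r and p between mean
#'   predicted PCS and mean accuracy per configuration), `subject_ranks`
#'   (per-subject rank of the measured optimum), `top1_rate`, `top5_rate`,
#'   `excluded_configs`, `mean_accuracy`
#' @export
evaluate_recommendations <- function(recommendations, records) {
  if (inherits(recommendations, "ranked_recommendation"))
    recommendations <- list(recommendations)
  b <- normalize_behavior(records)
  labels <- config_table()$label

  # per-configuration mean accuracy across subjects (unweighted)
  acc_cfg <- stats::aggregate(accuracy ~ config_label, data = b, FUN = mean)
  acc <- acc_cfg$accuracy[match(labels, acc_cfg$config_label)]
  if (anyNA(acc)) stop("behavioral records missing some configurations")

  # per-configuration mean predicted PCS across subjects
  pcs_mat <- vapply(recommendations, function(r) {
    r$ranking$pcs_pred[match(labels, r$ranking$config_label)]
  }, numeric(length(labels)))
  pcs_mean <- rowMeans(as.matrix(pcs_mat))

  pe <- pearson_test(pcs_mean, acc)

  subject_ranks <- vapply(recommendations, function(r) {
    bs <- b[b$subject_id == r$subject_id, ]
    if (!nrow(bs)) return(NA_integer_)
    best <- bs$config_label[order(-bs$accuracy,
                                  match(bs$config_label, labels))][1]
    as.integer(topk_rank(r, best))
  }, integer(1))
  names(subject_ranks) <- vapply(recommendations,
                                 function(r) r$subject_id, character(1))
  known <- !is.na(subject_ranks)
  structure(list(
    pearson = pe,
    subject_ranks = subject_ranks,
    top1_rate = mean(subject_ranks[known] <= 1),
    top5_rate = mean(subject_ranks[known] <= 5),
    excluded_configs = exclusion_filter(b),
    mean_accuracy = mean(acc)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation: r = %.3f (p = %.3g), Top-1 %.1f%%, Top-5 %.1f%%, mean acc %.2f%%, %d excluded>\n",
    x$pearson$r, x$pearson$p, 100 * x$top1_rate, 100 * x$top5_rate,
    100 * x$mean_accuracy, length(x$excluded_configs)))
  invisible(x)
}
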