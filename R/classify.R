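#' Flat exemplar-model baseline for extrapolation
#'
#' A simple exemplar model never extrapolates: outside the training range
#' it predicts the output of the nearest training boundary, giving a flat
#' line on each side.  Its MAE over the scheduled extrapolation inputs is
#' the classification baseline (34.72 for both study variants under the
#' reconstructed slope of 2.17).
#'
#' @param schedule A [build_schedule()] object.
#' @param spec The matching [function_spec()].
#' @return List with `prediction_left`, `prediction_right` (the flat
#'   predictions below/above the training range) and `baseline_mae`.
#' @examples
#' exemplar_baseline(build_schedule("study1a"), study_function("study1a"))
#' @export
exemplar_baseline <- function(schedule, spec) {
  ex <- schedule$extrapolation_inputs
  if (length(ex) == 0L) stop("exemplar_baseline: empty extrapolation set")
  if (any(ex >= schedule$training_min & ex <= schedule$training_max))
    stop("extrapolation inputs must lie outside the training range")
  flat_left <- evaluate_function(spec, schedule$training_min)
  flat_right <- evaluate_function(spec, schedule$training_max)
  flat <- ifelse(ex < schedule$training_min, flat_left, flat_right)
  list(prediction_left = flat_left,
       prediction_right = flat_right,
       baseline_mae = mean(abs(evaluate_function(spec, ex) - flat)))
}

#' Extrapolation MAE and its confidence interval
#'
#' @param abs_errors Per-trial absolute extrapolation errors (>= 2 values).
#' @param level Confidence level (default 0.95).
#' @param method `"t"` (default): mean +/- t(n-1) quantile * SE; `"z"`:
#'   normal quantile.  The lower bound is truncated at 0.
#' @return List with `mae`, `ci_lower`, `ci_upper`, `n`.
#' @export
extrapolation_mae_ci <- function(abs_errors, level = 0.95,
                                 method = c("t", "z")) {
  method <- match.arg(method)
  n <- length(abs_errors)
  if (n < 2L) stop("extrapolation_mae_ci: need at least 2 errors")
  if (any(!is.finite(abs_errors)) || any(abs_errors < 0))
    stop("extrapolation_mae_ci: errors must be finite and >= 0")
  m <- mean(abs_errors)
  se <- stats::sd(abs_errors) / sqrt(n)
  q <- if (method == "t") stats::qt(1 - (1 - level) / 2, n - 1)
  else stats::qnorm(1 - (1 - level) / 2)
  list(mae = m, ci_lower = max(0, m - q * se), ci_upper = m + q * se, n = n)
}

#' Two-step learner classification
#'
#' Step 1: a participant whose final completed training block has MAE at or
#' above the learning criterion (10) is a *non-learner*.  Step 2: for the
#' remaining learners, the MAE over the 30 extrapolation trials and its 95%
#' confidence interval are compared with the flat exemplar-model baseline;
#' the learner is an *abstraction* learner iff the CI upper bound falls
#' strictly below the baseline MAE, otherwise an *exemplar* learner (a CI
#' upper bound exactly at the baseline therefore classifies as exemplar).
#' Interpolation trials never enter the classification.  Sessions missing
#' transfer trials are *incomplete*.
#'
#' @param session A `cb_session`.
#' @param schedule,spec The session's schedule and function spec.
#' @param level,method CI options, see [extrapolation_mae_ci()].
#' @return An object of class `cb_classification`: `participant_id`,
#'   `category`, `final_training_mae`, `extrapolation_mae`, `ci_lower`,
#'   `ci_upper`, `baseline_mae`, `baseline_prediction_left`,
#'   `baseline_prediction_right`.
#' @export
classify_session <- function(session, schedule, spec,
                             level = 0.95, method = "t") {
  stopifnot(inherits(session, "cb_session"))
  bl <- exemplar_baseline(schedule, spec)
  out <- list(participant_id = session$participant_id,
              category = "incomplete",
              final_training_mae = NA_real_,
              extrapolation_mae = NA_real_,
              ci_lower = NA_real_, ci_upper = NA_real_,
              baseline_mae = bl$baseline_mae,
              baseline_prediction_left = bl$prediction_left,
              baseline_prediction_right = bl$prediction_right)
  ex_idx <- session$block == 0L &
    session$input %in% schedule$extrapolation_inputs
  complete <- !session$aborted &&
    session$n_training_blocks >= 1L &&
    sum(ex_idx) == length(schedule$extrapolation_inputs)
  if (session$n_training_blocks >= 1L)
    out$final_training_mae <- session$block_maes[session$n_training_blocks]
  if (!complete) return(structure(out, class = "cb_classification"))
  ci <- extrapolation_mae_ci(session$abs_error[ex_idx], level, method)
  out$extrapolation_mae <- ci$mae
  out$ci_lower <- ci$ci_lower
  out$ci_upper <- ci$ci_upper
  out$category <-
    if (out$final_training_mae >= schedule$learning_criterion) "nonlearner"
    else if (ci$ci_upper < bl$baseline_mae) "abstraction"
    else "exemplar"
  structure(out, class = "cb_classification")
}

#' @export
print.cb_classification <- function(x, ...) {
  cat(sprintf(
    "%s: %s (final training MAE %.2f; extrapolation MAE %.2f, 95%% CI [%.2f, %.2f]; baseline %.2f)\n",
    x$participant_id, x$category, x$final_training_mae,
    x$extrapolation_mae, x$ci_lower, x$ci_upper, x$baseline_mae))
  invisible(x)
}

#' Classify every session of a cohort
#'
#' @param sessions A `cb_cohort` or a list of `cb_session` objects.
#' @param schedule,spec Task schedule and function spec (taken from the
#'   cohort when one is passed).
#' @param level,method CI options.
#' @return Data frame with one row per participant, columns as in
#'   [classify_session()].
#' @export
classify_cohort <- function(sessions, schedule = NULL, spec = NULL,
                            level = 0.95, method = "t") {
  if (inherits(sessions, "cb_cohort")) {
    if (is.null(schedule)) schedule <- sessions$schedule
    if (is.null(spec)) spec <- sessions$fun
    sessions <- sessions$sessions
  }
  rows <- lapply(sessions, function(s)
    unclass(classify_session(s, schedule, spec, level, method)))
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
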