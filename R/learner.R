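#' Parameterise a synthetic learner
#'
#' Three behavioural phenotypes are emulated.  *Abstraction* learners
#' converge on the bilinear rule: their prediction for input `x` is the true
#' output plus Gaussian noise whose amplitude starts at `init_sd` and decays
#' geometrically across blocks at rate `learning_rate`, bottoming out at
#' `noise_sd`; at transfer they apply the learned rule to any input.
#' *Exemplar* learners behave identically inside the training range but do
#' not extrapolate: outside the range they predict the output of the nearest
#' training boundary (plus residual noise), producing flat extrapolation
#' curves.  *Non-learners* emit predictions whose absolute error on every
#' trial is at least `nonlearner_floor`, so their block MAE never drops
#' below the learning criterion.
#'
#' @param type `"abstraction"`, `"exemplar"` or `"nonlearner"`.
#' @param learning_rate Per-block fractional decay of the error amplitude,
#'   in (0, 1].  The default 0.5 halves the amplitude each block.
#' @param noise_sd Residual prediction noise SD (output units) after
#'   learning has converged.
#' @param init_sd Initial error amplitude (output units) in block 1.
#' @param nonlearner_floor Minimum per-trial absolute error for
#'   non-learners; must be at least the learning criterion (10).
#' @param nonlearner_spread SD of the additional half-normal error
#'   magnitude on top of the floor.
#' @param participant_id Optional identifier carried into the session log.
#' @return An object of class `cb_learner`.
#' @export
learner_params <- function(type = c("abstraction", "exemplar", "nonlearner"),
                           learning_rate = 0.5, noise_sd = 3, init_sd = 30,
                           nonlearner_floor = 10, nonlearner_spread = 15,
                           participant_id = NA_character_) {
  type <- match.arg(type)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            noise_sd >= 0, init_sd >= 0, nonlearner_spread >= 0)
  if (type == "nonlearner" && nonlearner_floor < 10)
    stop("nonlearner_floor must be >= the learning criterion (10)")
  structure(
    list(type = type, learning_rate = learning_rate, noise_sd = noise_sd,
         init_sd = init_sd, nonlearner_floor = nonlearner_floor,
         nonlearner_spread = nonlearner_spread,
         participant_id = participant_id),
    class = "cb_learner")
}

#' Generate predictions for a synthetic learner
#'
#' @param learner A `cb_learner`.
#' @param spec,schedule The task's [function_spec()] and [build_schedule()].
#' @param x Integer input(s) queried.
#' @param block 1-based training block, or 0 at transfer.
#' @param phase `"training"` or `"transfer"`.
#' @return Numeric prediction vector, same length as `x`.  Uses the current
#'   RNG stream; seed the session (or cohort) for reproducibility.
#' @examples
#' sch <- build_schedule("study1a"); f <- study_function("study1a")
#' ex <- learner_params("exemplar", noise_sd = 0)
#' predict_learner(ex, f, sch, 31, 0, "transfer")  # 148: flat at the boundary
#' @export
predict_learner <- function(learner, spec, schedule, x, block,
                            phase = c("training", "transfer")) {
  phase <- match.arg(phase)
  stopifnot(inherits(learner, "cb_learner"))
  n <- length(x)
  if (learner$type == "nonlearner") {
    magnitude <- learner$nonlearner_floor +
      abs(stats::rnorm(n, 0, learner$nonlearner_spread))
    return(evaluate_function(spec, x) +
             sample(c(-1, 1), n, replace = TRUE) * magnitude)
  }
  sd_now <- if (phase == "training")
    learner$noise_sd +
      learner$init_sd * (1 - learner$learning_rate)^(block - 1)
  else learner$noise_sd
  base <- if (learner$type == "abstraction")
    evaluate_function(spec, x)
  else # exemplar: nearest-boundary recall outside the training range
    evaluate_function(spec, pmin(pmax(x, schedule$training_min),
                                 schedule$training_max))
  if (sd_now > 0) base + stats::rnorm(n, 0, sd_now) else base
}
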