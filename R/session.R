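#' Mean absolute error of one training block
#'
#' @param abs_errors Non-empty numeric vector of per-trial absolute errors.
#' @return The arithmetic mean of the absolute errors.
#' @export
block_mae <- function(abs_errors) {
  if (length(abs_errors) == 0L) stop("block_mae: empty block")
  if (any(!is.finite(abs_errors)) || any(abs_errors < 0))
    stop("block_mae: absolute errors must be finite and >= 0")
  mean(abs_errors)
}

#' Between-block accuracy feedback
#'
#' From block 2 onward the task tells the participant whether their block
#' MAE improved.  Improvement means a strict reduction.
#'
#' @param prev_mae,cur_mae Block MAEs of the previous and current block.
#' @param message Return the verbatim on-screen message instead of the code?
#' @return `"improved"` or `"not_improved"` (or the on-screen string).
#' @export
feedback_message <- function(prev_mae, cur_mae, message = FALSE) {
  stopifnot(prev_mae >= 0, cur_mae >= 0)
  improved <- cur_mae < prev_mae
  if (!message) return(if (improved) "improved" else "not_improved")
  if (improved) "Your accuracy IMPROVED. Keep up the good work!"
  else "Your accuracy DID NOT IMPROVE. Keep working to improve your predictions!"
}

#' Run one simulated session of the concept-building task
#'
#' Presents each training input once per block in a freshly randomised
#' order, records the learner's prediction, the correct output and the
#' absolute error, and applies the variant's termination rule: variant
#' `"study1b"` always stops after the 10 base blocks; variant `"study1a"`
#' stops after block 10, 11 or 12 when that block's MAE drops below the
#' learning criterion, and unconditionally after block 13.  The transfer
#' phase then presents the 36 extrapolation + interpolation inputs once
#' each, intermixed in random order and without feedback; transfer trials
#' are logged with block 0.
#'
#' @param learner A `cb_learner` from [learner_params()], or a function
#'   `f(x, block, phase)` returning a prediction vector (used for scripted
#'   or adversarial learners in tests).
#' @param variant `"study1a"` or `"study1b"`.
#' @param seed Optional integer; when given, seeds the RNG so the session
#'   is exactly reproducible.
#' @param schedule,spec Optional prebuilt [build_schedule()] /
#'   [study_function()] objects (passing them avoids rebuilding per call in
#'   large simulations).
#' @return An object of class `cb_session`: a columnar trial log (`input`,
#'   `prediction`, `correct`, `abs_error`, `block`) plus `block_maes`,
#'   `n_training_blocks`, `feedback` (per-block improvement codes from
#'   block 2 on) and an `aborted` flag set when the learner returned a
#'   non-finite prediction.
#' @examples
#' s <- run_session(learner_params("abstraction", noise_sd = 0), "study1b", seed = 1)
#' s$n_training_blocks   # 10
#' tail(s$block_maes, 1) # 0
#' @export
run_session <- function(learner, variant = c("study1a", "study1b"),
                        seed = NULL, schedule = NULL, spec = NULL) {
  variant <- match.arg(variant)
  if (is.null(schedule)) schedule <- build_schedule(variant)
  if (is.null(spec)) spec <- study_function(variant)
  if (!is.null(seed)) set.seed(seed)

  tr <- schedule$training_inputs
  k <- length(tr)
  max_blocks <- schedule$n_base_blocks + schedule$max_extension_blocks
  n_transfer <- length(schedule$extrapolation_inputs) +
    length(schedule$interpolation_inputs)
  n_max <- k * max_blocks + n_transfer

  input <- numeric(n_max); pred <- numeric(n_max)
  correct <- numeric(n_max); blockv <- integer(n_max)
  block_maes <- numeric(max_blocks)
  pos <- 0L
  aborted <- FALSE
  nb <- 0L

  predict_fn <- if (is.function(learner)) learner else
    function(x, block, phase)
      predict_learner(learner, spec, schedule, x, block, phase)

  for (b in seq_len(max_blocks)) {
    ord <- tr[sample.int(k)]
    cb <- evaluate_function(spec, ord)
    pb <- predict_fn(ord, b, "training")
    if (length(pb) != k || any(!is.finite(pb))) { aborted <- TRUE; break }
    idx <- pos + seq_len(k)
    input[idx] <- ord; pred[idx] <- pb; correct[idx] <- cb
    blockv[idx] <- b
    block_maes[b] <- mean(abs(pb - cb))
    pos <- pos + k
    nb <- b
    if (b >= schedule$n_base_blocks &&
        (block_maes[b] < schedule$learning_criterion || b >= max_blocks))
      break
  }

  if (!aborted) {
    tin <- c(schedule$extrapolation_inputs, schedule$interpolation_inputs)
    ord <- tin[sample.int(n_transfer)]
    ct <- evaluate_function(spec, ord)
    pt <- predict_fn(ord, 0L, "transfer")
    if (length(pt) != n_transfer || any(!is.finite(pt))) {
      aborted <- TRUE
    } else {
      idx <- pos + seq_len(n_transfer)
      input[idx] <- ord; pred[idx] <- pt; correct[idx] <- ct
      blockv[idx] <- 0L
      pos <- pos + n_transfer
    }
  }

  keep <- seq_len(pos)
  bm <- block_maes[seq_len(nb)]
  fb <- if (nb >= 2L)
    ifelse(diff(bm) < 0, "improved", "not_improved")
  else character(0)
  structure(
    list(participant_id =
           if (is.function(learner)) NA_character_
           else learner$participant_id,
         variant = variant,
         input = input[keep], prediction = pred[keep],
         correct = correct[keep],
         abs_error = abs(pred[keep] - correct[keep]),
         block = blockv[keep],
         block_maes = bm,
         n_training_blocks = nb,
         feedback = fb,
         aborted = aborted),
    class = "cb_session")
}

#' @export
print.cb_session <- function(x, ...) {
  cat(sprintf("Concept-building session%s (%s): %d training blocks, %d trials%s\n",
              if (is.na(x$participant_id)) "" else paste0(" ", x$participant_id),
              x$variant, x$n_training_blocks, length(x$input),
              if (x$aborted) " [ABORTED]" else ""))
  if (x$n_training_blocks > 0L)
    cat("  block MAEs:", paste(sprintf("%.2f", x$block_maes), collapse = " "), "\n")
  invisible(x)
}

#' Flatten a session to the trial-level CSV layout
#'
#' @param x A `cb_session`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A data frame with columns `participant_id`, `study_variant`,
#'   `phase`, `block`, `trial_index`, `input_value`, `prediction`,
#'   `correct_output`, `abs_error`.  Transfer rows carry block 0.
#' @export
as.data.frame.cb_session <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(participant_id = x$participant_id,
             study_variant = x$variant,
             phase = ifelse(x$block == 0L, "transfer", "training"),
             block = x$block,
             trial_index = seq_along(x$input),
             input_value = x$input,
             prediction = x$prediction,
             correct_output = x$correct,
             abs_error = x$abs_error,
             stringsAsFactors = FALSE)
}
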