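#' Write / read trial-level task data as CSV
#'
#' The on-disk layout has one row per trial with columns `participant_id`,
#' `study_variant`, `phase`, `block`, `trial_index`, `input_value`,
#' `prediction`, `correct_output`, `abs_error`; transfer rows carry
#' block 0.
#'
#' @param sessions A `cb_cohort`, a list of `cb_session` objects, or one
#'   `cb_session`.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a list of `cb_session` objects rebuilt from the rows.
#' @export
write_trials <- function(sessions, path) {
  if (inherits(sessions, "cb_cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "cb_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "study_variant", "block", "input_value",
            "prediction", "correct_output")
  if (!all(need %in% names(df)))
    stop("read_trials: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, factor(df$participant_id,
                          levels = unique(df$participant_id))),
         function(d) {
           training <- d$block > 0L
           nb <- if (any(training)) max(d$block[training]) else 0L
           abs_err <- abs(d$prediction - d$correct_output)
           bm <- if (nb > 0L)
             vapply(seq_len(nb),
                    function(b) mean(abs_err[d$block == b]), 0)
           else numeric(0)
           structure(
             list(participant_id = d$participant_id[1L],
                  variant = d$study_variant[1L],
                  input = d$input_value, prediction = d$prediction,
                  correct = d$correct_output, abs_error = abs_err,
                  block = as.integer(d$block), block_maes = bm,
                  n_training_blocks = as.integer(nb),
                  feedback = if (nb >= 2L)
                    ifelse(diff(bm) < 0, "improved", "not_improved")
                  else character(0),
                  aborted = FALSE),
             class = "cb_session")
         })
}

#' Write / read item-level survey responses as CSV
#'
#' Columns: `participant_id`, `instrument`, `item_id`, `rating`.
#'
#' @param surveys Long response data frame (e.g. `cohort$surveys`).
#' @param path CSV file path.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
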