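test_that("bilinear rule reproduces boundary, vertex and mirrored outputs", {
  f1a <- study_function("study1a")
  expect_equal(evaluate_function(f1a, 61), 148)
  expect_equal(evaluate_function(f1a, 99), 148)  # symmetry about the vertex
  expect_equal(evaluate_function(f1a, 80), 148 + 2.17 * 19) # 189.23
  f1b <- study_function("study1b")
  expect_equal(evaluate_function(f1b, 81), 52)
  expect_equal(evaluate_function(f1b, 119), 52)
  # 30 input units below the lower training boundary (81):
  expect_equal(evaluate_function(f1b, 51), 52 + 2.17 * 30) # 117.10
  # mirrored pairs around each vertex agree
  expect_equal(evaluate_function(f1a, 80 + 0:19), evaluate_function(f1a, 80 - 0:19))
  expect_equal(evaluate_function(f1b, 100 + 0:19), evaluate_function(f1b, 100 - 0:19))
})

test_that("bilinear rule matches a piecewise-linear interpolation oracle", {
  for (variant in c("study1a", "study1b")) {
    sp <- study_function(variant)
    knots_x <- c(31, sp$training_min, sp$vertex_input, sp$training_max, 149)
    knots_y <- c(NA, sp$edge_output, sp$vertex_output, sp$edge_output, NA)
    # extend the arms linearly beyond the training range
    slope_sign <- if (sp$orientation == "peak") 1 else -1
    knots_y[1] <- sp$edge_output - slope_sign * sp$slope_magnitude * (sp$training_min - 31)
    knots_y[5] <- sp$edge_output - slope_sign * sp$slope_magnitude * (149 - sp$training_max)
    oracle <- stats::approxfun(knots_x, knots_y)
    xs <- 31:149
    expect_equal(evaluate_function(sp, xs), oracle(xs), tolerance = 1e-9)
  }
})

test_that("invalid function specs are rejected", {
  expect_error(function_spec("peak", 75, 148, 2.17, 61, 99), "midpoint")
  expect_error(function_spec("peak", 80, 148, 0, 61, 99), "slope")
  expect_error(function_spec("peak", 80, 148, -1, 61, 99), "slope")
})

test_that("study schedules carry the administered input sets", {
  s1a <- build_schedule("study1a")
  expect_identical(s1a$training_inputs, seq(61, 99, 2))
  expect_length(s1a$training_inputs, 20)
  expect_length(s1a$extrapolation_inputs, 30)
  expect_length(s1a$interpolation_inputs, 6)
  expect_identical(s1a$extrapolation_inputs, c(seq(31, 59, 2), seq(101, 129, 2)))
  # interpolation set kept exactly as administered, including 100 which
  # sits just above the stated training range
  expect_identical(s1a$interpolation_inputs, c(64, 72, 80, 88, 94, 100))
  expect_true(100 %in% s1a$interpolation_inputs)
  expect_identical(s1a$max_extension_blocks, 3L)
  expect_identical(s1a$n_base_blocks, 10L)
  expect_identical(s1a$learning_criterion, 10)

  s1b <- build_schedule("study1b")
  expect_identical(s1b$training_inputs, seq(81, 119, 2))
  expect_identical(s1b$interpolation_inputs, c(84, 92, 100, 108, 114, 120))
  expect_identical(s1b$max_extension_blocks, 0L)

  for (s in list(s1a, s1b)) {
    ex <- s$extrapolation_inputs
    expect_true(all(ex < s$training_min | ex > s$training_max))
    transfer <- c(ex, s$interpolation_inputs)
    expect_length(transfer, 36)
    expect_identical(anyDuplicated(transfer), 0L)
    expect_length(intersect(transfer, s$training_inputs), 0)
    # nearest-boundary distances on each side are {2, 4, ..., 30}
    left <- s$training_min - ex[ex < s$training_min]
    right <- ex[ex > s$training_max] - s$training_max
    expect_identical(sort(left), seq(2, 30, 2))
    expect_identical(sort(right), seq(2, 30, 2))
  }
  expect_error(build_schedule("study2x"))
})

test_that("block MAE is the mean absolute error of the block", {
  expect_equal(block_mae(rep(0, 20)), 0)
  expect_equal(block_mae(rep(10, 20)), 10)
  expect_equal(block_mae(seq(2, 40, 2)), 21) # arithmetic-series mean
  expect_error(block_mae(numeric(0)), "empty")
  expect_error(block_mae(c(1, -2)), ">= 0")
})

test_that("between-block feedback requires a strict MAE reduction", {
  expect_identical(feedback_message(12.0, 9.5), "improved")
  expect_identical(feedback_message(9.5, 9.5), "not_improved")
  expect_identical(feedback_message(0.0, 0.1), "not_improved")
  expect_identical(feedback_message(12.0, 9.5, message = TRUE),
                   "Your accuracy IMPROVED. Keep up the good work!")
  expect_identical(feedback_message(9.5, 9.5, message = TRUE),
                   "Your accuracy DID NOT IMPROVE. Keep working to improve your predictions!")
})

test_that("sessions follow the block plan and termination rules", {
  # fully noiseless abstraction learner, study1b: exactly 10 blocks, final MAE 0
  s <- run_session(learner_params("abstraction", noise_sd = 0, init_sd = 0),
                   "study1b", seed = 11)
  expect_identical(s$n_training_blocks, 10L)
  expect_equal(s$block_maes[10], 0)
  expect_false(s$aborted)
  # with the default initial amplitude the residual decay term remains but
  # the criterion is still met at block 10
  s_def <- run_session(learner_params("abstraction", noise_sd = 0),
                       "study1b", seed = 11)
  expect_identical(s_def$n_training_blocks, 10L)
  expect_lt(s_def$block_maes[10], 10)

  # a learner that never meets the criterion runs all 13 study1a blocks
  far_off <- function(x, block, phase) rep(1000, length(x))
  s13 <- run_session(far_off, "study1a", seed = 12)
  expect_identical(s13$n_training_blocks, 13L)

  # criterion met first at block 11: training stops there
  sch <- build_schedule("study1a"); sp <- study_function("study1a")
  late <- function(x, block, phase)
    if (phase == "training" && block <= 10) evaluate_function(sp, x) + 50
    else evaluate_function(sp, x)
  s11 <- run_session(late, "study1a", seed = 13, schedule = sch, spec = sp)
  expect_identical(s11$n_training_blocks, 11L)
  expect_true(all(s11$block_maes[1:10] >= 10))
  expect_lt(s11$block_maes[11], 10)

  # fixed seed -> identical session
  l <- learner_params("exemplar", participant_id = "p9")
  expect_identical(run_session(l, "study1a", seed = 99),
                   run_session(l, "study1a", seed = 99))
})

test_that("every training block is a permutation of the training inputs and transfer is the 36 scheduled inputs", {
  for (variant in c("study1a", "study1b")) {
    sch <- build_schedule(variant)
    for (type in c("abstraction", "exemplar", "nonlearner")) {
      s <- run_session(learner_params(type), variant,
                       seed = 7 + match(type, c("abstraction", "exemplar", "nonlearner")))
      expect_true(s$n_training_blocks %in%
                    if (variant == "study1a") 10:13 else 10L)
      for (b in seq_len(s$n_training_blocks))
        expect_identical(sort(s$input[s$block == b]), sch$training_inputs)
      expect_identical(sort(s$input[s$block == 0]),
                       sort(c(sch$extrapolation_inputs, sch$interpolation_inputs)))
      # block MAEs recompute from the trial log
      expect_equal(s$block_maes,
                   vapply(seq_len(s$n_training_blocks),
                          function(b) mean(s$abs_error[s$block == b]), 0))
    }
  }
})

test_that("a learner returning non-finite predictions aborts the session with a flag", {
  bad <- function(x, block, phase) rep(NaN, length(x))
  s <- run_session(bad, "study1a", seed = 5)
  expect_true(s$aborted)
  expect_identical(s$n_training_blocks, 0L)
})

test_that("the trial log round-trips through the CSV layout", {
  l <- learner_params("abstraction", participant_id = "pA")
  s <- run_session(l, "study1a", seed = 21)
  df <- as.data.frame(s)
  expect_identical(names(df),
                   c("participant_id", "study_variant", "phase", "block",
                     "trial_index", "input_value", "prediction",
                     "correct_output", "abs_error"))
  expect_true(all(df$block[df$phase == "transfer"] == 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(list(s), path)
  back <- read_trials(path)[[1]]
  expect_equal(back$input, s$input)
  expect_equal(back$prediction, s$prediction)
  expect_equal(back$block_maes, s$block_maes)
  expect_identical(back$n_training_blocks, s$n_training_blocks)
})
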