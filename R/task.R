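#' Define the bilinear input-output rule of the concept-building task
#'
#' The task's hidden rule is a symmetric V ("valley") or inverted V ("peak")
#' over integer inputs: output changes linearly with distance from a vertex
#' placed at the midpoint of the training range, and the outputs at the two
#' training boundaries are equal.  The vertex output is derived from the
#' boundary (edge) output and the slope, so a spec is fully determined by
#' orientation, vertex position, edge output, slope magnitude and the
#' training range.
#'
#' @param orientation `"peak"` (inverted V) or `"valley"` (regular V).
#' @param vertex_input Integer input at which the V turns; must equal the
#'   midpoint of `training_min` and `training_max`.
#' @param edge_output Output value at both training boundaries.
#' @param slope_magnitude Absolute slope, output units per input unit; > 0.
#' @param training_min,training_max Integer bounds of the training range.
#' @return An object of class `cb_function`.
#' @examples
#' f1a <- study_function("study1a")
#' evaluate_function(f1a, c(61, 80, 99))
#' @export
function_spec <- function(orientation = c("peak", "valley"), vertex_input,
                          edge_output, slope_magnitude,
                          training_min, training_max) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(vertex_input), length(vertex_input) == 1L,
            is.numeric(edge_output), length(edge_output) == 1L,
            is.numeric(slope_magnitude), length(slope_magnitude) == 1L,
            training_min < training_max)
  if (slope_magnitude <= 0)
    stop("slope_magnitude must be > 0")
  if (vertex_input != (training_min + training_max) / 2)
    stop("vertex_input must sit at the midpoint of the training range")
  half <- vertex_input - training_min
  vertex_output <- if (orientation == "peak")
    edge_output + slope_magnitude * half
  else
    edge_output - slope_magnitude * half
  structure(
    list(orientation = orientation, vertex_input = vertex_input,
         edge_output = edge_output, slope_magnitude = slope_magnitude,
         training_min = training_min, training_max = training_max,
         vertex_output = vertex_output),
    class = "cb_function")
}

#' @export
print.cb_function <- function(x, ...) {
  cat(sprintf(
    "Bilinear %s function: vertex (%g, %g), slope %g, training range [%g, %g], edge output %g\n",
    if (x$orientation == "peak") "inverted-V" else "V",
    x$vertex_input, x$vertex_output, x$slope_magnitude,
    x$training_min, x$training_max, x$edge_output))
  invisible(x)
}

#' Evaluate the bilinear rule at integer inputs
#'
#' @param spec A `cb_function` from [function_spec()] or [study_function()].
#' @param x Numeric vector of input values.
#' @return Numeric vector of correct outputs.
#' @export
evaluate_function <- function(spec, x) {
  stopifnot(inherits(spec, "cb_function"))
  d <- abs(x - spec$vertex_input)
  if (spec$orientation == "peak")
    spec$vertex_output - spec$slope_magnitude * d
  else
    spec$vertex_output + spec$slope_magnitude * d
}

# Slope reconstructed as (flat exemplar-model baseline MAE) / (mean distance
# of the scheduled extrapolation inputs from the nearest training boundary):
# 34.72 / 16 = 2.17 output units per input unit, identical in both variants.
.cb_default_slope <- 34.72 / 16

#' Study-variant function specifications
#'
#' The two study variants use mirrored rules: an inverted V peaking at input
#' 80 with boundary outputs 148 (variant `"study1a"`, training inputs
#' 61-99), and a regular V with vertex at input 100 and boundary outputs 52
#' (variant `"study1b"`, training inputs 81-119).  The slope magnitude
#' (2.17) is reconstructed from the flat exemplar baseline MAE of 34.72 and
#' the extrapolation schedule; it can be overridden.
#'
#' @param variant `"study1a"` or `"study1b"`.
#' @param slope_magnitude Output units per input unit.
#' @return A `cb_function`.
#' @export
study_function <- function(variant = c("study1a", "study1b"),
                           slope_magnitude = .cb_default_slope) {
  variant <- match.arg(variant)
  if (variant == "study1a")
    function_spec("peak", vertex_input = 80, edge_output = 148,
                  slope_magnitude = slope_magnitude,
                  training_min = 61, training_max = 99)
  else
    function_spec("valley", vertex_input = 100, edge_output = 52,
                  slope_magnitude = slope_magnitude,
                  training_min = 81, training_max = 119)
}

#' Build the trial schedule for a study variant
#'
#' Each variant trains on 20 unique odd inputs presented once per block.
#' Both run 10 base training blocks; variant `"study1a"` extends training by
#' up to three further blocks until the block MAE drops below the learning
#' criterion (10 output units), variant `"study1b"` always stops after block
#' 10.  The transfer phase mixes 30 extrapolation inputs (odd numbers
#' outside the training range) with 6 interpolation inputs (even numbers,
#' kept exactly as administered in the original task, including the value
#' just above the training range).
#'
#' @param variant `"study1a"` or `"study1b"`.
#' @return An object of class `cb_schedule` with fields `training_inputs`,
#'   `extrapolation_inputs`, `interpolation_inputs`, `n_base_blocks`,
#'   `max_extension_blocks`, `learning_criterion`, `training_min`,
#'   `training_max` and `variant`.
#' @examples
#' sch <- build_schedule("study1a")
#' length(sch$training_inputs)       # 20
#' length(sch$extrapolation_inputs)  # 30
#' @export
build_schedule <- function(variant = c("study1a", "study1b")) {
  variant <- match.arg(variant)
  if (variant == "study1a") {
    training <- seq(61, 99, by = 2)
    extrapolation <- c(seq(31, 59, by = 2), seq(101, 129, by = 2))
    interpolation <- c(64, 72, 80, 88, 94, 100)
    max_ext <- 3L
  } else {
    training <- seq(81, 119, by = 2)
    extrapolation <- c(seq(51, 79, by = 2), seq(121, 149, by = 2))
    interpolation <- c(84, 92, 100, 108, 114, 120)
    max_ext <- 0L
  }
  structure(
    list(variant = variant,
         training_inputs = training,
         extrapolation_inputs = extrapolation,
         interpolation_inputs = interpolation,
         n_base_blocks = 10L,
         max_extension_blocks = max_ext,
         learning_criterion = 10,
         training_min = min(training),
         training_max = max(training)),
    class = "cb_schedule")
}

#' @export
print.cb_schedule <- function(x, ...) {
  cat(sprintf("Concept-building schedule (%s):\n", x$variant))
  cat(sprintf("  %d training inputs [%g..%g], %d base blocks + up to %d extensions, criterion MAE < %g\n",
              length(x$training_inputs), x$training_min, x$training_max,
              x$n_base_blocks, x$max_extension_blocks, x$learning_criterion))
  cat(sprintf("  transfer: %d extrapolation + %d interpolation trials\n",
              length(x$extrapolation_inputs), length(x$interpolation_inputs)))
  invisible(x)
}
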