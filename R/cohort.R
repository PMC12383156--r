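#' Specify a synthetic cohort
#'
#' A cohort couples simulated task behaviour with simulated survey
#' responses.  Learner types are drawn from `mixture`; each participant's
#' latent deep and surface propensities are standard bivariate normal with
#' correlation `latent_corr`, and exemplar-type participants' latent means
#' are shifted by `coupling_deep` / `coupling_surface` (standardised
#' units).  The default zero couplings encode the null hypothesis of no
#' relationship between concept-building tendency and self-reported
#' approach; negative `coupling_deep` with positive `coupling_surface`
#' emulates the alternative (exemplar learners endorsing fewer deep and
#' more surface items).  Item ratings are the latent plus item noise,
#' anchored at the scale midpoint, rounded and clamped to 1..5.
#'
#' The default mixture (0.40 abstraction, 0.36 exemplar, 0.24 non-learner)
#' approximates the pooled classification proportions observed with this
#' task.
#'
#' @param n Number of participants (>= 1).
#' @param variant Task variant, `"study1a"` or `"study1b"`.
#' @param mixture Length-3 probabilities (abstraction, exemplar,
#'   nonlearner); must sum to 1.
#' @param coupling_deep,coupling_surface Latent mean shifts applied to
#'   exemplar-type participants.
#' @param latent_corr Correlation between deep and surface latents.
#' @param item_noise_sd SD of per-item rating noise.
#' @param instruments Character vector of instruments to administer
#'   (`"massist"`, `"rspq2f"`, or both).
#' @param learner_defaults Named list overriding [learner_params()]
#'   defaults (e.g. `list(noise_sd = 0)`).
#' @param rng_seed Integer seed; every random draw in
#'   [generate_cohort()] descends from it.
#' @return An object of class `cb_cohort_spec`.
#' @export
cohort_spec <- function(n, variant = c("study1a", "study1b"),
                        mixture = c(abstraction = 0.40, exemplar = 0.36,
                                    nonlearner = 0.24),
                        coupling_deep = 0, coupling_surface = 0,
                        latent_corr = 0, item_noise_sd = 1,
                        instruments = "massist",
                        learner_defaults = list(),
                        rng_seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(n) == 1L, is.finite(n), n >= 1)
  if (length(mixture) != 3L || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop("mixture must be 3 non-negative proportions summing to 1")
  if (abs(latent_corr) > 1) stop("|latent_corr| must be <= 1")
  stopifnot(item_noise_sd >= 0,
            all(instruments %in% c("massist", "rspq2f")))
  structure(
    list(n = as.integer(n), variant = variant,
         mixture = stats::setNames(as.numeric(mixture),
                                   c("abstraction", "exemplar", "nonlearner")),
         coupling_deep = coupling_deep,
         coupling_surface = coupling_surface,
         latent_corr = latent_corr, item_noise_sd = item_noise_sd,
         instruments = instruments,
         learner_defaults = learner_defaults,
         rng_seed = as.integer(rng_seed)),
    class = "cb_cohort_spec")
}

#' Simulate a full cohort: sessions, surveys and ground truth
#'
#' Draws learner types, runs one task session per participant via
#' [run_session()], then generates item-level Likert responses for the
#' requested instruments from latent deep/surface propensities.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cb_cohort`: `sessions` (list of
#'   `cb_session`), `surveys` (long data frame: `participant_id`,
#'   `instrument`, `item_id`, `rating`), `truth` (data frame of
#'   ground-truth labels), plus `spec`, `schedule` and `fun` (the task
#'   function spec).  Byte-identical across runs with the same spec.
#' @examples
#' coh <- generate_cohort(cohort_spec(20, "study1b", rng_seed = 42))
#' table(coh$truth$learner_type)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cb_cohort_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n
  schedule <- build_schedule(spec$variant)
  fun <- study_function(spec$variant)

  types <- sample(c("abstraction", "exemplar", "nonlearner"), n,
                  replace = TRUE, prob = spec$mixture)
  ids <- sprintf("P%05d", seq_len(n))

  learners <- lapply(c("abstraction", "exemplar", "nonlearner"), function(ty)
    do.call(learner_params, c(list(type = ty), spec$learner_defaults)))
  names(learners) <- c("abstraction", "exemplar", "nonlearner")

  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    lp <- learners[[types[i]]]
    lp$participant_id <- ids[i]
    sessions[[i]] <- run_session(lp, spec$variant,
                                 schedule = schedule, spec = fun)
  }

  # latent propensities: standard bivariate normal + exemplar coupling shift
  z_deep <- stats::rnorm(n)
  z_surf <- spec$latent_corr * z_deep +
    sqrt(1 - spec$latent_corr^2) * stats::rnorm(n)
  is_ex <- types == "exemplar"
  lat_deep <- z_deep + ifelse(is_ex, spec$coupling_deep, 0)
  lat_surf <- z_surf + ifelse(is_ex, spec$coupling_surface, 0)

  surveys <- do.call(rbind, lapply(spec$instruments, function(instr) {
    key <- scale_key(instr)
    items <- c(key$deep_items, key$surface_items)
    lat <- c(rep(list(lat_deep), length(key$deep_items)),
             rep(list(lat_surf), length(key$surface_items)))
    ratings <- vapply(seq_along(items), function(j) {
      raw <- 3 + lat[[j]] + stats::rnorm(n, 0, spec$item_noise_sd)
      pmin(5, pmax(1, round(raw)))
    }, numeric(n))
    data.frame(participant_id = rep(ids, times = length(items)),
               instrument = instr,
               item_id = rep(items, each = n),
               rating = as.integer(ratings),
               stringsAsFactors = FALSE)
  }))
  rownames(surveys) <- NULL

  structure(
    list(sessions = sessions,
         surveys = surveys,
         truth = data.frame(participant_id = ids, learner_type = types,
                            latent_deep = lat_deep, latent_surface = lat_surf,
                            stringsAsFactors = FALSE),
         spec = spec, schedule = schedule, fun = fun),
    class = "cb_cohort")
}

#' @export
print.cb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%s), instruments: %s\n",
              x$spec$n, x$spec$variant,
              paste(x$spec$instruments, collapse = ", ")))
  print(table(x$truth$learner_type))
  invisible(x)
}
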