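#' Configure an end-to-end simulated study
#'
#' Bundles the cohort specification with the analysis options used by
#' [run_study()].
#'
#' @param variant Task variant, `"study1a"` or `"study1b"`.
#' @param n Cohort size (ignored when `cohort` is supplied).
#' @param instrument Survey instrument analysed (`"massist"` or
#'   `"rspq2f"`).
#' @param cohort Optional prebuilt [cohort_spec()]; when omitted one is
#'   constructed from `variant`, `n`, `seed` and `...` (passed on to
#'   [cohort_spec()]).
#' @param ci_level,ci_method Classification CI options.
#' @param power_rho Population correlation used in the power analysis.
#' @param power_f Cohen's f used in the F-test power analysis.
#' @param include_nonlearners_in_correlations Exploratory mode: keep
#'   non-learners in the correlation analyses (used when correlating two
#'   instruments with each other); the default FALSE restricts all
#'   inferential analyses to classified abstraction/exemplar learners.
#' @param seed Integer master seed, forwarded to the cohort.
#' @param ... Further arguments to [cohort_spec()].
#' @return Object of class `cb_study_config`.
#' @export
study_config <- function(variant = c("study1a", "study1b"), n = 108,
                         instrument = c("massist", "rspq2f"),
                         cohort = NULL, ci_level = 0.95, ci_method = "t",
                         power_rho = 0.3, power_f = 0.25,
                         include_nonlearners_in_correlations = FALSE,
                         seed = 1L, ...) {
  variant <- match.arg(variant)
  instrument <- match.arg(instrument)
  if (is.null(cohort))
    cohort <- cohort_spec(n, variant, instruments = instrument,
                          rng_seed = seed, ...)
  if (!instrument %in% cohort$instruments)
    stop("cohort does not administer instrument '", instrument, "'")
  structure(list(variant = cohort$variant, cohort = cohort,
                 instrument = instrument, ci_level = ci_level,
                 ci_method = ci_method, power_rho = power_rho,
                 power_f = power_f,
                 include_nonlearners_in_correlations =
                   include_nonlearners_in_correlations,
                 seed = cohort$rng_seed),
            class = "cb_study_config")
}

# Correlation matrix in the reporting layout: concept-building code (0 =
# abstraction, 1 = exemplar), extrapolation MAE, deep score, surface score.
# Pairwise complete; the code column uses point-biserial correlations.
cb_correlation_matrix <- function(tab) {
  vars <- c(code = "code", extrapolation_mae = "extrapolation_mae",
            deep = "deep_score", surface = "surface_score")
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(names(vars), names(vars)))
  p <- r; nm <- r
  diag(r) <- 1
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    x <- tab[[vars[i]]]; y <- tab[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- if (vars[i] == "code" && all(x[ok] %in% 0:1))
        point_biserial(x[ok], y[ok]) else pearson_cor(x[ok], y[ok])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p_value
    }
    nm[i, j] <- nm[j, i] <- sum(ok)
  }
  list(r = r, p = p, n = nm)
}

# Inferential battery on a learner-level table (one row per classified
# abstraction/exemplar learner with complete scale scores).
cb_analyze_learners <- function(tab, power_rho, power_f, corr_tab = NULL) {
  anova <- mixed_anova_2x2(ifelse(tab$code == 0, "abstraction", "exemplar"),
                           tab$deep_score, tab$surface_score)
  n <- nrow(tab)
  bayes <- bic_posterior_null(anova["interaction", "F"], 1,
                              anova["interaction", "df2"], n)
  list(correlations = cb_correlation_matrix(corr_tab %||% tab),
       anova = anova,
       bayes = bayes,
       power = list(
         correlation = correlation_power(power_rho, n),
         f_test = f_test_power(power_f, 1, n)),
       n_learners = n)
}

#' Run a complete simulated study
#'
#' Generates the cohort, classifies every participant, scores the surveys,
#' and runs the full analysis battery: the correlation matrix over
#' concept-building code / extrapolation MAE / deep / surface scores, the
#' 2 x 2 mixed ANOVA with partial eta squared, the BIC posterior for the
#' null interaction, power analyses, and the per-input mean-prediction
#' curves by learner class.  Non-learners and incomplete sessions are
#' retained in the classification counts but excluded from the inferential
#' analyses (unless the exploratory correlation mode is enabled in the
#' config).  Deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @return Object of class `cb_study_report` with elements `counts`,
#'   `n_learners`, `correlations` (`r`, `p`, `n` matrices), `anova`,
#'   `bayes`, `power`, `figure_data`, `learner_table`, `classification`,
#'   `scores`, `instrument`, `variant`, `seed` and `config`.
#' @examples
#' rep1 <- run_study(study_config("study1b", n = 60, seed = 7))
#' rep1$counts
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "cb_study_config"))
  cohort <- generate_cohort(config$cohort)
  cls <- classify_cohort(cohort, level = config$ci_level,
                         method = config$ci_method)
  key <- scale_key(config$instrument)
  scores <- score_surveys(
    cohort$surveys[cohort$surveys$instrument == config$instrument, ], key)

  tab <- merge(cls[, c("participant_id", "category", "final_training_mae",
                       "extrapolation_mae", "ci_upper")],
               scores[, c("participant_id", "deep_score", "surface_score")],
               by = "participant_id", all.x = TRUE)
  tab$code <- ifelse(tab$category == "abstraction", 0,
                     ifelse(tab$category == "exemplar", 1, NA_real_))
  learners <- tab[!is.na(tab$code) & !is.na(tab$deep_score) &
                    !is.na(tab$surface_score), ]
  if (nrow(learners) < 4L)
    stop("run_study: too few classified learners with complete scores (",
         nrow(learners), ")")
  corr_tab <- if (config$include_nonlearners_in_correlations)
    tab[!is.na(tab$deep_score) & !is.na(tab$surface_score), ]
  else learners
  ana <- cb_analyze_learners(learners, config$power_rho, config$power_f,
                             corr_tab = corr_tab)

  counts <- table(factor(cls$category,
                         levels = c("abstraction", "exemplar",
                                    "nonlearner", "incomplete")))
  structure(
    c(list(variant = config$variant, instrument = config$instrument,
           seed = config$seed, counts = counts,
           figure_data = figure2_data(cohort$sessions, cls,
                                      cohort$schedule, cohort$fun),
           learner_table = learners, classification = cls, scores = scores,
           config = config),
      ana),
    class = "cb_study_report")
}

#' @export
print.cb_study_report <- function(x, digits = 2, ...) {
  cat(sprintf("Study report (%s, %s instrument, seed %d)\n",
              x$variant, x$instrument, x$seed))
  cat("Classification counts:\n")
  print(x$counts)
  cat(sprintf("Learner-only analysis n = %d\n\n", x$n_learners))
  cat("Correlations (lower triangle; * p < 0.05):\n")
  r <- x$correlations$r; p <- x$correlations$p
  txt <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  for (i in seq_len(nrow(r))) for (j in seq_len(i - 1L))
    txt[i, j] <- paste0(format(round(r[i, j], digits), nsmall = digits),
                        ifelse(!is.na(p[i, j]) && p[i, j] < 0.05, " *", ""))
  diag(txt) <- "-"
  print(txt, quote = FALSE)
  cat("\n")
  print(x$anova)
  cat("\nInteraction ")
  print(x$bayes)
  invisible(x)
}

#' Pool learner-level data from two or more study reports
#'
#' Concatenates the learner-level rows (classified learners with scores)
#' of compatible reports and re-runs the correlation, ANOVA, Bayes and
#' power analyses on the pooled sample.  All reports must use the same
#' survey instrument.
#'
#' @param ... Two or more `cb_study_report` objects (or a single list of
#'   them).
#' @param power_rho,power_f Power-analysis effect sizes for the pooled
#'   sample.
#' @return A `cb_study_report` with `variant = "pooled"`.
#' @export
pooled_analysis <- function(..., power_rho = 0.3, power_f = 0.25) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "cb_study_report"))
    reports <- reports[[1L]]
  stopifnot(length(reports) >= 2L,
            all(vapply(reports, inherits, TRUE, "cb_study_report")))
  instr <- unique(vapply(reports, `[[`, "", "instrument"))
  if (length(instr) != 1L)
    stop("pooled_analysis: instruments differ (",
         paste(instr, collapse = ", "), ")")
  tabs <- lapply(seq_along(reports), function(i) {
    t <- reports[[i]]$learner_table
    t$participant_id <- paste0("s", i, ":", t$participant_id)
    t
  })
  tab <- do.call(rbind, tabs)
  ana <- cb_analyze_learners(tab, power_rho, power_f)
  counts <- Reduce(`+`, lapply(reports, `[[`, "counts"))
  structure(
    c(list(variant = "pooled", instrument = instr,
           seed = NA_integer_, counts = counts,
           figure_data = NULL, learner_table = tab,
           classification = NULL, scores = NULL, config = NULL),
      ana),
    class = "cb_study_report")
}

#' Per-input mean prediction curves by learner class
#'
#' Aggregates, for each transfer input and each final-training-block
#' input, the mean prediction across all abstraction learners and across
#' all exemplar learners, alongside the correct output and the flat
#' exemplar-baseline prediction (extrapolation inputs only) — the data
#' behind the classic extrapolation figure.
#'
#' @param sessions List of `cb_session` objects (or a `cb_cohort`).
#' @param classification Data frame from [classify_cohort()].
#' @param schedule,spec Task schedule and function spec.
#' @return Data frame of class `cb_figure2`: `class`, `input`, `phase`
#'   (`"final_training"` or `"transfer"`), `mean_prediction`, `n`,
#'   `correct_output`, `baseline_prediction` (NA off the extrapolation
#'   range).  Classes with no members are omitted with a warning.
#' @export
figure2_data <- function(sessions, classification, schedule, spec) {
  if (inherits(sessions, "cb_cohort")) {
    schedule <- sessions$schedule; spec <- sessions$fun
    sessions <- sessions$sessions
  }
  cat_of <- stats::setNames(classification$category,
                            classification$participant_id)
  bl <- exemplar_baseline(schedule, spec)
  out <- list()
  for (cl in c("abstraction", "exemplar")) {
    members <- Filter(function(s) identical(unname(
      cat_of[s$participant_id]), cl), sessions)
    if (length(members) == 0L) {
      warning("figure2_data: no ", cl, " learners; series omitted")
      next
    }
    inp <- unlist(lapply(members, function(s)
      s$input[s$block == 0L | s$block == s$n_training_blocks]))
    prd <- unlist(lapply(members, function(s)
      s$prediction[s$block == 0L | s$block == s$n_training_blocks]))
    phs <- unlist(lapply(members, function(s)
      ifelse(s$block[s$block == 0L | s$block == s$n_training_blocks] == 0L,
             "transfer", "final_training")))
    agg <- stats::aggregate(prd, by = list(input = inp, phase = phs), mean)
    cnt <- stats::aggregate(prd, by = list(input = inp, phase = phs), length)
    out[[cl]] <- data.frame(class = cl, input = agg$input,
                            phase = agg$phase, mean_prediction = agg$x,
                            n = cnt$x, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("figure2_data: no classified learners at all")
  res$correct_output <- evaluate_function(spec, res$input)
  res$baseline_prediction <- ifelse(
    res$input < schedule$training_min, bl$prediction_left,
    ifelse(res$input > schedule$training_max, bl$prediction_right,
           NA_real_))
  rownames(res) <- NULL
  class(res) <- c("cb_figure2", "data.frame")
  res
}

#' Plot the mean-prediction curves
#'
#' Base-graphics rendering of [figure2_data()]: correct outputs as a
#' line, flat exemplar-baseline dashes, class means as points.
#'
#' @param x A `cb_figure2` data frame.
#' @param ... Passed to [plot()].
#' @export
plot.cb_figure2 <- function(x, ...) {
  ord <- order(x$input)
  plot(range(x$input), range(c(x$mean_prediction, x$correct_output)),
       type = "n", xlab = "input value", ylab = "output prediction", ...)
  xs <- sort(unique(x$input))
  graphics::lines(xs, x$correct_output[match(xs, x$input)], lwd = 2)
  bx <- x[!is.na(x$baseline_prediction), ]
  graphics::points(bx$input, bx$baseline_prediction, pch = 3, col = "grey40")
  cols <- c(abstraction = "blue", exemplar = "darkorange")
  for (cl in unique(x$class)) {
    d <- x[x$class == cl, ]
    graphics::points(d$input, d$mean_prediction, col = cols[[cl]], pch = 19)
  }
  graphics::legend("topright", bty = "n",
                   legend = c("correct", "flat baseline", unique(x$class)),
                   col = c("black", "grey40", cols[unique(x$class)]),
                   pch = c(NA, 3, rep(19, length(unique(x$class)))),
                   lty = c(1, NA, rep(NA, length(unique(x$class)))))
  invisible(x)
}
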