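# Independent oracles and fixture builders shared across test files.

# Brute-force cell-means sum-of-squares decomposition for a balanced
# 2 (between) x 2 (within) mixed design.  Independent of the package's
# contrast-based computation.
oracle_mixed_anova <- function(group, deep, surface) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2L, length(unique(table(g))) == 1L) # balanced only
  N <- length(g)
  y <- c(deep, surface)
  cond <- rep(c("deep", "surface"), each = N)
  subj <- rep(seq_len(N), 2L)
  gg <- rep(as.character(g), 2L)
  grand <- mean(y)
  m_g <- tapply(y, gg, mean)
  m_c <- tapply(y, cond, mean)
  m_gc <- tapply(y, list(gg, cond), mean)
  m_s <- tapply(y, subj, mean)
  n_g <- table(g)
  SS_between <- sum(2 * n_g[names(m_g)] * (m_g - grand)^2)
  SS_subj <- 2 * sum((m_s - m_g[as.character(g)])^2)
  SS_within <- sum(N * (m_c - grand)^2)
  SS_int <- 0
  for (l in levels(g)) for (cc in c("deep", "surface"))
    SS_int <- SS_int +
      n_g[[l]] * (m_gc[l, cc] - m_g[[l]] - m_c[[cc]] + grand)^2
  fitted <- m_gc[cbind(gg, cond)] + (m_s[subj] - m_g[gg])
  SS_err <- sum((y - fitted)^2)
  df_s <- N - 2L
  list(within = SS_within / (SS_err / df_s),
       between = SS_between / (SS_subj / df_s),
       interaction = SS_int / (SS_err / df_s))
}

# Upper tail of the noncentral F via its Poisson-mixture-of-beta series
# (does not call pf with an ncp argument).
oracle_ncf_tail <- function(crit, df1, df2, lambda) {
  x <- df1 * crit / (df1 * crit + df2)
  j <- 0:2000
  sum(stats::dpois(j, lambda / 2) *
        stats::pbeta(x, df1 / 2 + j, df2 / 2, lower.tail = FALSE))
}

# Build a minimal complete session directly from signed per-trial errors
# (one training block + full transfer phase), bypassing run_session, so the
# classifier can be probed at exact values.
make_session <- function(final_block_errors, extrap_errors,
                         interp_errors = rep(0, 6),
                         variant = "study1a", id = "T1",
                         schedule = build_schedule(variant),
                         spec = study_function(variant)) {
  tr <- schedule$training_inputs
  ex <- schedule$extrapolation_inputs
  ip <- schedule$interpolation_inputs
  stopifnot(length(final_block_errors) == length(tr),
            length(extrap_errors) == length(ex),
            length(interp_errors) == length(ip))
  correct <- evaluate_function(spec, c(tr, ex, ip))
  pred <- correct + c(final_block_errors, extrap_errors, interp_errors)
  block <- c(rep(1L, length(tr)), rep(0L, length(ex) + length(ip)))
  structure(
    list(participant_id = id, variant = variant,
         input = c(tr, ex, ip), prediction = pred, correct = correct,
         abs_error = abs(pred - correct), block = block,
         block_maes = mean(abs(final_block_errors)),
         n_training_blocks = 1L, feedback = character(0), aborted = FALSE),
    class = "cb_session")
}
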