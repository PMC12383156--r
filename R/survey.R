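#' Canonical scale keys for the two SAL instruments
#'
#' The M-ASSIST has 6 deep and 6 surface items scored by the per-scale
#' *mean* rating (range 1-5); the R-SPQ-2F has 10 deep and 10 surface
#' items scored by the per-scale *sum* (range 10-50).  The original item
#' wordings are proprietary to the instruments, so generic item ids
#' (D1.., S1..) are used throughout; a key read from YAML can carry real
#' ids.  `min_answered` controls missing-data tolerance: the M-ASSIST mean
#' is computed when at least 5 of 6 scale items are answered, the R-SPQ-2F
#' sum requires complete scales.
#'
#' @param instrument `"massist"` or `"rspq2f"`.
#' @param min_answered Minimum answered items per scale for a score to be
#'   defined; default 5 (massist) or 10 (rspq2f).
#' @return An object of class `cb_scale_key` with fields `instrument`,
#'   `deep_items`, `surface_items`, `reverse_items`, `aggregation`
#'   (`"mean"` or `"sum"`), `rating_min`, `rating_max`, `min_answered`.
#' @export
scale_key <- function(instrument = c("massist", "rspq2f"),
                      min_answered = NULL) {
  instrument <- match.arg(instrument)
  k <- if (instrument == "massist") 6L else 10L
  structure(
    list(instrument = instrument,
         deep_items = sprintf("D%d", seq_len(k)),
         surface_items = sprintf("S%d", seq_len(k)),
         reverse_items = character(0),
         aggregation = if (instrument == "massist") "mean" else "sum",
         rating_min = 1L, rating_max = 5L,
         min_answered = if (!is.null(min_answered)) as.integer(min_answered)
         else if (instrument == "massist") 5L else 10L),
    class = "cb_scale_key")
}

#' Read / write a scale key as YAML
#'
#' @param path YAML file path.
#' @return `read_scale_key()` returns a `cb_scale_key`.
#' @export
read_scale_key <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$instrument), !is.null(y$deep_items),
            !is.null(y$surface_items), !is.null(y$aggregation))
  structure(
    list(instrument = y$instrument,
         deep_items = as.character(y$deep_items),
         surface_items = as.character(y$surface_items),
         reverse_items = as.character(y$reverse_items %||% character(0)),
         aggregation = y$aggregation,
         rating_min = y$rating_min %||% 1L,
         rating_max = y$rating_max %||% 5L,
         min_answered = y$min_answered %||% length(y$deep_items)),
    class = "cb_scale_key")
}

#' @rdname read_scale_key
#' @param key A `cb_scale_key`.
#' @export
write_scale_key <- function(key, path) {
  stopifnot(inherits(key, "cb_scale_key"))
  yaml::write_yaml(unclass(key), path)
  invisible(path)
}

#' Validate a scale key against the instrument conventions
#'
#' Checks item counts (6+6 for the M-ASSIST, 10+10 for the R-SPQ-2F),
#' disjointness of the deep and surface item lists, and the aggregation
#' mode (mean for massist, sum for rspq2f).
#'
#' @param key A `cb_scale_key`.
#' @return Character vector of violations; empty when the key conforms.
#' @export
validate_key <- function(key) {
  stopifnot(inherits(key, "cb_scale_key"))
  v <- character(0)
  expected <- switch(key$instrument, massist = 6L, rspq2f = 10L, NA_integer_)
  if (is.na(expected))
    v <- c(v, sprintf("unknown instrument '%s'", key$instrument))
  else {
    if (length(key$deep_items) != expected)
      v <- c(v, sprintf("expected %d deep items, found %d",
                        expected, length(key$deep_items)))
    if (length(key$surface_items) != expected)
      v <- c(v, sprintf("expected %d surface items, found %d",
                        expected, length(key$surface_items)))
    agg <- if (key$instrument == "massist") "mean" else "sum"
    if (!identical(key$aggregation, agg))
      v <- c(v, sprintf("expected aggregation '%s', found '%s'",
                        agg, key$aggregation))
  }
  if (length(intersect(key$deep_items, key$surface_items)) > 0L)
    v <- c(v, "deep and surface item lists overlap")
  if (anyDuplicated(key$deep_items) || anyDuplicated(key$surface_items))
    v <- c(v, "duplicated item ids within a scale")
  v
}

#' Score item-level Likert responses into deep/surface scale scores
#'
#' @param responses Long data frame with columns `participant_id`,
#'   `item_id`, `rating` (and optionally `instrument`, which is checked
#'   against the key).  Ratings must be integers in 1..5 or NA (missing).
#'   Items keyed but absent from a participant's rows count as missing.
#' @param key A `cb_scale_key`.
#' @return Data frame: `participant_id`, `instrument`, `deep_score`,
#'   `surface_score`, `n_missing_items`.  Scores are NA when fewer than
#'   `key$min_answered` items of a scale were answered.
#' @examples
#' key <- scale_key("massist")
#' resp <- data.frame(participant_id = "p1",
#'                    item_id = c(key$deep_items, key$surface_items),
#'                    rating = rep(4L, 12))
#' score_surveys(resp, key)
#' @export
score_surveys <- function(responses, key) {
  stopifnot(inherits(key, "cb_scale_key"),
            all(c("participant_id", "item_id", "rating") %in%
                  names(responses)))
  if (!is.null(responses$instrument) &&
      !all(responses$instrument == key$instrument))
    stop("responses carry a different instrument than the key")
  keyed <- c(key$deep_items, key$surface_items)
  unknown <- setdiff(unique(responses$item_id), keyed)
  if (length(unknown) > 0L)
    stop("unknown item id(s): ", paste(unknown, collapse = ", "))
  r <- responses$rating
  ok <- is.na(r) | (r >= key$rating_min & r <= key$rating_max & r == round(r))
  if (!all(ok))
    stop("ratings must be integers in ", key$rating_min, "..",
         key$rating_max, " (or NA)")
  r <- as.numeric(r)
  rev <- responses$item_id %in% key$reverse_items
  r[rev] <- key$rating_min + key$rating_max - r[rev]

  pid <- factor(responses$participant_id,
                levels = unique(responses$participant_id))
  scale_of <- ifelse(responses$item_id %in% key$deep_items, "deep", "surface")
  score_one <- function(which_scale, n_items) {
    sel <- scale_of == which_scale
    sums <- tapply(ifelse(is.na(r[sel]), 0, r[sel]), pid[sel], sum,
                   default = 0)
    cnts <- tapply(!is.na(r[sel]), pid[sel], sum, default = 0L)
    score <- if (key$aggregation == "mean") sums / cnts else sums
    score[cnts < key$min_answered] <- NA_real_
    if (key$aggregation == "sum") score[cnts < n_items] <- NA_real_
    list(score = as.numeric(score), missing = n_items - as.integer(cnts))
  }
  d <- score_one("deep", length(key$deep_items))
  s <- score_one("surface", length(key$surface_items))
  data.frame(participant_id = levels(pid),
             instrument = key$instrument,
             deep_score = d$score,
             surface_score = s$score,
             n_missing_items = d$missing + s$missing,
             stringsAsFactors = FALSE)
}
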