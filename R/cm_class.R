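#' Compensatory / noncompensatory score thresholds
#'
#' For a set with single-variant scores `s_1..s_n`, the joint score `S`
#' is compared against thresholds placed 1.5 score-ranges outside the
#' single-score range:
#' `low = min(s) - 1.5 (max(s) - min(s))` and
#' `high = max(s) + 1.5 (max(s) - min(s))`.
#'
#' @param single_scores Numeric vector of single-variant scores (at
#'   least one, all finite, one consistent score type).
#' @return Named numeric vector `c(cm = low, noncm = high)`.
#' @examples
#' cm_thresholds(c(1, 2))       # -0.5, 3.5
#' cm_thresholds(c(2.2, 3.1))   # 0.85, 4.45
#' @export
cm_thresholds <- function(single_scores) {
  if (!is.numeric(single_scores) || length(single_scores) < 1L ||
      any(!is.finite(single_scores)))
    stop("'single_scores' must be a nonempty finite numeric vector",
         call. = FALSE)
  rng <- max(single_scores) - min(single_scores)
  c(cm = min(single_scores) - 1.5 * rng,
    noncm = max(single_scores) + 1.5 * rng)
}

#' Classify a scored variant set as compensatory or noncompensatory
#'
#' A set is a compensatory-mutation (CM) set when its joint score falls
#' at or below the low threshold - the combination scores far less
#' deleterious than its worst member - and a noncompensatory (nonCM)
#' set when the joint score is at or above the high threshold; anything
#' between is `"neither"`.  When all single scores are equal the range
#' is zero and both printed conditions would fire at `S == s`; such
#' degenerate sets are reported as `"neither"` with a flag, since the
#' definitions presuppose score dispersion.
#'
#' @param S Joint score of the set (same score type and scale as the
#'   single scores).
#' @param single_scores Single-variant scores `s_i`.
#' @return A list of class `cm_classification`: `label` (`"CM"`,
#'   `"nonCM"` or `"neither"`), `cm_threshold`, `noncm_threshold`,
#'   `degenerate`.
#' @examples
#' classify_cm(5.3, c(2.2, 3.1))$label   # "nonCM"
#' classify_cm(-1, c(1, 2))$label        # "CM"
#' @export
classify_cm <- function(S, single_scores) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S))
    stop("'S' must be a single finite number", call. = FALSE)
  th <- cm_thresholds(single_scores)
  degenerate <- th[["cm"]] == th[["noncm"]]
  label <- if (degenerate) "neither"
    else if (S <= th[["cm"]]) "CM"
    else if (S >= th[["noncm"]]) "nonCM"
    else "neither"
  structure(list(label = label,
                 cm_threshold = th[["cm"]],
                 noncm_threshold = th[["noncm"]],
                 degenerate = degenerate),
            class = "cm_classification")
}

#' @export
print.cm_classification <- function(x, ...) {
  cat("CM classification:", x$label,
      sprintf("(thresholds CM <= %.4g, nonCM >= %.4g%s)\n",
              x$cm_threshold, x$noncm_threshold,
              if (x$degenerate) "; degenerate zero-range" else ""))
  invisible(x)
}

#' Classify a table of scored sets
#'
#' @param scores Data frame with columns `set_id`, `S` and
#'   `single_scores` (semicolon-joined numbers), as written by
#'   [write_set_score_tsv()], or a list of `set_score_record`s.
#' @return Data frame: `set_id`, `label`, `cm_threshold`,
#'   `noncm_threshold`.
#' @export
classify_cm_table <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(rbind, lapply(scores, function(r)
      data.frame(set_id = r$set_id, S = r$S,
                 single_scores = paste(r$singles, collapse = ";"))))
  singles <- lapply(strsplit(as.character(scores$single_scores), ";"),
                    as.numeric)
  res <- mapply(function(S, s) classify_cm(S, s), scores$S, singles,
                SIMPLIFY = FALSE)
  data.frame(set_id = scores$set_id,
             label = vapply(res, `[[`, character(1), "label"),
             cm_threshold = vapply(res, `[[`, numeric(1), "cm_threshold"),
             noncm_threshold = vapply(res, `[[`, numeric(1),
                                      "noncm_threshold"))
}
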