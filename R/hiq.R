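#' Hyper-complementation score threshold
#'
#' Scores more than two median standard errors above the wild-type-like
#' score of 1 are considered hyper-complementing: the threshold is
#' `1 + 2 * median(se)` over all variants' standard errors (for the CHK2
#' map this evaluates to 1.46).
#'
#' @param se_values standard errors of all variants in the map.
#' @return the threshold.
#' @export
hyper_threshold <- function(se_values) {
  se_values <- se_values[is.finite(se_values)]
  if (length(se_values) == 0L) stop("no standard errors supplied")
  if (any(se_values < 0)) stop("data error: negative standard error")
  1 + 2 * stats::median(se_values)
}

#' High-confidence ("HiQ") subset filter
#'
#' Keeps a variant only if (a) the interval `score +/- se` does not
#' contain the synonymous/nonsense midpoint (0.5), i.e. the score is
#' confidently on one side of the damaging boundary, and (b) the score
#' does not exceed the hyper-complementation threshold. Interval
#' containment is inclusive at the endpoints; the hyper cut is strict
#' (`score > hyper_cut` removes).
#'
#' @param scores a `mave_scores` object or a data.frame with `score` and
#'   `se` columns.
#' @param midpoint the excluded midpoint (default 0.5).
#' @param hyper_cut hyper-complementation threshold; `NULL` computes
#'   [hyper_threshold()] from all supplied SEs.
#' @return list with `hiq` (the kept rows), `decisions` (one row per
#'   input variant: `kept`, `reason` in kept / interval_spans_midpoint /
#'   hyper_complementing) and `hyper_cut`.
#' @export
hiq_filter <- function(scores, midpoint = 0.5, hyper_cut = NULL) {
  df <- if (inherits(scores, "mave_scores")) scores$scores else scores
  stopifnot(all(c("score", "se") %in% names(df)))
  if (any(df$se < 0, na.rm = TRUE)) stop("data error: negative standard error")
  if (is.null(hyper_cut)) hyper_cut <- hyper_threshold(df$se)
  spans <- (df$score - df$se) <= midpoint & midpoint <= (df$score + df$se)
  hyper <- df$score > hyper_cut
  reason <- ifelse(spans, "interval_spans_midpoint",
                   ifelse(hyper, "hyper_complementing", "kept"))
  kept <- reason == "kept"
  decisions <- data.frame(df[, intersect(c("hgvs_pro", "position", "ref_aa",
                                           "alt_aa", "vclass"), names(df)),
                             drop = FALSE],
                          score = df$score, se = df$se,
                          kept = kept, reason = reason,
                          stringsAsFactors = FALSE)
  list(hiq = df[kept, , drop = FALSE], decisions = decisions,
       hyper_cut = hyper_cut)
}
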