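#' Balanced precision-recall curve
#'
#' Evaluates how well functional scores separate pathogenic from benign
#' reference variants, with low scores treated as evidence of
#' pathogenicity (loss of function). At each threshold `t` a variant is
#' called pathogenic when `score <= t`; recall is the fraction of
#' pathogenic variants captured and balanced precision is the precision
#' expected in a test set with a 50% prior probability of pathogenicity:
#' `sens / (sens + (1 - spec))`. Reported alongside are the area under
#' the balanced precision vs recall curve (AUBPRC, trapezoid over recall)
#' and R90BP, the maximum recall achieved at balanced precision >= 0.90
#' (0 when no threshold reaches it).
#'
#' @param score numeric functional scores.
#' @param label logical or character labels; `TRUE`/`"P"...` marks
#'   pathogenic.
#' @return object of class `balanced_pr`: list with `points` (threshold,
#'   recall, precision, balanced_precision), `aubprc`, `r90bp`, `n_pos`,
#'   `n_neg`.
#' @examples
#' bpr <- balanced_pr(c(0.1, 0.2, 0.8, 0.9), c("P", "P", "B", "B"))
#' bpr$aubprc
#' @export
balanced_pr <- function(score, label) {
  stopifnot(length(score) == length(label))
  ok <- is.finite(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  pos <- if (is.logical(label)) label else
    grepl("^p|^TRUE$|^1$", as.character(label), ignore.case = TRUE)
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("undefined curve: need both pathogenic and benign variants")
  }
  thr <- sort(unique(score))
  sens <- vapply(thr, function(t) sum(score[pos] <= t) / P, 0)
  fpr <- vapply(thr, function(t) sum(score[!pos] <= t) / N, 0)
  prec <- vapply(thr, function(t) {
    called <- score <= t
    if (!any(called)) return(NA_real_)
    sum(pos & called) / sum(called)
  }, 0)
  bp <- ifelse(sens + fpr > 0, sens / (sens + fpr), NA_real_)
  points <- data.frame(threshold = thr, recall = sens, precision = prec,
                       balanced_precision = bp)
  cp <- points[!is.na(points$balanced_precision), , drop = FALSE]
  # anchor at recall 0 with the earliest observed balanced precision
  r <- c(0, cp$recall)
  b <- c(cp$balanced_precision[1], cp$balanced_precision)
  aubprc <- sum(diff(r) * (utils::head(b, -1) + utils::tail(b, -1)) / 2)
  hit <- cp$balanced_precision >= 0.90
  r90bp <- if (any(hit)) max(cp$recall[hit]) else 0
  structure(list(points = points, aubprc = aubprc, r90bp = r90bp,
                 n_pos = P, n_neg = N),
            class = "balanced_pr")
}

#' @export
print.balanced_pr <- function(x, ...) {
  cat("Balanced precision-recall evaluation\n")
  cat("  n =", x$n_pos, "pathogenic /", x$n_neg, "benign\n")
  cat("  AUBPRC =", round(x$aubprc, 3), "  R90BP =", round(x$r90bp, 3), "\n")
  invisible(x)
}

#' @export
plot.balanced_pr <- function(x, ...) {
  p <- x$points[!is.na(x$points$balanced_precision), ]
  plot(p$recall, p$balanced_precision, type = "s", lwd = 2,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "recall", ylab = "balanced precision",
       main = sprintf("AUBPRC %.2f, R90BP %.2f", x$aubprc, x$r90bp), ...)
  abline(h = 0.9, lty = 3)
  invisible(x)
}
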