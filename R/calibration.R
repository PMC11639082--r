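#' Kernel density estimates of reference score distributions
#'
#' Fits Gaussian kernel density estimates to the functional scores of the
#' pathogenic (positive) and benign (negative) reference variants.
#' Bandwidths are chosen by biased cross-validation, falling back to
#' Silverman's rule for fewer than 10 points (biased cross-validation is
#' unstable at tiny n).
#'
#' @param positives,negatives numeric score vectors of the two reference
#'   classes (>= 1 each; >= 3 recommended).
#' @param bw_method `"bcv"` (default) or `"nrd0"`.
#' @return list of class `ref_densities`: evaluable density functions
#'   `f_pos(x)`, `f_neg(x)`, the bandwidths, and the `support` interval
#'   (score range extended by one bandwidth on each side) used for the
#'   uniform regularizer.
#' @export
fit_reference_densities <- function(positives, negatives,
                                    bw_method = c("bcv", "nrd0")) {
  bw_method <- match.arg(bw_method)
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("calibration error: empty reference class")
  }
  h_pos <- kde_bandwidth(positives, bw_method)
  h_neg <- kde_bandwidth(negatives, bw_method)
  support <- c(min(c(positives, negatives)) - max(h_pos, h_neg),
               max(c(positives, negatives)) + max(h_pos, h_neg))
  structure(list(f_pos = kde_function(positives, h_pos),
                 f_neg = kde_function(negatives, h_neg),
                 bw_pos = h_pos, bw_neg = h_neg,
                 n_pos = length(positives), n_neg = length(negatives),
                 support = support),
            class = "ref_densities")
}

kde_bandwidth <- function(x, method) {
  if (length(x) < 2L || stats::sd(x) == 0) {
    return(max(stats::bw.nrd0(c(x, x + 1e-6)), 1e-3))
  }
  if (method == "bcv" && length(x) >= 10L) {
    h <- suppressWarnings(try(stats::bw.bcv(x), silent = TRUE))
    if (!inherits(h, "try-error") && is.finite(h) && h > 0) return(h)
  }
  stats::bw.nrd0(x)
}

# Gaussian kernel density as an evaluable closure
kde_function <- function(x, h) {
  force(x); force(h)
  function(q) {
    vapply(q, function(z) mean(stats::dnorm((z - x) / h)) / h, 0)
  }
}

#' Log-likelihood ratio of pathogenicity for a score
#'
#' Base-10 log ratio of the pathogenic to the benign reference density,
#' each regularized against a uniform density on the support interval:
#' `log10(((1-eps) f_pos + eps u) / ((1-eps) f_neg + eps u))`. The
#' regularizer keeps ratios finite in sparsely covered score regions.
#' Scores outside the support are evaluated at the clamped edge with a
#' warning.
#'
#' @param score numeric scores.
#' @param densities a `ref_densities` object.
#' @param epsilon uniform regularization weight (default 0.01).
#' @return base-10 log-likelihood ratios.
#' @export
compute_llr <- function(score, densities, epsilon = 0.01) {
  stopifnot(inherits(densities, "ref_densities"),
            epsilon >= 0, epsilon <= 1)
  sup <- densities$support
  out_of_support <- score < sup[1] | score > sup[2]
  if (any(out_of_support, na.rm = TRUE)) {
    warning(sum(out_of_support, na.rm = TRUE),
            " score(s) outside the calibration support were clamped")
    score <- pmin(pmax(score, sup[1]), sup[2])
  }
  u <- 1 / diff(sup)
  num <- (1 - epsilon) * densities$f_pos(score) + epsilon * u
  den <- (1 - epsilon) * densities$f_neg(score) + epsilon * u
  log10(num / den)
}

# LLR thresholds: log10 of the ACMG/AMP odds-of-pathogenicity ladder
# (Tavtigian-style: ~2.08, 4.33, 18.7, 350 -> 0.32, 0.64, 1.3, 2.5)
LLR_THRESHOLDS <- c(supporting = 0.32, moderate = 0.64, strong = 1.3,
                    very_strong = 2.5)
LLR_BENIGN <- -0.32

#' Map a log-likelihood ratio to an ACMG/AMP evidence strength
#'
#' Categories: LLR above 2.5 is `PS3_very_strong`; (1.3, 2.5] is
#' `PS3_strong`; (0.64, 1.3] is `PS3_moderate`; [0.32, 0.64] is
#' `PS3_supporting`; the open gap (-0.32, 0.32) is `indeterminate`; LLR
#' at or below -0.32 is `BS3_supporting` (the strongest benign level the
#' scheme assigns; more negative values clamp to it).
#'
#' @param llr numeric (finite) log-likelihood ratios, base 10.
#' @return factor of evidence categories.
#' @export
evidence_category <- function(llr) {
  if (any(is.na(llr))) stop("NaN/NA LLR")
  lev <- c("PS3_very_strong", "PS3_strong", "PS3_moderate", "PS3_supporting",
           "indeterminate", "BS3_supporting")
  out <- ifelse(llr > LLR_THRESHOLDS["very_strong"], "PS3_very_strong",
         ifelse(llr > LLR_THRESHOLDS["strong"], "PS3_strong",
         ifelse(llr > LLR_THRESHOLDS["moderate"], "PS3_moderate",
         ifelse(llr >= LLR_THRESHOLDS["supporting"], "PS3_supporting",
         ifelse(llr > LLR_BENIGN, "indeterminate", "BS3_supporting")))))
  factor(out, levels = lev)
}

#' Calibrate functional scores to clinical evidence strengths
#'
#' Fits the reference score densities ([fit_reference_densities()]) from
#' labeled pathogenic/benign variants and returns a calibration object
#' whose `predict` method converts any functional score into a base-10
#' log-likelihood ratio of pathogenicity and its ACMG/AMP evidence
#' category.
#'
#' @param reference data.frame with a `score` column and a `label` column
#'   (`"P"`/pathogenic vs `"B"`/benign; anything matching `^[Pp]` is
#'   treated as pathogenic).
#' @param epsilon uniform regularization weight.
#' @param bw_method bandwidth selector, see [fit_reference_densities()].
#' @return object of class `mave_llr`.
#' @examples
#' ref <- data.frame(score = c(0.0, 0.1, 0.2, 0.9, 1.0, 1.1),
#'                   label = c("P", "P", "P", "B", "B", "B"))
#' cal <- llr_calibrate(ref)
#' predict(cal, c(0.05, 1.0))
#' @export
llr_calibrate <- function(reference, epsilon = 0.01,
                          bw_method = c("bcv", "nrd0")) {
  stopifnot(all(c("score", "label") %in% names(reference)))
  is_pos <- grepl("^p", as.character(reference$label), ignore.case = TRUE)
  pos <- reference$score[is_pos]
  neg <- reference$score[!is_pos]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("calibration error: need both pathogenic and benign reference variants")
  }
  dens <- fit_reference_densities(pos, neg, match.arg(bw_method))
  structure(list(densities = dens, epsilon = epsilon,
                 reference = reference,
                 thresholds = LLR_THRESHOLDS, benign_threshold = LLR_BENIGN),
            class = "mave_llr")
}

#' @rdname llr_calibrate
#' @param object a fitted `mave_llr` calibration.
#' @param newdata numeric scores, or a data.frame with a `score` column.
#' @param ... unused.
#' @return for `predict`: data.frame with `score`, `llr` and `evidence`.
#' @export
predict.mave_llr <- function(object, newdata, ...) {
  score <- if (is.data.frame(newdata)) newdata$score else newdata
  llr <- compute_llr(score, object$densities, object$epsilon)
  out <- data.frame(score = score, llr = llr,
                    evidence = evidence_category(llr))
  if (is.data.frame(newdata) && "hgvs_pro" %in% names(newdata)) {
    out <- cbind(hgvs_pro = newdata$hgvs_pro, out)
  }
  out
}

#' @export
print.mave_llr <- function(x, ...) {
  d <- x$densities
  cat("Score-to-LLR calibration (Gaussian KDE, base-10 LLR)\n")
  cat("  reference: ", d$n_pos, " pathogenic, ", d$n_neg, " benign\n", sep = "")
  cat("  bandwidths:", signif(d$bw_pos, 3), "/", signif(d$bw_neg, 3),
      " support: [", signif(d$support[1], 3), ",",
      signif(d$support[2], 3), "]\n")
  invisible(x)
}

#' @export
plot.mave_llr <- function(x, n = 200, ...) {
  sup <- x$densities$support
  q <- seq(sup[1], sup[2], length.out = n)
  fp <- x$densities$f_pos(q)
  fn <- x$densities$f_neg(q)
  plot(q, fp, type = "l", col = "steelblue", lwd = 2,
       xlab = "functional score", ylab = "density",
       main = "Reference score densities", ylim = range(c(fp, fn)), ...)
  lines(q, fn, col = "forestgreen", lwd = 2)
  legend("topright", legend = c("pathogenic", "benign"),
         col = c("steelblue", "forestgreen"), lwd = 2, bty = "n")
  invisible(x)
}
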