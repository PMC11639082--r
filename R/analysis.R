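# Map-level statistical analyses: positional summaries, annotation
# stratifications, moving-window stability correlation, hotspot tests,
# case-control odds ratios.

#' CHK2 kinase-motif mutational hotspot positions
#'
#' The 16 hotspot positions falling inside named kinase motifs
#' (GxGxxG: 227, 229, 232; VAIK: 246-249; HRD: 345-347; DFG: 368-370;
#' APE: 392-394), and optionally the additional named hotspot positions
#' outside those motifs that the map found damaging (352, 354, 386; the
#' remaining non-motif hotspots are not individually published).
#'
#' @param extras include the non-motif hotspot positions.
#' @return data.frame with `position` and `hotspot_motif`.
#' @export
chk2_hotspots <- function(extras = FALSE) {
  motif <- data.frame(
    position = c(227L, 229L, 232L, 246:249, 345:347, 368:370, 392:394),
    hotspot_motif = c(rep("GxGxxG", 3), rep("VAIK", 4), rep("HRD", 3),
                      rep("DFG", 3), rep("APE", 3)),
    stringsAsFactors = FALSE)
  if (!extras) return(motif)
  rbind(motif, data.frame(position = c(352L, 354L, 386L),
                          hotspot_motif = c("HRD+5", "HRD+7", "APE-6"),
                          stringsAsFactors = FALSE))
}

#' CHK2 domain boundaries
#'
#' Forkhead-associated (FHA) domain residues 92-205 and kinase domain
#' residues 212-501.
#'
#' @param positions residue indices to label.
#' @return character vector `"FHA"`, `"kinase"` or `"other"`.
#' @export
chk2_domain <- function(positions) {
  ifelse(positions >= 92 & positions <= 205, "FHA",
         ifelse(positions >= 212 & positions <= 501, "kinase", "other"))
}

as_score_df <- function(scores) {
  if (inherits(scores, "mave_scores")) scores$scores else scores
}

#' Median missense score per position
#'
#' @param scores a `mave_scores` object or score data.frame.
#' @param classes variant classes included (default missense only).
#' @return data.frame with `position` and `median_score`; positions with
#'   no scored substitutions are absent.
#' @export
positional_median <- function(scores, classes = "missense") {
  df <- as_score_df(scores)
  df <- df[df$vclass %in% classes & is.finite(df$score), , drop = FALSE]
  med <- tapply(df$score, df$position, stats::median)
  data.frame(position = as.integer(names(med)),
             median_score = as.numeric(med), row.names = NULL)
}

#' Compare two score groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test plus the absolute difference of group
#' medians. The exact null distribution is used when both groups have at
#' most 25 values and there are no ties; otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param scores_a,scores_b numeric vectors.
#' @return list with `delta_median` (absolute), `p`, `statistic` (the
#'   rank-sum W of the first group) and `exact` (logical).
#' @export
group_compare <- function(scores_a, scores_b) {
  scores_a <- scores_a[is.finite(scores_a)]
  scores_b <- scores_b[is.finite(scores_b)]
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both groups must contain at least one value")
  }
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  exact <- length(scores_a) <= 25 && length(scores_b) <= 25 && !ties
  wt <- stats::wilcox.test(scores_a, scores_b, exact = exact,
                           correct = TRUE)
  list(delta_median = abs(stats::median(scores_a) - stats::median(scores_b)),
       p = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}

#' Moving-window median correlation between two positional tracks
#'
#' Takes the median of each track within windows of `width` consecutive
#' positions moved by `step`, then reports the Spearman correlation of
#' the windowed medians (used e.g. to relate positional functional scores
#' to predicted folding-energy changes).
#'
#' @param x,y data.frames with `position` and a value column (second
#'   column), or named numeric vectors keyed by position.
#' @param width window width in positions (>= 2).
#' @param step window step.
#' @return list with `windows` (start, median_x, median_y), `rho`, `p`;
#'   `rho` is `NA` with a message when a track is constant.
#' @export
moving_window_correlation <- function(x, y, width = 10, step = 1) {
  if (width < 2) stop("width must be >= 2")
  tx <- as_track(x); ty <- as_track(y)
  common <- sort(intersect(names(tx), names(ty)))
  if (length(common) < width) stop("fewer common positions than the window width")
  pos <- as.integer(common)
  tx <- tx[common]; ty <- ty[common]
  starts <- seq(min(pos), max(pos) - width + 1L, by = step)
  med <- function(track, s) {
    in_win <- pos >= s & pos < s + width
    if (!any(in_win)) return(NA_real_)
    stats::median(track[in_win])
  }
  mx <- vapply(starts, med, 0, track = tx)
  my <- vapply(starts, med, 0, track = ty)
  ok <- is.finite(mx) & is.finite(my)
  windows <- data.frame(start = starts, median_x = mx, median_y = my)
  if (stats::sd(mx[ok]) == 0 || stats::sd(my[ok]) == 0) {
    message("constant track: correlation undefined")
    return(list(windows = windows, rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(mx[ok], my[ok], method = "spearman"))
  list(windows = windows, rho = unname(ct$estimate), p = ct$p.value)
}

as_track <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("position" %in% names(x))
    val_col <- setdiff(names(x), "position")[1]
    stats::setNames(x[[val_col]], x$position)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Annotation-stratified score comparison
#'
#' Forms two strata from a per-position annotation track using the
#' published thresholds and compares their scores with [group_compare()].
#' Conservation (`"conservation"`): positions with grade below -0.47 are
#' conserved, above 0.91 not conserved; compared on positional median
#' scores. Solvent accessibility (`"rsa"`): side-chain relative
#' accessibility below 20 percent is inaccessible, above 50 accessible;
#' compared on per-variant scores at those positions.
#'
#' @param scores a `mave_scores` object or score data.frame.
#' @param annotations data.frame with `position` plus `conservation`
#'   and/or `rsa` columns.
#' @param stratify `"conservation"` or `"rsa"`.
#' @param domain optional domain filter (`"FHA"`, `"kinase"`) applied via
#'   [chk2_domain()] before stratifying.
#' @param thresholds stratum cutpoints `c(low, high)`; positions between
#'   them are dropped.
#' @return [group_compare()] result plus the stratum sizes; the first
#'   group is the low-annotation stratum (conserved / inaccessible).
#' @export
stratified_comparison <- function(scores, annotations,
                                  stratify = c("conservation", "rsa"),
                                  domain = NULL, thresholds = NULL) {
  stratify <- match.arg(stratify)
  df <- as_score_df(scores)
  stopifnot("position" %in% names(annotations),
            stratify %in% names(annotations))
  if (is.null(thresholds)) {
    thresholds <- switch(stratify, conservation = c(-0.47, 0.91),
                         rsa = c(20, 50))
  }
  if (!is.null(domain)) {
    annotations <- annotations[chk2_domain(annotations$position) %in% domain, ]
  }
  val <- annotations[[stratify]]
  low_pos <- annotations$position[!is.na(val) & val < thresholds[1]]
  high_pos <- annotations$position[!is.na(val) & val > thresholds[2]]
  if (length(low_pos) == 0L || length(high_pos) == 0L) {
    stop("empty stratum: thresholds leave no positions on one side")
  }
  if (stratify == "conservation") {
    pm <- positional_median(df)
    a <- pm$median_score[pm$position %in% low_pos]
    b <- pm$median_score[pm$position %in% high_pos]
  } else {
    mis <- df[df$vclass == "missense", ]
    a <- mis$score[mis$position %in% low_pos]
    b <- mis$score[mis$position %in% high_pos]
  }
  if (length(a) == 0L || length(b) == 0L) stop("empty stratum after score join")
  res <- group_compare(a, b)
  res$n <- c(low = length(a), high = length(b))
  res
}

#' Odds ratio with Fisher's exact test
#'
#' For a 2x2 carriers/non-carriers by cases/controls table, returns the
#' cross-product odds ratio `(a d) / (b c)` (with a Haldane 0.5
#' continuity correction if any cell is zero, flagged in the output) and
#' the two-sided Fisher exact p value.
#'
#' @param a,b,c,d cell counts: `a` = case carriers, `b` = control
#'   carriers, `c` = case non-carriers, `d` = control non-carriers.
#'   Alternatively `a` may be a 2x2 matrix.
#' @return list with `or`, `p`, `corrected` (logical).
#' @export
contingency_odds <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(m < 0) || any(m != round(m))) stop("cell counts must be non-negative integers")
  if (sum(m) == 0) stop("empty table")
  corrected <- any(m == 0)
  mm <- if (corrected) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  p <- stats::fisher.test(m)$p.value
  list(or = or, p = p, corrected = corrected)
}

#' Composition summary of a score map
#'
#' Counts scored variants per class, the fraction of missense variants
#' above the damaging threshold (synonymous-like) and below the
#' nonsense-like threshold, nonsense score means split at a C-terminal
#' cutoff, and coverage relative to all possible and (when a CDS is
#' supplied) single-nucleotide-variant-reachable substitutions.
#'
#' @param scores a `mave_scores` object or score data.frame.
#' @param damaging score threshold separating damaging from tolerated
#'   (default 0.5).
#' @param nonsense_like threshold under which scores look nonsense-like
#'   (default 0.2).
#' @param cterm_cutoff position splitting the nonsense summary (e.g. 489);
#'   `NULL` skips the split.
#' @param cds optional coding sequence for SNV-reachable coverage.
#' @param n_positions protein length used for the all-possible
#'   denominator; inferred from the data when `NULL`.
#' @return list of class `map_summary`.
#' @export
map_summary <- function(scores, damaging = 0.5, nonsense_like = 0.2,
                        cterm_cutoff = NULL, cds = NULL, n_positions = NULL) {
  df <- as_score_df(scores)
  if (nrow(df) == 0L) {
    return(structure(list(n_missense = 0L, n_nonsense = 0L,
                          n_synonymous = 0L, frac_above_damaging = 0,
                          frac_below_nonsense_like = 0,
                          damaging = damaging, nonsense_like = nonsense_like),
                     class = "map_summary"))
  }
  mis <- df[df$vclass == "missense", ]
  out <- list(
    n_missense = nrow(mis),
    n_nonsense = sum(df$vclass == "nonsense"),
    n_synonymous = sum(df$vclass == "synonymous"),
    frac_above_damaging = mean(mis$score > damaging),
    frac_below_nonsense_like = mean(mis$score < nonsense_like),
    damaging = damaging, nonsense_like = nonsense_like)
  non <- df[df$vclass == "nonsense", ]
  if (!is.null(cterm_cutoff) && nrow(non)) {
    early <- non$score[non$position <= cterm_cutoff]
    late <- non$score[non$position > cterm_cutoff]
    out$nonsense_early <- c(mean = mean(early), sd = stats::sd(early),
                            n = length(early))
    out$nonsense_late <- c(mean = mean(late), sd = stats::sd(late),
                           n = length(late))
    out$n_damaging_nonsense_early <- sum(early < damaging)
    out$cterm_cutoff <- cterm_cutoff
  }
  np <- n_positions %||% max(df$position)
  # all possible substitutions: 19 per position, initiator Met excluded
  out$n_possible <- 19L * (np - 1L)
  out$coverage_all <- nrow(mis[mis$position > 1, ]) / out$n_possible
  if (!is.null(cds)) {
    reach <- snv_reachable(cds)
    out$n_snv_reachable <- nrow(reach)
    key <- paste(mis$position, mis$ref_aa, mis$alt_aa)
    out$coverage_snv <- mean(paste(reach$position, reach$ref_aa,
                                   reach$alt_aa) %in% key)
  }
  structure(out, class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Map composition\n")
  cat("  missense:", x$n_missense, " nonsense:", x$n_nonsense,
      " synonymous:", x$n_synonymous, "\n")
  cat(sprintf("  %.1f%% of missense above %.2f; %.1f%% below %.2f\n",
              100 * x$frac_above_damaging, x$damaging,
              100 * x$frac_below_nonsense_like, x$nonsense_like))
  if (!is.null(x$nonsense_early)) {
    cat(sprintf("  nonsense <= %d: mean %.2f (sd %.2f, n %d); > %d: mean %.2f (sd %.2f, n %d)\n",
                x$cterm_cutoff, x$nonsense_early["mean"],
                x$nonsense_early["sd"], as.integer(x$nonsense_early["n"]),
                x$cterm_cutoff, x$nonsense_late["mean"],
                x$nonsense_late["sd"], as.integer(x$nonsense_late["n"])))
  }
  cat(sprintf("  coverage: %.1f%% of all possible substitutions\n",
              100 * x$coverage_all))
  if (!is.null(x$coverage_snv)) {
    cat(sprintf("  %.1f%% of %d SNV-reachable substitutions\n",
                100 * x$coverage_snv, x$n_snv_reachable))
  }
  invisible(x)
}
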