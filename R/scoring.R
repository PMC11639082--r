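#' Scoring configuration
#'
#' Thresholds and numerical settings of the score pipeline. Defaults are
#' the assay's published filter settings where stated (minimum of 10
#' pre-selection reads; replicate divergence beyond 3x the Poisson
#' expectation) and documented choices elsewhere.
#'
#' @param min_pre_reads minimum pre-selection marginal count; variants
#'   below it are flagged `low_pre_reads`.
#' @param alpha significance level of the one-sided exact Poisson test
#'   that a variant's pre-selection count exceeds the wild-type-control
#'   error rate; non-significant variants are flagged
#'   `wt_indistinguishable`.
#' @param divergence_factor replicates whose enrichment log ratios differ
#'   by more than this multiple of their Poisson (delta-method) standard
#'   deviation flag the variant `replicate_divergent`.
#' @param nonsense_cterm_cutoff last position whose nonsense variants
#'   anchor the 0 end of the score scale (e.g. 489 for CHK2, where
#'   C-terminal truncations retain function); `NULL` uses all nonsense
#'   variants. Nonsense variants beyond the cutoff are flagged
#'   `c_terminal_nonsense` but still scored.
#' @param floor_pseudo pseudo-reads substituted when the corrected
#'   post-selection frequency is non-positive: the frequency floor is
#'   `floor_pseudo / effective depth`, giving fully depleted variants a
#'   finite, strongly negative log ratio.
#' @param log_base base of the enrichment log ratio. Immaterial after
#'   rescaling (the anchors cancel it); natural log by default.
#' @param nu0 pseudo-degrees-of-freedom of the Baldi-Long variance prior.
#' @param B bootstrap iterations for calibration-anchor error
#'   propagation.
#' @param seed seed of the bootstrap resampling.
#' @param bootstrap_calibration propagate the uncertainty of the
#'   synonymous/nonsense calibration medians into each score's standard
#'   error (on by default; off reduces the error to the regularized
#'   replicate component).
#' @return an object of class `score_config`.
#' @export
score_config <- function(min_pre_reads = 10, alpha = 0.05,
                         divergence_factor = 3,
                         nonsense_cterm_cutoff = NULL,
                         floor_pseudo = 0.5, log_base = exp(1),
                         nu0 = 3, B = 1000, seed = 42,
                         bootstrap_calibration = TRUE) {
  stopifnot(min_pre_reads >= 0, alpha > 0, alpha < 1,
            divergence_factor > 0, floor_pseudo > 0, log_base > 1,
            nu0 >= 0, B >= 100)
  structure(list(min_pre_reads = min_pre_reads, alpha = alpha,
                 divergence_factor = divergence_factor,
                 nonsense_cterm_cutoff = nonsense_cterm_cutoff,
                 floor_pseudo = floor_pseudo, log_base = log_base,
                 nu0 = nu0, B = as.integer(B), seed = as.integer(seed),
                 bootstrap_calibration = bootstrap_calibration),
            class = "score_config")
}

#' Wild-type-corrected enrichment log ratio
#'
#' Subtracts the wild-type-control frequency from the pre- and
#' post-selection frequencies and returns the log ratio of the corrected
#' frequencies. A non-positive corrected post-selection frequency is
#' floored at `floor_pseudo / post_depth` (half a pseudo-read by
#' default); a non-positive corrected pre-selection frequency yields `NA`
#' (such variants are indistinguishable from wild-type sequencing error
#' and are filtered upstream).
#'
#' @param phi_pre,phi_post,phi_wt frequencies (vectorized).
#' @param post_depth effective depth of the post-selection library, used
#'   by the floor rule.
#' @param floor_pseudo pseudo-read count of the floor rule.
#' @param base log base.
#' @return numeric vector of log ratios.
#' @export
corrected_log_ratio <- function(phi_pre, phi_post, phi_wt,
                                post_depth = 1e6, floor_pseudo = 0.5,
                                base = exp(1)) {
  cpre <- phi_pre - phi_wt
  cpost <- phi_post - phi_wt
  floor_val <- floor_pseudo / post_depth
  cpost <- ifelse(cpost <= 0, floor_val, cpost)
  out <- rep(NA_real_, length(cpre))
  pos <- which(cpre > 0)
  out[pos] <- log(cpost[pos] / cpre[pos], base = base)
  out
}

#' Rescale log ratios to the synonymous/nonsense score scale
#'
#' Affine rescaling so that the median of the synonymous calibration set
#' maps to 1 and the median of the nonsense calibration set maps to 0.
#'
#' @param log_phi log ratios to rescale.
#' @param syn_log_phi,nonsense_log_phi calibration sets (log ratios of
#'   synonymous and of eligible nonsense variants).
#' @return rescaled scores.
#' @export
rescale_scores <- function(log_phi, syn_log_phi, nonsense_log_phi) {
  if (length(syn_log_phi) == 0L || length(nonsense_log_phi) == 0L) {
    stop("calibration failure: empty synonymous or nonsense calibration set")
  }
  ms <- stats::median(syn_log_phi, na.rm = TRUE)
  mn <- stats::median(nonsense_log_phi, na.rm = TRUE)
  if (!is.finite(ms) || !is.finite(mn) || ms == mn) {
    stop("calibration failure: synonymous and nonsense medians coincide")
  }
  (log_phi - mn) / (ms - mn)
}

#' Baldi-Long regularization of replicate variance
#'
#' Shrinks each variant's between-replicate variance toward a prior
#' variance that depends on read support:
#' `(nu0 * sigma0^2 + (n - 1) * s^2) / (nu0 + n - 1)`.
#' When no prior is supplied, `sigma0^2(support)` is fitted across
#' variants by a monotone-decreasing (isotonic) regression of the raw
#' variances on log10 read support, reflecting that better-supported
#' variants are measured more precisely.
#'
#' @param raw_sd per-variant between-replicate standard deviations.
#' @param read_support per-variant read support (e.g. summed
#'   pre-selection counts).
#' @param pseudo_df prior pseudo-degrees-of-freedom `nu0`.
#' @param n_rep replicate count per variant (scalar or vector).
#' @param prior_var optional prior variance: a scalar, a vector matching
#'   `raw_sd`, or `NULL` to fit the monotone prior.
#' @return numeric vector of regularized standard errors (per-replicate
#'   scale); the fitted prior variance is attached as attribute
#'   `"prior_var"`.
#' @export
regularize_errors <- function(raw_sd, read_support = NULL, pseudo_df = 3,
                              n_rep = 2, prior_var = NULL) {
  if (any(raw_sd < 0, na.rm = TRUE)) {
    stop("data error: negative standard deviation input")
  }
  s2 <- raw_sd^2
  if (is.null(prior_var)) {
    if (is.null(read_support)) {
      stop("read_support is required to fit the variance prior")
    }
    prior_var <- fit_variance_prior(s2, read_support)
  }
  prior_var <- rep_len(prior_var, length(s2))
  n_rep <- rep_len(n_rep, length(s2))
  s2_obs <- ifelse(is.na(s2), 0, s2)
  n_eff <- ifelse(is.na(s2), 1, n_rep)
  reg <- (pseudo_df * prior_var + (n_eff - 1) * s2_obs) /
    pmax(pseudo_df + n_eff - 1, .Machine$double.eps)
  out <- sqrt(reg)
  attr(out, "prior_var") <- prior_var
  out
}

# monotone-decreasing prior variance as a function of log10 read support,
# fitted by isotonic regression (on the negated support axis)
fit_variance_prior <- function(s2, support) {
  ok <- is.finite(s2) & is.finite(support)
  if (sum(ok) < 2L) return(rep(stats::median(s2, na.rm = TRUE), length(s2)))
  x <- -log10(support[ok] + 1)
  iso <- stats::isoreg(x, s2[ok])
  # collapse duplicated support values (block means preserve monotonicity)
  xs <- sort(iso$x)
  yf <- iso$yf
  ux <- unique(xs)
  uy <- as.numeric(tapply(yf, match(xs, ux), mean))
  f <- if (length(ux) == 1L) function(z) rep(uy, length(z)) else
    stats::approxfun(ux, uy, rule = 2)
  pmax(f(-log10(support + 1)), 1e-12)
}

#' Bootstrap standard error of a variant score
#'
#' Resamples replicate-level log ratios (and, when supplied, the
#' synonymous and nonsense calibration sets whose medians anchor the
#' score scale) and returns the standard deviation of the resulting
#' rescaled score. When only replicates are resampled, the small-sample
#' bias of the bootstrap SE of a mean is corrected by `sqrt(n / (n-1))`.
#'
#' @param replicate_scores the variant's per-replicate values (rescaled
#'   scores, or log ratios when calibration sets are supplied).
#' @param B bootstrap iterations (>= 100).
#' @param seed RNG seed.
#' @param syn,nonsense optional calibration sets (log ratios); when given,
#'   their medians are re-estimated in every bootstrap draw and
#'   `replicate_scores` are interpreted as log ratios to be rescaled.
#' @return bootstrap standard error; `NA` (with a warning) for a single
#'   replicate.
#' @export
bootstrap_se <- function(replicate_scores, B = 1000, seed = 1,
                         syn = NULL, nonsense = NULL) {
  if (B < 100) stop("config error: B must be >= 100")
  n <- length(replicate_scores)
  if (n < 2L && is.null(syn)) {
    warning("single replicate: bootstrap SE unavailable, falling back to regularized SE")
    return(NA_real_)
  }
  set.seed(seed)
  means <- colMeans(matrix(sample(replicate_scores, n * B, replace = TRUE),
                           nrow = n))
  if (is.null(syn)) {
    return(stats::sd(means) * sqrt(n / (n - 1)))
  }
  ms <- apply(matrix(sample(syn, length(syn) * B, replace = TRUE),
                     nrow = length(syn)), 2, stats::median)
  mn <- apply(matrix(sample(nonsense, length(nonsense) * B, replace = TRUE),
                     nrow = length(nonsense)), 2, stats::median)
  stats::sd((means - mn) / (ms - mn))
}

#' Inverse-variance weighted replicate aggregation
#'
#' @param scores per-replicate (or per-codon-change) score estimates.
#' @param variances their variances; equal variances reduce to a simple
#'   mean.
#' @return list with the weighted mean `score` and combined variance
#'   `var` (`1 / sum(1/variances)`).
#' @export
aggregate_replicates <- function(scores, variances) {
  stopifnot(length(scores) == length(variances))
  ok <- is.finite(scores) & is.finite(variances) & variances >= 0
  scores <- scores[ok]; variances <- variances[ok]
  if (length(scores) == 0L) stop("no usable replicate scores to aggregate")
  if (any(variances == 0)) {
    zero <- variances == 0
    return(list(score = mean(scores[zero]), var = 0))
  }
  w <- 1 / variances
  list(score = sum(w * scores) / sum(w), var = 1 / sum(w))
}

# ---- internal assembly -----------------------------------------------------

# long count table -> wide per (region, codon change, replicate) with
# pre/post/wt counts, depths and frequencies
build_wide_counts <- function(counts) {
  need <- c("condition", "replicate", "codon_index", "ref_codon",
            "alt_codon", "count", "depth")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"region" %in% names(counts)) counts$region <- 1L
  key <- function(d) paste(d$region, d$codon_index, d$alt_codon, d$replicate)
  split_cond <- split(counts, counts$condition)
  if (!all(c("pre", "post", "wt_control") %in% names(split_cond))) {
    stop("count table must contain pre, post and wt_control conditions")
  }
  pre <- split_cond$pre; post <- split_cond$post; wt <- split_cond$wt_control
  wide <- pre[, c("region", "codon_index", "ref_codon", "alt_codon",
                  "replicate")]
  wide$pre_count <- pre$count
  wide$pre_depth <- pre$depth
  i_post <- match(key(pre), key(post))
  if (anyNA(i_post)) {
    warning(sum(is.na(i_post)), " variant-replicate(s) missing a ",
            "post-selection record were dropped")
  }
  wide$post_count <- post$count[i_post]
  wide$post_depth <- post$depth[i_post]
  i_wt <- match(key(pre), key(wt))
  if (anyNA(i_wt)) {
    # fall back to a single shared wt control replicate
    wkey <- paste(wt$region, wt$codon_index, wt$alt_codon)
    i_wt2 <- match(paste(pre$region, pre$codon_index, pre$alt_codon), wkey)
    if (anyNA(i_wt2)) {
      stop("missing WT control counts for ",
           sum(is.na(i_wt2)), " variant(s)")
    }
    i_wt <- ifelse(is.na(i_wt), i_wt2, i_wt)
  }
  wide$wt_count <- wt$count[i_wt]
  wide$wt_depth <- wt$depth[i_wt]
  wide <- wide[!is.na(wide$post_count), , drop = FALSE]
  wide$phi_pre <- wide$pre_count / wide$pre_depth
  wide$phi_post <- wide$post_count / wide$post_depth
  wide$phi_wt <- wide$wt_count / wide$wt_depth
  wide$vclass <- classify_codon_change(wide$ref_codon, wide$alt_codon)
  rownames(wide) <- NULL
  wide
}

#' Quality-control filters on a count table
#'
#' Applies the three read-level filters to each variant-replicate record:
#' `low_pre_reads` (pre-selection marginal count below the minimum),
#' `wt_indistinguishable` (pre-selection count not significantly above
#' the wild-type-control miscall rate by a one-sided exact Poisson test,
#' or corrected pre-selection frequency non-positive) and
#' `replicate_divergent` (any two replicate log ratios further apart than
#' `divergence_factor` times their Poisson delta-method standard
#' deviation; flags all replicates of the variant). The filters are
#' independent of one another, so the flag set does not depend on the
#' order in which they are considered.
#'
#' @param counts long count table (see [variant_scores()]).
#' @param config a [score_config()].
#' @return wide per-(codon change, replicate) table with frequency
#'   columns, `log_phi`, and logical flag columns.
#' @export
qc_filters <- function(counts, config = score_config()) {
  wide <- build_wide_counts(counts)
  wide$log_phi <- corrected_log_ratio(wide$phi_pre, wide$phi_post,
                                      wide$phi_wt, wide$post_depth,
                                      config$floor_pseudo, config$log_base)
  wide$low_pre_reads <- wide$pre_count < config$min_pre_reads
  # one-sided exact Poisson test of pre count vs wt rate scaled to pre depth
  lambda0 <- wide$phi_wt * wide$pre_depth
  p_wt <- stats::ppois(wide$pre_count - 1, lambda0, lower.tail = FALSE)
  wide$wt_indistinguishable <- p_wt >= config$alpha |
    (wide$phi_pre - wide$phi_wt) <= 0
  wide$replicate_divergent <- flag_divergent(wide, config)
  wide
}

# replicate divergence: pairwise |delta log_phi| (natural-log scale)
# against divergence_factor x Poisson delta-method SD
flag_divergent <- function(wide, config) {
  vkey <- paste(wide$region, wide$codon_index, wide$alt_codon)
  ln_scale <- log(config$log_base)
  post_eff <- pmax(wide$post_count, config$floor_pseudo)
  var_nat <- 1 / pmax(wide$pre_count, 0.5) + 1 / post_eff
  flag <- logical(nrow(wide))
  for (idx in split(seq_len(nrow(wide)), vkey)) {
    if (length(idx) < 2L) next
    lp <- wide$log_phi[idx] * ln_scale
    if (anyNA(lp)) next
    pairs <- utils::combn(seq_along(idx), 2)
    d <- abs(lp[pairs[1, ]] - lp[pairs[2, ]])
    sd_pair <- sqrt(var_nat[idx][pairs[1, ]] + var_nat[idx][pairs[2, ]])
    if (any(d > config$divergence_factor * sd_pair)) flag[idx] <- TRUE
  }
  flag
}

#' Fit functional scores from tile-seq counts
#'
#' The central fitting function: converts a long marginal-count table
#' (conditions `pre`, `post`, `wt_control`; >= 2 replicates) into an
#' amino-acid-level functional score map. Stages: frequencies and
#' wild-type-corrected enrichment log ratios per codon change and
#' replicate; quality filters ([qc_filters()]); per-replicate affine
#' rescaling so the synonymous median is 1 and the (position-eligible)
#' nonsense median is 0; Baldi-Long regularization of replicate variance
#' ([regularize_errors()]); bootstrap propagation of calibration-anchor
#' uncertainty; inverse-variance aggregation of replicates and of codon
#' changes encoding the same amino-acid change.
#'
#' @param counts data.frame with columns `condition`, `replicate`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `count`, `depth` and
#'   optionally `region` (rescaling is done within regions).
#' @param config a [score_config()].
#' @return object of class `mave_scores`: list with `scores` (released
#'   map: `hgvs_pro`, `position`, `ref_aa`, `alt_aa`, `vclass`, `score`,
#'   `se`, `df`, `flags`), `audit` (all codon-change records incl.
#'   filtered ones with flag strings), `calibration` (per region/replicate
#'   anchor medians) and `config`.
#' @seealso [hiq_filter()], [map_summary()], [llr_calibrate()]
#' @export
variant_scores <- function(counts, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  wide <- qc_filters(counts, config)
  wide$position <- wide$codon_index
  wide$ref_aa <- translate_codons(wide$ref_codon)
  wide$alt_aa <- translate_codons(wide$alt_codon)
  cutoff <- config$nonsense_cterm_cutoff
  wide$cal_nonsense <- wide$vclass == "nonsense" &
    (is.null(cutoff) | wide$position <= (cutoff %||% Inf))
  wide$c_terminal_nonsense <- wide$vclass == "nonsense" & !wide$cal_nonsense
  wide$rec_ok <- !wide$low_pre_reads & !wide$wt_indistinguishable &
    !wide$replicate_divergent & !is.na(wide$log_phi)

  # per (region, replicate) calibration medians from unflagged records
  grp <- interaction(wide$region, wide$replicate, drop = TRUE)
  cal <- lapply(levels(grp), function(g) {
    rows <- wide[grp == g & wide$rec_ok, ]
    syn <- rows$log_phi[rows$vclass == "synonymous"]
    non <- rows$log_phi[rows$cal_nonsense]
    if (length(syn) == 0L || length(non) == 0L) {
      stop("calibration failure: region/replicate ", g,
           " lacks synonymous or nonsense variants")
    }
    ms <- stats::median(syn); mn <- stats::median(non)
    if (ms == mn) stop("calibration failure: anchors coincide in ", g)
    list(group = g, syn = syn, non = non, ms = ms, mn = mn)
  })
  names(cal) <- levels(grp)
  ms_of <- vapply(cal, `[[`, 0, "ms")[as.character(grp)]
  mn_of <- vapply(cal, `[[`, 0, "mn")[as.character(grp)]
  wide$score_rep <- (wide$log_phi - mn_of) / (ms_of - mn_of)

  # variant (codon-change) level aggregation over unflagged replicates
  ok <- wide[wide$rec_ok, , drop = FALSE]
  vkey <- paste(ok$region, ok$codon_index, ok$alt_codon)
  idx <- split(seq_len(nrow(ok)), vkey)
  vt <- data.frame(vkey = names(idx), stringsAsFactors = FALSE)
  first <- vapply(idx, `[`, 0L, 1L)
  for (col in c("region", "codon_index", "ref_codon", "alt_codon",
                "position", "ref_aa", "alt_aa", "vclass",
                "c_terminal_nonsense")) {
    vt[[col]] <- ok[[col]][first]
  }
  vt$n_rep <- lengths(idx)
  vt$mean_score <- vapply(idx, function(i) mean(ok$score_rep[i]), 0)
  vt$raw_sd <- vapply(idx, function(i)
    if (length(i) > 1) stats::sd(ok$score_rep[i]) else NA_real_, 0)
  vt$support <- vapply(idx, function(i) sum(ok$pre_count[i]), 0)

  reg_se <- regularize_errors(vt$raw_sd, vt$support,
                              pseudo_df = config$nu0, n_rep = vt$n_rep)
  vt$var_rep <- as.numeric(reg_se)^2 / vt$n_rep

  # calibration-anchor uncertainty by bootstrap, shared across variants
  if (config$bootstrap_calibration) {
    vt$var_cal <- calibration_bootstrap_var(ok, idx, cal, grp_levels = NULL,
                                            B = config$B, seed = config$seed)
  } else {
    vt$var_cal <- 0
  }
  vt$se <- sqrt(vt$var_rep + vt$var_cal)

  # collapse codon changes encoding the same amino-acid change
  akey <- paste(vt$position, vt$ref_aa, vt$alt_aa)
  aidx <- split(seq_len(nrow(vt)), akey)
  afirst <- vapply(aidx, `[`, 0L, 1L)
  scores <- data.frame(position = vt$position[afirst],
                       ref_aa = vt$ref_aa[afirst],
                       alt_aa = vt$alt_aa[afirst],
                       vclass = vt$vclass[afirst],
                       stringsAsFactors = FALSE)
  agg <- lapply(aidx, function(i)
    aggregate_replicates(vt$mean_score[i], vt$se[i]^2))
  scores$score <- vapply(agg, `[[`, 0, "score")
  scores$se <- sqrt(vapply(agg, `[[`, 0, "var"))
  scores$df <- vapply(aidx, function(i) sum(vt$n_rep[i]), 0)
  scores$flags <- ifelse(vt$c_terminal_nonsense[afirst],
                         "c_terminal_nonsense", "")
  scores$hgvs_pro <- format_protein_variant(scores)
  scores <- scores[order(scores$position, scores$alt_aa), , drop = FALSE]
  rownames(scores) <- NULL

  audit <- wide
  audit$flags <- flag_string(audit)

  calibration <- data.frame(group = names(cal),
                            median_syn = vapply(cal, `[[`, 0, "ms"),
                            median_nonsense = vapply(cal, `[[`, 0, "mn"),
                            n_syn = vapply(cal, function(x) length(x$syn), 0L),
                            n_nonsense = vapply(cal, function(x) length(x$non), 0L),
                            row.names = NULL)
  structure(list(scores = scores, audit = audit, calibration = calibration,
                 config = config),
            class = "mave_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flag_string <- function(wide) {
  f <- cbind(low_pre_reads = wide$low_pre_reads,
             wt_indistinguishable = wide$wt_indistinguishable,
             replicate_divergent = wide$replicate_divergent,
             c_terminal_nonsense = wide$c_terminal_nonsense)
  apply(f, 1, function(r) paste(colnames(f)[which(r)], collapse = ";"))
}

# bootstrap variance contribution of the calibration medians: for each
# (region, replicate) group, resample its synonymous and nonsense sets B
# times, rescale every record's log ratio under each draw, average over
# each variant's replicates, and take the variance across draws.
calibration_bootstrap_var <- function(ok, idx, cal, grp_levels, B, seed) {
  set.seed(seed)
  grp <- as.character(interaction(ok$region, ok$replicate, drop = TRUE))
  boot <- lapply(cal, function(cc) {
    ms_b <- apply(matrix(sample(cc$syn, length(cc$syn) * B, replace = TRUE),
                         ncol = B), 2, stats::median)
    mn_b <- apply(matrix(sample(cc$non, length(cc$non) * B, replace = TRUE),
                         ncol = B), 2, stats::median)
    list(ms = ms_b, mn = mn_b)
  })
  # record x B matrix of rescaled scores under resampled anchors
  mat <- matrix(0, nrow(ok), B)
  for (g in names(boot)) {
    rows <- which(grp == g)
    if (!length(rows)) next
    ms <- boot[[g]]$ms; mn <- boot[[g]]$mn
    mat[rows, ] <- (outer(ok$log_phi[rows], rep(1, B)) -
                      matrix(mn, length(rows), B, byrow = TRUE)) /
      matrix(ms - mn, length(rows), B, byrow = TRUE)
  }
  group_id <- rep(NA_integer_, nrow(ok))
  for (j in seq_along(idx)) group_id[idx[[j]]] <- j
  vmat <- rowsum(mat, group_id) / as.numeric(lengths(idx))
  m1 <- rowMeans(vmat)
  m2 <- rowMeans(vmat^2)
  pmax((m2 - m1^2) * B / (B - 1), 0)
}

#' @export
print.mave_scores <- function(x, ...) {
  cat("Variant effect map:", nrow(x$scores), "scored amino-acid variants\n")
  tab <- table(x$scores$vclass)
  cat("  ", paste(names(tab), tab, collapse = ", "), "\n")
  cat("  filtered codon-change records:",
      sum(x$audit$flags != "" & x$audit$flags != "c_terminal_nonsense"),
      "of", nrow(x$audit), "\n")
  invisible(x)
}

#' @export
summary.mave_scores <- function(object, damaging = 0.5, nonsense_like = 0.2,
                                cterm_cutoff = NULL, cds = NULL, ...) {
  map_summary(object, damaging = damaging, nonsense_like = nonsense_like,
              cterm_cutoff = cterm_cutoff, cds = cds)
}

#' @export
as.data.frame.mave_scores <- function(x, ...) x$scores

#' @export
plot.mave_scores <- function(x, breaks = 40, ...) {
  s <- x$scores
  cls <- c(missense = "grey60", nonsense = "steelblue", synonymous = "forestgreen")
  h <- hist(s$score, breaks = breaks, plot = FALSE)
  plot(h, col = "grey85", border = "white", main = "Functional score map",
       xlab = "functional score", ...)
  for (cl in c("nonsense", "synonymous")) {
    lines(stats::density(s$score[s$vclass == cl], na.rm = TRUE)$x,
          stats::density(s$score[s$vclass == cl], na.rm = TRUE)$y *
            length(s$score) * diff(h$breaks)[1],
          col = cls[cl], lwd = 2)
  }
  abline(v = c(0, 1), lty = 3)
  invisible(x)
}
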