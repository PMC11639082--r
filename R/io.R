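# Readers/writers for the pipeline's file dialects and the end-to-end
# pipeline runner.

SCORE_COLUMN_ALIASES <- list(
  hgvs_pro = c("hgvs_pro", "hgvs_p", "hgvsp", "variant", "hgvs", "mutation"),
  score = c("score", "functional_score", "fitness_score"),
  se = c("se", "sd", "stderr", "error", "score_se"),
  df = c("df", "n_rep", "degrees_of_freedom"),
  flags = c("flags", "filter", "qc_flags")
)

resolve_alias <- function(cols, aliases) {
  hit <- match(aliases, tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit)) cols[hit[1]] else NA_character_
}

#' Read a variant score table
#'
#' Reads a MaveDB-style score CSV: a `hgvs_pro` column (several common
#' aliases are recognized) in HGVS p. notation plus a `score` column and
#' optional `se`, `df` and `flags`. Rows whose variant string does not
#' parse are dropped with a warning naming their line numbers; unknown
#' columns are preserved.
#'
#' @param path CSV file with a header.
#' @return data.frame with `hgvs_pro`, `position`, `ref_aa`, `alt_aa`,
#'   `vclass`, `score` and any further columns.
#' @export
read_score_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcol <- resolve_alias(names(raw), SCORE_COLUMN_ALIASES$hgvs_pro)
  scol <- resolve_alias(names(raw), SCORE_COLUMN_ALIASES$score)
  if (is.na(vcol)) stop("no variant (hgvs_pro) column found in ", path)
  if (is.na(scol)) stop("no score column found in ", path)
  parsed <- lapply(raw[[vcol]], function(s)
    tryCatch(parse_protein_variant(s), error = function(e) NULL))
  bad <- vapply(parsed, is.null, TRUE)
  if (any(bad)) {
    warning("dropped ", sum(bad), " unparseable row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  }
  v <- do.call(rbind, parsed[!bad])
  out <- cbind(v, raw[!bad, setdiff(names(raw), vcol), drop = FALSE])
  names(out)[names(out) == scol] <- "score"
  out$score <- as.numeric(out$score)
  secol <- resolve_alias(names(out), SCORE_COLUMN_ALIASES$se)
  if (!is.na(secol)) {
    names(out)[names(out) == secol] <- "se"
    out$se <- suppressWarnings(as.numeric(out$se))
  }
  rownames(out) <- NULL
  out
}

#' Write a variant score table
#'
#' Deterministic MaveDB-compatible CSV: columns `hgvs_pro`, `score`,
#' `se`, `df`, `flags` (flags as semicolon-joined tokens; missing SE
#' serialized as an empty field), sorted by position then alternate
#' residue, floats at 6 significant digits.
#'
#' @param scores a `mave_scores` object or score data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(scores, path) {
  df <- as_score_df(scores)
  stopifnot(all(c("hgvs_pro", "score") %in% names(df)))
  df <- df[order(df$position, df$alt_aa), , drop = FALSE]
  out <- data.frame(hgvs_pro = df$hgvs_pro,
                    score = signif(df$score, 6),
                    se = if ("se" %in% names(df)) signif(df$se, 6) else NA,
                    df = if ("df" %in% names(df)) df$df else NA,
                    flags = if ("flags" %in% names(df)) df$flags else "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a marginal count table (TSV)
#'
#' Columns: `condition`, `replicate`, `tile`, `codon_index`, `ref_codon`,
#' `alt_codon`, `count`, `depth`.
#'
#' @param counts long count table.
#' @param path TSV path.
#' @return the path (writer) or the table (reader).
#' @export
write_count_table <- function(counts, path) {
  ord <- order(counts$condition, counts$replicate, counts$codon_index,
               counts$alt_codon)
  utils::write.table(counts[ord, , drop = FALSE], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full pipeline on a simulated experiment
#'
#' End-to-end composition: simulate (unless an experiment is supplied),
#' score, HiQ-filter, calibrate LLRs against a reference set, and
#' summarize. Writes versioned artifacts (count TSV, score CSV, HiQ
#' decision log, LLR CSV, summary and manifest JSON) when `out_dir` is
#' given; reruns with the same configuration and seed are byte-identical.
#'
#' @param sim a [sim_config()] or an existing `sim_experiment`.
#' @param score_cfg a [score_config()].
#' @param reference optional reference data.frame (`hgvs_pro`, `label`);
#'   when `NULL`, a synthetic reference is derived from the simulation
#'   truth (damaging truth < 0.2 pathogenic, > 0.8 benign) so the
#'   calibration stage can be exercised.
#' @param out_dir optional output directory.
#' @return list with `experiment`, `fit` (`mave_scores`), `hiq`,
#'   `calibration` (`mave_llr`), `evaluation` (`balanced_pr`), `summary`
#'   and `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), score_cfg = score_config(),
                         reference = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(difftime(Sys.time(), t, units = "secs"))))
    res
  }
  exp <- if (inherits(sim, "sim_experiment")) sim else
    stage("simulate", simulate_experiment(sim))
  fit <- stage("score", variant_scores(exp$counts, score_cfg))
  hiq <- stage("hiq", hiq_filter(fit))
  truth <- truth_table(exp)

  if (is.null(reference)) {
    key <- paste(truth$position, truth$ref_aa, truth$alt_aa)
    mis <- truth[truth$vclass == "missense" &
                   (truth$fitness < 0.2 | truth$fitness > 0.8), ]
    lab <- ifelse(mis$fitness < 0.2, "P", "B")
    scored <- hiq$hiq
    skey <- paste(scored$position, scored$ref_aa, scored$alt_aa)
    i <- match(paste(mis$position, mis$ref_aa, mis$alt_aa), skey)
    reference <- data.frame(hgvs_pro = mis$hgvs_pro[!is.na(i)],
                            score = scored$score[i[!is.na(i)]],
                            label = lab[!is.na(i)])
    # keep the synthetic reference small, as clinical reference sets are
    set.seed(score_cfg$seed)
    if (nrow(reference) > 60L) {
      reference <- reference[sample.int(nrow(reference), 60L), ]
    }
  } else if (!"score" %in% names(reference)) {
    skey <- paste(fit$scores$position, fit$scores$ref_aa, fit$scores$alt_aa)
    rv <- parse_protein_variant(reference$hgvs_pro)
    i <- match(paste(rv$position, rv$ref_aa, rv$alt_aa), skey)
    reference$score <- fit$scores$score[i]
    reference <- reference[!is.na(reference$score), ]
  }
  cal <- stage("calibrate", llr_calibrate(reference))
  eval_pr <- stage("evaluate", balanced_pr(reference$score, reference$label))
  summ <- stage("analyze", map_summary(fit, cds = exp$cds))

  manifest <- list(
    stages = c("simulate", "score", "hiq", "calibrate", "analyze"),
    seed = if (inherits(sim, "sim_experiment")) sim$config$seed else sim$seed,
    score_seed = score_cfg$seed,
    n_scored = nrow(fit$scores), n_hiq = nrow(hiq$hiq),
    hyper_cut = hiq$hyper_cut,
    aubprc = eval_pr$aubprc, r90bp = eval_pr$r90bp,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(exp$counts, file.path(out_dir, "counts.tsv"))
    write_score_table(fit, file.path(out_dir, "scores.csv"))
    utils::write.csv(hiq$decisions, file.path(out_dir, "hiq_decisions.csv"),
                     row.names = FALSE, quote = FALSE)
    # map scores beyond the reference support are clamped by design
    llr <- suppressWarnings(predict(cal, fit$scores))
    llr$llr <- signif(llr$llr, 6)
    utils::write.csv(llr, file.path(out_dir, "llr.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(experiment = exp, fit = fit, hiq = hiq, calibration = cal,
       evaluation = eval_pr, summary = summ, manifest = manifest)
}
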