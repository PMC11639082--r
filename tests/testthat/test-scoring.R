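test_that("wild-type-corrected log ratios follow the floor rule", {
  expect_equal(corrected_log_ratio(1e-4, 1e-4, 0), 0)
  expect_equal(corrected_log_ratio(1e-4, 1e-3, 0, base = 10), 1)
  expect_equal(corrected_log_ratio(1e-4, 1e-3, 0), log(10))
  # corrected post <= 0 floors at half a pseudo-read over depth
  got <- corrected_log_ratio(2e-4, 1e-4, 1e-4, post_depth = 1e6,
                             floor_pseudo = 0.5)
  expect_equal(got, log((0.5 / 1e6) / 1e-4))
  # corrected pre <= 0 yields NA (filtered upstream)
  expect_true(is.na(corrected_log_ratio(1e-4, 2e-4, 1e-4)))
})

test_that("rescaling anchors synonymous and nonsense medians exactly", {
  set.seed(8)
  syn <- rnorm(31, -1, 0.3)
  non <- rnorm(15, -3, 0.4)
  sc_syn <- rescale_scores(syn, syn, non)
  sc_non <- rescale_scores(non, syn, non)
  expect_identical(median(sc_syn), 1)
  expect_identical(median(sc_non), 0)
  expect_equal(rescale_scores(-2, syn_log_phi = c(-1, -1, -1),
                              nonsense_log_phi = c(-3, -3)), 0.5)
  expect_equal(rescale_scores(median(non), syn, non), 0)
  expect_error(rescale_scores(1, c(2, 2), c(2, 2)), "calibration failure")
})

test_that("rescaled map is invariant to the log base of the enrichment ratio", {
  counts <- toy_counts()
  f_e <- variant_scores(counts, score_config(log_base = exp(1), B = 100))
  f_10 <- variant_scores(counts, score_config(log_base = 10, B = 100))
  f_2 <- variant_scores(counts, score_config(log_base = 2, B = 100))
  expect_equal(f_e$scores$score, f_10$scores$score, tolerance = 1e-12)
  expect_equal(f_e$scores$score, f_2$scores$score, tolerance = 1e-12)
})

test_that("Baldi-Long regularization matches the closed-form pooling", {
  # explicit prior: fixed point, no-prior limit, and a hand-computed case
  expect_equal(as.numeric(regularize_errors(0.1, pseudo_df = 3, n_rep = 2,
                                            prior_var = 0.01))^2, 0.01)
  expect_equal(as.numeric(regularize_errors(0.2, pseudo_df = 0, n_rep = 2,
                                            prior_var = 0.01))^2, 0.04)
  got <- as.numeric(regularize_errors(0.2, pseudo_df = 3, n_rep = 2,
                                      prior_var = 0.01))^2
  expect_equal(got, (3 * 0.01 + 1 * 0.04) / 4)  # 0.0175
  expect_error(regularize_errors(c(-0.1, 0.2), prior_var = 0.01), "negative")
})

test_that("fitted variance prior decreases with read support", {
  set.seed(4)
  support <- rep(c(10, 100, 1000, 10000), each = 50)
  s2 <- rexp(200, rate = support / 10)  # variance shrinks with support
  se <- regularize_errors(sqrt(s2), read_support = support, pseudo_df = 3,
                          n_rep = 2)
  prior <- attr(se, "prior_var")
  agg <- tapply(prior, support, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) <= 1e-12))
})

test_that("bootstrap SE matches the closed-form SE of a two-replicate mean", {
  expect_equal(bootstrap_se(c(0.5, 0.5, 0.5), B = 500, seed = 1), 0)
  se <- bootstrap_se(c(0.4, 0.6), B = 2000, seed = 1)
  closed <- sd(c(0.4, 0.6)) / sqrt(2)
  expect_lt(abs(se - closed) / closed, 0.1)
  se2 <- bootstrap_se(c(0.4, 0.6), B = 4000, seed = 2)
  expect_lt(abs(se2 - se) / se, 0.05)
  expect_warning(single <- bootstrap_se(0.4, B = 500, seed = 1), "single replicate")
  expect_true(is.na(single))
})

test_that("bootstrap with degenerate calibration sets returns zero error", {
  se <- bootstrap_se(c(0.2, 0.2), B = 500, seed = 3,
                     syn = rep(-1, 5), nonsense = rep(-4, 5))
  expect_equal(se, 0)
})

test_that("QC filters flag low support, WT-level signal, and divergent replicates", {
  counts <- toy_counts()
  # push one variant's pre counts below 10 reads
  low <- counts$condition == "pre" & counts$codon_index == 5
  counts$count[low] <- 9L
  w <- qc_filters(counts, score_config())
  expect_true(all(w$low_pre_reads[w$codon_index == 5]))
  expect_false(any(w$low_pre_reads[w$codon_index != 5]))

  # pre frequency equal to the WT control at equal depth: indistinguishable
  eq <- toy_counts()
  tgt <- eq$codon_index == 2 & eq$alt_codon == "GAA"
  eq$count[tgt & eq$condition == "pre"] <- 2L
  w2 <- qc_filters(eq, score_config())
  expect_true(all(w2$wt_indistinguishable[w2$codon_index == 2 &
                                            w2$alt_codon == "GAA"]))

  # replicate divergence under the 3x Poisson delta-method rule
  div <- toy_counts()
  sel <- div$codon_index == 3 & div$alt_codon == "CCG" &
    div$condition == "post"
  div$count[sel] <- c(1000L, 1003L)
  pre_sel <- div$codon_index == 3 & div$alt_codon == "CCG" &
    div$condition == "pre"
  div$count[pre_sel] <- 1000L
  w3 <- qc_filters(div, score_config())
  expect_false(any(w3$replicate_divergent[w3$codon_index == 3 &
                                            w3$alt_codon == "CCG"]))
  div$count[sel] <- c(1000L, 1500L)
  w4 <- qc_filters(div, score_config())
  expect_true(all(w4$replicate_divergent[w4$codon_index == 3 &
                                           w4$alt_codon == "CCG"]))
  # hand check: |log 1500/1000| vs 3 * sqrt(sum of 1/counts)
  d <- abs(log(1500 / 1000))
  sd3 <- 3 * sqrt(1 / 1000 + 1 / 1000 + 1 / 1000 + 1 / 1500)
  expect_true(d > sd3)
})

test_that("QC flags are independent of row order", {
  counts <- toy_counts()
  w <- qc_filters(counts, score_config())
  set.seed(1)
  perm <- sample(nrow(counts))
  wp <- qc_filters(counts[perm, ], score_config())
  key <- function(d) paste(d$codon_index, d$alt_codon, d$replicate)
  i <- match(key(w), key(wp))
  for (fl in c("low_pre_reads", "wt_indistinguishable", "replicate_divergent")) {
    expect_identical(w[[fl]], wp[[fl]][i])
  }
})

test_that("missing WT control is a hard error", {
  counts <- toy_counts()
  expect_error(variant_scores(counts[counts$condition != "wt_control", ],
                              score_config()), "wt_control")
})

test_that("inverse-variance aggregation weights replicates correctly", {
  expect_equal(aggregate_replicates(c(0.2, 0.4), c(0.01, 0.01))$score, 0.3)
  got <- aggregate_replicates(c(1.0, 0.0), c(0.01, 0.04))
  expect_equal(got$score, 0.8)
  expect_equal(got$var, 1 / (100 + 25))
  expect_equal(aggregate_replicates(0.7, 0.02)$score, 0.7)
  expect_error(aggregate_replicates(numeric(0), numeric(0)), "no usable")
})

test_that("flagged records are kept in the audit trail, not the released map", {
  counts <- toy_counts()
  low <- counts$condition == "pre" & counts$codon_index == 5
  counts$count[low] <- 5L
  f <- variant_scores(counts, score_config(B = 100))
  expect_false(any(f$scores$position == 5))
  aud <- f$audit[f$audit$codon_index == 5, ]
  expect_true(all(grepl("low_pre_reads", aud$flags)))
})

test_that("C-terminal nonsense variants are excluded from the anchor but scored", {
  e <- simulate_experiment(sim_config(n_positions = 60, tile_size = 30,
                                      depth = 5e4, n_clones = 5e4, seed = 12))
  f <- variant_scores(e$counts, score_config(B = 100,
                                             nonsense_cterm_cutoff = 40))
  non <- f$scores[f$scores$vclass == "nonsense", ]
  late <- non[non$position > 40, ]
  expect_true(nrow(late) > 0)
  expect_true(all(late$flags == "c_terminal_nonsense"))
  expect_true(all(non$flags[non$position <= 40] == ""))
})
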