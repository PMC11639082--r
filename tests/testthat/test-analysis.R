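test_that("positional medians summarize missense scores per residue", {
  df <- data.frame(position = c(10, 10, 10, 11, 11),
                   vclass = c("missense", "missense", "missense",
                              "missense", "synonymous"),
                   score = c(0.1, 0.2, 0.9, 0.4, 1.0))
  pm <- positional_median(df)
  expect_equal(pm$median_score[pm$position == 10], 0.2)
  expect_equal(pm$median_score[pm$position == 11], 0.4)
  expect_false(12 %in% pm$position)
})

test_that("group comparison agrees with exhaustive rank enumeration", {
  g <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_true(g$exact)
  expect_equal(g$p, 0.1)  # 2 of 20 orderings per tail
  expect_equal(g$delta_median, 3)

  set.seed(23)
  for (i in 1:8) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    a <- round(runif(n_a), 3); b <- round(runif(n_b), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(group_compare(a, b)$p, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-10)
  }
})

test_that("identical groups compare as indistinguishable", {
  x <- c(0.2, 0.5, 0.9, 1.2)
  g <- group_compare(x, x)
  expect_equal(g$delta_median, 0)
  expect_gt(g$p, 0.95)
})

test_that("large tied groups fall back to the corrected normal approximation", {
  a <- rep(c(0.1, 0.2), 30)
  b <- rep(c(0.2, 0.3), 30)
  g <- group_compare(a, b)
  expect_false(g$exact)
  expect_lt(g$p, 0.01)
})

test_that("moving-window medians recover exact inverse tracks and reject degenerate ones", {
  pos <- 1:60
  x <- data.frame(position = pos, value = sin(pos / 5) + pos / 30)
  y <- data.frame(position = pos, value = -(sin(pos / 5) + pos / 30))
  mw <- moving_window_correlation(x, y, width = 10)
  expect_equal(mw$rho, -1)
  expect_equal(nrow(mw$windows), 60 - 10 + 1)

  const <- data.frame(position = pos, value = rep(1, 60))
  expect_message(mw0 <- moving_window_correlation(x, const, width = 10),
                 "constant track")
  expect_true(is.na(mw0$rho))
  expect_error(moving_window_correlation(x[1:5, ], y[1:5, ], width = 10),
               "fewer common positions")
})

test_that("windowed Spearman is shift-invariant and recovers planted structure", {
  set.seed(24)
  pos <- 1:150
  base <- cumsum(rnorm(150))
  x <- data.frame(position = pos, value = base)
  y <- data.frame(position = pos, value = -base + rnorm(150, sd = 0.2))
  mw <- moving_window_correlation(x, y, width = 10)
  expect_lt(mw$rho, -0.85)
  y2 <- y; y2$value <- y2$value + 100
  x2 <- x; x2$value <- x2$value + 7
  mw2 <- moving_window_correlation(x2, y2, width = 10)
  expect_equal(mw2$rho, mw$rho, tolerance = 1e-12)
})

test_that("annotation thresholds partition positions into the stated strata", {
  ann <- data.frame(position = 1:5,
                    conservation = c(-1.2, 0.0, 1.0, -0.5, 0.95))
  df <- data.frame(position = rep(1:5, each = 2), vclass = "missense",
                   score = c(0.1, 0.2, 0.5, 0.6, 0.9, 1.0, 0.2, 0.3, 1.1, 0.8))
  # conserved: positions 1, 4 (< -0.47); not conserved: 3, 5 (> 0.91)
  res <- stratified_comparison(df, ann, "conservation")
  expect_equal(unname(res$n), c(2L, 2L))
  pm <- positional_median(df)
  expect_equal(res$delta_median,
               abs(median(pm$median_score[pm$position %in% c(1, 4)]) -
                     median(pm$median_score[pm$position %in% c(3, 5)])))
  expect_error(stratified_comparison(df,
                                     data.frame(position = 1:5,
                                                conservation = rep(0, 5)),
                                     "conservation"),
               "empty stratum")
})

test_that("planted conservation shift is recovered within tolerance", {
  set.seed(25)
  n_pos <- 300
  conserved <- rep(c(TRUE, FALSE), length.out = n_pos)
  ann <- data.frame(position = 1:n_pos,
                    conservation = ifelse(conserved, -1, 1.2))
  score <- ifelse(rep(conserved, each = 5), 0.5, 0.9) + rnorm(5 * n_pos, 0, 0.1)
  df <- data.frame(position = rep(1:n_pos, each = 5), vclass = "missense",
                   score = score)
  res <- stratified_comparison(df, ann, "conservation")
  expect_lt(abs(res$delta_median - 0.4), 0.1)
  expect_lt(res$p, 1e-6)
})

test_that("solvent-accessibility stratification compares per-variant scores", {
  set.seed(26)
  ann <- data.frame(position = 1:100, rsa = rep(c(5, 80), 50))
  df <- data.frame(position = rep(1:100, each = 3), vclass = "missense",
                   score = ifelse(rep(rep(c(TRUE, FALSE), 50), each = 3),
                                  0.3, 0.8) + rnorm(300, 0, 0.05))
  res <- stratified_comparison(df, ann, "rsa")
  expect_equal(sum(res$n), 300L)
  expect_lt(abs(res$delta_median - 0.5), 0.1)
})

test_that("odds ratios match the cross-product and Fisher p the hypergeometric sum", {
  expect_equal(contingency_odds(10, 10, 10, 10)$or, 1.0)
  got <- contingency_odds(4, 1, 1, 4)
  expect_equal(got$or, 16)
  expect_equal(got$p, oracle_fisher_p(4, 1, 1, 4), tolerance = 1e-10)
  # exhaustive agreement over a grid of small tables
  for (a in 0:4) for (b in 0:3) for (cc in 1:3) for (d in 1:3) {
    if (a + b == 0) next
    expect_equal(contingency_odds(a, b, cc, d)$p,
                 oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("zero cells take the Haldane correction and transposition preserves the OR", {
  z <- contingency_odds(5, 0, 3, 4)
  expect_true(z$corrected)
  expect_true(is.finite(z$or) && z$or > 0)
  m <- matrix(c(12, 5, 7, 20), 2, 2)
  expect_equal(contingency_odds(m)$or, contingency_odds(t(m))$or)
  expect_error(contingency_odds(-1, 2, 3, 4), "non-negative")
})

test_that("map summary reports composition fractions and coverage", {
  df <- data.frame(position = 2:5, ref_aa = "A", alt_aa = "V",
                   vclass = "missense", score = c(0.9, 0.6, 0.3, 0.1))
  s <- map_summary(df, n_positions = 5)
  expect_equal(s$n_missense, 4L)
  expect_equal(s$frac_above_damaging, 0.5)
  expect_equal(s$frac_below_nonsense_like, 0.25)
  expect_equal(s$n_possible, 19L * 4L)
  empty <- map_summary(df[0, ])
  expect_equal(empty$n_missense, 0L)
})

test_that("nonsense summary splits at the C-terminal cutoff", {
  df <- data.frame(position = c(10, 20, 480, 495, 500),
                   ref_aa = "Q", alt_aa = "*", vclass = "nonsense",
                   score = c(0.0, 0.1, -0.1, 0.7, 0.8))
  s <- map_summary(df, cterm_cutoff = 489)
  expect_equal(unname(s$nonsense_early["mean"]), 0)
  expect_equal(unname(s$nonsense_late["mean"]), 0.75)
  expect_equal(s$n_damaging_nonsense_early, 3L)
})

test_that("hotspot positions and domain boundaries match the published motifs", {
  hs <- chk2_hotspots()
  expect_equal(nrow(hs), 16L)
  expect_setequal(hs$position[hs$hotspot_motif == "DFG"], 368:370)
  expect_setequal(hs$position[hs$hotspot_motif == "GxGxxG"],
                  c(227, 229, 232))
  expect_equal(nrow(chk2_hotspots(extras = TRUE)), 19L)
  expect_equal(chk2_domain(c(100, 300, 50, 520)),
               c("FHA", "kinase", "other", "other"))
})
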