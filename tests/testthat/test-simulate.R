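small_cfg <- function(seed = 5, depth = 2e4, ...) {
  sim_config(n_positions = 40, tile_size = 20, depth = depth,
             n_clones = 5e4, seed = seed, ...)
}

test_that("identical seeds give bitwise-identical count tables", {
  a <- simulate_experiment(small_cfg())
  b <- simulate_experiment(small_cfg())
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_experiment(small_cfg(seed = 6))
  expect_false(identical(a$counts$count, c2$counts$count))
})

test_that("adding a replicate leaves existing replicates untouched", {
  a <- simulate_experiment(small_cfg())
  b <- simulate_experiment(small_cfg(n_replicates = 3))
  ka <- paste(a$counts$condition, a$counts$replicate, a$counts$codon_index,
              a$counts$alt_codon)
  kb <- paste(b$counts$condition, b$counts$replicate, b$counts$codon_index,
              b$counts$alt_codon)
  i <- match(ka, kb)
  expect_false(anyNA(i))
  expect_identical(a$counts$count, b$counts$count[i])
})

test_that("neutral selection with no error leaves expected frequencies unchanged", {
  cfg <- small_cfg(error_rate = 0, selection_strength = 0,
                   fitness_mixture = c(wt = 1, lof = 0, intermediate = 0, hyper = 0))
  e <- simulate_experiment(cfg)
  pre <- e$counts[e$counts$condition == "pre", ]
  post <- e$counts[e$counts$condition == "post", ]
  expect_equal(e$variants$post_freq, e$variants$lib_freq, tolerance = 1e-12)
  # realized totals agree within Poisson sampling error
  expect_equal(sum(post$count) / sum(post$depth),
               sum(pre$count) / sum(pre$depth), tolerance = 0.05)
  wt <- e$counts[e$counts$condition == "wt_control", ]
  expect_true(all(wt$count == 0))
})

test_that("a lethal variant under absorbing selection never appears post-selection", {
  cfg <- small_cfg(error_rate = 0, enrichment = function(f) as.numeric(f > 0.5))
  e <- simulate_experiment(cfg)
  lethal <- e$variants[e$variants$fitness < 0.5, ]
  post <- e$counts[e$counts$condition == "post", ]
  key <- paste(post$codon_index, post$alt_codon)
  lk <- paste(lethal$position, lethal$alt_codon)
  expect_true(all(post$count[key %in% lk] == 0))
})

test_that("truth table classes and anchor fitness values are consistent", {
  e <- simulate_experiment(small_cfg())
  tt <- truth_table(e)
  expect_true(all(tt$fitness[tt$vclass == "synonymous"] == 1))
  expect_true(all(tt$fitness[tt$vclass == "nonsense"] <= 0.1))
  expect_identical(tt$vclass,
                   ifelse(tt$alt_aa == "*", "nonsense",
                          ifelse(tt$ref_aa == tt$alt_aa, "synonymous",
                                 "missense")))
})

test_that("missense fitness mixture fractions match the configured weights", {
  e <- simulate_experiment(sim_config(n_positions = 300, depth = 1e4,
                                      n_clones = 5e4, seed = 21))
  tt <- truth_table(e)
  mis <- tt$fitness[tt$vclass == "missense"]
  n <- length(mis)
  expect_gt(n, 1500)
  # classify draws back to components by their disjoint supports
  frac <- c(wt = mean(mis > 0.8 & mis < 1.3), lof = mean(mis < 0.2),
            hyper = mean(mis >= 1.3))
  w <- c(wt = 0.6, lof = 0.25, hyper = 0.05)
  for (k in names(w)) {
    ci <- 2.58 * sqrt(w[k] * (1 - w[k]) / n)
    # mixture tails bleed slightly across the 0.2/0.8 cuts; allow that on
    # top of the binomial 99% interval
    expect_lt(abs(frac[k] - w[k]), ci + 0.02)
  }
})

test_that("expected marginal count totals scale linearly with depth", {
  lo <- simulate_experiment(small_cfg(depth = 2e4))
  hi <- simulate_experiment(small_cfg(depth = 8e4))
  r <- sum(hi$counts$count[hi$counts$condition == "pre"]) /
    sum(lo$counts$count[lo$counts$condition == "pre"])
  expect_equal(r, 4, tolerance = 0.1)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(n_positions = 1), "positions")
  expect_error(sim_config(n_replicates = 1), "replicates")
  expect_error(sim_config(mutation_load = 2), "multi-mutant")
  expect_error(sim_config(error_rate = 2), "error_rate")
  expect_error(sim_config(fitness_mixture = c(wt = 1, lof = 1,
                                              intermediate = 0, hyper = 0)),
               "sum to 1")
})

test_that("near-infinite depth with no error recovers latent fitness", {
  cfg <- sim_config(n_positions = 30, tile_size = 30, depth = 1e6,
                    n_clones = 2e5, error_rate = 0, seed = 9)
  e <- simulate_experiment(cfg)
  f <- variant_scores(e$counts, score_config(B = 200))
  s <- f$scores
  tt <- truth_table(e)
  i <- match(paste(s$position, s$ref_aa, s$alt_aa),
             paste(tt$position, tt$ref_aa, tt$alt_aa))
  resid <- s$score - tt$fitness[i]
  expect_lt(stats::quantile(abs(resid), 0.9), 0.05)
})

test_that("the full pipeline recovers latent fitness on a scaled-down run", {
  # 200 positions at 5e4 reads/tile: root-mean-square error of recovered
  # scores vs truth for QC-passing variants, tolerance frozen from a
  # pilot run of this configuration
  e <- simulate_experiment(sim_config(n_positions = 200, depth = 5e4,
                                      seed = 7))
  f <- variant_scores(e$counts, score_config(B = 200))
  s <- f$scores
  tt <- truth_table(e)
  i <- match(paste(s$position, s$ref_aa, s$alt_aa),
             paste(tt$position, tt$ref_aa, tt$alt_aa))
  rmse <- sqrt(mean((s$score - tt$fitness[i])^2))
  expect_lt(rmse, 0.25)
  expect_gt(cor(s$score, tt$fitness[i]), 0.9)
})
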