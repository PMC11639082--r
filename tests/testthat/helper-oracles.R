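# Independent brute-force oracles used to cross-check the implementation.

# exhaustive two-sided Wilcoxon rank-sum p value: enumerate every
# assignment of the pooled values to group A, compare rank sums
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  sums <- apply(combos, 2, function(i) sum(r[i]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# exhaustive two-sided Fisher exact p: enumerate all tables with the
# observed margins, sum hypergeometric probabilities <= observed
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c        # first-column margin (cases)
  n <- b + d
  k <- a + b        # carrier margin
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# scalar double-loop Gaussian kernel density estimate
oracle_kde <- function(q, x, h) {
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    s <- 0
    for (j in seq_along(x)) {
      s <- s + exp(-0.5 * ((q[i] - x[j]) / h)^2) / sqrt(2 * pi)
    }
    out[i] <- s / (length(x) * h)
  }
  out
}

# brute-force balanced PR curve by explicit threshold enumeration
oracle_balanced_pr_points <- function(score, pos) {
  thr <- sort(unique(score))
  do.call(rbind, lapply(thr, function(t) {
    tp <- sum(score[pos] <= t); fn <- sum(score[pos] > t)
    fp <- sum(score[!pos] <= t); tn <- sum(score[!pos] > t)
    sens <- tp / (tp + fn); fpr <- fp / (fp + tn)
    data.frame(threshold = t, recall = sens,
               balanced_precision = if (sens + fpr > 0) sens / (sens + fpr) else NA)
  }))
}

# small deterministic count table built by hand around known frequencies
toy_counts <- function() {
  grid <- expand.grid(condition = c("pre", "post", "wt_control"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  vars <- data.frame(codon_index = c(2L, 2L, 3L, 3L, 4L, 5L),
                     ref_codon = c("AAA", "AAA", "CTG", "CTG", "TAC", "GAA"),
                     alt_codon = c("AAG", "GAA", "CTA", "CCG", "TAA", "GAC"))
  # AAA>AAG syn, AAA>GAA missense, CTG>CTA syn, CTG>CCG missense,
  # TAC>TAA nonsense, GAA>GAC missense
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cbind(grid[i, ], vars, row.names = NULL)
  }))
  depth <- 1e5
  base_count <- c(400, 500, 450, 380, 420, 460)
  post_mult <- c(1, 1, 1, 0.1, 0.02, 0.5)
  out$depth <- depth
  out$count <- NA_integer_
  for (i in seq_len(nrow(out))) {
    j <- match(paste(out$codon_index[i], out$alt_codon[i]),
               paste(vars$codon_index, vars$alt_codon))
    out$count[i] <- switch(out$condition[i],
      pre = base_count[j] + 10 * out$replicate[i],
      post = round(base_count[j] * post_mult[j]) + 10 * out$replicate[i],
      wt_control = 2L)
  }
  out$tile <- 1L
  out
}
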