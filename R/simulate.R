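#' Configuration for a simulated tile-seq selection experiment
#'
#' Defines the generative conditions of a multiplexed complementation
#' selection: a mutagenized ORF sequenced in tiles at high depth before
#' and after selection, alongside a wild-type control library that
#' measures per-codon miscall rates. Defaults mirror the assay the
#' generator emulates: a ~540-residue ORF, two replicates, an average
#' mutation load of 0.3 amino-acid changes per clone with under 5% of
#' clones carrying multiple variants, and deep tile sequencing (the
#' published depth of ~2M reads per tile, here configurable so tests can
#' scale it down).
#'
#' @param n_positions number of codons (residues) in the ORF.
#' @param tile_size codons per sequencing tile; tiles partition
#'   `1..n_positions` without overlap (last tile may be shorter).
#' @param depth expected reads per tile per condition/replicate.
#' @param n_replicates number of selection replicates (>= 2).
#' @param mutation_load mean amino-acid-changing variants per clone
#'   (Poisson).
#' @param multi_mutant_fraction maximum tolerated fraction of clones with
#'   more than one variant; the Poisson load implies this fraction and a
#'   config exceeding it is rejected.
#' @param error_rate probability of erroneously observing a given
#'   specific alternate codon in a read (the wild-type-control miscall
#'   rate). The default spreads a total per-codon-call miscall
#'   probability of 1e-4 uniformly over the 63 alternate codons.
#' @param selection_strength scalar `g` of the default enrichment model
#'   `exp(g * (fitness - 1))`, normalized so wild-type-like fitness 1 has
#'   enrichment 1.
#' @param enrichment optional function fitness -> relative enrichment,
#'   overriding the exponential default.
#' @param fitness_mixture named weights over the missense fitness mixture
#'   components `wt` (~Normal(1, 0.05)), `lof` (~Normal(0, 0.05)),
#'   `intermediate` (~Uniform(0.2, 0.8)) and `hyper` (~Normal(1.7, 0.1),
#'   truncated above 1) — the last models hyper-complementing variants.
#' @param n_clones clones in the mutagenized pool.
#' @param seed integer seed; all randomness in [simulate_experiment()]
#'   derives from it via fixed per-(condition, replicate, tile)
#'   substreams, so adding replicates does not perturb existing ones.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_positions = 543, tile_size = 50, depth = 2e6,
                       n_replicates = 2, mutation_load = 0.3,
                       multi_mutant_fraction = 0.05, error_rate = 1e-4 / 63,
                       selection_strength = 3, enrichment = NULL,
                       fitness_mixture = c(wt = 0.6, lof = 0.25,
                                           intermediate = 0.1, hyper = 0.05),
                       n_clones = 1e6, seed = 1) {
  if (n_positions < 2) stop("config error: need at least 2 positions")
  if (depth <= 0) stop("config error: depth must be positive")
  if (n_replicates < 2) stop("config error: need >= 2 replicates")
  if (error_rate < 0 || error_rate > 1) {
    stop("config error: error_rate must be in [0, 1]")
  }
  if (mutation_load <= 0) stop("config error: mutation_load must be > 0")
  implied_multi <- 1 - exp(-mutation_load) * (1 + mutation_load)
  if (implied_multi > multi_mutant_fraction) {
    stop("config error: mutation_load ", mutation_load, " implies ",
         signif(implied_multi, 3), " multi-mutant clones, above the ",
         multi_mutant_fraction, " limit")
  }
  if (abs(sum(fitness_mixture) - 1) > 1e-8 || any(fitness_mixture < 0)) {
    stop("config error: fitness_mixture weights must be non-negative and sum to 1")
  }
  stopifnot(all(c("wt", "lof", "intermediate", "hyper") %in%
                  names(fitness_mixture)))
  g <- selection_strength
  if (is.null(enrichment)) enrichment <- function(f) exp(g * (f - 1))
  tile_starts <- seq(1L, n_positions, by = tile_size)
  tiles <- data.frame(tile = seq_along(tile_starts), start = tile_starts,
                      end = pmin(tile_starts + tile_size - 1L, n_positions))
  structure(list(n_positions = as.integer(n_positions),
                 tiles = tiles, depth = depth,
                 n_replicates = as.integer(n_replicates),
                 mutation_load = mutation_load,
                 multi_mutant_fraction = multi_mutant_fraction,
                 error_rate = error_rate,
                 selection_strength = selection_strength,
                 enrichment = enrichment,
                 fitness_mixture = fitness_mixture,
                 n_clones = as.integer(n_clones),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seed below 2^31 for a (condition, replicate, tile)
substream_seed <- function(seed, condition, replicate, tile) {
  cond <- match(condition, c("pre", "post", "wt_control"))
  as.integer((abs(seed) %% 100000L) * 6151 + cond * 1299721 +
               replicate * 104729 + tile * 7919) %% 2147483647L
}

#' Simulate a tile-seq selection experiment with known truth
#'
#' Draws a random ORF, places every single-nucleotide codon neighbour of
#' every codon in the library, assigns each amino-acid-level variant a
#' latent fitness from the configured mixture (synonymous = 1 exactly,
#' nonsense = 0), builds a clone pool with Poisson mutation load, and
#' samples marginal read counts per codon change for the pre-selection,
#' post-selection and wild-type-control libraries of each replicate.
#' Counts follow the generative model: pre ~ Poisson(depth x (library
#' frequency + error rate)), wt_control ~ Poisson(depth x error rate) and
#' post ~ Poisson(depth x (selected frequency + error rate)), where the
#' selected frequency weights each clone by `enrichment(clone fitness)`
#' (a multi-mutant clone's fitness is the minimum over its variants).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_experiment`: list with `counts` (long
#'   data.frame: condition, replicate, tile, codon_index, ref_codon,
#'   alt_codon, count, depth), `variants` (codon-level table with latent
#'   fitness and library frequencies), `truth` (amino-acid-level truth
#'   table), `cds` and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  cds <- paste0("ATG", paste(sample(setdiff(sense, "ATG"),
                                    config$n_positions - 1L, replace = TRUE),
                             collapse = ""))

  vars <- snv_neighbour_table(cds)
  if (nrow(vars) == 0L) stop("config error: no variants to simulate")

  # amino-acid-level latent fitness, shared across codon changes
  aa_key <- paste(vars$position, vars$ref_aa, vars$alt_aa)
  aa <- vars[!duplicated(aa_key), c("position", "ref_aa", "alt_aa", "vclass")]
  aa$fitness <- draw_fitness(aa$vclass, config$fitness_mixture)
  vars$fitness <- aa$fitness[match(aa_key, paste(aa$position, aa$ref_aa, aa$alt_aa))]

  # clone pool: Poisson(load) variants per clone, uniform over codon changes
  k <- stats::rpois(config$n_clones, config$mutation_load)
  slots <- sample.int(nrow(vars), sum(k), replace = TRUE)
  clone_of_slot <- rep.int(seq_along(k), k)
  n_carrier <- tabulate(slots, nbins = nrow(vars))
  vars$lib_freq <- n_carrier / config$n_clones

  # selection: clone fitness = min over carried variants; wt clones = 1
  slot_fit <- vars$fitness[slots]
  clone_fit <- rep.int(1, config$n_clones)
  agg <- tapply(slot_fit, clone_of_slot, min)
  clone_fit[as.integer(names(agg))] <- agg
  w <- config$enrichment(clone_fit)
  total_w <- sum(w)
  carrier_w <- vapply(split(w[clone_of_slot], slots), sum, 0)
  vars$post_freq <- 0
  vars$post_freq[as.integer(names(carrier_w))] <- carrier_w / total_w

  tile_of <- function(pos) {
    findInterval(pos, config$tiles$start)
  }
  vars$tile <- tile_of(vars$position)

  conds <- c("pre", "post", "wt_control")
  out <- vector("list", length(conds) * config$n_replicates * nrow(config$tiles))
  i <- 0L
  for (cond in conds) {
    for (rep_i in seq_len(config$n_replicates)) {
      for (t in config$tiles$tile) {
        set.seed(substream_seed(config$seed, cond, rep_i, t))
        v <- vars[vars$tile == t, , drop = FALSE]
        d <- stats::rpois(1L, config$depth)
        lambda <- switch(cond,
          pre = d * (v$lib_freq + config$error_rate),
          post = d * (v$post_freq + config$error_rate),
          wt_control = rep(d * config$error_rate, nrow(v)))
        cnt <- pmin(stats::rpois(nrow(v), lambda), d)
        i <- i + 1L
        out[[i]] <- data.frame(condition = cond, replicate = rep_i, tile = t,
                               codon_index = v$position,
                               ref_codon = v$ref_codon, alt_codon = v$alt_codon,
                               count = cnt, depth = d,
                               stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  aa$hgvs_pro <- format_protein_variant(aa)
  rownames(aa) <- NULL
  structure(list(counts = counts, variants = vars, truth = aa,
                 cds = cds, config = config),
            class = "sim_experiment")
}

# all 9 single-nucleotide codon neighbours per codon (codon-level rows)
snv_neighbour_table <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- translate_codons(codons)
  nt <- c("A", "C", "G", "T")
  rows <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    if (aa[i] == "*") next
    ref <- strsplit(codons[i], "")[[1]]
    alts <- character(9L)
    k <- 0L
    for (p in 1:3) for (b in setdiff(nt, ref[p])) {
      mut <- ref; mut[p] <- b
      k <- k + 1L
      alts[k] <- paste(mut, collapse = "")
    }
    alt_aa <- translate_codons(alts)
    rows[[i]] <- data.frame(position = i, ref_codon = codons[i],
                            alt_codon = alts, ref_aa = aa[i],
                            alt_aa = alt_aa,
                            vclass = ifelse(alt_aa == "*", "nonsense",
                                            ifelse(alt_aa == aa[i],
                                                   "synonymous", "missense")),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# latent fitness draws: synonymous exactly 1, nonsense exactly 0,
# missense from the configured four-component mixture
draw_fitness <- function(vclass, mixture) {
  n <- length(vclass)
  fit <- numeric(n)
  fit[vclass == "synonymous"] <- 1
  fit[vclass == "nonsense"] <- 0
  mis <- which(vclass == "missense")
  if (length(mis)) {
    comp <- sample(names(mixture), length(mis), replace = TRUE,
                   prob = mixture)
    draws <- numeric(length(mis))
    draws[comp == "wt"] <- stats::rnorm(sum(comp == "wt"), 1, 0.05)
    draws[comp == "lof"] <- stats::rnorm(sum(comp == "lof"), 0, 0.05)
    draws[comp == "intermediate"] <- stats::runif(sum(comp == "intermediate"),
                                                  0.2, 0.8)
    draws[comp == "hyper"] <- pmax(stats::rnorm(sum(comp == "hyper"), 1.7, 0.1),
                                   1.05)
    fit[mis] <- draws
    attr(fit, "component") <- NULL
  }
  fit
}

#' Ground-truth table of a simulated experiment
#'
#' @param exp a `sim_experiment`.
#' @return data.frame with one row per simulated amino-acid-level variant:
#'   `position`, `ref_aa`, `alt_aa`, `vclass`, `fitness`, `hgvs_pro`.
#' @export
truth_table <- function(exp) {
  stopifnot(inherits(exp, "sim_experiment"))
  exp$truth
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Simulated tile-seq experiment\n")
  cat("  positions:", x$config$n_positions,
      " tiles:", nrow(x$config$tiles),
      " replicates:", x$config$n_replicates, "\n")
  cat("  codon changes:", nrow(x$variants),
      " aa variants:", nrow(x$truth), "\n")
  cat("  class counts:", paste(names(table(x$truth$vclass)),
                               table(x$truth$vclass), collapse = ", "), "\n")
  invisible(x)
}

#' Expand a marginal count table into per-read call records
#'
#' Utility for exercising the call-level counting path on simulated
#' data: each counted alternate codon becomes a decidable call record
#' with a posterior above the counting threshold, and the remaining
#' effective depth becomes wild-type sentinel records.
#'
#' @param counts rows of a count table for one condition/replicate/tile.
#' @param max_depth cap on reads expanded per codon (keeps test inputs
#'   small).
#' @return data.frame of call records: `read_id`, `codon_index`,
#'   `alt_codon`, `posterior`, `decidable`.
#' @export
counts_to_calls <- function(counts, max_depth = 1000L) {
  stopifnot(all(c("codon_index", "alt_codon", "count", "depth") %in%
                  names(counts)))
  recs <- vector("list", nrow(counts) + 1L)
  rid <- 0L
  for (i in seq_len(nrow(counts))) {
    n_alt <- min(counts$count[i], max_depth)
    if (n_alt > 0) {
      recs[[i]] <- data.frame(
        read_id = paste0("r", rid + seq_len(n_alt)),
        codon_index = counts$codon_index[i],
        alt_codon = counts$alt_codon[i],
        posterior = 0.99, decidable = TRUE, stringsAsFactors = FALSE)
      rid <- rid + n_alt
    }
  }
  # one block of WT-sentinel reads per codon fills depth up to the cap
  per_codon <- unique(counts[, c("codon_index", "depth")])
  alt_tot <- tapply(pmin(counts$count, max_depth), counts$codon_index, sum)
  wt <- lapply(seq_len(nrow(per_codon)), function(j) {
    ci <- per_codon$codon_index[j]
    n_wt <- min(per_codon$depth[j], max_depth) -
      as.integer(alt_tot[as.character(ci)])
    if (n_wt <= 0) return(NULL)
    data.frame(read_id = paste0("w", ci, "_", seq_len(n_wt)),
               codon_index = ci, alt_codon = "=", posterior = 1,
               decidable = TRUE, stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, recs), do.call(rbind, wt))
  rownames(out) <- NULL
  out
}
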