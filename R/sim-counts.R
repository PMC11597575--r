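#' Configuration for the synthetic count generator
#'
#' Bundles and validates all parameters of the negative-binomial count
#' simulator. Defaults emulate a four-condition cold-stress design: a 22 degC
#' control and three low-temperature treatments (0, 4, 10 degC), three
#' biological replicates each, with sequencing depth around 5 million reads
#' per library.
#'
#' The NB parameterization throughout this package is
#' `variance = mu + phi * mu^2`, i.e. `phi` is the squared biological
#' coefficient of variation and `phi = 0` recovers the Poisson.
#'
#' @param n_genes Number of genes (> 0).
#' @param conditions Ordered condition labels; the first is the control.
#' @param reps_per_condition Biological replicates per condition (default 3).
#' @param lib_size_mean Expected total counts per sample.
#' @param lib_size_cv Coefficient of variation of library sizes (log-normal).
#' @param baseline_log2_mean_range Interval for per-gene baseline log2
#'   relative abundance (drawn uniformly).
#' @param dispersion NB dispersion phi >= 0.
#' @param de_fraction_per_condition Fraction of genes with a planted effect in
#'   each treatment condition; scalar or one value per treatment.
#' @param logfc_mean,logfc_sd Mean and sd of the planted signed log2 fold
#'   changes (normal draws).
#' @param nested_effects If `TRUE`, the planted gene sets are nested along the
#'   treatment order (each treatment's DE set is a subset of the previous
#'   one), mimicking graded cold responses; default independent draws.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       conditions = c("22C", "0C", "4C", "10C"),
                       reps_per_condition = 3,
                       lib_size_mean = 5e6,
                       lib_size_cv = 0.1,
                       baseline_log2_mean_range = c(0, 12),
                       dispersion = 0.1,
                       de_fraction_per_condition = 0.1,
                       logfc_mean = 0,
                       logfc_sd = 2,
                       nested_effects = FALSE,
                       seed = 1L) {
  stopifnot(length(conditions) >= 2, !anyDuplicated(conditions))
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!is.numeric(reps_per_condition) || reps_per_condition < 1)
    stop("reps_per_condition must be a positive integer")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (lib_size_mean <= 0 || lib_size_cv < 0)
    stop("library size parameters must be positive")
  n_treat <- length(conditions) - 1L
  de_frac <- rep_len(de_fraction_per_condition, n_treat)
  if (any(de_frac < 0 | de_frac > 1))
    stop("de_fraction_per_condition must lie in [0, 1]")
  stopifnot(length(baseline_log2_mean_range) == 2,
            diff(baseline_log2_mean_range) >= 0,
            logfc_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 conditions = as.character(conditions),
                 reps_per_condition = as.integer(reps_per_condition),
                 lib_size_mean = lib_size_mean,
                 lib_size_cv = lib_size_cv,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 dispersion = dispersion,
                 de_fraction_per_condition = de_frac,
                 logfc_mean = logfc_mean,
                 logfc_sd = logfc_sd,
                 nested_effects = isTRUE(nested_effects),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Draws per-gene baseline log2 abundances `b_g` uniformly over the
#' configured range, plants condition-specific log2 effects `beta_gc` in a
#' random subset of genes per treatment, draws library sizes log-normally,
#' and samples counts `NB(mean = s_j * 2^(b_g + beta_gc), dispersion = phi)`
#' where `s_j` scales each sample's expected total to its library size.
#' `phi = 0` uses Poisson draws.
#'
#' All randomness is consumed from a generator seeded with `config$seed`;
#' the caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth`, the ground
#'   truth: a data.frame with one row per (gene, treatment condition) holding
#'   `true_log2fc` and `is_de`, carried as a list also containing per-gene
#'   baselines and (after [simulate_go_annotation()]) planted terms.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, lib_size_mean = 1e5))
#' dim(sim$counts)
#' head(sim$truth$effects)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_preserve_seed()
  set.seed(config$seed)

  n <- config$n_genes
  conds <- config$conditions
  reps <- config$reps_per_condition
  treatments <- conds[-1]
  gene_ids <- sprintf("gene%0*d", max(4, nchar(n)), seq_len(n))

  b <- stats::runif(n, config$baseline_log2_mean_range[1],
                    config$baseline_log2_mean_range[2])

  # planted log2 effects: one column per treatment, 0 for non-DE genes
  beta <- matrix(0, n, length(treatments),
                 dimnames = list(gene_ids, treatments))
  n_de <- round(config$de_fraction_per_condition * n)
  if (config$nested_effects) {
    pool <- seq_len(n)
    for (k in seq_along(treatments)) {
      size <- min(n_de[k], length(pool))
      pool <- pool[sample.int(length(pool), size)]
      if (size > 0)
        beta[pool, k] <- .nonzero_rnorm(size, config$logfc_mean, config$logfc_sd)
    }
  } else {
    for (k in seq_along(treatments)) {
      if (n_de[k] > 0) {
        idx <- sample(n, n_de[k])
        beta[idx, k] <- .nonzero_rnorm(n_de[k], config$logfc_mean, config$logfc_sd)
      }
    }
  }

  sdlog <- sqrt(log1p(config$lib_size_cv^2))
  meanlog <- log(config$lib_size_mean) - sdlog^2 / 2
  n_samples <- length(conds) * reps
  lib_sizes <- stats::rlnorm(n_samples, meanlog, sdlog)

  sample_conds <- rep(conds, each = reps)
  sample_ids <- paste0(sample_conds, "_r", rep(seq_len(reps), length(conds)))

  counts <- matrix(0L, n, n_samples, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    eff <- if (sample_conds[j] == conds[1]) 0 else beta[, sample_conds[j]]
    abun <- 2^(b + eff)
    mu <- lib_sizes[j] * abun / sum(abun)
    counts[, j] <- if (config$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else
      stats::rpois(n, mu)
  }

  effects <- data.frame(
    gene_id = rep(gene_ids, times = length(treatments)),
    condition = rep(treatments, each = n),
    true_log2fc = as.vector(beta),
    is_de = as.vector(beta != 0),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(effects = effects,
                          baseline_log2 = stats::setNames(b, gene_ids),
                          control = conds[1],
                          terms = NULL),
                     class = "truth_table")
  list(counts = count_matrix(counts, sample_conds), truth = truth)
}

# normal draws guaranteed nonzero so is_de <=> true_log2fc != 0 holds exactly
.nonzero_rnorm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x == 0)) x[x == 0] <- stats::rnorm(sum(x == 0), mean, sd)
  x
}

#' Per-gene effect summary from a truth table
#'
#' Mean planted log2 fold change of each gene across treatment conditions —
#' the per-gene quantity the annotation generator weights by.
#'
#' @param truth A `truth_table` from [simulate_counts()].
#' @return Named numeric vector, one value per gene.
#' @export
truth_gene_effect <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  eff <- truth$effects
  out <- tapply(eff$true_log2fc, eff$gene_id, mean)
  out[order(names(out))]
}
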