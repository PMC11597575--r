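#' Gene Ontology annotation container
#'
#' @param members Named list: term id -> character vector of member gene ids
#'   (non-empty, no duplicates within a term).
#' @param terms Optional data.frame with columns `term_id`, `name`,
#'   `namespace` (one of BP, CC, MF); defaults are generated.
#' @return Object of class `go_annotation`: list with `terms` (data.frame)
#'   and `members` (named list).
#' @export
go_annotation <- function(members, terms = NULL) {
  if (!length(members)) {
    return(structure(list(
      terms = data.frame(term_id = character(), name = character(),
                         namespace = character(), stringsAsFactors = FALSE),
      members = list()), class = "go_annotation"))
  }
  if (is.null(names(members)) || anyDuplicated(names(members)))
    stop("members must be a named list with unique term ids")
  if (any(!lengths(members)))
    stop("every term must have at least one member gene")
  members <- lapply(members, function(g) unique(as.character(g)))
  if (is.null(terms)) {
    terms <- data.frame(term_id = names(members), name = names(members),
                        namespace = "BP", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term_id", "name", "namespace") %in% names(terms)),
            setequal(terms$term_id, names(members)),
            all(terms$namespace %in% c("BP", "CC", "MF")))
  terms <- terms[match(names(members), terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  structure(list(terms = terms, members = members), class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("go_annotation:", length(x$members), "terms,",
      length(unique(unlist(x$members, use.names = FALSE))), "distinct genes\n")
  invisible(x)
}

#' Simulate a GO annotation with planted enriched terms
#'
#' Builds `n_terms` gene sets over the simulated gene universe. A fraction of
#' terms is "planted": their members are drawn with weight proportional to
#' `exp(strength * effect)` for an up-term (or `exp(-strength * effect)` for
#' a down-term), where `effect` is each gene's mean planted log2 fold change
#' across treatments ([truth_gene_effect()]). Non-planted terms draw members
#' uniformly, so their membership is independent of the planted effects.
#'
#' @param truth A `truth_table` from [simulate_counts()].
#' @param n_terms Number of terms to generate.
#' @param size_range Integer interval for term sizes (within
#'   `[1, n_genes]`); sizes are drawn uniformly.
#' @param planted_fraction Fraction of terms planted as effect-associated, in
#'   `[0, 1]`.
#' @param planted_strength Non-negative weight exponent for planted terms.
#' @param planted_direction Direction(s) for planted terms: "up", "down", or
#'   "both" (alternating).
#' @param namespace Namespace label(s) assigned to terms (recycled).
#' @param seed Integer seed (independent of the count simulator's).
#' @return List with `annotation` (a [go_annotation()]) and `truth`, the
#'   input truth table extended with a `terms` data.frame
#'   (`term_id`, `planted`, `direction`, `strength`).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, lib_size_mean = 1e5))
#' ann <- simulate_go_annotation(sim$truth, n_terms = 20, seed = 2)
#' ann$annotation
#' @export
simulate_go_annotation <- function(truth, n_terms = 500,
                                   size_range = c(5, 200),
                                   planted_fraction = 0.1,
                                   planted_strength = 1,
                                   planted_direction = "up",
                                   namespace = "BP",
                                   seed = 1L) {
  stopifnot(inherits(truth, "truth_table"), n_terms >= 1)
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  if (planted_strength < 0) stop("planted_strength must be >= 0")
  effect <- truth_gene_effect(truth)
  genes <- names(effect)
  n_genes <- length(genes)
  size_range <- as.integer(round(size_range))
  if (size_range[1] < 1 || size_range[2] > n_genes || size_range[1] > size_range[2])
    stop("size_range must be an interval within [1, n_genes]")

  withr::local_preserve_seed()
  set.seed(seed)
  n_planted <- round(planted_fraction * n_terms)
  planted <- seq_len(n_terms) <= n_planted   # first terms planted; ids shuffled below
  dir <- rep(NA_character_, n_terms)
  if (n_planted > 0) {
    dir[planted] <- switch(planted_direction,
      up = "up", down = "down",
      both = rep_len(c("up", "down"), n_planted),
      stop("planted_direction must be 'up', 'down' or 'both'"))
  }

  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  term_ids <- sprintf("GO:S%06d", seq_len(n_terms))
  members <- vector("list", n_terms)
  names(members) <- term_ids
  for (i in seq_len(n_terms)) {
    w <- if (planted[i]) {
      s <- if (dir[i] == "up") planted_strength else -planted_strength
      # cap exponent to keep weights finite for extreme planted effects
      exp(pmin(s * effect, 700))
    } else rep(1, n_genes)
    members[[i]] <- sort(genes[sample.int(n_genes, sizes[i], prob = w)])
  }

  terms <- data.frame(term_id = term_ids,
                      name = paste0("simulated term ", seq_len(n_terms)),
                      namespace = rep_len(namespace, n_terms),
                      stringsAsFactors = FALSE)
  truth$terms <- data.frame(term_id = term_ids, planted = planted,
                            direction = dir,
                            strength = ifelse(planted, planted_strength, 0),
                            stringsAsFactors = FALSE)
  list(annotation = go_annotation(members, terms), truth = truth)
}

#' Simulate a long-format qPCR Ct table
#'
#' Emits Ct values for `n_targets` target genes plus one reference gene in
#' each condition and replicate. The reference gene's expected Ct is constant
#' across conditions; each target's Ct is its gene-specific baseline plus the
#' condition's delta-Ct shift (a shift of -1 doubles relative expression).
#' Measurement noise is Gaussian on the Ct scale.
#'
#' @param n_targets Number of target genes.
#' @param reference_label Reference (housekeeping) gene id; must be non-empty.
#' @param delta_ct_effects Named numeric vector, condition -> delta-Ct shift
#'   applied to every target in that condition (control usually 0).
#' @param reps Biological replicates per condition.
#' @param noise_sd Gaussian sd of Ct measurement noise (cycles), >= 0.
#' @param reference_ct Expected Ct of the reference gene.
#' @param target_ct_range Interval for target baseline Cts (uniform draws).
#' @param seed Integer seed.
#' @return A data.frame of class `ct_table` with columns
#'   `condition`, `gene`, `replicate`, `ct`.
#' @examples
#' ct <- simulate_ct_table(2, delta_ct_effects = c(`22C` = 0, `0C` = -2),
#'                         noise_sd = 0, seed = 1)
#' head(ct)
#' @export
simulate_ct_table <- function(n_targets = 4,
                              reference_label = "AtUBQ5",
                              delta_ct_effects = c(`22C` = 0, `0C` = -3,
                                                   `4C` = -2, `10C` = -1),
                              reps = 3,
                              noise_sd = 0.2,
                              reference_ct = 20,
                              target_ct_range = c(22, 28),
                              seed = 1L) {
  if (!nzchar(reference_label)) stop("reference_label must be a non-empty gene id")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(delta_ct_effects)) || !length(delta_ct_effects))
    stop("delta_ct_effects must be a named condition -> shift mapping")
  stopifnot(n_targets >= 1, reps >= 1)

  withr::local_preserve_seed()
  set.seed(seed)
  conds <- names(delta_ct_effects)
  targets <- sprintf("target%02d", seq_len(n_targets))
  base <- stats::setNames(stats::runif(n_targets, target_ct_range[1],
                                       target_ct_range[2]), targets)
  grid <- expand.grid(replicate = paste0("r", seq_len(reps)),
                      gene = c(reference_label, targets),
                      condition = conds,
                      stringsAsFactors = FALSE)[, 3:1]
  expected <- ifelse(grid$gene == reference_label, reference_ct,
                     base[grid$gene] + delta_ct_effects[grid$condition])
  grid$ct <- expected + if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  rownames(grid) <- NULL
  class(grid) <- c("ct_table", "data.frame")
  grid
}
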