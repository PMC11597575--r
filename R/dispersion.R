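#' Estimate a common negative-binomial dispersion by conditional likelihood
#'
#' Counts are first scaled to a common pseudo-library (the geometric mean of
#' the samples' effective library sizes), then the NB dispersion `phi`
#' (variance = mu + phi mu^2) common to all genes is chosen to maximize the
#' conditional log-likelihood of the within-group counts given each group's
#' total — the classical replicate-based estimator for pairwise designs,
#' which does not require estimating per-gene means. The 1-D maximization
#' uses golden-section search over phi in [1e-6, 10] (log parameterized),
#' with the interval endpoints checked so boundary optima are returned
#' exactly.
#'
#' @param cm A [count_matrix()].
#' @param conditions Pair of condition labels to use; default the first two
#'   levels. Only samples of these conditions contribute.
#' @param factors Optional precomputed [tmm_factors()].
#' @return List of class `dispersion_estimate` with elements `common`
#'   (phi >= 0), `tagwise` (NULL; not estimated) and `method`.
#' @export
estimate_common_dispersion <- function(cm, conditions = NULL, factors = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(conditions)) conditions <- levels(cm$conditions)[1:2]
  stopifnot(length(conditions) == 2)
  idx <- lapply(conditions, function(cc) .samples_of(cm, cc))
  if (all(lengths(idx) < 2))
    stop("dispersion is not estimable with a single replicate in both groups")

  eff <- effective_lib_sizes(cm, factors)
  samples <- unlist(idx)
  pseudo_lib <- exp(mean(log(eff[samples])))
  # library-size-equalized pseudo-counts (kept continuous; lgamma handles it)
  pc <- sweep(cm$counts[, samples, drop = FALSE], 2,
              pseudo_lib / eff[samples], "*")
  groups <- rep(seq_along(idx), lengths(idx))

  nll <- function(log10_phi) {
    r <- 1 / 10^log10_phi
    ll <- 0
    for (g in seq_along(idx)) {
      n_g <- sum(groups == g)
      if (n_g < 2) next
      yg <- pc[, groups == g, drop = FALSE]
      z <- rowSums(yg)
      ll <- ll + sum(rowSums(lgamma(yg + r)) - n_g * lgamma(r) +
                     lgamma(n_g * r) - lgamma(z + n_g * r))
    }
    -ll
  }

  lo <- log10(1e-6); hi <- log10(10)
  tol <- 1e-6
  opt <- .golden_section(nll, lo, hi, tol = tol)
  # snap to an exact bound when the optimum sits on it (within search tol)
  if (opt - lo < 10 * tol) opt <- lo
  if (hi - opt < 10 * tol) opt <- hi
  cand <- c(opt, lo, hi)
  best <- cand[which.min(vapply(cand, nll, numeric(1)))]
  structure(list(common = 10^best, tagwise = NULL,
                 method = "conditional likelihood, golden section"),
            class = "dispersion_estimate")
}

# minimizes f on [a, b]; returns argmin
.golden_section <- function(f, a, b, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.6g (%s)\n", x$common, x$method))
  invisible(x)
}
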