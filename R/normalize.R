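#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. For each sample
#' against the reference, genes with a zero in either sample are dropped,
#' log2 ratios (M) and average log2 abundances (A) are computed after
#' library-size scaling, the most extreme 30% of M values and 5% of A values
#' are trimmed on each side, and the factor is the precision-weighted mean of
#' the remaining M values on the log2 scale. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param cm A [count_matrix()].
#' @param reference_sample Sample id to normalize against; default picks the
#'   sample whose upper-quartile CPM is closest to the mean upper-quartile.
#' @return Named positive numeric vector of factors, one per sample, with
#'   geometric mean 1. Multiply library sizes by these to obtain effective
#'   library sizes.
#' @export
tmm_factors <- function(cm, reference_sample = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  y <- cm$counts
  lib <- colSums(y)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(y)[lib == 0], collapse = ", "))

  f75 <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- if (is.null(reference_sample)) {
    which.min(abs(f75 - mean(f75)))
  } else {
    r <- match(reference_sample, colnames(y))
    if (is.na(r)) stop("unknown reference sample: ", reference_sample)
    r
  }

  f <- vapply(seq_len(ncol(y)), function(j)
    .tmm_pair(y[, j], y[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(y))
}

# one sample vs reference; trim fractions fixed at 0.30 (M) and 0.05 (A)
.tmm_pair <- function(obs, ref, n_obs, n_ref) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_obs <- obs[keep] / n_obs
  p_ref <- ref[keep] / n_ref
  m <- log2(p_obs / p_ref)
  a <- (log2(p_obs) + log2(p_ref)) / 2
  # delta-method precision weights on M
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * 0.30) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel) || all(w[sel] == 0)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

#' Effective library sizes (raw totals times TMM factors)
#'
#' @param cm A [count_matrix()].
#' @param factors Optional precomputed [tmm_factors()].
#' @return Named numeric vector of effective library sizes.
#' @export
effective_lib_sizes <- function(cm, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(cm)
  colSums(cm$counts) * factors[cm$sample_ids]
}
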