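#' Signed significance score
#'
#' Per-gene predictor for the enrichment regression:
#' `x = sign(logFC) * -log10(FDR)`, with `sign(0) = 0` so genes with FDR = 1
#' or logFC = 0 score exactly 0. The FDR is floored before taking logs so
#' underflowed adjusted p-values give a large finite score rather than
#' infinity.
#'
#' @param logfc Numeric vector of log2 fold changes.
#' @param fdr Numeric vector of BH-adjusted p-values in `[0, 1]`.
#' @param fdr_floor Positive floor applied to `fdr` (default 1e-300).
#' @return Numeric vector of signed scores.
#' @examples
#' signed_score(c(2, -1.3, 5), c(0.01, 0.001, 1))  # 2, -3, 0
#' @export
signed_score <- function(logfc, fdr, fdr_floor = 1e-300) {
  if (anyNA(fdr) || any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  sign(logfc) * -log10(pmax(fdr, fdr_floor))
}

# ---- logistic fitting ------------------------------------------------------

# IRLS for logit(P(y=1)) = b0 + b1*x; returns coefficients, covariance,
# deviance, convergence flag. Newton steps via closed-form 2x2 solves.
.logit_irls <- function(x, y, max_iter = 100, tol = 1e-10) {
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  b0 <- stats::qlogis(p0); b1 <- 0
  dev_old <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
    det <- sw * swxx - swx^2
    if (!is.finite(det) || det <= 0) break
    swz <- sum(w * z); swxz <- sum(w * x * z)
    b0 <- (swxx * swz - swx * swxz) / det
    b1 <- (sw * swxz - swx * swz) / det
    dev <- .binom_deviance(y, b0 + b1 * x)
    if (!is.finite(dev)) break
    if (abs(dev - dev_old) < tol * (abs(dev) + 1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- b0 + b1 * x
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
  det <- sw * swxx - swx^2
  list(beta0 = b0, beta1 = b1,
       var0 = swxx / det, var1 = sw / det,
       deviance = .binom_deviance(y, eta), converged = converged)
}

.binom_deviance <- function(y, eta) {
  # -2 log-likelihood, computed stably from eta
  2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}

# Firth-penalized logistic fit: score adjusted by hat leverages so estimates
# stay finite under separation; covariance from the Fisher information
.logit_firth <- function(x, y, max_iter = 200, tol = 1e-10) {
  b0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)); b1 <- 0
  pen_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
    det <- sw * swxx - swx^2
    if (!is.finite(det) || det <= 0) break
    h <- w * (swxx - 2 * x * swx + x * x * sw) / det
    ystar <- y + h * (0.5 - mu)
    z <- eta + (ystar - mu) / w
    swz <- sum(w * z); swxz <- sum(w * x * z)
    b0_new <- (swxx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    # damp steps that blow up the penalized likelihood
    step <- 1
    repeat {
      bb0 <- b0 + step * (b0_new - b0); bb1 <- b1 + step * (b1_new - b1)
      pen <- .firth_penlik(x, y, bb0, bb1)
      if (is.finite(pen) && (pen >= pen_old || step < 1e-4)) break
      if (step < 1e-4) { bb0 <- b0; bb1 <- b1; pen <- pen_old; break }
      step <- step / 2
    }
    b0 <- bb0; b1 <- bb1
    if (abs(pen - pen_old) < tol * (abs(pen) + 1)) { converged <- TRUE; break }
    pen_old <- pen
  }
  eta <- b0 + b1 * x
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
  det <- sw * swxx - swx^2
  list(beta0 = b0, beta1 = b1, var0 = swxx / det, var1 = sw / det,
       deviance = .binom_deviance(y, eta), converged = converged)
}

.firth_penlik <- function(x, y, b0, b1) {
  eta <- b0 + b1 * x
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  det <- sum(w) * sum(w * x * x) - sum(w * x)^2
  -.binom_deviance(y, eta) / 2 + 0.5 * log(det)
}

#' Logistic enrichment fit for one gene set
#'
#' Fits `logit P(member) = beta0 + beta1 * x` over the whole gene universe by
#' iteratively reweighted least squares (at most 100 iterations, deviance
#' tolerance 1e-10), where `x` is the signed significance score. The
#' enrichment p-value is the two-sided Wald test on the slope (a
#' likelihood-ratio test is available via `p_type`), and the reported score
#' is `sign(beta1) * -log10(p)`. If the fit separates (|beta1| > 30, a
#' degenerate weight matrix, or non-convergence), the model is refitted with
#' Firth's Jeffreys-prior penalty, which keeps estimates finite, and flagged
#' `fit_method = "firth"`.
#'
#' @param x Named numeric vector of signed scores (names = gene ids), or an
#'   unnamed vector with `genes` supplied.
#' @param members Character vector of member gene ids (the y = 1 class).
#' @param genes Gene ids parallel to `x` (defaults to `names(x)`).
#' @param p_type `"wald"` (default) or `"lrt"`.
#' @return One-row data.frame with `beta0`, `beta1`, `se1`, `p_enrich`,
#'   `score`, `n_in`, `n_out`, `fit_method`, `converged`.
#' @export
fit_logistic_enrichment <- function(x, members, genes = names(x),
                                    p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  if (is.null(genes)) stop("gene ids required (names of x or `genes`)")
  stopifnot(length(genes) == length(x))
  y <- as.numeric(genes %in% members)
  n_in <- sum(y); n_out <- length(y) - n_in
  if (n_in == 0 || n_out == 0)
    stop("degenerate term: all or none of the universe is a member")

  fit <- .logit_irls(x, y)
  method <- "irls"
  # weight collapse: every fitted probability saturated at 0/1 means the
  # covariate (quasi-)separates the classes and the MLE is not finite
  mu_hat <- stats::plogis(fit$beta0 + fit$beta1 * x)
  w_max <- max(mu_hat * (1 - mu_hat))
  if (!fit$converged || !is.finite(fit$beta1) || abs(fit$beta1) > 30 ||
      !is.finite(fit$var1) || fit$var1 <= 0 || w_max < 1e-4) {
    fit <- .logit_firth(x, y)
    method <- "firth"
  }
  se1 <- sqrt(fit$var1)
  if (p_type == "wald") {
    zstat <- fit$beta1 / se1
    log_p <- log(2) + stats::pnorm(-abs(zstat), log.p = TRUE)
  } else {
    dev0 <- .binom_deviance(y, rep(stats::qlogis(mean(y)), length(y)))
    lr <- max(dev0 - fit$deviance, 0)
    log_p <- stats::pchisq(lr, df = 1, lower.tail = FALSE, log.p = TRUE)
  }
  p <- max(exp(log_p), 1e-300)
  p <- min(p, 1)
  data.frame(beta0 = fit$beta0, beta1 = fit$beta1, se1 = se1,
             p_enrich = p, score = sign(fit$beta1) * -log10(p),
             n_in = n_in, n_out = n_out, fit_method = method,
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Enrichment of every annotation term against one DE table
#'
#' Computes the signed score `x` over the full measured gene universe (all
#' genes of the DE table, not only DEGs) and fits the logistic membership
#' model for every term whose membership within the universe has at least
#' `min_term_size` genes on both sides. Skipped terms are recorded with a
#' reason in the `"skipped"` attribute.
#'
#' @param de A `de_result`.
#' @param annotation A [go_annotation()].
#' @param min_term_size Minimum members (and non-members) within the
#'   universe, default 5.
#' @param fdr_floor Floor for the FDR before logs (default 1e-300).
#' @param p_type `"wald"` (default) or `"lrt"`.
#' @return data.frame of class `enrichment_table`, one row per fitted term:
#'   `term_id`, `name`, `namespace`, `n_in`, `beta0`, `beta1`, `se1`,
#'   `p_enrich`, `score`, `fit_method`, `converged`, plus `p_bh` (BH across
#'   fitted terms; informational, not used for ranking). Attribute
#'   `"skipped"`: data.frame of term_id + reason.
#' @export
enrich_all <- function(de, annotation, min_term_size = 5,
                       fdr_floor = 1e-300, p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  stopifnot(inherits(annotation, "go_annotation"),
            all(c("gene_id", "logFC", "FDR") %in% names(de)))
  universe <- de$gene_id
  x <- signed_score(de$logFC, de$FDR, fdr_floor)
  empty <- data.frame(term_id = character(), name = character(),
                      namespace = character(), n_in = integer(),
                      beta0 = numeric(), beta1 = numeric(), se1 = numeric(),
                      p_enrich = numeric(), score = numeric(),
                      fit_method = character(), converged = logical(),
                      p_bh = numeric(), stringsAsFactors = FALSE)
  skipped <- data.frame(term_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (!length(annotation$members)) {
    attr(empty, "skipped") <- skipped
    class(empty) <- c("enrichment_table", "data.frame")
    return(empty)
  }

  rows <- vector("list", length(annotation$members))
  for (i in seq_along(annotation$members)) {
    tid <- names(annotation$members)[i]
    in_univ <- intersect(annotation$members[[i]], universe)
    n_in <- length(in_univ)
    if (n_in < min_term_size || n_in > length(universe) - min_term_size) {
      reason <- if (n_in < min_term_size) "too few members in universe"
                else "covers (almost) the whole universe"
      skipped <- rbind(skipped, data.frame(term_id = tid, reason = reason,
                                           stringsAsFactors = FALSE))
      next
    }
    rec <- fit_logistic_enrichment(x, in_univ, genes = universe,
                                   p_type = p_type)
    rows[[i]] <- cbind(data.frame(term_id = tid,
                                  name = annotation$terms$name[i],
                                  namespace = annotation$terms$namespace[i],
                                  stringsAsFactors = FALSE),
                       rec[, c("n_in", "beta0", "beta1", "se1", "p_enrich",
                               "score", "fit_method", "converged")])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) out$p_bh <- bh_fdr(out$p_enrich)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Term-by-condition matrix of enrichment scores
#'
#' Assembles the heatmap-ready matrix of signed enrichment scores for one
#' namespace: rows are the union of fitted terms across conditions, columns
#' the conditions, entries the score, with 0 where a term was not fitted for
#' a condition.
#'
#' @param tables Named list, condition -> `enrichment_table`.
#' @param namespace One of `"BP"`, `"CC"`, `"MF"` (default `"BP"`).
#' @return Numeric matrix terms x conditions.
#' @export
enrichment_heatmap_matrix <- function(tables, namespace = "BP") {
  if (!length(tables) || is.null(names(tables)))
    stop("need a named list of enrichment tables")
  terms <- sort(unique(unlist(lapply(tables, function(tb)
    tb$term_id[tb$namespace == namespace]), use.names = FALSE)))
  mat <- matrix(0, length(terms), length(tables),
                dimnames = list(terms, names(tables)))
  for (cc in names(tables)) {
    tb <- tables[[cc]]
    tb <- tb[tb$namespace == namespace, , drop = FALSE]
    mat[match(tb$term_id, terms), cc] <- tb$score
  }
  mat
}

#' Top enriched biological-process terms
#'
#' Ranks the BP rows of an enrichment table: `direction = "induced"` returns
#' the `k` largest positive scores (descending), `"repressed"` the `k` most
#' negative (ascending). Ties break by term id. If fewer than `k` terms
#' qualify, all are returned and the `"n_found"` attribute records how many.
#'
#' @param table An `enrichment_table`.
#' @param k Number of terms requested (default 5).
#' @param direction `"induced"` or `"repressed"`.
#' @return data.frame of the selected rows in rank order, with attribute
#'   `"n_found"`.
#' @export
top_bp <- function(table, k = 5, direction = c("induced", "repressed")) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  tb <- table[table$namespace == "BP", , drop = FALSE]
  tb <- if (direction == "induced") {
    tb <- tb[tb$score > 0, , drop = FALSE]
    tb[order(-tb$score, tb$term_id), , drop = FALSE]
  } else {
    tb <- tb[tb$score < 0, , drop = FALSE]
    tb[order(tb$score, tb$term_id), , drop = FALSE]
  }
  out <- tb[seq_len(min(k, nrow(tb))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_found") <- nrow(out)
  out
}
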