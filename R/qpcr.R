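#' Relative expression by the 2^-deltaCt method
#'
#' For every target gene, condition and replicate, the Ct of the target is
#' normalized by subtracting the Ct of the reference gene measured in the
#' same condition and replicate (`deltaCt = Ct_target - Ct_reference`), and
#' relative expression is `2^-deltaCt`. Means and standard deviations are
#' taken over biological replicates. If a control condition is given, each
#' (gene, condition) mean is additionally expressed as a fold change over
#' the gene's control-condition mean.
#'
#' Adding a constant to every Ct (target and reference alike) leaves all
#' values unchanged — relative expression depends only on Ct differences.
#'
#' @param ct A `ct_table` (data.frame with columns `condition`, `gene`,
#'   `replicate`, `ct`; Ct finite).
#' @param reference_gene Reference gene id; must be measured in every
#'   (condition, replicate) that has a target measurement.
#' @param control_condition Optional control label for fold changes.
#' @return List of class `relative_expression`: `values` (per-replicate
#'   data.frame with `condition`, `gene`, `replicate`, `delta_ct`, `rel_expr`)
#'   and `summary` (per gene x condition: `mean`, `sd`, `n`, and
#'   `fold_change` when a control is given).
#' @examples
#' ct <- simulate_ct_table(2, noise_sd = 0, seed = 1)
#' relative_expression(ct, "AtUBQ5", control_condition = "22C")$summary
#' @export
relative_expression <- function(ct, reference_gene,
                                control_condition = NULL) {
  stopifnot(all(c("condition", "gene", "replicate", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive")
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (!nrow(ref)) stop("reference gene not present: ", reference_gene)
  tgt <- ct[ct$gene != reference_gene, , drop = FALSE]

  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  if (anyNA(ref_ct)) {
    miss <- unique(tgt[is.na(ref_ct), c("condition", "replicate")])
    stop("missing reference measurement for: ",
         paste(sprintf("(%s, %s)", miss$condition, miss$replicate),
               collapse = ", "))
  }
  values <- data.frame(condition = tgt$condition, gene = tgt$gene,
                       replicate = tgt$replicate,
                       delta_ct = tgt$ct - ref_ct,
                       stringsAsFactors = FALSE)
  values$rel_expr <- 2^(-values$delta_ct)

  agg <- function(f) stats::aggregate(rel_expr ~ gene + condition, values, f)
  s <- agg(mean); names(s)[3] <- "mean"
  s$sd <- agg(stats::sd)$rel_expr
  s$n <- agg(length)$rel_expr
  if (!is.null(control_condition)) {
    if (!control_condition %in% s$condition)
      stop("control condition not present: ", control_condition)
    ctrl <- s[s$condition == control_condition, c("gene", "mean")]
    s$fold_change <- s$mean / ctrl$mean[match(s$gene, ctrl$gene)]
  }
  structure(list(values = values, summary = s),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post test
#'
#' Classical one-way fixed-effects ANOVA across condition groups followed by
#' Tukey's honest-significant-difference pairwise comparisons (studentized
#' range distribution), via [stats::aov()] and [stats::TukeyHSD()]. When the
#' total within-group variance is zero the result is flagged degenerate and
#' p-values are returned as NA rather than fabricating significance.
#'
#' @param groups Named list, condition -> numeric replicate values (>= 2
#'   groups, each >= 2 values).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return List of class `anova_tukey`: `F`, `p`, `df`, `pairwise`
#'   (data.frame `pair`, `diff`, `lwr`, `upr`, `p_adj`), `degenerate`,
#'   `alpha`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least two values")
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  within_ss <- sum(tapply(d$value, d$group,
                          function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    return(structure(list(F = NA_real_, p = NA_real_,
                          df = c(length(groups) - 1,
                                 nrow(d) - length(groups)),
                          pairwise = NULL, degenerate = TRUE, alpha = alpha),
                     class = "anova_tukey"))
  }
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
                 df = tab[, "Df"], pairwise = pairwise,
                 degenerate = FALSE, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  if (x$degenerate) {
    cat("one-way ANOVA: degenerate (zero within-group variance)\n")
  } else {
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
                x$df[1], x$df[2], x$F, x$p))
    print(x$pairwise)
  }
  invisible(x)
}
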