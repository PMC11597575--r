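# Independent oracles and small fixture builders shared across the suite.

# two-sided conditional binomial exact p (doubling of the smaller tail,
# observed point in both tails, capped at 1) -- the phi -> 0 limit of the
# exact NB test, computed directly from the binomial distribution
binom_two_sided_p <- function(s_treat, total, n_ctrl, n_treat) {
  if (total == 0) return(1)
  q <- n_treat / (n_ctrl + n_treat)
  lower <- stats::pbinom(s_treat, total, q)
  upper <- 1 - stats::pbinom(s_treat - 1, total, q)
  min(1, 2 * min(lower, upper))
}

# hand application of the BH step-up rule (independent of stats::p.adjust)
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# binomial log-likelihood of the two-parameter logit model
logit_loglik <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  sum(y * eta - log1p(exp(eta)))
}

# brute-force ML: coarse grid then derivative-free polish, independent of
# the IRLS implementation under test
brute_force_logit <- function(x, y) {
  grid <- expand.grid(b0 = seq(-6, 6, by = 0.5), b1 = seq(-6, 6, by = 0.5))
  ll <- apply(grid, 1, logit_loglik, x = x, y = y)
  start <- as.numeric(grid[which.max(ll), ])
  opt <- stats::optim(start, function(b) -logit_loglik(b, x, y),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, function(b) -logit_loglik(b, x, y),
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# small count_matrix straight from a matrix of integers
toy_cm <- function(m, conditions) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  count_matrix(m, conditions)
}

# unadjusted pooled-variance pairwise t p-values matching the ANOVA layout
pairwise_t_oracle <- function(groups) {
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = rep(names(groups), lengths(groups)))
  fit <- stats::aov(value ~ group, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  combs <- utils::combn(names(groups), 2, simplify = FALSE)
  sapply(combs, function(pr) {
    m <- sapply(groups[pr], mean)
    se <- sqrt(mse * sum(1 / lengths(groups[pr])))
    2 * stats::pt(-abs(diff(m)) / se, fit$df.residual)
  })
}
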