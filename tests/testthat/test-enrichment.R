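test_that("signed score has the documented closed-form values", {
  expect_equal(signed_score(2.0, 0.01), 2.0)
  expect_equal(signed_score(-1.3, 0.001), -3.0)
  expect_equal(signed_score(5.0, 1.0), 0.0)
  expect_equal(signed_score(0, 0.001), 0.0)          # sign(0) = 0
  expect_equal(signed_score(1, 0), 300)              # floored, finite
  expect_error(signed_score(1, 1.5), "\\[0, 1\\]")
})

test_that("IRLS coefficients match brute-force likelihood maximization", {
  set.seed(8)
  for (k in 1:25) {
    n <- sample(10:50, 1)
    x <- rnorm(n, sd = sample(c(0.5, 1, 2), 1))
    y <- rbinom(n, 1, plogis(runif(1, -1, 1) + runif(1, -1, 1) * x))
    if (sum(y) == 0 || sum(y) == n) next
    names(x) <- sprintf("g%02d", seq_len(n))
    rec <- fit_logistic_enrichment(x, names(x)[y == 1])
    if (rec$fit_method != "irls") next   # separated draws have no finite MLE
    oracle <- brute_force_logit(x, y)
    expect_lt(max(abs(c(rec$beta0, rec$beta1) - oracle)), 1e-6)
  }
})

test_that("fit agrees with glm on a fixed moderate fixture", {
  set.seed(15)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(-1 + 0.8 * x))
  names(x) <- sprintf("g%03d", 1:200)
  rec <- fit_logistic_enrichment(x, names(x)[y == 1])
  g <- stats::glm(y ~ x, family = stats::binomial)
  expect_equal(rec$beta1, unname(stats::coef(g)[2]), tolerance = 1e-8)
  expect_equal(rec$se1, unname(summary(g)$coefficients[2, 2]),
               tolerance = 1e-6)
  expect_equal(rec$p_enrich, unname(summary(g)$coefficients[2, 4]),
               tolerance = 1e-6)
  # LRT variant matches the analysis-of-deviance chi-square p
  rec_lrt <- fit_logistic_enrichment(x, names(x)[y == 1], p_type = "lrt")
  p_dev <- stats::anova(g, test = "Chisq")[2, "Pr(>Chi)"]
  expect_equal(rec_lrt$p_enrich, p_dev, tolerance = 1e-6)
})

test_that("score is antisymmetric under score negation", {
  set.seed(5)
  x <- rnorm(300)
  names(x) <- sprintf("g%03d", 1:300)
  members <- names(x)[rbinom(300, 1, plogis(-1.5 + x)) == 1]
  a <- fit_logistic_enrichment(x, members)
  b <- fit_logistic_enrichment(-x, members)
  expect_equal(b$beta1, -a$beta1)
  expect_equal(b$score, -a$score)
  expect_equal(b$p_enrich, a$p_enrich)
  expect_equal(sign(a$score), sign(a$beta1))
  expect_equal(abs(a$score), -log10(a$p_enrich))
})

test_that("separation triggers the Firth fallback with a finite score", {
  set.seed(2)
  x <- c(rnorm(50, -3), rnorm(50, 3))
  names(x) <- sprintf("g%03d", 1:100)
  members <- names(x)[x > 0]   # membership exactly sign(x)
  rec <- fit_logistic_enrichment(x, members)
  expect_identical(rec$fit_method, "firth")
  expect_true(is.finite(rec$beta1))
  expect_true(is.finite(rec$score))
  expect_gt(rec$score, 0)
})

test_that("null p-values are calibrated in the balanced moderate regime", {
  sim <- simulate_counts(sim_config(n_genes = 1000, lib_size_mean = 2e5,
                                    conditions = c("C", "T"), seed = 42))
  de <- nb_exact_test(sim$counts, "C", "T")
  x <- signed_score(de$logFC, de$FDR)
  set.seed(7)
  ps <- replicate(200, {
    members <- sample(de$gene_id, 500)
    fit_logistic_enrichment(x, members, genes = de$gene_id)$p_enrich
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("degenerate terms are rejected or skipped", {
  x <- stats::setNames(rnorm(20), sprintf("g%02d", 1:20))
  expect_error(fit_logistic_enrichment(x, names(x)), "degenerate")
  expect_error(fit_logistic_enrichment(x, character(0)), "degenerate")

  de <- data.frame(gene_id = names(x), logFC = x, logCPM = 5,
                   PValue = 0.5, FDR = 1)
  ann <- go_annotation(list(whole = names(x), tiny = names(x)[1],
                            ok = names(x)[1:8]))
  et <- enrich_all(de, ann)
  expect_identical(et$term_id, "ok")
  skipped <- attr(et, "skipped")
  expect_setequal(skipped$term_id, c("whole", "tiny"))
})

test_that("enrich_all on an empty annotation yields an empty table", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:10), logFC = rnorm(10),
                   logCPM = 5, PValue = 0.5, FDR = 1)
  et <- enrich_all(de, go_annotation(list()))
  expect_s3_class(et, "enrichment_table")
  expect_equal(nrow(et), 0)
})

test_that("a planted up-term outranks the null terms", {
  sim <- simulate_counts(sim_config(n_genes = 2000, lib_size_mean = 1e6,
                                    conditions = c("C", "T"),
                                    de_fraction_per_condition = 0.2,
                                    seed = 19))
  de <- nb_exact_test(sim$counts, "C", "T")
  ann <- simulate_go_annotation(sim$truth, n_terms = 60,
                                size_range = c(30, 150),
                                planted_fraction = 1 / 60,
                                planted_strength = 1, seed = 23)
  et <- enrich_all(de, ann$annotation)
  planted_id <- ann$truth$terms$term_id[ann$truth$terms$planted]
  planted_score <- et$score[et$term_id == planted_id]
  null_scores <- et$score[et$term_id != planted_id]
  expect_gt(planted_score, stats::quantile(null_scores, 0.95))
})

test_that("stronger planting never loosens the median recovered score", {
  scores <- sapply(c(0.5, 2), function(strength) {
    med <- sapply(1:3, function(s) {
      sim <- simulate_counts(sim_config(n_genes = 800, lib_size_mean = 5e5,
                                        conditions = c("C", "T"),
                                        de_fraction_per_condition = 0.2,
                                        seed = s))
      de <- nb_exact_test(sim$counts, "C", "T")
      ann <- simulate_go_annotation(sim$truth, n_terms = 10,
                                    size_range = c(40, 80),
                                    planted_fraction = 0.1,
                                    planted_strength = strength,
                                    seed = s + 50)
      planted_id <- ann$truth$terms$term_id[ann$truth$terms$planted]
      et <- enrich_all(de, ann$annotation)
      et$score[et$term_id == planted_id]
    })
    stats::median(med)
  })
  expect_gte(scores[2], scores[1])
})

test_that("heatmap matrix fills missing terms with zero", {
  t1 <- data.frame(term_id = c("GO:1", "GO:2"), namespace = "BP",
                   score = c(2.5, -1.0))
  t2 <- data.frame(term_id = c("GO:2", "GO:3"), namespace = "BP",
                   score = c(-1.5, 4.0))
  mat <- enrichment_heatmap_matrix(list(`0C` = t1, `4C` = t2), "BP")
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(mat["GO:1", "4C"], 0)
  expect_equal(mat["GO:3", "0C"], 0)
  expect_equal(mat["GO:2", ], c(`0C` = -1.0, `4C` = -1.5))

  single <- enrichment_heatmap_matrix(list(`0C` = t1), "BP")
  expect_equal(unname(single[, 1]), t1$score[order(t1$term_id)])
})

test_that("top_bp ranks by signed score with a full-sort oracle", {
  set.seed(33)
  tb <- data.frame(term_id = sprintf("GO:%03d", 1:40),
                   namespace = rep(c("BP", "CC"), each = 20),
                   score = rnorm(40, sd = 3))
  top <- top_bp(tb, k = 5, direction = "induced")
  bp <- tb[tb$namespace == "BP" & tb$score > 0, ]
  oracle <- bp[order(-bp$score, bp$term_id), ][1:5, "term_id"]
  expect_identical(top$term_id, oracle)

  rep5 <- top_bp(tb, k = 5, direction = "repressed")
  bpn <- tb[tb$namespace == "BP" & tb$score < 0, ]
  expect_identical(rep5$term_id,
                   bpn[order(bpn$score, bpn$term_id), ][1:5, "term_id"])

  all_neg <- tb[tb$score < 0 & tb$namespace == "BP", ]
  empty <- top_bp(all_neg, k = 5, direction = "induced")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_found"), 0)
})
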