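test_that("count simulator honours shape, domain and determinism contracts", {
  cfg <- sim_config(n_genes = 1000, lib_size_mean = 2e5, seed = 7)
  sim <- simulate_counts(cfg)
  expect_equal(dim(sim$counts), c(1000L, 12L))
  expect_true(all(sim$counts$counts >= 0))
  expect_true(is.integer(sim$counts$counts))
  expect_identical(levels(sim$counts$conditions), c("22C", "0C", "4C", "10C"))

  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$truth$effects, sim2$truth$effects)

  # a different seed changes the draw
  sim3 <- simulate_counts(sim_config(n_genes = 1000, lib_size_mean = 2e5,
                                     seed = 8))
  expect_false(identical(sim$counts$counts, sim3$counts$counts))

  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_counts(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("de_fraction = 0 plants nothing and is_de mirrors nonzero effects", {
  sim0 <- simulate_counts(sim_config(n_genes = 400, lib_size_mean = 1e5,
                                     de_fraction_per_condition = 0, seed = 3))
  expect_false(any(sim0$truth$effects$is_de))
  expect_true(all(sim0$truth$effects$true_log2fc == 0))

  sim1 <- simulate_counts(sim_config(n_genes = 400, lib_size_mean = 1e5,
                                     de_fraction_per_condition = 0.2, seed = 3))
  eff <- sim1$truth$effects
  expect_identical(eff$is_de, eff$true_log2fc != 0)
  # per-condition planted count matches the requested fraction
  expect_equal(as.vector(tapply(eff$is_de, eff$condition, sum)[unique(eff$condition)]),
               rep(80L, 3))
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(reps_per_condition = 0), "reps")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(de_fraction_per_condition = 1.5), "de_fraction")
})

test_that("counts reproduce the NB mean-variance relation", {
  # all genes share one mean: fixed baseline, no effects, equal libraries
  phi <- 0.4
  cfg <- sim_config(n_genes = 20000, conditions = c("A", "B"),
                    reps_per_condition = 1, lib_size_mean = 1e6,
                    lib_size_cv = 0, baseline_log2_mean_range = c(5, 5),
                    dispersion = phi, de_fraction_per_condition = 0, seed = 5)
  y <- as.numeric(simulate_counts(cfg)$counts$counts)
  m <- mean(y); v <- stats::var(y)
  phi_hat <- (v / m - 1) / m
  expect_lt(abs(phi_hat - phi), 0.05)

  # Poisson limit
  cfg0 <- sim_config(n_genes = 20000, conditions = c("A", "B"),
                     reps_per_condition = 1, lib_size_mean = 1e6,
                     lib_size_cv = 0, baseline_log2_mean_range = c(5, 5),
                     dispersion = 0, de_fraction_per_condition = 0, seed = 5)
  y0 <- as.numeric(simulate_counts(cfg0)$counts$counts)
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.05)
})

test_that("nested effects produce nested DE gene sets", {
  cfg <- sim_config(n_genes = 500, lib_size_mean = 1e5,
                    de_fraction_per_condition = c(0.3, 0.2, 0.1),
                    nested_effects = TRUE, seed = 9)
  eff <- simulate_counts(cfg)$truth$effects
  sets <- lapply(split(eff, eff$condition),
                 function(d) d$gene_id[d$is_de])
  expect_true(all(sets[["4C"]] %in% sets[["0C"]]))
  expect_true(all(sets[["10C"]] %in% sets[["4C"]]))
  expect_equal(lengths(sets[c("0C", "4C", "10C")]),
               c(`0C` = 150L, `4C` = 100L, `10C` = 50L))
})

test_that("annotation generator respects sizes and plants what it claims", {
  sim <- simulate_counts(sim_config(n_genes = 300, lib_size_mean = 1e5,
                                    seed = 2))
  ann <- simulate_go_annotation(sim$truth, n_terms = 50,
                                size_range = c(5, 200),
                                planted_fraction = 0.2, seed = 4)
  sizes <- lengths(ann$annotation$members)
  expect_true(all(sizes >= 5 & sizes <= 200))
  expect_equal(sum(ann$truth$terms$planted), 10)  # round(0.2 * 50)
  # every planted term id exists in the emitted annotation
  expect_true(all(ann$truth$terms$term_id %in% names(ann$annotation$members)))
  # determinism
  ann2 <- simulate_go_annotation(sim$truth, n_terms = 50,
                                 size_range = c(5, 200),
                                 planted_fraction = 0.2, seed = 4)
  expect_identical(ann$annotation$members, ann2$annotation$members)
  expect_error(simulate_go_annotation(sim$truth, n_terms = 10,
                                      planted_fraction = 2), "planted_fraction")
  expect_error(simulate_go_annotation(sim$truth, n_terms = 10,
                                      size_range = c(0, 500)), "size_range")
})

test_that("unplanted membership is uncorrelated with planted effects", {
  sim <- simulate_counts(sim_config(n_genes = 200, lib_size_mean = 1e5,
                                    de_fraction_per_condition = 0.3, seed = 6))
  effect <- truth_gene_effect(sim$truth)
  cors <- sapply(1:100, function(s) {
    ann <- simulate_go_annotation(sim$truth, n_terms = 5,
                                  size_range = c(20, 100),
                                  planted_fraction = 0, seed = s)
    mean(sapply(ann$annotation$members, function(mem) {
      y <- as.numeric(names(effect) %in% mem)
      stats::cor(y, effect)
    }))
  })
  expect_lt(abs(mean(cors)), 0.01)
})

test_that("a planted up-term shifts its members' mean effect upward", {
  sim <- simulate_counts(sim_config(n_genes = 300, lib_size_mean = 1e5,
                                    de_fraction_per_condition = 0.3, seed = 2))
  effect <- truth_gene_effect(sim$truth)
  ann <- simulate_go_annotation(sim$truth, n_terms = 1, size_range = c(50, 50),
                                planted_fraction = 1, planted_strength = 1,
                                planted_direction = "up", seed = 10)
  members <- ann$annotation$members[[1]]
  expect_gt(mean(effect[members]), mean(effect))
})

test_that("Ct table generator gives exact identities in the noiseless case", {
  ct <- simulate_ct_table(3, delta_ct_effects = c(`22C` = 0, `0C` = 0),
                          noise_sd = 0, seed = 1)
  rel <- relative_expression(ct, "AtUBQ5", control_condition = "22C")
  expect_true(all(rel$summary$fold_change == 1))

  ct2 <- simulate_ct_table(3, delta_ct_effects = c(`22C` = 0, cold = -1),
                           noise_sd = 0, seed = 1)
  rel2 <- relative_expression(ct2, "AtUBQ5", control_condition = "22C")
  expect_true(all(rel2$summary$fold_change[rel2$summary$condition == "cold"] == 2))

  expect_identical(simulate_ct_table(3, seed = 5), simulate_ct_table(3, seed = 5))
  expect_error(simulate_ct_table(3, reference_label = ""), "reference_label")
  expect_error(simulate_ct_table(3, noise_sd = -1), "noise_sd")
})
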