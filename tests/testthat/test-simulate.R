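test_that("identical config and seed give bitwise-identical simulations", {
  cfg <- sim_config(n_genes = 200, conditions = 3,
                    replicates_per_condition = 3, seed = 11)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(sim_config(n_genes = 200, conditions = 3,
                                   replicates_per_condition = 3, seed = 12))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(10, proportions = c(0.5, 0.4)), "sum to 1")
  expect_error(sim_config(0), "positive integer")
  expect_error(sim_config(10, effect_size_min = 1), "exceed 1")
  expect_error(sim_config(10, size_factor_range = c(-1, 2)), "positive")
})

test_that("all-equal simulation recovers configured means per condition", {
  labs <- paste0("C", 1:5)
  cfg <- sim_config(n_genes = 10000, conditions = labs,
                    replicates_per_condition = 4,
                    patterns = list(EE = pattern_all_equal(labs)),
                    proportions = 1,
                    size_factor_range = c(1, 1), seed = 5)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$size_factors == 1))
  target <- mean(sim$truth$means)   # every condition shares these means
  emp <- sapply(labs, function(k)
    mean(sim$counts[, sim$condition_map == k]))
  expect_true(all(abs(emp - target) / target < 0.02))
})

test_that("true pattern labels converge to the configured mixture", {
  cfg <- sim_config(n_genes = 5000, conditions = 5,
                    replicates_per_condition = 4,
                    proportions = c(0.9, 0.1), seed = 21)
  sim <- simulate_counts(cfg)
  frac_de <- mean(sim$truth$pattern == "DE")
  expect_lt(abs(frac_de - 0.1), 0.02)
})

test_that("simulated moments match the NB mean/variance formulas", {
  # many replicates of one condition: empirical mean ~ mu * l, empirical
  # variance ~ mu*l*(1 + phi*mu)
  labs <- "A"
  cfg <- sim_config(n_genes = 400, conditions = labs,
                    replicates_per_condition = 500,
                    patterns = list(EE = pattern_all_equal(labs)),
                    proportions = 1, size_factor_range = c(1, 1),
                    mean_log_range = log(c(50, 500)), seed = 8)
  sim <- simulate_counts(cfg)
  mu <- sim$truth$means[, 1]
  phi <- sim$truth$dispersion
  emp_mean <- rowMeans(sim$counts)
  emp_var <- apply(sim$counts, 1, var)
  expect_lt(median(abs(emp_mean - mu) / mu), 0.02)
  th_var <- mu * (1 + phi * mu)
  expect_lt(median(abs(emp_var - th_var) / th_var), 0.15)
})

test_that("unequal blocks are separated by at least the configured fold", {
  labs <- paste0("C", 1:5)
  cfg <- sim_config(n_genes = 500, conditions = labs,
                    replicates_per_condition = 2,
                    proportions = c(0.5, 0.5), effect_size_min = 2,
                    seed = 3)
  sim <- simulate_counts(cfg)
  de <- sim$truth$pattern == "DE"
  folds <- t(apply(sim$truth$means[de, ], 1, function(m)
    m[-1] / m[-length(m)]))
  expect_true(all(folds >= 2 - 1e-9))   # ordering tag is "increasing"
  ee_means <- sim$truth$means[!de, ]
  expect_true(all(ee_means == ee_means[, 1]))  # equal blocks exactly equal
})

test_that("phenotype simulation honours shape and requested ordering", {
  ord <- c("OV90", "OVCAR4", "OVCAR3", "OVCA432", "OVCAR5")
  ph <- simulate_phenotype(ord, noise_sd = 0, n_donors = 3,
                           marker = "CD68", seed = 2)
  expect_equal(nrow(ph), 3 * length(ord))
  expect_identical(derive_condition_order(ph, "CD68"), ord)
  # small-noise recovery for a short chain
  ph2 <- simulate_phenotype(c("A", "B", "C"), noise_sd = 0.1,
                            n_donors = 3, seed = 4)
  expect_identical(derive_condition_order(ph2, "CD68"), c("A", "B", "C"))
  expect_error(simulate_phenotype(c("A", "A")), "distinct")
})

test_that("counts, truth and config round-trip through their text formats", {
  cfg <- sim_config(n_genes = 40, conditions = 3,
                    replicates_per_condition = 2, seed = 9)
  sim <- simulate_counts(cfg)
  td <- withr::local_tempdir()
  write_counts(sim$counts, file.path(td, "counts.tsv"))
  expect_identical(read_counts(file.path(td, "counts.tsv")), sim$counts)
  write_condition_map(sim$condition_map, file.path(td, "map.tsv"))
  cm <- read_condition_map(file.path(td, "map.tsv"))
  expect_identical(unname(cm), as.character(sim$condition_map))
  write_sim_config(cfg, file.path(td, "config.yaml"))
  cfg2 <- read_sim_config(file.path(td, "config.yaml"))
  expect_identical(simulate_counts(cfg2)$counts, sim$counts)
  write_sim_truth(sim, file.path(td, "truth.tsv"))
  tr <- read.delim(file.path(td, "truth.tsv"))
  expect_identical(tr$pattern, unname(sim$truth$pattern))
})
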