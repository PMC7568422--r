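test_that("block marginal handles the empty and single-count cases exactly", {
  expect_identical(marginal_loglik(integer(0), numeric(0), 1, 1), 0)
  # x = 0, r = 1, alpha = beta = 1: integral of q dq over (0,1) = 1/2
  expect_equal(marginal_loglik(0, 1, 1, 1), log(0.5), tolerance = 1e-12)
  expect_error(marginal_loglik(-1, 1, 1, 1), "non-negative")
  expect_error(marginal_loglik(1.5, 1, 1, 1), "non-negative")
  expect_error(marginal_loglik(1, -1, 1, 1), "positive")
})

test_that("block marginal agrees with numerical quadrature on small cases", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    x <- sample(0:5, n, replace = TRUE)
    r <- runif(n, 0.3, 3)
    alpha <- runif(1, 0.5, 3)
    beta <- runif(1, 0.5, 3)
    expect_equal(marginal_loglik(x, r, alpha, beta),
                 log(oracle_marginal(x, r, alpha, beta)),
                 tolerance = 1e-6)
  }
})

test_that("a single supplied pattern yields posterior 1 everywhere", {
  sim <- simulate_counts(sim_config(n_genes = 50, conditions = 2,
                                    replicates_per_condition = 3, seed = 1))
  fit <- suppressWarnings(
    ebpat(sim$counts, sim$condition_map,
          patterns = pattern_all_equal(levels(sim$condition_map))))
  expect_true(all(posterior(fit) == 1))
})

test_that("posteriors with fixed hyperparameters equal direct Bayes-rule computation", {
  # 3-gene, 2-condition toy; oracle built from scalar marginal_loglik calls
  counts <- rbind(g1 = c(4L, 6L, 40L, 52L),
                  g2 = c(10L, 12L, 11L, 9L),
                  g3 = c(0L, 3L, 7L, 2L))
  cond <- c("A", "A", "B", "B")
  sf <- c(1, 1.2, 0.8, 1)
  r0 <- c(5, 8, 2)
  alpha <- 0.7; beta <- 1.9
  p <- c(0.6, 0.4)
  pats <- list(EE = pattern_all_equal(c("A", "B")),
               DE = pattern_all_unequal(c("A", "B")))
  fit <- ebpat(counts, cond, patterns = pats, size_factors = sf,
               alpha = alpha, beta = beta, r0 = r0, mixture = p,
               estimate_hyper = FALSE)
  for (g in 1:3) {
    r <- r0[g] * sf
    lee <- marginal_loglik(counts[g, ], r, alpha, beta)
    lde <- marginal_loglik(counts[g, cond == "A"], r[cond == "A"],
                           alpha, beta) +
           marginal_loglik(counts[g, cond == "B"], r[cond == "B"],
                           alpha, beta)
    post_ee <- p[1] * exp(lee) / (p[1] * exp(lee) + p[2] * exp(lde))
    expect_equal(unname(posterior(fit)[g, "EE"]), post_ee,
                 tolerance = 1e-10)
  }
})

test_that("posterior rows sum to one and EM ascends the likelihood", {
  cfg <- sim_config(n_genes = 400, conditions = 5,
                    replicates_per_condition = 4,
                    proportions = c(0.8, 0.2), seed = 13)
  sim <- simulate_counts(cfg)
  fit <- suppressWarnings(ebpat(sim$counts, sim$condition_map))
  expect_true(all(abs(rowSums(posterior(fit)) - 1) < 1e-8))
  expect_true(all(diff(fit$logLik_trace) > -1e-6))
  expect_true(fit$converged)
  expect_true(all(posterior(fit) >= 0 & posterior(fit) <= 1))
})

test_that("all-zero genes are dropped and reported", {
  sim <- simulate_counts(sim_config(n_genes = 30, conditions = 2,
                                    replicates_per_condition = 3, seed = 2))
  x <- sim$counts
  x[c(3, 7), ] <- 0L
  expect_message(
    fit <- suppressWarnings(ebpat(x, sim$condition_map)),
    "all-zero")
  expect_setequal(fit$dropped, rownames(x)[c(3, 7)])
  expect_equal(nrow(posterior(fit)), 28)
})

test_that("mixture recovery on synthetic two-condition data", {
  labs <- c("A", "B")
  cfg <- sim_config(n_genes = 2000, conditions = labs,
                    replicates_per_condition = 4,
                    patterns = list(
                      EE = pattern_all_equal(labs),
                      DE = pattern_all_unequal(labs,
                                               ordering = "increasing")),
                    proportions = c(0.7, 0.3), seed = 31)
  sim <- simulate_counts(cfg)
  fit <- suppressWarnings(ebpat(sim$counts, sim$condition_map))
  expect_lt(abs(unname(fit$mixture["{A}{B}"]) - 0.3), 0.05)
})

test_that("model methods expose the fit coherently", {
  sim <- simulate_counts(sim_config(n_genes = 100, conditions = 2,
                                    replicates_per_condition = 3, seed = 6))
  fit <- suppressWarnings(ebpat(sim$counts, sim$condition_map))
  expect_s3_class(fit, "ebpat")
  expect_output(print(fit), "Empirical-Bayes")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ebpat")
  expect_equal(sum(sm$map_counts), sm$n_genes)
  cf <- coef(fit)
  expect_named(cf, c("alpha", "beta", names(fit$mixture)))
  expect_equal(sum(cf[-(1:2)]), 1, tolerance = 1e-9)
  expect_s3_class(logLik(fit), "logLik")
  sim2 <- simulate(fit, seed = 1)
  expect_identical(dim(sim2), dim(fit$counts))
  expect_length(attr(sim2, "pattern"), nrow(fit$counts))
})
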