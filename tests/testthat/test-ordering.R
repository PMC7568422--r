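test_that("constraint chains parse and round-trip to canonical text", {
  cs <- parse_constraint("A<=B<=C")
  expect_identical(cs$labels, c("A", "B", "C"))
  expect_identical(cs$relations, c("<=", "<="))
  expect_identical(format(cs), "A<=B<=C")
  cs2 <- parse_constraint("A<=B>=C=D")
  expect_identical(cs2$relations, c("<=", ">=", "="))
  expect_identical(format(cs2), "A<=B>=C=D")
  expect_error(parse_constraint("A<=<=B"), "malformed")
  expect_error(parse_constraint("A"), "malformed")
  expect_error(parse_constraint("A<=B<=A"), "distinct")
})

test_that("the named presets encode the screen's directionality criteria", {
  c1 <- constraint_preset("c1_main")
  expect_identical(c1$labels,
                   c("OV90", "OVCAR4", "OVCAR3", "OVCAR5", "OVCA432"))
  expect_identical(c1$relations, rep("<=", 4))
  c2 <- constraint_preset("c2_main")
  expect_identical(c2$relations, c("<=", "<=", "<=", ">="))
  c1s <- constraint_preset("c1_supp")
  expect_identical(c1s$relations, c("=", "=", "<=", "<="))
  expect_true(c1s$strict)
  expect_error(constraint_preset("c9"), "unknown")
})

test_that("printed candidate rows gate as their pairwise comparisons dictate", {
  means <- candidate_means_fixture()
  c1 <- constraint_preset("c1_main")
  c2 <- constraint_preset("c2_main")
  # TGFA rises monotonically
  expect_true(check_ordering(means["TGFA", ], c1)$pass)
  # GDNF fails both: 0.16 > 0.00 breaks the third <= of the chain, and the
  # final >= of the peak-shaped criterion fails because 0.00 < 47.86
  g1 <- check_ordering(means["GDNF", ], c1)
  expect_false(g1$pass)
  expect_equal(g1$first_violation, 3L)
  expect_equal(g1$margin, 0.16)
  g2 <- check_ordering(means["GDNF", ], c2)
  expect_false(g2$pass)
  expect_equal(g2$first_violation, 3L)
})

test_that("equality chains accept equal values and tolerances behave", {
  eq <- parse_constraint("A=B=C")
  expect_true(check_ordering(c(A = 5, B = 5, C = 5), eq)$pass)
  expect_false(check_ordering(c(A = 5, B = 5.1, C = 5), eq)$pass)
  eq_tol <- parse_constraint("A=B=C", rel_tol = 0.05)
  expect_true(check_ordering(c(A = 5, B = 5.1, C = 5), eq_tol)$pass)
  # strict semantics: the right side must clear the tolerance band
  st <- parse_constraint("A<=B", strict = TRUE)
  expect_false(check_ordering(c(A = 5, B = 5), st)$pass)
  expect_true(check_ordering(c(A = 5, B = 6), st)$pass)
  expect_error(check_ordering(c(A = 1), parse_constraint("A<=B")),
               "missing")
})

test_that("gate keeps genes passing any constraint and reports violations", {
  means <- candidate_means_fixture()
  out <- apply_gate(rownames(means), means,
                    list(constraint_preset("c1_main"),
                         constraint_preset("c2_main")), mode = "any")
  expect_setequal(out$genes, c("AMH", "EPGN", "LIF", "TGFA"))
  expect_equal(nrow(out$report), 2 * nrow(means))
  expect_true(all(out$report$pass[out$report$gene %in% out$genes &
                                    out$report$constraint == "c1_main"]))
  # disjunction semantics: a gene passing only the second constraint stays
  mu <- rbind(peak = c(OV90 = 1, OVCAR4 = 2, OVCAR3 = 3,
                       OVCAR5 = 4, OVCA432 = 2))
  keep <- apply_gate("peak", mu,
                     list(constraint_preset("c1_main"),
                          constraint_preset("c2_main")), mode = "any")
  expect_identical(keep$genes, "peak")
  drop <- apply_gate("peak", mu,
                     list(constraint_preset("c1_main"),
                          constraint_preset("c2_main")), mode = "all")
  expect_length(drop$genes, 0)
  # vacuous input
  expect_length(apply_gate(character(0), means,
                           list(constraint_preset("c1_main")))$genes, 0)
  expect_error(apply_gate("AMH", means, list()), "at least one")
})

test_that("gate verdicts respect reversal symmetry and tolerance monotonicity", {
  set.seed(10)
  labs <- LETTERS[1:5]
  flip <- c("<=" = ">=", ">=" = "<=", "=" = "=")
  for (i in 1:50) {
    v <- round(runif(5, 0, 100), 2)
    rels <- sample(c("<=", ">=", "="), 4, replace = TRUE)
    rt <- sample(c(0, 0.05, 0.2), 1)
    chain <- paste0(labs[1], paste0(rels, labs[-1], collapse = ""))
    cs <- parse_constraint(chain, rel_tol = rt)
    fwd <- check_ordering(stats::setNames(v, labs), cs)$pass
    rev_chain <- paste0(labs[1],
                        paste0(rev(flip[rels]), labs[-1], collapse = ""))
    cs_rev <- parse_constraint(rev_chain, rel_tol = rt)
    bwd <- check_ordering(stats::setNames(rev(v), labs), cs_rev)$pass
    expect_identical(fwd, bwd)
    # widening the tolerance never turns this pass into a fail
    if (fwd)
      expect_true(check_ordering(
        stats::setNames(v, labs),
        parse_constraint(chain, rel_tol = rt + 0.3))$pass)
  }
})

test_that("condition ordering is recovered from phenotype tables", {
  ord68 <- c("OV90", "OVCAR4", "OVCAR3", "OVCA432", "OVCAR5")
  ph <- simulate_phenotype(ord68, noise_sd = 0, n_donors = 3,
                           marker = "CD68", seed = 1)
  expect_identical(derive_condition_order(ph, "CD68"), ord68)
  # invariance to donor permutation and uniform scaling
  ph_perm <- ph[sample(nrow(ph)), ]
  expect_identical(derive_condition_order(ph_perm, "CD68"), ord68)
  ph_scaled <- ph
  ph_scaled$count <- ph_scaled$count * 7
  expect_identical(derive_condition_order(ph_scaled, "CD68"), ord68)
  # ties break lexicographically with a warning
  tied <- data.frame(donor = "d1", condition = c("B", "A"),
                     marker = "CD68", count = c(5, 5))
  expect_warning(out <- derive_condition_order(tied, "CD68"), "tied")
  expect_identical(out, c("A", "B"))
  single <- data.frame(donor = "d1", condition = "A", marker = "CD68",
                       count = 3)
  expect_identical(derive_condition_order(single, "CD68"), "A")
  expect_error(derive_condition_order(ph, "CD163"), "absent")
})

test_that("phenotype-derived constraint is the monotone chain of the ranking", {
  ph <- simulate_phenotype(c("X", "Y", "Z"), noise_sd = 0, n_donors = 2,
                           marker = "CD163", seed = 3)
  cs <- phenotype_constraint(ph, "CD163")
  expect_identical(format(cs), "X<=Y<=Z")
})

test_that("univariate R-squared matches the closed-form sums and edge cases", {
  expect_equal(univariate_r2(1:5, 2 * (1:5) + 3)$r2, 1)
  expect_equal(univariate_r2(1:5, -2 * (1:5))$direction, -1)
  # orthogonal feature on a symmetric design
  expect_equal(univariate_r2(c(-1, 0, 1, 0), c(0, 1, 0, -1))$r2, 0)
  set.seed(11)
  x <- rnorm(5); y <- rnorm(5)
  n <- 5
  r2_brute <- ((n * sum(x * y) - sum(x) * sum(y))^2) /
    ((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(univariate_r2(x, y)$r2, r2_brute, tolerance = 1e-12)
  expect_warning(out <- univariate_r2(rep(1, 5), y), "constant")
  expect_true(is.na(out$r2))
  expect_error(univariate_r2(1:5, rep(2, 5)), "constant")
  expect_error(univariate_r2(1:2, 1:2), "length")
})
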