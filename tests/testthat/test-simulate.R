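test_that("junction-count simulation is deterministic and conserves counts", {
  sc <- ir_scenario(n_events = 50, frac_inc = 0.1, frac_dec = 0.1, seed = 42)
  a <- simulate_ir_counts(sc)
  b <- simulate_ir_counts(sc)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$counts$inclusion >= 0))
  expect_true(all(a$counts$skipping >= 0))
  expect_true(all(a$counts$inclusion == round(a$counts$inclusion)))
})

test_that("truth labels follow the planted fractions and clamping", {
  sc <- ir_scenario(n_events = 100, frac_inc = 0.2, frac_dec = 0.3,
                    delta_psi = 0.4, seed = 7)
  tr <- simulate_ir_counts(sc)$truth
  expect_equal(sum(tr$label == "IncIR"), 20)
  expect_equal(sum(tr$label == "DecIR"), 30)
  expect_true(all(tr$psi_CON >= 0.01 & tr$psi_CON <= 0.99))
  expect_true(all(tr$psi_BMT >= 0.01 & tr$psi_BMT <= 0.99))
  expect_true(all(tr$delta_true[tr$label == "IncIR"] > 0))
  expect_true(all(tr$delta_true[tr$label == "DecIR"] < 0))
  # no planted effects -> empty planted lists
  tr0 <- simulate_ir_counts(ir_scenario(n_events = 40, seed = 1))$truth
  expect_equal(sum(tr0$label != "null"), 0)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(ir_scenario(frac_inc = 0.7, frac_dec = 0.5),
               class = "irmarker_config_error")
  expect_error(ir_scenario(overdispersion_rho = 1),
               class = "irmarker_config_error")
  expect_error(simulate_expression(dispersion = 0),
               class = "irmarker_config_error")
  expect_error(simulate_expression(lib_sizes = c(1, 2)),
               class = "irmarker_config_error")
  expect_error(simulate_interactome(10, 0.5, 6, 6, 0),
               class = "irmarker_config_error")
})

test_that("beta-binomial draws reduce to binomial variance at rho = 0", {
  set.seed(99)
  n <- 50; psi <- 0.3
  draws0 <- rbeta_binom(10000, n, psi, 0)
  v_bin <- n * psi * (1 - psi)
  expect_lt(abs(var(draws0) - v_bin) / v_bin, 0.05)
  # and inflate variance by ~ 1 + (n-1) rho when rho > 0
  rho <- 0.1
  draws1 <- rbeta_binom(10000, n, psi, rho)
  infl <- var(draws1) / v_bin
  expect_gt(infl, 1.3)
  expect_lt(abs(infl - (1 + (n - 1) * rho)) / (1 + (n - 1) * rho), 0.15)
})

test_that("three-group scenario plants recovery trajectories", {
  sc <- ir_scenario(n_events = 30, groups = c(CON = 4, BMT = 6, AMT = 6),
                    frac_inc = 0.5, delta_psi = 0.3, seed = 5)
  tr <- simulate_ir_counts(sc)$truth
  planted <- tr[tr$label == "IncIR", ]
  expect_true(all(planted$psi_AMT == planted$psi_CON))
  expect_true(all(planted$psi_BMT > planted$psi_CON))
  expect_true(all(tr$psi_AMT[tr$label == "null"] == tr$psi_CON[tr$label == "null"]))
})

test_that("expression simulation respects library sizes and planted DE split", {
  sim <- simulate_expression(n_genes = 300, frac_de = 0.2, log2fc = 1,
                             seed = 11)
  expect_equal(sum(sim$truth$label == "up"), 30)
  expect_equal(sum(sim$truth$label == "down"), 30)
  m <- as.matrix(sim$counts[-1])
  expect_true(all(m >= 0))
  big <- simulate_expression(n_genes = 2000, lib_sizes = c(3, rep(1, 13)),
                             seed = 12)
  mm <- as.matrix(big$counts[-1])
  expect_gt(sum(mm[, 1]) / mean(colSums(mm[, -1])), 2.5)
})

test_that("saturated interactome is complete bipartite between the sets", {
  sim <- simulate_interactome(10, 0, 4, 5, 1, seed = 2)
  net <- as_interactome(sim$edges)
  lc <- link_counts(net, sim$query_set, sim$target_set)
  expect_equal(lc$observed_total, 4 * 5)
  expect_true(all(lc$counts$link_count == 5))
  expect_true(all(sim$edges$score >= 0.7 & sim$edges$score <= 1))
})

test_that("set construction achieves requested Venn regions exactly", {
  s <- build_sets_with_overlap(4546, c(a_only = 403, b_only = 252, ab = 94))
  expect_length(s$sets$A, 497)
  expect_length(s$sets$B, 346)
  expect_length(intersect(s$sets$A, s$sets$B), 94)

  empty <- build_sets_with_overlap(100, c(0, 0, 0))
  expect_length(empty$sets$A, 0)
  expect_length(empty$sets$B, 0)

  s3 <- build_sets_with_overlap(10, rep(1, 7))
  v <- venn3(s3$sets$A, s3$sets$B, s3$sets$C)
  expect_equal(unname(v$pairwise), c(2, 2, 2))
  expect_equal(v$triple, 1)
  expect_equal(unname(v$regions), rep(1L, 7))

  expect_error(build_sets_with_overlap(5, c(4, 4, 1)),
               class = "irmarker_config_error")
})
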