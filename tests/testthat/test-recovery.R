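make_calls <- function(ids, calls) {
  tibble::tibble(event_id = ids,
                 call = factor(calls, levels = c("IncIR", "DecIR", "NS")))
}

test_that("venn recovery intersects the two runs with mutually exclusive patterns", {
  run1 <- make_calls(c("e1", "e2", "e3", "e4"),
                     c("IncIR", "DecIR", "IncIR", "NS"))
  run2 <- make_calls(c("e1", "e2", "e3", "e4"),
                     c("DecIR", "IncIR", "NS", "DecIR"))
  out <- venn_recovery(run1, run2)
  expect_equal(as.character(out$pattern[out$event_id == "e1"]), "reverse_V")
  expect_equal(as.character(out$pattern[out$event_id == "e2"]), "V")
  expect_equal(as.character(out$pattern[out$event_id == "e3"]), "none")
  expect_equal(as.character(out$pattern[out$event_id == "e4"]), "none")
  # disjoint universes warn and intersect
  run3 <- make_calls(c("e1", "e9"), c("DecIR", "IncIR"))
  expect_warning(out2 <- venn_recovery(run1, run3), "universes differ")
  expect_equal(out2$event_id, "e1")
})

test_that("relabeling the outer groups swaps reverse_V and V exactly", {
  set.seed(12)
  ids <- sprintf("e%02d", 1:20)
  c1 <- sample(c("IncIR", "DecIR", "NS"), 20, replace = TRUE)
  c2 <- sample(c("IncIR", "DecIR", "NS"), 20, replace = TRUE)
  fwd <- venn_recovery(make_calls(ids, c1), make_calls(ids, c2))
  flip <- function(x) ifelse(x == "IncIR", "DecIR", ifelse(x == "DecIR", "IncIR", x))
  rev <- venn_recovery(make_calls(ids, flip(c1)), make_calls(ids, flip(c2)))
  expect_equal(sum(fwd$pattern == "reverse_V"), sum(rev$pattern == "V"))
  expect_equal(sum(fwd$pattern == "V"), sum(rev$pattern == "reverse_V"))
})

test_that("ANOVA F and p match the sum-of-squares oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_trajectory(vals, grp)
  expect_equal(res$f_stat, oracle_anova_f(vals, grp), tolerance = 1e-10)
  expect_equal(res$p_value,
               pf(oracle_anova_f(vals, grp), 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  # equal means, nonzero within-group variance -> tiny F, large p
  flat <- anova_trajectory(c(1, 2, 3, 1, 2, 3, 1, 2, 3), grp)
  expect_lt(flat$f_stat, 1e-10)
  expect_gt(flat$p_value, 0.99)
  expect_error(anova_trajectory(c(1, NA, 2, 3), c("a", "a", "b", "b")),
               class = "irmarker_domain_error")
})

test_that("ANOVA p agrees with a permutation p on small balanced examples", {
  set.seed(40)
  vals <- rnorm(9, mean = rep(c(0, 0.8, 0), each = 3))
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_trajectory(vals, grp)
  perm <- replicate(10000, oracle_anova_f(vals, sample(grp)))
  p_perm <- mean(perm >= res$f_stat)
  expect_lt(abs(res$p_value - p_perm), 0.02)
})

test_that("Tukey adjusted p dominates the pairwise t-test p", {
  set.seed(41)
  for (k in 1:5) {
    vals <- rnorm(12, mean = rep(runif(3, 0, 1), each = 4))
    grp <- rep(c("a", "b", "c"), each = 4)
    res <- anova_trajectory(vals, grp)
    for (pair in res$tukey$pair) {
      gs <- strsplit(pair, "-")[[1]]
      tt <- t.test(vals[grp == gs[1]], vals[grp == gs[2]], var.equal = TRUE)
      expect_gte(res$tukey$adj_p[res$tukey$pair == pair], tt$p.value - 1e-10)
    }
  }
})

test_that("planted reverse-V trajectories are recovered end to end", {
  sc <- ir_scenario(n_events = 120, groups = c(CON = 6, BMT = 8, AMT = 8),
                    frac_inc = 0.4, delta_psi = 0.3,
                    baseline_psi_dist = c(200, 800), depth_mean = 100,
                    seed = 19)
  sim <- simulate_ir_counts(sc)
  rec <- suppressMessages(recover_ir(sim$counts, c("CON", "BMT", "AMT")))
  calls <- dplyr::inner_join(tidy(rec), sim$truth, by = "event_id")
  planted <- calls[calls$label == "IncIR", ]
  nulls <- calls[calls$label == "null", ]
  expect_gte(mean(planted$pattern == "reverse_V"), 0.8)
  expect_lte(mean(nulls$pattern != "none"), 0.07)
  # recovered loci carry omnibus ANOVA results
  expect_true(all(!is.na(planted$anova_p[planted$pattern == "reverse_V"])))
})

test_that("recovery summary conserves counts and reports group means", {
  sc <- ir_scenario(n_events = 40, groups = c(CON = 5, BMT = 5, AMT = 5),
                    frac_dec = 0.3, delta_psi = 0.3,
                    baseline_psi_dist = c(500, 500), depth_mean = 100,
                    seed = 23)
  sim <- simulate_ir_counts(sc)
  rec <- suppressMessages(recover_ir(sim$counts, c("CON", "BMT", "AMT")))
  sm <- recovery_summary(rec, counts = sim$counts)
  expect_equal(sum(sm$patterns$n), nrow(tidy(rec)))
  expect_equal(sum(sm$patterns$fraction), 1)
  if (!is.null(sm$psi_means)) {
    v_loci <- unique(sm$psi_means$event_id[sm$psi_means$pattern == "V"])
    for (ev in head(v_loci, 3)) {
      tr <- sm$psi_means[sm$psi_means$event_id == ev, ]
      expect_lt(tr$mean_psi[tr$group == "BMT"], tr$mean_psi[tr$group == "CON"])
    }
  }
  # all-none case
  none <- tibble::tibble(event_id = "e1",
                         pattern = factor("none", levels = c("reverse_V", "V", "none")))
  sm0 <- recovery_summary(none)
  expect_equal(sm0$patterns$fraction[sm0$patterns$pattern == "none"], 1)
})
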