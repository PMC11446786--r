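test_that("interactome construction filters, scales and canonicalizes", {
  edges <- tibble::tibble(
    gene_a = c("A", "B", "A", "E", "D"),
    gene_b = c("B", "A", "C", "F", "D"),
    score = c(0.70, 0.65, 0.95, 0.69, 0.99))
  net <- as_interactome(edges)
  # 0.69 excluded, 0.70 retained (inclusive cutoff); (A,B)/(B,A) collapse
  # to their best score; self-loop D-D dropped
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_false("E" %in% net$nodes)
  expect_equal(net$edges$score[net$edges$gene_a == "A" &
                                 net$edges$gene_b == "B"], 0.70)
  # STRING-dialect 0-1000 scores are auto-scaled
  string <- tibble::tibble(gene_a = c("X", "Y"), gene_b = c("Y", "Z"),
                           score = c(700, 450))
  net2 <- as_interactome(string)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$score, 0.70)
})

test_that("link counts match brute-force edge scans", {
  # star: hub connected to 5 leaves
  star <- tibble::tibble(gene_a = "hub", gene_b = paste0("leaf", 1:5),
                         score = 0.9)
  net <- as_interactome(star)
  lc <- link_counts(net, "hub", paste0("leaf", 1:5))
  expect_equal(lc$observed_total, 5)
  # complete bipartite 3 x 4
  q <- paste0("q", 1:3); t <- paste0("t", 1:4)
  kb <- tidyr::expand_grid(gene_a = q, gene_b = t) |>
    dplyr::mutate(score = 0.8)
  net2 <- as_interactome(kb)
  lc2 <- link_counts(net2, q, t)
  brute <- sum(apply(expand.grid(q, t), 1, function(pair) {
    any((net2$edges$gene_a == min(pair) & net2$edges$gene_b == max(pair)))
  }))
  expect_equal(lc2$observed_total, brute)
  expect_equal(lc2$observed_total, 12)
  # a query gene inside the target set counts its target neighbors,
  # never itself: t1 touches only query genes here, so it counts zero
  lc3 <- link_counts(net2, c(q, "t1"), t)
  expect_equal(lc3$counts$link_count[lc3$counts$gene == "t1"], 0)
  # ... but gains exactly one link when t1-t2 is added
  net3 <- as_interactome(dplyr::bind_rows(
    kb, tibble::tibble(gene_a = "t1", gene_b = "t2", score = 0.9)))
  lc4 <- link_counts(net3, c(q, "t1"), t)
  expect_equal(lc4$counts$link_count[lc4$counts$gene == "t1"], 1)
  expect_error(link_counts(net2, "absent", t), class = "irmarker_domain_error")
})

test_that("link totals are invariant under node relabeling", {
  sim <- simulate_interactome(40, 0.15, 6, 8, 0.1, seed = 8)
  net <- as_interactome(sim$edges)
  perm <- setNames(sprintf("z%02d", sample(40)), sim$nodes)
  edges2 <- tibble::tibble(gene_a = unname(perm[sim$edges$gene_a]),
                           gene_b = unname(perm[sim$edges$gene_b]),
                           score = sim$edges$score)
  net2 <- as_interactome(edges2)
  lc1 <- link_counts(net, sim$query_set, sim$target_set)
  lc2 <- link_counts(net2, unname(perm[sim$query_set]),
                     unname(perm[sim$target_set]))
  expect_equal(lc1$observed_total, lc2$observed_total)
})

test_that("random-set null is reproducible and behaves on degenerate graphs", {
  sim <- simulate_interactome(50, 0.1, 8, 10, 0, seed = 6)
  net <- as_interactome(sim$edges)
  n1 <- random_set_null(net, 8, sim$target_set, K = 50, seed = 99)
  n2 <- random_set_null(net, 8, sim$target_set, K = 50, seed = 99)
  expect_identical(n1, n2)
  expect_error(random_set_null(net, 8, sim$target_set, K = 0),
               class = "irmarker_config_error")
  # zero-edge graph: all null totals zero
  lonely <- as_interactome(tibble::tibble(gene_a = letters[1:6],
                                          gene_b = letters[c(2:6, 1)],
                                          score = 0.1))
  expect_equal(nrow(lonely$edges), 0)
})

test_that("null totals match the analytic Erdos-Renyi expectation", {
  sim <- simulate_interactome(200, 0.05, 20, 30, 0, seed = 44)
  net <- as_interactome(sim$edges)
  nulls <- random_set_null(net, 20, sim$target_set, K = 500, seed = 7)
  expected <- 20 * 30 * 0.05
  expect_lt(abs(mean(nulls) - expected) / expected, 0.1)
})

test_that("empirical p follows the add-one rule and its bounds", {
  expect_equal(empirical_p(100, rep(0, 199)), 1 / 200)
  expect_equal(empirical_p(0, rep(5, 10)), 1)
  nulls <- c(1, 5, 10)
  ps <- vapply(c(0, 2, 6, 11), empirical_p, numeric(1), null_totals = nulls)
  expect_true(all(diff(ps) <= 0)) # monotone non-increasing in observed
  expect_true(all(ps >= 1 / 4 & ps <= 1))
})

test_that("ranking sorts by count with lexicographic tie-break", {
  counts <- tibble::tibble(gene = c("A", "C", "B"), link_count = c(3, 1, 5))
  top2 <- rank_links(counts, top_n = 2)
  expect_equal(top2$gene, c("B", "A"))
  tie <- rank_links(tibble::tibble(gene = c("B", "A"), link_count = c(2, 2)))
  expect_equal(tie$gene, c("A", "B"))
  # complete bipartite: every query gene ties at |target|
  q <- paste0("q", 1:3); t <- paste0("t", 1:4)
  kb <- tidyr::expand_grid(gene_a = q, gene_b = t) |> dplyr::mutate(score = 1)
  lc <- link_counts(as_interactome(kb), q, t)
  expect_true(all(rank_links(lc$counts)$link_count == 4))
})

test_that("planted excess connectivity is detected by the permutation test", {
  sim <- simulate_interactome(300, 0.01, 30, 40, 0.2, seed = 10)
  net <- as_interactome(sim$edges)
  enr <- link_enrichment(net, sim$query_set, sim$target_set, K = 199, seed = 3)
  expect_lte(glance(enr)$empirical_p, 0.05)
  expect_gt(glance(enr)$z, 2)
})
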