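test_that("intron ratio follows the length-adjusted closed form", {
  expect_equal(compute_psi(0, 5), 0)
  expect_equal(compute_psi(7, 0), 1)
  expect_equal(compute_psi(10, 10, inc_form_len = 2, skip_form_len = 1), 1 / 3)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5), class = "irmarker_domain_error")
  # with equal form lengths it is the plain count fraction
  i <- c(3, 10, 50); s <- c(9, 1, 50)
  expect_equal(compute_psi(i, s, 7, 7), i / (i + s))
})

test_that("psi is monotone in each count with the other fixed", {
  s <- 20
  psis <- compute_psi(0:50, s, 3, 2)
  expect_true(all(diff(psis) >= 0))
  i <- 20
  psis2 <- compute_psi(i, 0:50, 3, 2)
  expect_true(all(diff(psis2) <= 0))
})

test_that("coverage filter is strict and drops all-missing events", {
  counts <- tibble::tibble(
    event_id = rep(c("e1", "e2", "e3"), each = 2),
    sample_id = rep(c("s1", "s2"), times = 3),
    group = rep(c("A", "B"), times = 3),
    inclusion = c(5, 6, 2, 3, 0, 0),
    skipping  = c(5, 5, 3, 2, 0, 0),
    inc_form_len = 1, skip_form_len = 1)
  psi <- psi_matrix(counts, coverage_min = 10)
  # e1: totals 10 and 11 -> s1 masked (strict >), s2 kept
  expect_true(is.na(psi$s1[psi$event_id == "e1"]))
  expect_false(is.na(psi$s2[psi$event_id == "e1"]))
  # e2 below threshold everywhere, e3 zero everywhere -> both dropped
  expect_equal(psi$event_id, "e1")
  expect_equal(attr(psi, "n_events_kept"), 1)
})

test_that("matrix filter agrees with a brute-force cell filter", {
  set.seed(8)
  n_ev <- 100; n_s <- 10
  counts <- tidyr::expand_grid(event_id = sprintf("e%03d", 1:n_ev),
                               sample_id = sprintf("s%02d", 1:n_s)) |>
    dplyr::mutate(group = rep(rep(c("A", "B"), each = n_s / 2), n_ev),
                  inclusion = rpois(n_ev * n_s, 6),
                  skipping = rpois(n_ev * n_s, 6),
                  inc_form_len = 1, skip_form_len = 1)
  psi <- psi_matrix(counts, coverage_min = 10)
  m <- as.matrix(psi[setdiff(names(psi), c("event_id", "gene"))])
  for (r in sample(nrow(psi), 20)) {
    for (s in sample(n_s, 4)) {
      row <- counts[counts$event_id == psi$event_id[r] &
                      counts$sample_id == colnames(m)[s], ]
      keep <- row$inclusion + row$skipping > 10
      expect_equal(unname(!is.na(m[r, s])), keep)
      if (keep) {
        expect_equal(unname(m[r, s]),
                     row$inclusion / (row$inclusion + row$skipping))
      }
    }
  }
})

test_that("identical samples coincide in ordination space", {
  set.seed(3)
  counts <- tidyr::expand_grid(event_id = sprintf("e%02d", 1:30),
                               sample_id = c("s1", "s2", "s3", "s4")) |>
    dplyr::mutate(group = rep(c("A", "A", "B", "B"), 30),
                  inclusion = rpois(120, 30), skipping = rpois(120, 30),
                  inc_form_len = 1, skip_form_len = 1)
  # make s2 an exact copy of s1
  dup <- counts[counts$sample_id == "s1", c("event_id", "inclusion", "skipping")]
  counts$inclusion[counts$sample_id == "s2"] <-
    dup$inclusion[match(counts$event_id[counts$sample_id == "s2"], dup$event_id)]
  counts$skipping[counts$sample_id == "s2"] <-
    dup$skipping[match(counts$event_id[counts$sample_id == "s2"], dup$event_id)]
  psi <- psi_matrix(counts, coverage_min = 10)
  for (meth in c("pca", "mds")) {
    ord <- ordinate(psi, method = meth)
    co <- as.matrix(ord[, setdiff(names(ord), c("sample_id", "group"))])
    expect_equal(co[ord$sample_id == "s1", ], co[ord$sample_id == "s2", ],
                 tolerance = 1e-8)
  }
})

test_that("PCA and classical MDS give identical inter-sample distances in full dimension", {
  set.seed(14)
  counts <- tidyr::expand_grid(event_id = sprintf("e%02d", 1:40),
                               sample_id = sprintf("s%d", 1:6)) |>
    dplyr::mutate(group = rep(rep(c("A", "B"), each = 3), 40),
                  inclusion = rpois(240, 40), skipping = rpois(240, 40),
                  inc_form_len = 1, skip_form_len = 1)
  psi <- psi_matrix(counts, coverage_min = 10)
  stopifnot(attr(psi, "n_events_kept") == 40) # complete matrix
  k <- 5 # full rank for 6 samples
  pca <- ordinate(psi, "pca", n_components = k)
  mds <- ordinate(psi, "mds", n_components = k)
  d_pca <- dist(as.matrix(pca[, paste0("PC", 1:k)]))
  d_mds <- dist(as.matrix(mds[, paste0("MDS", 1:k)]))
  expect_equal(as.vector(d_pca), as.vector(d_mds), tolerance = 1e-8)
})

test_that("planted group effects separate groups along PC1", {
  sc <- ir_scenario(n_events = 200, frac_inc = 0.15, frac_dec = 0.15,
                    delta_psi = 0.3, depth_mean = 100, seed = 21)
  sim <- simulate_ir_counts(sc)
  ord <- ordinate(psi_matrix(sim$counts), "pca")
  by_group <- split(ord$PC1, ord$group)
  centroid_gap <- abs(mean(by_group[[1]]) - mean(by_group[[2]]))
  within_sd <- mean(vapply(by_group, sd, numeric(1)))
  expect_gt(centroid_gap, 2 * within_sd)
})

test_that("ordination errors are raised for degenerate inputs", {
  counts <- toy_counts()
  psi <- psi_matrix(counts)
  expect_error(ordinate(psi, "pca", n_components = 10),
               class = "irmarker_domain_error")
})
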