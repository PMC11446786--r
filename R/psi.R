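#' Length-adjusted intron ratio from junction counts
#'
#' Computes the intron ratio (percent-spliced-in, \eqn{\psi}) of a retained
#' intron from inclusion-supporting and skipping-junction read counts,
#' normalising each count by the effective length of the read form that can
#' produce it:
#' \deqn{\psi = \frac{I / L_I}{I / L_I + S / L_S}}
#' where `I` is the inclusion count, `S` the skipping count, and `LI`, `LS`
#' the inclusion/skipping form lengths. When both counts are zero the ratio is
#' undefined and `NA` is returned.
#'
#' @param inclusion,skipping Non-negative integer vectors of junction read
#'   counts (recycled to common length).
#' @param inc_form_len,skip_form_len Positive effective form lengths. With the
#'   default `1`/`1` the ratio reduces to the raw count fraction
#'   `I / (I + S)`.
#' @return Numeric vector of intron ratios in `[0, 1]`, `NA` where
#'   `I + S = 0`.
#' @examples
#' compute_psi(10, 10, inc_form_len = 2, skip_form_len = 1) # 1/3
#' compute_psi(c(0, 7), c(5, 0))                            # 0 and 1
#' @export
compute_psi <- function(inclusion, skipping, inc_form_len = 1, skip_form_len = 1) {
  if (any(inclusion < 0, na.rm = TRUE) || any(skipping < 0, na.rm = TRUE)) {
    stop_domain("compute_psi: junction counts must be non-negative")
  }
  if (any(inc_form_len < 1) || any(skip_form_len < 1)) {
    stop_domain("compute_psi: form lengths must be >= 1")
  }
  inc_rate <- inclusion / inc_form_len
  skip_rate <- skipping / skip_form_len
  psi <- inc_rate / (inc_rate + skip_rate)
  psi[(inclusion + skipping) == 0] <- NA_real_
  psi
}

# Map psi to the raw read-level inclusion probability and back. The LRT is
# carried out on theta (the probability governing the observed counts); the
# transform is a monotone bijection so likelihood maxima are preserved.
psi_to_theta <- function(psi, inc_form_len, skip_form_len) {
  psi * inc_form_len / (psi * inc_form_len + (1 - psi) * skip_form_len)
}

theta_to_psi <- function(theta, inc_form_len, skip_form_len) {
  (theta / inc_form_len) / (theta / inc_form_len + (1 - theta) / skip_form_len)
}

#' Intron-ratio matrix with coverage filtering
#'
#' Converts a long junction-count table into an events x samples matrix of
#' intron ratios, masking cells whose total junction coverage does not exceed
#' `coverage_min` (strict `I + S > coverage_min` to keep a cell, mirroring a
#' "coverage of > 10 reads" rule). Events masked in every sample are dropped.
#'
#' @param counts Tibble in long format with columns `event_id`, `sample_id`,
#'   `group`, `inclusion`, `skipping` and optionally `inc_form_len`,
#'   `skip_form_len` (defaulting to 1 with a warning when absent).
#' @param coverage_min Integer coverage threshold; a cell is kept only when
#'   `inclusion + skipping > coverage_min`.
#' @return A tibble of class `psi_matrix` with one row per retained event
#'   (`event_id`, optional `gene`, then one numeric column per sample).
#'   Attributes: `coverage_min`, `groups` (named character vector
#'   sample -> group), `n_events_in`, `n_events_kept`.
#' @examples
#' counts <- simulate_ir_counts(ir_scenario(n_events = 50, seed = 1))$counts
#' psi <- psi_matrix(counts, coverage_min = 10)
#' attr(psi, "n_events_kept")
#' @export
psi_matrix <- function(counts, coverage_min = 10) {
  check_counts_tbl(counts, "psi_matrix")
  if (!all(c("inc_form_len", "skip_form_len") %in% names(counts))) {
    rlang::warn("psi_matrix: no form-length columns; assuming inc_form_len = skip_form_len = 1")
    counts$inc_form_len <- counts$inc_form_len %||% 1
    counts$skip_form_len <- counts$skip_form_len %||% 1
  }
  has_gene <- "gene" %in% names(counts)

  long <- counts |>
    dplyr::mutate(
      psi = compute_psi(.data$inclusion, .data$skipping,
                        .data$inc_form_len, .data$skip_form_len),
      psi = dplyr::if_else(.data$inclusion + .data$skipping > coverage_min,
                           .data$psi, NA_real_)
    )

  groups <- long |>
    dplyr::distinct(.data$sample_id, .data$group)
  group_map <- setNames(as.character(groups$group), groups$sample_id)

  id_cols <- c("event_id", if (has_gene) "gene")
  wide <- long |>
    dplyr::select(dplyr::all_of(id_cols), "sample_id", "psi") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "psi")

  sample_cols <- setdiff(names(wide), id_cols)
  keep <- rowSums(!is.na(as.matrix(wide[sample_cols]))) > 0
  out <- wide[keep, , drop = FALSE]

  structure(out,
            class = c("psi_matrix", class(out)),
            coverage_min = coverage_min,
            groups = group_map,
            n_events_in = nrow(wide),
            n_events_kept = nrow(out))
}

# Extract the numeric sample block of a psi_matrix as a base matrix
# (events in rows, samples in columns).
psi_values <- function(psi) {
  id_cols <- intersect(c("event_id", "gene"), names(psi))
  m <- as.matrix(psi[setdiff(names(psi), id_cols)])
  rownames(m) <- psi$event_id
  m
}

#' Sample ordination on the intron-ratio matrix
#'
#' Projects samples into a low-dimensional space from their intron-ratio
#' profiles, either by principal component analysis (SVD of the
#' column-centered matrix) or classical multidimensional scaling (principal
#' coordinates of pairwise Euclidean distances). Events with any missing
#' ratio are dropped first rather than imputed, so the ordination reflects
#' only fully observed loci.
#'
#' @param psi A `psi_matrix` (see [psi_matrix()]).
#' @param method `"pca"` or `"mds"`.
#' @param n_components Number of components to return.
#' @return Tibble of class `ir_ordination` with columns `sample_id`, `group`,
#'   and `PC1..PCk` (or `MDS1..MDSk`). For PCA the attribute `var_explained`
#'   holds the per-component explained-variance fractions; `n_events_used`
#'   records how many complete events entered.
#' @examples
#' counts <- simulate_ir_counts(ir_scenario(n_events = 100, seed = 1))$counts
#' ordinate(psi_matrix(counts), method = "pca")
#' @export
ordinate <- function(psi, method = c("pca", "mds"), n_components = 2) {
  method <- match.arg(method)
  m <- psi_values(psi)
  if (ncol(m) < 2) stop_domain("ordinate: need at least two samples")
  complete <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  if (nrow(complete) < n_components) {
    stop_domain("ordinate: only %d complete events for %d components",
                nrow(complete), n_components)
  }
  x <- t(complete) # samples in rows
  group_map <- attr(psi, "groups")

  if (method == "pca") {
    fit <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(fit$x))
    coords <- fit$x[, seq_len(k), drop = FALSE]
    var_explained <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
    colnames(coords) <- paste0("PC", seq_len(k))
  } else {
    d <- dist(x)
    k <- min(n_components, nrow(x) - 1)
    coords <- cmdscale(d, k = k)
    var_explained <- NULL
    colnames(coords) <- paste0("MDS", seq_len(k))
  }

  out <- tibble::as_tibble(coords) |>
    dplyr::mutate(sample_id = rownames(x),
                  group = unname(group_map[rownames(x)]),
                  .before = 1)
  structure(out,
            class = c("ir_ordination", class(out)),
            method = method,
            var_explained = var_explained,
            n_events_used = nrow(complete))
}
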