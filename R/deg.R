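# Differential expression: trimmed-mean (TMM) scaling factors and a
# negative-binomial likelihood-ratio test with common dispersion, plus the
# dual p/FDR + fold-change calling rule.

as_counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (!"gene" %in% names(counts)) {
    stop_domain("expected a matrix or a tibble with a 'gene' column")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes one scaling factor per sample from doubly trimmed log count
#' ratios against a reference sample. The reference is the sample whose
#' upper quartile is closest to the mean upper quartile. For each sample,
#' genes with a zero count in either the sample or the reference are
#' removed; `M = log2` count ratio and `A =` mean `log2` abundance are
#' trimmed symmetrically (`trim_m` of M, `trim_a` of A), and the
#' precision-weighted mean of the surviving M values gives the `log2`
#' factor. Factors are rescaled to geometric mean 1.
#'
#' Because the ratios are taken on raw counts, the factors absorb both
#' sequencing depth and composition: a library sequenced twice as deep
#' recovers a factor twice that of its peers.
#'
#' @param counts Count matrix or tibble with a `gene` column.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of factors, one per sample, geometric mean 1.
#' @examples
#' m <- matrix(rpois(400, 50), ncol = 4,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' tmm_factors(m)
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- as_counts_matrix(counts)
  if (ncol(m) < 2) stop_domain("tmm_factors: need at least two samples")
  if (any(colSums(m) == 0)) stop_domain("tmm_factors: sample with all-zero counts")

  uq <- apply(m, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))

  log_f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(0)
    y_s <- m[, s]; y_r <- m[, ref]
    keep <- y_s > 0 & y_r > 0
    y_s <- y_s[keep]; y_r <- y_r[keep]
    if (length(y_s) == 0) return(0)
    M <- log2(y_s / y_r)
    A <- 0.5 * (log2(y_s) + log2(y_r))
    lo_m <- quantile(M, trim_m); hi_m <- quantile(M, 1 - trim_m)
    lo_a <- quantile(A, trim_a); hi_a <- quantile(A, 1 - trim_a)
    keep2 <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
    if (!any(keep2)) return(stats::median(M))
    w <- 1 / (1 / y_s[keep2] + 1 / y_r[keep2]) # asymptotic precision of M
    sum(w * M[keep2]) / sum(w)
  }, numeric(1))

  f <- 2^log_f
  f <- f / geom_mean(f)
  setNames(f, colnames(m))
}

#' Negative-binomial likelihood-ratio test for differential expression
#'
#' Per-gene NB likelihood-ratio test of equal means between two groups, with
#' a common dispersion estimated across genes by adjusted-profile-likelihood
#' maximization (delegated to edgeR) and expression offsets from the TMM
#' factors of [tmm_factors()]. Genes expressed below `min_cpm`
#' counts-per-million in fewer than the smaller group size samples are
#' filtered before testing, as are genes with all-zero counts.
#'
#' @param counts Count matrix or tibble with `gene` column.
#' @param groups Named character vector mapping sample -> group label.
#' @param group_a,group_b The two group labels; `log2fc` is `b` over `a`.
#' @param trim_m,trim_a Passed to [tmm_factors()].
#' @param min_cpm CPM threshold of the expression filter (`NULL` disables).
#' @return Object of class `deg_fit`; [tidy()] gives the per-gene table
#'   (`gene`, `log2fc`, `p_value`, `q_value`), [glance()] the fit summary.
#' @examples
#' sim <- simulate_expression(n_genes = 200, frac_de = 0.1, seed = 3)
#' fit <- deg_test(sim$counts, sim$groups, "CON", "BMT")
#' glance(fit)
#' @export
deg_test <- function(counts, groups, group_a, group_b,
                     trim_m = 0.30, trim_a = 0.05, min_cpm = 1) {
  m <- as_counts_matrix(counts)
  groups <- groups[colnames(m)]
  if (any(is.na(groups))) stop_domain("deg_test: samples missing from group map")
  keep_s <- groups %in% c(group_a, group_b)
  m <- m[, keep_s, drop = FALSE]
  grp <- factor(groups[keep_s], levels = c(group_a, group_b))
  if (min(table(grp)) < 2) stop_domain("deg_test: need >= 2 samples per group")

  all_zero <- rowSums(m) == 0
  if (any(all_zero)) {
    rlang::inform(sprintf("deg_test: %d all-zero gene(s) excluded", sum(all_zero)))
    m <- m[!all_zero, , drop = FALSE]
  }
  if (!is.null(min_cpm)) {
    cpm <- sweep(m, 2, colSums(m), "/") * 1e6
    min_n <- min(table(grp))
    keep_g <- rowSums(cpm > min_cpm) >= min_n
    if (any(!keep_g)) {
      rlang::inform(sprintf("deg_test: %d low-expression gene(s) filtered",
                            sum(!keep_g)))
      m <- m[keep_g, , drop = FALSE]
    }
  }
  if (nrow(m) == 0) stop_domain("deg_test: no genes left after filtering")

  factors <- tmm_factors(m, trim_m = trim_m, trim_a = trim_a)
  # the factors absorb depth, so the effective library size is the factor on
  # a common scale (mean raw library size keeps counts-per-million sensible)
  eff_lib <- factors * mean(colSums(m))

  y <- edgeR::DGEList(counts = m, group = grp)
  y$samples$lib.size <- eff_lib
  y$samples$norm.factors <- rep(1, ncol(m))
  design <- stats::model.matrix(~grp)
  y <- edgeR::estimateGLMCommonDisp(y, design)
  fit <- edgeR::glmFit(y, design, dispersion = y$common.dispersion)
  lrt <- edgeR::glmLRT(fit, coef = 2)

  records <- tibble::tibble(
    gene = rownames(lrt$table),
    log2fc = lrt$table$logFC,
    p_value = lrt$table$PValue,
    q_value = bh_fdr(lrt$table$PValue)) |>
    dplyr::arrange(.data$p_value, .data$gene)

  structure(
    list(records = records,
         factors = factors,
         common_dispersion = y$common.dispersion,
         groups = c(a = group_a, b = group_b)),
    class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  cat(sprintf("NB differential expression: %s vs %s, %d genes, dispersion %.4f\n",
              x$groups["b"], x$groups["a"], nrow(x$records),
              x$common_dispersion))
  invisible(x)
}

#' @rdname deg_test
#' @param x A `deg_fit` object.
#' @param ... Unused.
#' @export
tidy.deg_fit <- function(x, ...) x$records

#' @rdname deg_test
#' @export
glance.deg_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$records),
                 common_dispersion = x$common_dispersion)
}

#' Call differentially expressed genes
#'
#' Applies the dual significance rule to a differential-expression table:
#' a gene is `up` when its fold change exceeds `fc_min` (strictly) and
#' either `p < p_max` or `q < fdr_max`; `down` symmetrically when the fold
#' change is below `1 / fc_min`.
#'
#' @param x A `deg_fit` or tibble with `gene`, `log2fc`, `p_value`,
#'   `q_value`.
#' @param p_max,fdr_max,fc_min Rule thresholds (`fc_min` on the natural
#'   fold-change scale; `1.2` corresponds to `|log2fc| > 0.263`).
#' @return List with `up` and `down` gene vectors and `records` (the input
#'   table with a `call` column).
#' @examples
#' tbl <- tibble::tibble(gene = "g1", log2fc = 0.30, p_value = 0.04,
#'                       q_value = 0.2)
#' call_degs(tbl)$up
#' @export
call_degs <- function(x, p_max = 0.05, fdr_max = 0.1, fc_min = 1.2) {
  records <- if (inherits(x, "deg_fit")) x$records else x
  if (nrow(records) == 0) {
    return(list(up = character(), down = character(),
                records = dplyr::mutate(records, call = character())))
  }
  sig <- records$p_value < p_max | records$q_value < fdr_max
  call <- rep("NS", nrow(records))
  call[sig & records$log2fc > log2(fc_min)] <- "up"
  call[sig & records$log2fc < -log2(fc_min)] <- "down"
  records$call <- factor(call, levels = c("up", "down", "NS"))
  list(up = records$gene[records$call == "up"],
       down = records$gene[records$call == "down"],
       records = records)
}
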