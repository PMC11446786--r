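# Cross-study gene-set overlap: fold enrichment against a stated background
# universe, hypergeometric/Fisher tests, and three-set Venn partitioning.

#' Fold enrichment of a two-set overlap
#'
#' Observed overlap divided by its expectation under independent uniform
#' draws from a background universe of `background_n` genes:
#' `FE = k * background_n / (n_a * n_b)`.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param k Observed overlap.
#' @param background_n Size of the background universe.
#' @return Fold enrichment (>= 0).
#' @examples
#' fold_enrichment(497, 346, 94, 4546) # about 2.5
#' @export
fold_enrichment <- function(n_a, n_b, k, background_n) {
  if (n_a <= 0 || n_b <= 0) stop_domain("fold_enrichment: zero-size set")
  if (k > min(n_a, n_b)) stop_domain("fold_enrichment: overlap exceeds a set size")
  if (n_a > background_n || n_b > background_n) {
    stop_domain("fold_enrichment: set larger than background")
  }
  k * background_n / (n_a * n_b)
}

#' Hypergeometric / Fisher test of a two-set overlap
#'
#' `sided = "greater"` gives the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing at least the observed overlap; `sided = "two"`
#' gives Fisher's exact two-sided p (sum of table probabilities no larger
#' than the observed one).
#'
#' @inheritParams fold_enrichment
#' @param sided `"greater"` (enrichment) or `"two"`.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_overlap(5, 4, 4, 10) # 5/210
#' @export
fisher_overlap <- function(n_a, n_b, k, background_n,
                           sided = c("greater", "two")) {
  sided <- match.arg(sided)
  cells <- c(k, n_a - k, n_b - k, background_n - n_a - n_b + k)
  if (any(cells < 0)) stop_domain("fisher_overlap: negative contingency cell")
  if (sided == "greater") {
    phyper(k - 1, n_a, background_n - n_a, n_b, lower.tail = FALSE)
  } else {
    tab <- matrix(cells, nrow = 2)
    fisher.test(tab, alternative = "two.sided")$p.value
  }
}

#' Overlap statistics for two gene sets
#'
#' Computes the overlap of two gene sets (exact, case-sensitive symbol
#' match), its fold enrichment over a stated background, and the upper-tail
#' hypergeometric p-value.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param background_n Background universe size (must be stated explicitly;
#'   e.g. 4546 annotated IR-capable loci, or 22000 genes for expression).
#' @param sided Passed to [fisher_overlap()].
#' @return One-row tibble of class `ir_overlap`: `n_a`, `n_b`, `k`,
#'   `background_n`, `expected`, `fold_enrichment`, `fisher_p`.
#' @examples
#' s <- build_sets_with_overlap(4546, c(403, 252, 94))
#' overlap_test(s$sets$A, s$sets$B, 4546)
#' @export
overlap_test <- function(set_a, set_b, background_n,
                         sided = c("greater", "two")) {
  sided <- match.arg(sided)
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_a <- length(set_a); n_b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  out <- tibble::tibble(
    n_a = n_a, n_b = n_b, k = k, background_n = background_n,
    expected = n_a * n_b / background_n,
    fold_enrichment = fold_enrichment(n_a, n_b, k, background_n),
    fisher_p = fisher_overlap(n_a, n_b, k, background_n, sided = sided))
  structure(out, class = c("ir_overlap", class(out)))
}

#' @rdname overlap_test
#' @param x An `ir_overlap` row.
#' @param ... Unused.
#' @export
glance.ir_overlap <- function(x, ...) tibble::as_tibble(x)

#' Three-set Venn partition
#'
#' Counts the seven exclusive regions of three sets and the derived
#' quantities used when comparing gene lists across studies: per-set totals,
#' pairwise and triple overlaps, and for each set the number of its members
#' shared with at least one other set.
#'
#' @param set_a,set_b,set_c Character vectors (duplicates ignored).
#' @return List with `regions` (named integer vector `a_only`, `b_only`,
#'   `c_only`, `ab`, `ac`, `bc`, `abc`; pairwise regions exclude the third
#'   set), `totals`, `pairwise` (full pairwise intersections), `triple`,
#'   and `shared` (per-set count of members in >= 1 other set).
#' @export
venn3 <- function(set_a, set_b, set_c) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- unique(c(a, b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  regions <- c(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab = sum(in_a & in_b & !in_c),
    ac = sum(in_a & !in_b & in_c),
    bc = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c))
  list(
    regions = regions,
    totals = c(A = length(a), B = length(b), C = length(c)),
    pairwise = c(AB = regions[["ab"]] + regions[["abc"]],
                 AC = regions[["ac"]] + regions[["abc"]],
                 BC = regions[["bc"]] + regions[["abc"]]),
    triple = regions[["abc"]],
    shared = c(A = regions[["ab"]] + regions[["ac"]] + regions[["abc"]],
               B = regions[["ab"]] + regions[["bc"]] + regions[["abc"]],
               C = regions[["ac"]] + regions[["bc"]] + regions[["abc"]]))
}
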