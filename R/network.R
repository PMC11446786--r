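# PPI link-count enrichment: score-filtered interactome, link counts of a
# query gene set against a functional target set, hub ranking, and a
# random-set permutation null.

#' Build a score-filtered interactome from an edge table
#'
#' Canonicalizes an undirected weighted edge list: confidence scores on a
#' 0-1000 dialect are rescaled to `[0, 1]` (auto-detected when any score
#' exceeds 1), self-loops are removed, duplicate pairs are collapsed to the
#' highest-scoring record, and edges below `score_cutoff` (inclusive keep at
#' the cutoff) are dropped.
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `score` (as read by
#'   [read_edges()]).
#' @param score_cutoff Minimum confidence score retained.
#' @return Object of class `interactome` with elements `edges` (canonical
#'   tibble, `gene_a < gene_b`), `nodes`, `score_cutoff`.
#' @export
as_interactome <- function(edges, score_cutoff = 0.7) {
  req <- c("gene_a", "gene_b", "score")
  if (!all(req %in% names(edges))) {
    stop_domain("as_interactome: edge table needs columns %s",
                paste(req, collapse = ", "))
  }
  if (any(!is.finite(edges$score))) stop_domain("as_interactome: non-numeric scores")
  if (any(edges$score > 1)) edges$score <- edges$score / 1000
  edges <- edges[edges$gene_a != edges$gene_b, ]
  edges <- tibble::tibble(gene_a = pmin(edges$gene_a, edges$gene_b),
                          gene_b = pmax(edges$gene_a, edges$gene_b),
                          score = edges$score) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  edges <- edges[edges$score >= score_cutoff, ]
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 score_cutoff = score_cutoff),
            class = "interactome")
}

#' @rdname as_interactome
#' @param path Path to a 3-column tab-separated edge file.
#' @export
load_interactome <- function(path, score_cutoff = 0.7) {
  as_interactome(read_edges(path), score_cutoff = score_cutoff)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("Interactome: %d nodes, %d edges (score >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$score_cutoff))
  invisible(x)
}

# Per-node count of distinct neighbors inside `target_set`. Self pairs are
# impossible (no self-loops), so a query gene that is itself in the target
# set simply counts its other target neighbors.
target_degree <- function(net, target_set) {
  e <- net$edges
  both <- tibble::tibble(node = c(e$gene_a, e$gene_b),
                         neighbor = c(e$gene_b, e$gene_a))
  hits <- both[both$neighbor %in% target_set, ]
  counts <- table(hits$node)
  deg <- setNames(rep(0L, length(net$nodes)), net$nodes)
  deg[names(counts)] <- as.integer(counts)
  deg
}

#' Links between a query gene set and a target gene set
#'
#' For every query gene present in the network, counts its distinct
#' neighbors belonging to the target set; the observed total is the sum
#' over query genes (i.e. the number of query-target edges, counting an
#' edge once per query endpoint).
#'
#' @param net An `interactome`.
#' @param query_set,target_set Character vectors of gene symbols.
#' @return List with `counts` (tibble `gene`, `link_count`, all query genes
#'   found in the network, zeros included) and `observed_total`.
#' @export
link_counts <- function(net, query_set, target_set) {
  query_eff <- intersect(query_set, net$nodes)
  if (length(query_eff) == 0) {
    stop_domain("link_counts: no query gene present in the network")
  }
  deg <- target_degree(net, target_set)
  counts <- tibble::tibble(gene = query_eff,
                           link_count = unname(deg[query_eff]))
  list(counts = counts, observed_total = sum(counts$link_count))
}

#' Random-set null distribution of link totals
#'
#' Draws `K` gene sets of a given size uniformly without replacement from a
#' universe (by default, all network nodes outside the target set) and
#' scores each by its total link count to the target set.
#'
#' @param net An `interactome`.
#' @param set_size Size of each random set.
#' @param target_set Target gene set.
#' @param K Number of random sets.
#' @param seed Integer seed.
#' @param universe Candidate pool; defaults to `setdiff(nodes, target_set)`.
#' @return Integer vector of `K` null totals.
#' @export
random_set_null <- function(net, set_size, target_set, K = 999, seed = 1,
                            universe = NULL) {
  if (K < 1) stop_config("random_set_null: K must be >= 1")
  universe <- universe %||% setdiff(net$nodes, target_set)
  if (length(universe) < set_size) {
    stop_config("random_set_null: universe smaller than set_size")
  }
  deg <- target_degree(net, target_set)
  set.seed(as.integer(seed))
  vapply(seq_len(K), function(k) {
    sum(deg[sample(universe, set_size)])
  }, numeric(1))
}

#' Permutation p-value from a null distribution
#'
#' `p = (#\{null >= observed\} + 1) / (K + 1)`, the standard add-one
#' permutation estimate, bounded below by `1/(K+1)`.
#'
#' @param observed_total Observed link total.
#' @param null_totals Numeric vector of null totals.
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed_total, null_totals) {
  if (length(null_totals) == 0) stop_domain("empirical_p: empty null distribution")
  (sum(null_totals >= observed_total) + 1) / (length(null_totals) + 1)
}

#' Rank query genes by link count
#'
#' @param counts Tibble `gene`, `link_count` (from [link_counts()]).
#' @param top_n Number of rows returned.
#' @return Tibble sorted by `link_count` descending, ties broken
#'   lexicographically by symbol, with a `rank` column.
#' @export
rank_links <- function(counts, top_n = 30) {
  counts |>
    dplyr::arrange(dplyr::desc(.data$link_count), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "gene", "link_count") |>
    head(top_n)
}

#' Link-count enrichment of a gene set against a functional set
#'
#' End-to-end enrichment analysis: observed query-target link counts, a
#' `K`-set permutation null ([random_set_null()]), the add-one empirical
#' p-value, and — when `K >= 30` — a normal-approximation z-test against
#' the null mean and standard deviation as a secondary statistic.
#'
#' @inheritParams random_set_null
#' @param query_set Query gene set (e.g. IR genes).
#' @param match_size Size of the random sets; defaults to the number of
#'   query genes present in the network (equal-size random sets).
#' @return Object of class `link_enrichment`; [tidy()] returns per-gene
#'   counts, [glance()] the totals, `empirical_p`, `z` and `p_normal`.
#' @examples
#' sim <- simulate_interactome(60, 0.05, 8, 10, 0.4, seed = 5)
#' net <- as_interactome(sim$edges)
#' enr <- link_enrichment(net, sim$query_set, sim$target_set, K = 99, seed = 1)
#' glance(enr)
#' @export
link_enrichment <- function(net, query_set, target_set, K = 999, seed = 1,
                            universe = NULL, match_size = NULL) {
  obs <- link_counts(net, query_set, target_set)
  size <- match_size %||% nrow(obs$counts)
  nulls <- random_set_null(net, size, target_set, K = K, seed = seed,
                           universe = universe)
  p_emp <- empirical_p(obs$observed_total, nulls)
  z <- p_norm <- NA_real_
  if (K >= 30 && sd(nulls) > 0) {
    z <- (obs$observed_total - mean(nulls)) / sd(nulls)
    p_norm <- stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(counts = obs$counts, observed_total = obs$observed_total,
                 null_totals = nulls, K = K, empirical_p = p_emp,
                 z = z, p_normal = p_norm),
            class = "link_enrichment")
}

#' @export
print.link_enrichment <- function(x, ...) {
  cat(sprintf("Link enrichment: observed %d links vs %d random sets, p = %.4g\n",
              x$observed_total, x$K, x$empirical_p))
  invisible(x)
}

#' @rdname link_enrichment
#' @param x A `link_enrichment` object.
#' @param ... Unused.
#' @export
tidy.link_enrichment <- function(x, ...) x$counts

#' @rdname link_enrichment
#' @export
glance.link_enrichment <- function(x, ...) {
  tibble::tibble(observed_total = x$observed_total,
                 null_mean = mean(x$null_totals),
                 null_sd = sd(x$null_totals),
                 K = x$K,
                 empirical_p = x$empirical_p,
                 z = x$z,
                 p_normal = x$p_normal)
}
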