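# Synthetic-data generators: junction-count tables with planted differential
# IR, negative-binomial expression matrices, interactomes with planted excess
# connectivity, and gene-set triples with exact Venn-region counts. Every
# generator returns ground truth alongside the data so calibration and power
# of the downstream statistics can be measured.

#' Beta-binomial random draws
#'
#' Draws counts from a beta-binomial with mean proportion `prob` and
#' intra-class correlation `rho` (`alpha = prob(1-rho)/rho`,
#' `beta = (1-prob)(1-rho)/rho`). `rho = 0` is the pure binomial.
#'
#' @param n Number of draws.
#' @param size Integer vector of trial counts (recycled).
#' @param prob Mean inclusion proportion(s).
#' @param rho Intra-class correlation in `[0, 1)`.
#' @return Integer vector of counts.
#' @export
rbeta_binom <- function(n, size, prob, rho) {
  if (any(rho < 0) || any(rho >= 1)) stop_config("rbeta_binom: rho must be in [0, 1)")
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  if (all(rho == 0)) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- rbeta(n, a, b)
  rbinom(n, size, p)
}

#' Scenario for synthetic intron-retention counts
#'
#' Bundles the parameters of the junction-count generator. Defaults mirror a
#' small case-control blood-transcriptome study arm: 6 control and 8 case
#' subjects; an optional third (post-treatment) group is paired with the
#' case subjects. Baseline intron ratios are Beta-distributed, case-group
#' ratios of planted events are shifted by `delta_psi` and clamped to
#' `[0.01, 0.99]`, and a third group reverts a fraction `frac_recover` of
#' planted events to baseline (a reverse-V / V trajectory).
#'
#' @param n_events Number of intron events.
#' @param groups Named integer vector, group label -> number of samples, in
#'   group order (2 or 3 groups).
#' @param baseline_psi_dist Length-2 `(alpha, beta)` of the Beta distribution
#'   of baseline intron ratios.
#' @param frac_inc,frac_dec Fractions of events with a planted increase /
#'   decrease in the second group (`frac_inc + frac_dec <= 1`).
#' @param delta_psi Planted effect magnitude in `[0, 1]`.
#' @param overdispersion_rho Intra-class correlation of inclusion counts in
#'   `[0, 1)`.
#' @param depth_mean,depth_dispersion Mean and NB dispersion of total
#'   junction reads per event per sample.
#' @param frac_recover Fraction of planted events reverting to baseline in a
#'   third group (ignored for 2-group designs).
#' @param subject_effect_sd SD of a per-subject logit-normal random effect on
#'   the intron ratio; subjects are shared between groups 2 and 3 when those
#'   groups have equal size (a paired pre/post design).
#' @param events_per_gene Events mapped to each synthetic gene.
#' @param seed Integer seed; identical scenarios produce identical tables.
#' @return List of class `ir_scenario`.
#' @export
ir_scenario <- function(n_events = 2000,
                        groups = c(CON = 6, BMT = 8),
                        baseline_psi_dist = c(2, 6),
                        frac_inc = 0, frac_dec = 0,
                        delta_psi = 0.2,
                        overdispersion_rho = 0.01,
                        depth_mean = 50, depth_dispersion = 0.3,
                        frac_recover = 1,
                        subject_effect_sd = 0,
                        events_per_gene = 1,
                        seed = 1) {
  if (frac_inc < 0 || frac_dec < 0 || frac_inc + frac_dec > 1) {
    stop_config("ir_scenario: need frac_inc, frac_dec >= 0 and frac_inc + frac_dec <= 1")
  }
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    stop_config("ir_scenario: overdispersion_rho must be in [0, 1)")
  }
  if (delta_psi < 0 || delta_psi > 1) stop_config("ir_scenario: delta_psi must be in [0, 1]")
  if (length(groups) < 2 || length(groups) > 3 || is.null(names(groups))) {
    stop_config("ir_scenario: groups must be a named vector of 2 or 3 sample sizes")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) {
    stop_config("ir_scenario: depth parameters must be positive")
  }
  structure(list(n_events = as.integer(n_events), groups = groups,
                 baseline_psi_dist = baseline_psi_dist,
                 frac_inc = frac_inc, frac_dec = frac_dec,
                 delta_psi = delta_psi,
                 overdispersion_rho = overdispersion_rho,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 frac_recover = frac_recover,
                 subject_effect_sd = subject_effect_sd,
                 events_per_gene = as.integer(events_per_gene),
                 seed = as.integer(seed)),
            class = "ir_scenario")
}

clamp_psi <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Simulate junction counts with planted differential intron retention
#'
#' Generates a long inclusion/skipping count table under the model the
#' differential-IR test assumes: per cell, a total junction depth drawn
#' negative-binomially, and an inclusion count drawn beta-binomially around
#' the group's true intron ratio with intra-class correlation
#' `overdispersion_rho`.
#'
#' @param scenario An [ir_scenario()].
#' @return List with `counts` (tibble `event_id`, `gene`, `sample_id`,
#'   `group`, `inclusion`, `skipping`, `inc_form_len`, `skip_form_len`) and
#'   `truth` (tibble `event_id`, `gene`, `label` in
#'   `IncIR`/`DecIR`/`null`, one `psi_<group>` column per group, and
#'   `delta_true` = group-2 minus group-1 true ratio).
#' @examples
#' sim <- simulate_ir_counts(ir_scenario(n_events = 10, seed = 2))
#' head(sim$counts)
#' @export
simulate_ir_counts <- function(scenario) {
  if (!inherits(scenario, "ir_scenario")) scenario <- do.call(ir_scenario, scenario)
  set.seed(scenario$seed)
  n <- scenario$n_events
  g_labels <- names(scenario$groups)
  n_groups <- length(g_labels)

  event_id <- sprintf("ev%05d", seq_len(n))
  gene <- sprintf("g%05d", ceiling(seq_len(n) / scenario$events_per_gene))

  base <- clamp_psi(rbeta(n, scenario$baseline_psi_dist[1],
                          scenario$baseline_psi_dist[2]))
  k_inc <- round(scenario$frac_inc * n)
  k_dec <- round(scenario$frac_dec * n)
  label <- rep("null", n)
  if (k_inc > 0) label[seq_len(k_inc)] <- "IncIR"
  if (k_dec > 0) label[k_inc + seq_len(k_dec)] <- "DecIR"

  psi <- matrix(base, nrow = n, ncol = n_groups,
                dimnames = list(event_id, g_labels))
  shift <- ifelse(label == "IncIR", scenario$delta_psi,
                  ifelse(label == "DecIR", -scenario$delta_psi, 0))
  psi[, 2] <- clamp_psi(base + shift)
  if (n_groups == 3) {
    planted <- which(label != "null")
    recovered <- planted[seq_len(round(scenario$frac_recover * length(planted)))]
    psi[, 3] <- psi[, 2]
    psi[recovered, 3] <- base[recovered]
  }

  # per-sample subject effects on the logit scale; groups 2 and 3 share
  # subjects when sizes match (paired pre/post design)
  n_per <- unname(scenario$groups)
  sample_id <- unlist(lapply(seq_len(n_groups), function(g) {
    sprintf("%s_%d", g_labels[g], seq_len(n_per[g]))
  }))
  sample_group <- rep(g_labels, n_per)
  eff <- rep(0, length(sample_id))
  if (scenario$subject_effect_sd > 0) {
    eff1 <- stats::rnorm(n_per[1], 0, scenario$subject_effect_sd)
    eff2 <- stats::rnorm(n_per[2], 0, scenario$subject_effect_sd)
    eff <- c(eff1, eff2)
    if (n_groups == 3) {
      eff3 <- if (n_per[3] == n_per[2]) eff2 else
        stats::rnorm(n_per[3], 0, scenario$subject_effect_sd)
      eff <- c(eff, eff3)
    }
  }

  n_samples <- length(sample_id)
  cell_psi <- psi[, match(sample_group, g_labels), drop = FALSE]
  if (scenario$subject_effect_sd > 0) {
    cell_psi <- stats::plogis(stats::qlogis(cell_psi) +
                                rep(eff, each = n)[seq_len(n * n_samples)])
    dim(cell_psi) <- c(n, n_samples)
  }

  depth <- rnbinom(n * n_samples, mu = scenario$depth_mean,
                   size = 1 / scenario$depth_dispersion)
  incl <- rbeta_binom(n * n_samples, depth, as.vector(cell_psi),
                      scenario$overdispersion_rho)

  counts <- tibble::tibble(
    event_id = rep(event_id, times = n_samples),
    gene = rep(gene, times = n_samples),
    sample_id = rep(sample_id, each = n),
    group = rep(sample_group, each = n),
    inclusion = incl,
    skipping = depth - incl,
    inc_form_len = 1,
    skip_form_len = 1)

  truth <- tibble::tibble(event_id = event_id, gene = gene, label = label)
  for (g in g_labels) truth[[paste0("psi_", g)]] <- psi[, g]
  truth$delta_true <- psi[, 2] - psi[, 1]

  list(counts = counts, truth = truth, scenario = scenario)
}

#' Simulate a negative-binomial expression count matrix
#'
#' Gene-level counts with log-normal baseline means, library-size scaling and
#' an even split of planted up/down fold changes in the second group. Any
#' third group reverts planted genes to baseline (expression recovery).
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of group sizes (first group is the
#'   reference).
#' @param frac_de Fraction of genes with a planted fold change.
#' @param log2fc Planted absolute log2 fold change.
#' @param dispersion NB dispersion (1/size); must be positive.
#' @param lib_sizes Relative library scale factors, one per sample (default
#'   all 1).
#' @param mean_expr Mean of the baseline expression distribution.
#' @param seed Integer seed.
#' @return List with `counts` (tibble, `gene` column then one column per
#'   sample), `groups` (named character vector sample -> group) and `truth`
#'   (tibble `gene`, `label` in `up`/`down`/`null`, `log2fc_true`).
#' @export
simulate_expression <- function(n_genes = 2000, groups = c(CON = 6, BMT = 8),
                                frac_de = 0, log2fc = 1, dispersion = 0.1,
                                lib_sizes = NULL, mean_expr = 100, seed = 1) {
  if (dispersion <= 0) stop_config("simulate_expression: dispersion must be positive")
  if (frac_de < 0 || frac_de > 1) stop_config("simulate_expression: frac_de must be in [0, 1]")
  n_samples <- sum(groups)
  lib_sizes <- lib_sizes %||% rep(1, n_samples)
  if (length(lib_sizes) != n_samples || any(lib_sizes <= 0)) {
    stop_config("simulate_expression: lib_sizes must be positive, one per sample")
  }
  set.seed(as.integer(seed))

  gene <- sprintf("g%05d", seq_len(n_genes))
  mu <- rlnorm(n_genes, meanlog = log(mean_expr) - 0.5, sdlog = 1)

  k <- round(frac_de * n_genes)
  k_up <- floor(k / 2)
  label <- rep("null", n_genes)
  if (k > 0) {
    label[seq_len(k_up)] <- "up"
    label[k_up + seq_len(k - k_up)] <- "down"
  }
  lfc <- ifelse(label == "up", log2fc, ifelse(label == "down", -log2fc, 0))

  g_labels <- names(groups)
  sample_group <- rep(g_labels, groups)
  sample_id <- unlist(lapply(seq_along(groups), function(g) {
    sprintf("%s_%d", g_labels[g], seq_len(groups[g]))
  }))

  counts <- matrix(0L, nrow = n_genes, ncol = n_samples,
                   dimnames = list(gene, sample_id))
  for (s in seq_len(n_samples)) {
    fc <- if (sample_group[s] == g_labels[2]) 2^lfc else 1
    counts[, s] <- rnbinom(n_genes, mu = mu * fc * lib_sizes[s],
                           size = 1 / dispersion)
  }

  list(counts = tibble::as_tibble(counts, rownames = "gene"),
       groups = setNames(sample_group, sample_id),
       truth = tibble::tibble(gene = gene, label = label, log2fc_true = lfc))
}

#' Simulate an interactome with planted excess connectivity
#'
#' Erdős–Rényi background graph plus independently added query-target edges,
#' with edge confidence scores uniform on `[0.7, 1.0]`. The query and target
#' sets are disjoint node blocks.
#'
#' @param n_genes Number of nodes.
#' @param edge_prob Background edge probability.
#' @param query_set_size,target_set_size Sizes of the two designated sets
#'   (`query_set_size + target_set_size <= n_genes`).
#' @param excess_edge_prob Extra, independent probability of each
#'   query-target edge.
#' @param seed Integer seed.
#' @return List with `edges` (tibble `gene_a`, `gene_b`, `score`, canonical
#'   `gene_a < gene_b`), `query_set`, `target_set`, `nodes`.
#' @export
simulate_interactome <- function(n_genes, edge_prob, query_set_size,
                                 target_set_size, excess_edge_prob, seed = 1) {
  probs <- c(edge_prob, excess_edge_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop_config("simulate_interactome: probabilities must be in [0, 1]")
  }
  if (query_set_size + target_set_size > n_genes) {
    stop_config("simulate_interactome: query and target sets exceed n_genes")
  }
  set.seed(as.integer(seed))
  nodes <- sprintf("n%05d", seq_len(n_genes))
  query <- nodes[seq_len(query_set_size)]
  target <- nodes[query_set_size + seq_len(target_set_size)]

  ia <- rep(seq_len(n_genes - 1), times = (n_genes - 1):1)
  ja <- unlist(lapply(seq_len(n_genes - 1), function(i) (i + 1):n_genes))
  present <- stats::runif(length(ia)) < edge_prob
  if (excess_edge_prob > 0) {
    bipartite <- (ia <= query_set_size &
                    ja > query_set_size & ja <= query_set_size + target_set_size)
    present <- present | (bipartite & stats::runif(length(ia)) < excess_edge_prob)
  }
  a <- nodes[ia[present]]
  b <- nodes[ja[present]]
  edges <- tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b),
                          score = stats::runif(length(a), 0.7, 1.0))
  list(edges = edges, query_set = query, target_set = target, nodes = nodes)
}

#' Build gene sets achieving exact Venn-region counts
#'
#' Constructs two or three gene sets over a synthetic universe so that every
#' exclusive Venn region has exactly the requested number of genes.
#'
#' @param background_n Size of the gene universe.
#' @param region_counts For two sets, `(a_only, b_only, ab)`; for three sets
#'   the 7 exclusive regions `(a_only, b_only, c_only, ab, ac, bc, abc)`
#'   (pairwise regions exclude the third set). Names, when given, are
#'   honoured; otherwise this positional order is assumed.
#' @param seed Optional seed; when given, the universe is shuffled before
#'   block assignment so membership is not positional.
#' @return List with `sets` (named list `A`, `B` and possibly `C`),
#'   `universe`, and the validated `regions`.
#' @examples
#' s <- build_sets_with_overlap(4546, c(a_only = 403, b_only = 252, ab = 94))
#' length(s$sets$A) # 497
#' @export
build_sets_with_overlap <- function(background_n, region_counts, seed = NULL) {
  rc <- region_counts
  two_names <- c("a_only", "b_only", "ab")
  three_names <- c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc")
  if (length(rc) == 3) {
    names(rc) <- if (is.null(names(rc))) two_names else names(rc)
    rc <- rc[two_names]
  } else if (length(rc) == 7) {
    names(rc) <- if (is.null(names(rc))) three_names else names(rc)
    rc <- rc[three_names]
  } else {
    stop_config("build_sets_with_overlap: region_counts must have length 3 or 7")
  }
  if (any(is.na(rc)) || any(rc < 0) || any(rc != round(rc))) {
    stop_config("build_sets_with_overlap: region counts must be non-negative integers")
  }
  if (sum(rc) > background_n) {
    stop_config("build_sets_with_overlap: regions sum to %d > background %d",
                sum(rc), background_n)
  }
  universe <- sprintf("gene%05d", seq_len(background_n))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    universe <- sample(universe)
  }
  blocks <- split(universe[seq_len(sum(rc))],
                  rep(seq_along(rc), times = rc))
  names(blocks) <- names(rc)[as.integer(names(blocks))]
  pick <- function(nm) {
    as.character(unlist(blocks[intersect(nm, names(blocks))], use.names = FALSE))
  }
  sets <- if (length(rc) == 3) {
    list(A = pick(c("a_only", "ab")), B = pick(c("b_only", "ab")))
  } else {
    list(A = pick(c("a_only", "ab", "ac", "abc")),
         B = pick(c("b_only", "ab", "bc", "abc")),
         C = pick(c("c_only", "ac", "bc", "abc")))
  }
  list(sets = sets, universe = universe, regions = rc)
}
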