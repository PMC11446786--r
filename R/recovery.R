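# Drug-induced IR recovery across an ordered three-group design
# (control -> pre-treatment -> post-treatment): Venn intersection of two
# differential-IR runs and per-locus trajectory ANOVA.

#' Classify recovery patterns from two differential-IR runs
#'
#' Intersects per-event calls from the control-vs-pre and pre-vs-post
#' comparisons: a locus significantly increased pre-treatment and decreased
#' post-treatment is a `reverse_V` (rise-then-fall) recovery, the converse a
#' `V`; every other tested event is `none`. When the two runs were tested on
#' different event universes a warning is raised and the intersection
#' proceeds on the common subset.
#'
#' @param run_pre_vs_control,run_post_vs_pre `diff_ir` objects (or tidied
#'   tibbles with `event_id` and `call`).
#' @return Tibble `event_id`, `pattern` in `reverse_V` / `V` / `none`.
#' @export
venn_recovery <- function(run_pre_vs_control, run_post_vs_pre) {
  e1 <- if (inherits(run_pre_vs_control, "diff_ir")) run_pre_vs_control$events else run_pre_vs_control
  e2 <- if (inherits(run_post_vs_pre, "diff_ir")) run_post_vs_pre$events else run_post_vs_pre
  common <- intersect(e1$event_id, e2$event_id)
  if (length(common) < length(union(e1$event_id, e2$event_id))) {
    rlang::warn(sprintf(
      "venn_recovery: event universes differ; proceeding on %d common events",
      length(common)))
  }
  c1 <- setNames(as.character(e1$call), e1$event_id)[common]
  c2 <- setNames(as.character(e2$call), e2$event_id)[common]
  pattern <- rep("none", length(common))
  pattern[c1 == "IncIR" & c2 == "DecIR"] <- "reverse_V"
  pattern[c1 == "DecIR" & c2 == "IncIR"] <- "V"
  tibble::tibble(event_id = common,
                 pattern = factor(pattern, levels = c("reverse_V", "V", "none")))
}

#' One-way ANOVA with Tukey HSD for a single locus trajectory
#'
#' Fixed-effects one-way ANOVA of per-sample intron ratios across (typically
#' three) groups, with Tukey honest-significant-difference pairwise
#' comparisons via the studentized-range distribution.
#'
#' @param psi Numeric vector of per-sample intron ratios (may contain `NA`).
#' @param groups Group label per sample; at least two non-missing
#'   observations required per group.
#' @return List with `f_stat`, `p_value`, and `tukey` (tibble `pair`,
#'   `diff`, `adj_p`).
#' @examples
#' anova_trajectory(c(1, 2, 3, 2, 3, 4, 5, 6, 7),
#'                  rep(c("a", "b", "c"), each = 3))
#' @export
anova_trajectory <- function(psi, groups) {
  ok <- !is.na(psi)
  psi <- psi[ok]
  grp <- factor(groups[ok])
  if (any(table(grp) < 2) || nlevels(grp) < 2) {
    stop_domain("anova_trajectory: need >= 2 non-missing values per group")
  }
  fit <- aov(psi ~ grp)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$grp
  tibble_tk <- tibble::tibble(pair = rownames(tk),
                              diff = tk[, "diff"],
                              adj_p = tk[, "p adj"])
  list(f_stat = s[["F value"]][1],
       p_value = s[["Pr(>F)"]][1],
       tukey = tibble_tk)
}

#' Three-group IR recovery analysis
#'
#' Runs the two-leg differential-IR comparison (control vs pre-treatment,
#' pre- vs post-treatment) on a three-group junction-count table, classifies
#' each common event's recovery pattern by [venn_recovery()], and tests the
#' ratio trajectory of each recovered locus by one-way ANOVA. Tukey pairwise
#' comparisons are attached only when the omnibus ANOVA is significant at
#' `anova_alpha`.
#'
#' @param counts Long junction-count tibble containing three groups.
#' @param group_labels Character vector of the three group labels in order
#'   (control, pre-treatment, post-treatment).
#' @param p_max,fdr_max,min_delta,coverage_min Thresholds passed to
#'   [diff_ir()] for both legs.
#' @param anova_alpha Gate for attaching Tukey comparisons.
#' @return Object of class `ir_recovery`: `calls` tibble (`event_id`,
#'   `pattern`, `anova_f`, `anova_p`, `tukey` list-column), plus the two leg
#'   fits. [glance()] tabulates the patterns.
#' @examples
#' sc <- ir_scenario(n_events = 40, groups = c(CON = 4, BMT = 4, AMT = 4),
#'                   frac_inc = 0.25, delta_psi = 0.3, depth_mean = 80,
#'                   seed = 9)
#' rec <- recover_ir(simulate_ir_counts(sc)$counts, c("CON", "BMT", "AMT"))
#' glance(rec)
#' @export
recover_ir <- function(counts, group_labels, p_max = 0.05, fdr_max = 0.1,
                       min_delta = 0.05, coverage_min = 10,
                       anova_alpha = 0.05) {
  if (length(group_labels) != 3) {
    stop_domain("recover_ir: exactly three ordered group labels required")
  }
  leg1 <- diff_ir(counts, group_labels[1], group_labels[2], p_max = p_max,
                  fdr_max = fdr_max, min_delta = min_delta,
                  coverage_min = coverage_min)
  leg2 <- diff_ir(counts, group_labels[2], group_labels[3], p_max = p_max,
                  fdr_max = fdr_max, min_delta = min_delta,
                  coverage_min = coverage_min)
  calls <- venn_recovery(leg1, leg2)

  sub <- counts[counts$group %in% group_labels, ]
  if (!"inc_form_len" %in% names(sub)) sub$inc_form_len <- 1
  if (!"skip_form_len" %in% names(sub)) sub$skip_form_len <- 1
  sub$psi <- compute_psi(sub$inclusion, sub$skipping,
                         sub$inc_form_len, sub$skip_form_len)
  sub$psi[sub$inclusion + sub$skipping <= coverage_min] <- NA_real_

  recovered <- calls$event_id[calls$pattern != "none"]
  anova_res <- purrr::map(calls$event_id, function(ev) {
    if (!ev %in% recovered) return(list(f_stat = NA_real_, p_value = NA_real_,
                                        tukey = NULL))
    rows <- sub[sub$event_id == ev, ]
    tryCatch(anova_trajectory(rows$psi, rows$group),
             irmarker_domain_error = function(e) {
               list(f_stat = NA_real_, p_value = NA_real_, tukey = NULL)
             })
  })
  calls$anova_f <- purrr::map_dbl(anova_res, "f_stat")
  calls$anova_p <- purrr::map_dbl(anova_res, "p_value")
  calls$tukey <- purrr::map2(anova_res, calls$anova_p, function(r, p) {
    if (!is.null(r$tukey) && !is.na(p) && p < anova_alpha) r$tukey else NULL
  })

  structure(list(calls = calls, leg_pre_vs_control = leg1,
                 leg_post_vs_pre = leg2, group_labels = group_labels),
            class = "ir_recovery")
}

#' @export
print.ir_recovery <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("IR recovery (%s -> %s -> %s): %d reverse-V, %d V of %d events\n",
              x$group_labels[1], x$group_labels[2], x$group_labels[3],
              g$n_reverse_v, g$n_v, g$n_events))
  invisible(x)
}

#' @rdname recover_ir
#' @param x An `ir_recovery` object.
#' @param ... Unused.
#' @export
tidy.ir_recovery <- function(x, ...) x$calls

#' @rdname recover_ir
#' @export
glance.ir_recovery <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$calls),
    n_reverse_v = sum(x$calls$pattern == "reverse_V"),
    n_v = sum(x$calls$pattern == "V"),
    n_none = sum(x$calls$pattern == "none"))
}

#' Summarise recovery-pattern calls
#'
#' Tabulates recovery patterns and, when the underlying count table is
#' supplied, reports the mean intron ratio per group at each recovered locus
#' (the numbers behind a per-group box plot of recovered loci).
#'
#' @param calls Tibble from [venn_recovery()] (or the `calls` of an
#'   `ir_recovery`).
#' @param counts Optional long junction-count tibble for per-group means.
#' @param coverage_min Coverage mask applied before averaging.
#' @return List with `patterns` (tibble `pattern`, `n`, `fraction`) and
#'   `psi_means` (tibble `event_id`, `pattern`, `group`, `mean_psi`; `NULL`
#'   without `counts`).
#' @export
recovery_summary <- function(calls, counts = NULL, coverage_min = 10) {
  if (inherits(calls, "ir_recovery")) calls <- calls$calls
  patterns <- calls |>
    dplyr::count(.data$pattern, name = "n", .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))

  psi_means <- NULL
  if (!is.null(counts)) {
    recovered <- calls[calls$pattern != "none", c("event_id", "pattern")]
    if (nrow(recovered) > 0) {
      sub <- counts[counts$event_id %in% recovered$event_id, ]
      if (!"inc_form_len" %in% names(sub)) sub$inc_form_len <- 1
      if (!"skip_form_len" %in% names(sub)) sub$skip_form_len <- 1
      sub$psi <- compute_psi(sub$inclusion, sub$skipping,
                             sub$inc_form_len, sub$skip_form_len)
      sub$psi[sub$inclusion + sub$skipping <= coverage_min] <- NA_real_
      psi_means <- sub |>
        dplyr::group_by(.data$event_id, .data$group) |>
        dplyr::summarise(mean_psi = mean(.data$psi, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::left_join(recovered, by = "event_id") |>
        dplyr::select("event_id", "pattern", "group", "mean_psi")
    }
  }
  list(patterns = patterns, psi_means = psi_means)
}
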