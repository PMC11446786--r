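# Readers and writers: self-describing TSV tables ('#'-prefixed metadata
# header lines), GMT gene sets, 3-column edge lists, the rMATS retained-
# intron (RI.MATS.JC.txt) dialect, and a YAML pipeline configuration.

write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, function(col) {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

read_tsv_meta <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", na = "NA",
                  col_types = col_types %||% readr::cols(),
                  show_col_types = FALSE, progress = FALSE)
}

#' Read and write long junction-count tables
#'
#' Long format: one row per (event, sample) with columns `event_id`,
#' optional `gene`, `sample_id`, `group`, `inclusion`, `skipping`, and
#' optional `inc_form_len`, `skip_form_len`. Writers prefix '#' metadata
#' lines (ignored by the reader).
#'
#' @param counts Count tibble as produced by [simulate_ir_counts()].
#' @param path File path.
#' @param meta Named list written as '#' header lines.
#' @return The tibble (reader) or `path`, invisibly (writer).
#' @export
read_ir_counts <- function(path) {
  tbl <- read_tsv_meta(path)
  check_counts_tbl(tbl, "read_ir_counts")
  tbl
}

#' @rdname read_ir_counts
#' @export
write_ir_counts <- function(counts, path, meta = list()) {
  check_counts_tbl(counts, "write_ir_counts")
  write_tsv_meta(counts, path, meta)
}

#' Read and write gene-by-sample count matrices
#'
#' Tab-separated, first column `gene`, one column per sample.
#'
#' @param counts Tibble with `gene` column or matrix with rownames.
#' @inheritParams read_ir_counts
#' @export
read_count_matrix <- function(path) {
  tbl <- read_tsv_meta(path)
  if (names(tbl)[1] != "gene") names(tbl)[1] <- "gene"
  tbl
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path, meta = list()) {
  if (is.matrix(counts)) {
    counts <- tibble::as_tibble(counts, rownames = "gene")
  }
  write_tsv_meta(counts, path, meta)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene ...`.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return Named list of character vectors (reader) or `path` (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop_domain("read_gmt: malformed line '%s'", l)
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write weighted edge lists
#'
#' Three tab-separated columns `gene_a`, `gene_b`, `score` (with or without
#' a header line). Malformed rows raise an error naming the line.
#'
#' @param path File path.
#' @param edges Tibble with the three columns.
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_domain("read_edges: empty edge file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1
  if (identical(tolower(fields[[1]][1]), "gene_a")) start <- 2
  rows <- seq(start, length(lines))
  bad <- rows[vapply(fields[rows], length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop_domain("read_edges: malformed row at line %d of %s", bad[1], path)
  }
  scores <- suppressWarnings(
    as.numeric(vapply(fields[rows], `[[`, character(1), 3)))
  if (any(is.na(scores))) {
    stop_domain("read_edges: non-numeric score at line %d of %s",
                rows[which(is.na(scores))[1]], path)
  }
  tibble::tibble(
    gene_a = vapply(fields[rows], `[[`, character(1), 1),
    gene_b = vapply(fields[rows], `[[`, character(1), 2),
    score = scores)
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  write_tsv_meta(edges[c("gene_a", "gene_b", "score")], path)
}

#' Read an rMATS retained-intron junction-count file
#'
#' Parses the `RI.MATS.JC.txt` dialect: per-event rows with comma-joined
#' replicate counts in `IJC_SAMPLE_1` / `SJC_SAMPLE_1` / `IJC_SAMPLE_2` /
#' `SJC_SAMPLE_2` and effective form lengths in `IncFormLen` /
#' `SkipFormLen`. Replicates become per-sample rows; sample groups are
#' labelled `group_1_label` and `group_2_label`.
#'
#' @param path File path.
#' @param group_1_label,group_2_label Group labels assigned to the two
#'   sample blocks.
#' @return Long junction-count tibble (see [read_ir_counts()]).
#' @export
read_rmats_ri <- function(path, group_1_label = "1", group_2_label = "2") {
  tbl <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(ID = "c", GeneID = "c", geneSymbol = "c",
                            IJC_SAMPLE_1 = "c", SJC_SAMPLE_1 = "c",
                            IJC_SAMPLE_2 = "c", SJC_SAMPLE_2 = "c",
                            .default = readr::col_guess()))
  req <- c("ID", "GeneID", "geneSymbol", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
           "IJC_SAMPLE_2", "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop_domain("read_rmats_ri: missing columns: %s",
                paste(missing, collapse = ", "))
  }
  split_counts <- function(x) lapply(strsplit(as.character(x), ","), as.integer)

  out <- vector("list", nrow(tbl))
  for (r in seq_len(nrow(tbl))) {
    i1 <- split_counts(tbl$IJC_SAMPLE_1[r])[[1]]
    s1 <- split_counts(tbl$SJC_SAMPLE_1[r])[[1]]
    i2 <- split_counts(tbl$IJC_SAMPLE_2[r])[[1]]
    s2 <- split_counts(tbl$SJC_SAMPLE_2[r])[[1]]
    if (length(i1) != length(s1) || length(i2) != length(s2)) {
      stop_domain("read_rmats_ri: ragged replicate counts in row %d (ID %s)",
                  r, tbl$ID[r])
    }
    out[[r]] <- tibble::tibble(
      event_id = as.character(tbl$ID[r]),
      gene = tbl$geneSymbol[r],
      sample_id = c(sprintf("%s_%d", group_1_label, seq_along(i1)),
                    sprintf("%s_%d", group_2_label, seq_along(i2))),
      group = c(rep(group_1_label, length(i1)),
                rep(group_2_label, length(i2))),
      inclusion = c(i1, i2),
      skipping = c(s1, s2),
      inc_form_len = tbl$IncFormLen[r],
      skip_form_len = tbl$SkipFormLen[r])
  }
  dplyr::bind_rows(out)
}

#' Write a long junction-count table in rMATS retained-intron dialect
#'
#' Inverse of [read_rmats_ri()] for two-group tables: replicate counts are
#' comma-joined per event, and `IncLevel1` / `IncLevel2` columns carry the
#' per-sample length-adjusted intron ratios.
#'
#' @param counts Long junction-count tibble with exactly two groups.
#' @param path File path.
#' @param group_a,group_b Group labels mapped to sample blocks 1 and 2 (in
#'   group order of the table when omitted).
#' @export
write_rmats_ri <- function(counts, path, group_a = NULL, group_b = NULL) {
  check_counts_tbl(counts, "write_rmats_ri")
  g <- unique(as.character(counts$group))
  group_a <- group_a %||% g[1]
  group_b <- group_b %||% g[2]
  if (!"inc_form_len" %in% names(counts)) counts$inc_form_len <- 1
  if (!"skip_form_len" %in% names(counts)) counts$skip_form_len <- 1
  if (!"gene" %in% names(counts)) counts$gene <- NA_character_

  join <- function(x) paste(x, collapse = ",")
  rows <- counts |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    dplyr::arrange(.data$event_id, .data$group, .data$sample_id) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      GeneID = .data$gene[1],
      geneSymbol = .data$gene[1],
      IJC_SAMPLE_1 = join(.data$inclusion[.data$group == group_a]),
      SJC_SAMPLE_1 = join(.data$skipping[.data$group == group_a]),
      IJC_SAMPLE_2 = join(.data$inclusion[.data$group == group_b]),
      SJC_SAMPLE_2 = join(.data$skipping[.data$group == group_b]),
      IncFormLen = .data$inc_form_len[1],
      SkipFormLen = .data$skip_form_len[1],
      IncLevel1 = join(round(compute_psi(
        .data$inclusion[.data$group == group_a],
        .data$skipping[.data$group == group_a],
        .data$inc_form_len[1], .data$skip_form_len[1]), 3)),
      IncLevel2 = join(round(compute_psi(
        .data$inclusion[.data$group == group_b],
        .data$skipping[.data$group == group_b],
        .data$inc_form_len[1], .data$skip_form_len[1]), 3)),
      .groups = "drop") |>
    dplyr::rename(ID = "event_id")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Aggregates every tunable threshold of the pipeline in one serializable
#' object: the dual significance rule for differential IR and expression,
#' the coverage and interaction-score cutoffs, permutation count, seed and
#' background universe sizes.
#'
#' @param p_max,fdr_max,min_delta,fc_min,coverage_min,score_cutoff
#'   Thresholds (see the stage functions for semantics).
#' @param k_permutations Random sets for link enrichment.
#' @param seed Global seed.
#' @param background_ir,background_deg Overlap background universe sizes for
#'   IR genes and expressed genes.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(p_max = 0.05, fdr_max = 0.1, min_delta = 0.05,
                            fc_min = 1.2, coverage_min = 10,
                            score_cutoff = 0.7, k_permutations = 999,
                            seed = 1, background_ir = 4546,
                            background_deg = 22000) {
  cfg <- list(p_max = p_max, fdr_max = fdr_max, min_delta = min_delta,
              fc_min = fc_min, coverage_min = coverage_min,
              score_cutoff = score_cutoff,
              k_permutations = as.integer(k_permutations),
              seed = as.integer(seed),
              background_ir = as.integer(background_ir),
              background_deg = as.integer(background_deg))
  bad <- names(cfg)[vapply(cfg, function(v) !is.numeric(v) || v <= 0, logical(1))]
  if (length(bad) > 0) {
    stop_config("pipeline_config: non-positive value for %s",
                paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
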