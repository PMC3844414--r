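# Multi-metric ranking: directional z-scores summed over key metrics,
# leave-one-metric-out bounds, average ranks, the paired-read consistency
# summary score, and metric correlations.

metric_cols <- function(tbl) setdiff(names(tbl), c("assembly", "label", "species"))

assembly_ids <- function(tbl) {
  key <- intersect(c("assembly", "label"), names(tbl))[1]
  if (is.na(key)) abort("metric table needs an 'assembly' or 'label' column")
  tbl[[key]]
}

check_directions <- function(tbl, directions) {
  metrics <- metric_cols(tbl)
  missing <- setdiff(metrics, names(directions))
  if (length(missing) > 0) {
    abort(paste0("no direction declared for metric(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(directions[metrics]), c("higher_better", "lower_better"))
  if (length(bad) > 0) {
    abort("directions must be 'higher_better' or 'lower_better'")
  }
  metrics
}

#' Directional z-scores summed over key metrics
#'
#' Standardises each metric over its non-missing values (`z = (x - mean)/sd`),
#' negates lower-is-better metrics, and sums across metrics per assembly.
#' Missing values contribute 0 to an assembly's sum; a metric with zero
#' spread contributes 0 for every assembly, with a warning.
#'
#' @param tbl Metric table: an `assembly` (or `label`) column plus one
#'   numeric column per metric.
#' @param directions Named character vector mapping every metric to
#'   `"higher_better"` or `"lower_better"`; defaults to the key-metric
#'   registry directions.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Tibble with `assembly`, one `z` column per metric, and `sum_z`,
#'   sorted best-first.
#' @export
zscore_rank <- function(tbl, directions = registry_directions(),
                        sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(tbl) < 2) abort("z-scores need at least 2 assemblies")
  metrics <- check_directions(tbl, directions)
  z <- sapply(metrics, function(m) {
    x <- tbl[[m]]
    obs <- !is.na(x)
    if (sum(obs) < 2) abort(paste0("metric '", m, "' has fewer than 2 values"))
    mu <- mean(x[obs])
    s <- sd(x[obs])
    if (sd_type == "population") s <- s * sqrt((sum(obs) - 1) / sum(obs))
    zi <- rep(0, length(x))              # missing values contribute 0
    if (is.na(s) || s == 0) {
      warn(paste0("metric '", m, "' has zero spread; its z-scores are 0"))
    } else {
      zi[obs] <- (x[obs] - mu) / s
      if (directions[[m]] == "lower_better") zi <- -zi
    }
    zi
  })
  z <- matrix(z, nrow = nrow(tbl), dimnames = list(NULL, metrics))
  out <- dplyr::bind_cols(tibble(assembly = assembly_ids(tbl)), as_tibble(z))
  out$sum_z <- rowSums(z)
  arrange(out, dplyr::desc(.data$sum_z))
}

#' Leave-one-metric-out bounds on the summed z-score
#'
#' Removes each metric in turn, recomputes the summed z-score, and reports
#' the per-assembly minimum and maximum over all single-metric deletions —
#' the error bars on z-score rankings.
#'
#' @inheritParams zscore_rank
#' @return Tibble with `assembly`, `sum_z`, `min_sum`, `max_sum`.
#' @export
loo_bounds <- function(tbl, directions = registry_directions(),
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  metrics <- check_directions(tbl, directions)
  if (length(metrics) < 2) abort("leave-one-out needs at least 2 metrics")
  full <- zscore_rank(tbl, directions, sd_type)
  # a metric's z-scores do not depend on the other metrics, so each
  # deletion just subtracts that metric's (direction-adjusted) column
  z <- as.matrix(full[metrics])
  loo <- full$sum_z - z
  tibble(assembly = full$assembly,
         sum_z = full$sum_z,
         min_sum = apply(loo, 1, min),
         max_sum = apply(loo, 1, max))
}

#' Average rank across metrics
#'
#' Ranks assemblies within each metric (rank 1 = best given the metric's
#' direction, ties get the midrank, missing values excluded) and averages
#' the ranks over the metrics for which an assembly has data.
#'
#' @inheritParams zscore_rank
#' @return Tibble with `assembly`, `avg_rank`, `n_metrics`, sorted best-first.
#' @export
average_rank <- function(tbl, directions = registry_directions()) {
  if (nrow(tbl) < 2) abort("ranking needs at least 2 assemblies")
  metrics <- check_directions(tbl, directions)
  ranks <- sapply(metrics, function(m) {
    x <- tbl[[m]]
    if (directions[[m]] == "higher_better") x <- -x
    r <- rep(NA_real_, length(x))
    r[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average")
    r
  })
  ranks <- matrix(ranks, nrow = nrow(tbl), dimnames = list(NULL, metrics))
  tibble(assembly = assembly_ids(tbl),
         avg_rank = rowMeans(ranks, na.rm = TRUE),
         n_metrics = rowSums(!is.na(ranks))) |>
    arrange(.data$avg_rank)
}

#' Pairwise metric correlations
#'
#' Pearson correlations between metrics over pairwise-complete assemblies,
#' with two-sided p-values. Pairs with fewer than 3 complete observations
#' are reported as missing.
#'
#' @inheritParams zscore_rank
#' @return Long tibble with `metric1`, `metric2`, `n`, `r`, `p_value`.
#' @export
metric_correlations <- function(tbl) {
  metrics <- metric_cols(tbl)
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    x <- tbl[[p[1]]]; y <- tbl[[p[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(tibble(metric1 = p[1], metric2 = p[2], n = sum(ok),
                    r = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "pearson"))
    tibble(metric1 = p[1], metric2 = p[2], n = sum(ok),
           r = unname(ct$estimate), p_value = ct$p.value)
  }) |>
    bind_rows()
}

#' Paired-read consistency summary score
#'
#' Combines, per assembly, the number of error-free bases with the scaffold
#' N50 before and after breaking the assembly at detected scaffolding
#' errors. Each of the three statistics is normalised by its within-species
#' maximum (the best assembly gets 1), then
#' `score = ef_norm * broken_norm^2 / orig_norm`.
#'
#' @param tbl Tibble with columns `assembly` (or `label`),
#'   `error_free_bases`, `original_n50`, `broken_n50`, one row per assembly
#'   of one species.
#' @return Tibble with `assembly` and `reapr_score`.
#' @export
reapr_summary <- function(tbl) {
  need <- c("error_free_bases", "original_n50", "broken_n50")
  if (!all(need %in% names(tbl))) {
    abort(paste0("missing column(s): ",
                 paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  if (nrow(tbl) < 1) abort("need at least one assembly")
  vals <- tbl[need]
  if (any(as.matrix(vals) < 0, na.rm = TRUE)) abort("inputs must be non-negative")
  if (any(tbl$broken_n50 > tbl$original_n50)) {
    abort("broken_n50 cannot exceed original_n50")
  }
  maxima <- vapply(vals, max, numeric(1))
  if (any(maxima <= 0)) {
    abort("each statistic must have a positive maximum across assemblies")
  }
  ef <- tbl$error_free_bases / unname(maxima["error_free_bases"])
  orig <- tbl$original_n50 / unname(maxima["original_n50"])
  broken <- tbl$broken_n50 / unname(maxima["broken_n50"])
  tibble(assembly = assembly_ids(tbl),
         reapr_score = ef * broken^2 / orig)
}

#' Rank assemblies by summed z-score with bounds and average rank
#'
#' One-stop ranking: per-metric z-scores summed, leave-one-out bounds, and
#' the average-rank ordering, in one table.
#'
#' @inheritParams zscore_rank
#' @return Tibble with `assembly`, `sum_z`, `min_sum`, `max_sum`,
#'   `avg_rank`, `rank`, sorted best-first by `sum_z`.
#' @export
rank_assemblies <- function(tbl, directions = registry_directions(),
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  lb <- loo_bounds(tbl, directions, sd_type)
  ar <- average_rank(tbl, directions)
  lb |>
    left_join(ar, by = "assembly") |>
    mutate(rank = row_number()) |>
    select("assembly", "rank", "sum_z", "min_sum", "max_sum",
           "avg_rank", "n_metrics")
}

#' The key-metric registry
#'
#' The ten canonical key metrics used for overall ranking, with their
#' optimisation direction, the module that computes them (external-tool
#' metrics are accepted in the table but never computed here), and species
#' availability (fosmid-based metrics exist only where fosmid data do).
#'
#' @return Tibble with `metric`, `description`, `direction`, `source`,
#'   `external`, `availability`.
#' @export
key_metric_registry <- function() {
  tibble::tribble(
    ~metric, ~description, ~direction, ~source, ~external, ~availability,
    "ng50_scaffold", "NG50 scaffold length", "higher_better", "contiguity", FALSE, "all",
    "ng50_contig", "NG50 contig length", "higher_better", "contiguity", FALSE, "all",
    "gene_sized_absdiff",
    "absolute difference between gene-sized (>=25 Kbp) scaffold content and genome size",
    "lower_better", "contiguity", FALSE, "all",
    "cegma_core_genes", "number of 458 core eukaryotic genes detected",
    "higher_better", "external", TRUE, "all",
    "fosmid_coverage", "coverage of validated fosmid regions",
    "higher_better", "compass", FALSE, "fosmid_species",
    "fosmid_validity", "validity against validated fosmid regions",
    "higher_better", "compass", FALSE, "fosmid_species",
    "vfr_tag_score", "validated-region tag-pair summary score",
    "higher_better", "vfr_tags", FALSE, "fosmid_species",
    "optmap_level1", "optical map level-1 coverage",
    "higher_better", "external", TRUE, "all",
    "optmap_level123", "optical map level-1+2+3 coverage",
    "higher_better", "external", TRUE, "all",
    "reapr_score", "paired-read consistency summary score",
    "higher_better", "reapr", FALSE, "all"
  )
}

#' @rdname key_metric_registry
#' @export
registry_directions <- function() {
  reg <- key_metric_registry()
  setNames(reg$direction, reg$metric)
}

#' Read and write metric tables
#'
#' The canonical CSV exchange format: one row per assembly, a header row,
#' empty fields for missing values, and a sidecar JSON file declaring each
#' metric's direction. [read_metric_table()] attaches the directions as the
#' `"directions"` attribute.
#'
#' @param tbl Metric table.
#' @param path CSV path.
#' @param directions Named direction vector (defaults to the registry for
#'   the table's metric columns).
#' @param directions_path Sidecar JSON path (default `<path>.directions.json`).
#' @return `read_metric_table()`: the tibble with a `"directions"`
#'   attribute; `write_metric_table()`: `path`, invisibly.
#' @export
write_metric_table <- function(tbl, path, directions = NULL,
                               directions_path = paste0(path, ".directions.json")) {
  if (is.null(directions)) {
    directions <- registry_directions()
    directions <- directions[intersect(names(directions), names(tbl))]
  }
  check_directions(tbl, directions)
  readr::write_csv(tbl, path, na = "")
  jsonlite::write_json(as.list(directions), directions_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path, directions_path = paste0(path, ".directions.json")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, na = "")
  if (file.exists(directions_path)) {
    dirs <- unlist(jsonlite::read_json(directions_path))
    attr(tbl, "directions") <- dirs
  }
  tbl
}

#' Export the master metric table
#'
#' One row per assembly and one column per registered metric, in registry
#' order, with empty fields for metrics that were not computed. Extra
#' columns in the input are preserved after the registered ones.
#'
#' @param tbl Tibble of per-assembly results with an `assembly`/`label` column.
#' @param path CSV output path.
#' @return The exported tibble, invisibly.
#' @export
export_master_table <- function(tbl, path) {
  reg <- key_metric_registry()
  out <- tibble(assembly = assembly_ids(tbl))
  for (m in reg$metric) {
    out[[m]] <- if (m %in% names(tbl)) tbl[[m]] else NA_real_
  }
  extra <- setdiff(names(tbl), c("assembly", "label", reg$metric))
  for (m in extra) out[[m]] <- tbl[[m]]
  readr::write_csv(out, path, na = "")
  invisible(out)
}
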