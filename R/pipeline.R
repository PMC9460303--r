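#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end reliability pipeline: the window
#' grid, the feature tunables, the significance level, the duration filter
#' and the seed used by any synthetic-study generation. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()]), and
#' every output file written by [report_results()] embeds its hash.
#'
#' @param grid A [window_grid()].
#' @param registry A [feature_registry()].
#' @param opts A [feature_options()] list.
#' @param alpha Significance level for all tests (default 0.05; no
#'   multiple-testing correction by default, set `p_adjust = "BH"` for
#'   Benjamini-Hochberg-adjusted users' analyses downstream).
#' @param min_duration_s Run-duration filter threshold (strictly greater
#'   than; default 180 s, the reference window).
#' @param exact Wilcoxon/Spearman exact-p policy (`"auto"`, `"exact"`,
#'   `"approx"`).
#' @param seed Integer seed recorded with the outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid = window_grid(),
                            registry = feature_registry(),
                            opts = feature_options(),
                            alpha = 0.05,
                            min_duration_s = 180,
                            exact = "auto",
                            seed = 1L) {
  structure(list(grid = grid, registry = registry, opts = opts,
                 alpha = alpha, min_duration_s = min_duration_s,
                 exact = exact, seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable short hash of the configuration (md5 of its YAML serialisation)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(.config_as_list(config), tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

.config_as_list <- function(config) {
  list(
    windows = config$grid$sizes_s, step_s = config$grid$step_s,
    features = config$registry$feature_id,
    opts = unclass(config$opts),
    alpha = config$alpha, min_duration_s = config$min_duration_s,
    exact = config$exact, seed = config$seed
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    grid = window_grid(unlist(raw$windows), raw$step_s),
    registry = feature_registry(features = unlist(raw$features)),
    opts = do.call(feature_options, raw$opts),
    alpha = raw$alpha, min_duration_s = raw$min_duration_s,
    exact = raw$exact, seed = raw$seed
  )
}

#' Run the end-to-end reliability pipeline
#'
#' Filters the study to runs longer than the reference window, extracts
#' every registry feature at every grid window, logs the per-run
#' Kolmogorov-Smirnov normality screen, and produces the Wilcoxon
#' acceptance matrix, the Spearman/Fisher correlation summary, window-trend
#' regressions of both matrices' rows, and per-run/feature/window
#' non-parametric Bland-Altman summaries.
#'
#' @param study A [study_set()].
#' @param config A [pipeline_config()].
#' @return A `reliability_results` bundle: list with `features` (long
#'   tibble), `ks_log`, `acceptance`, `correlation`,
#'   `trend_acceptance` / `trend_correlation` (tibbles, one row per
#'   feature), `bland_altman` (tibble), `config`, `config_hash`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  stopifnot(inherits(study, "study_set"))
  kept <- filter_runs_by_duration(study, config$min_duration_s)
  if (length(kept) == 0L) {
    stop(sprintf(
      "run_pipeline: no runs longer than the %g-s duration filter",
      config$min_duration_s), call. = FALSE)
  }
  features <- extract_study(kept, grid = config$grid,
                            registry = config$registry, opts = config$opts)
  ks_log <- features |>
    dplyr::group_by(.data$subject_id, .data$run_id, .data$feature_id,
                    .data$window_s) |>
    dplyr::summarise(
      n_defined = sum(is.finite(.data$value)),
      ks_p = if (sum(is.finite(.data$value)) >= 8L)
        ks_normality(.data$value) else NA_real_,
      .groups = "drop"
    )
  acceptance <- wilcoxon_acceptance_matrix(
    features, alpha = config$alpha, exact = config$exact)
  correlation <- correlation_summary(
    features, alpha = config$alpha, step_s = config$grid$step_s,
    exact = config$exact)
  wins <- as.numeric(sub("s$", "", colnames(acceptance$pct)))
  trend <- function(mat) {
    dplyr::bind_rows(lapply(rownames(mat), function(f) {
      fit <- tryCatch(window_trend_regression(mat[f, ], wins),
                      error = function(e) list(slope = NA_real_,
                                               intercept = NA_real_,
                                               r2 = NA_real_))
      tibble::tibble(feature_id = f, slope = fit$slope,
                     intercept = fit$intercept, r2 = fit$r2)
    }))
  }
  ba <- .bland_altman_table(features, acceptance$ref_window_s,
                            config$grid$step_s)
  structure(
    list(features = features, ks_log = ks_log,
         acceptance = acceptance, correlation = correlation,
         trend_acceptance = trend(acceptance$pct),
         trend_correlation = trend(correlation$fisher_mean),
         bland_altman = ba,
         config = config, config_hash = config_hash(config)),
    class = "reliability_results"
  )
}

# per run/feature/window Bland-Altman summaries as a tidy table
.bland_altman_table <- function(features, ref_window_s, step_s) {
  rows <- list()
  for (run in .split_runs(features)) {
    by_feat <- split(run, factor(run$feature_id,
                                 levels = unique(run$feature_id)))
    for (df in by_feat) {
      ref <- df[df$window_s == ref_window_s, c("center_s", "value")]
      if (!nrow(ref)) next
      for (w in sort(unique(df$window_s), decreasing = TRUE)) {
        sh <- df[df$window_s == w, c("center_s", "value")]
        s <- tryCatch(bland_altman(sh, ref, step_s = step_s),
                      error = function(e) NULL)
        if (is.null(s)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = df$subject_id[1], run_id = df$run_id[1],
          feature_id = df$feature_id[1], window_s = w,
          bias = s$bias, loa_low = s$loa_low, loa_high = s$loa_high,
          frac_within = s$frac_within, n = s$n
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.reliability_results <- function(x, ...) {
  cat(sprintf(
    "<reliability_results> %d features x %d windows, %d runs (hash %s)\n",
    nrow(x$acceptance$pct), ncol(x$acceptance$pct),
    dplyr::n_distinct(paste(x$features$subject_id, x$features$run_id)),
    x$config_hash))
  invisible(x)
}

# write one CSV with a config-hash/drop-count comment header
.write_csv_stamped <- function(df, path, hash, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  if (!is.null(note)) writeLines(sprintf("# %s", note), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.matrix_to_df <- function(mat) {
  data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
             row.names = NULL)
}

#' Write the result bundle to a directory
#'
#' Writes the acceptance and correlation matrices, both regression tables,
#' the Bland-Altman table, the KS log, the configuration (YAML) and a text
#' summary listing the top-5 features per window size by Fisher-mean
#' correlation (ties broken by registry order). Every CSV carries the
#' configuration hash and drop-count totals in a comment header.
#'
#' @param results A `reliability_results` bundle from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_results <- function(results, dir) {
  stopifnot(inherits(results, "reliability_results"))
  if (is.null(results$acceptance) || !nrow(results$features)) {
    stop("report_results: empty results bundle", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- results$config_hash
  drops <- sprintf("dropped cells: wilcoxon %d, spearman %d",
                   sum(results$acceptance$n_dropped),
                   sum(results$correlation$n_dropped))
  paths <- c(
    .write_csv_stamped(.matrix_to_df(results$acceptance$pct),
                       file.path(dir, "acceptance_matrix.csv"), h, drops),
    .write_csv_stamped(.matrix_to_df(results$correlation$fisher_mean),
                       file.path(dir, "fisher_mean_matrix.csv"), h, drops),
    .write_csv_stamped(.matrix_to_df(results$correlation$sig_pct),
                       file.path(dir, "significant_correlation_pct.csv"),
                       h, drops),
    .write_csv_stamped(results$trend_acceptance,
                       file.path(dir, "trend_acceptance.csv"), h),
    .write_csv_stamped(results$trend_correlation,
                       file.path(dir, "trend_correlation.csv"), h),
    .write_csv_stamped(results$bland_altman,
                       file.path(dir, "bland_altman.csv"), h),
    .write_csv_stamped(results$ks_log,
                       file.path(dir, "ks_normality_log.csv"), h),
    .write_csv_stamped(results$features,
                       file.path(dir, "features_long.csv"), h)
  )
  cfg_path <- file.path(dir, "config.yml")
  write_pipeline_config(results$config, cfg_path)
  top_path <- file.path(dir, "top5_by_window.txt")
  writeLines(c(sprintf("# config_hash: %s", h),
               "# top-5 features per window by Fisher-mean correlation",
               "# (ties broken by registry order)",
               .top5_lines(results$correlation$fisher_mean)), top_path)
  invisible(c(paths, cfg_path, top_path))
}

.top5_lines <- function(fisher) {
  out <- character(0)
  for (w in colnames(fisher)) {
    v <- fisher[, w]
    ord <- order(-v, seq_along(v), na.last = TRUE)  # registry-order ties
    top <- utils::head(ord[is.finite(v[ord])], 5)
    out <- c(out, sprintf("%s: %s", w, paste(
      sprintf("%s=%.2f", rownames(fisher)[top], v[top]), collapse = ", ")))
  }
  out
}
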