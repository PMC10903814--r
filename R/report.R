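# Summary tables: static effectiveness and dynamic index aggregates.

#' Pivot long scores into a DMU x period matrix
#'
#' @param scores Data frame with columns `dmu`, `period`, `rho` (e.g. rows
#'   of [score_period()] bound over periods).
#' @return Numeric matrix, DMUs in rows (input order), periods in columns.
#' @export
score_matrix <- function(scores) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("dmu", "period", "rho") %in% names(scores)))
  dmus <- unique(as.character(scores$dmu))
  periods <- unique(as.character(scores$period))
  M <- matrix(NA_real_, length(dmus), length(periods),
              dimnames = list(dmus, periods))
  M[cbind(as.character(scores$dmu), as.character(scores$period))] <- scores$rho
  M
}

.as_score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    M <- scores
  } else {
    M <- score_matrix(scores)
  }
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)
    stop("missing score cells: ",
         paste(sprintf("(%s, %s)", rownames(M)[bad[, 1]],
                       colnames(M)[bad[, 2]]), collapse = ", "))
  }
  M
}

#' Static efficiency summary
#'
#' Builds the standard presentation of a comprehensive-efficiency table
#' from a complete DMU x period score matrix: per-DMU and per-period
#' arithmetic means, the grand mean, per-period DEA-effective counts and
#' proportions (via [classify_effectiveness()]: score >= 1), and the list
#' of DMUs effective in every period. On a balanced matrix the grand mean
#' equals both the mean of the row means and the mean of the column means.
#'
#' @param scores DMU x period numeric matrix, or long data frame with
#'   columns `dmu`, `period`, `rho`.
#' @return A `static_summary`: list with `score_matrix`, `dmu_means`,
#'   `period_means`, `grand_mean`, `effective_counts`,
#'   `effective_proportions` (percent), `persistent_effective`, `n_dmu`.
#' @export
static_summary <- function(scores) {
  M <- .as_score_matrix(scores)
  eff <- classify_effectiveness(as.vector(M)) == "effective"
  effM <- matrix(eff, nrow(M), ncol(M), dimnames = dimnames(M))
  counts <- colSums(effM)
  res <- list(
    score_matrix = M,
    dmu_means = rowMeans(M),
    period_means = colMeans(M),
    grand_mean = mean(M),
    effective_counts = counts,
    effective_proportions = 100 * counts / nrow(M),
    persistent_effective = rownames(M)[rowSums(effM) == ncol(M)],
    n_dmu = nrow(M))
  class(res) <- "static_summary"
  res
}

#' @export
print.static_summary <- function(x, ...) {
  cat(sprintf("static_summary: %d DMUs x %d periods, grand mean %.3f\n",
              x$n_dmu, ncol(x$score_matrix), x$grand_mean))
  cat("  effective per period:",
      paste(sprintf("%s: %d (%.2f%%)", names(x$effective_counts),
                    x$effective_counts, x$effective_proportions),
            collapse = "; "), "\n")
  cat("  effective in every period:",
      if (length(x$persistent_effective))
        paste(x$persistent_effective, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' DMUs effective in every period
#'
#' @inheritParams static_summary
#' @return Character vector of DMU labels, in input order.
#' @export
persistent_effective <- function(scores) {
  static_summary(scores)$persistent_effective
}

#' Dynamic (Malmquist) summary
#'
#' Aggregates Malmquist records into the two published layouts — component
#' means per interval and per DMU — plus the overall mean row (identical
#' between the two layouts on complete record sets), the count of DMUs
#' whose per-DMU mean of each component falls strictly below the cross-DMU
#' arithmetic mean of that component, and the count of DMUs with mean
#' TFPCH strictly above 1. A table that is already one row per DMU (no
#' `interval` column) is treated as a set of per-DMU means.
#'
#' @param records Data frame of Malmquist records with columns `dmu`,
#'   `effch`, `tech`, `pech`, `sech`, `tfpch` (or `tfp`), optionally
#'   `interval` and `complete`. Incomplete records are excluded and
#'   counted.
#' @return A `dynamic_summary`: list with `interval_table`, `dmu_table`,
#'   `overall_means`, `below_mean_counts`, `tfpch_growth_dmus`,
#'   `n_tfpch_gt1`, `n_excluded`.
#' @export
dynamic_summary <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty Malmquist record set")
  if (!"interval" %in% names(records)) records$interval <- "overall"
  dmu_tab <- aggregate_dmu_means(records)
  int_tab <- aggregate_interval_means(records)
  cc <- .complete_records(records)
  overall <- colMeans(cc$records[.mqt_components])
  col_means <- colMeans(dmu_tab[.mqt_components])
  below <- vapply(.mqt_components,
                  function(k) sum(dmu_tab[[k]] < col_means[[k]]),
                  integer(1))
  growth <- dmu_tab$dmu[dmu_tab$tfpch > 1]
  res <- list(interval_table = int_tab, dmu_table = dmu_tab,
              overall_means = overall, below_mean_counts = below,
              tfpch_growth_dmus = growth, n_tfpch_gt1 = length(growth),
              n_excluded = cc$n_excluded)
  class(res) <- "dynamic_summary"
  res
}

#' @export
print.dynamic_summary <- function(x, ...) {
  cat(sprintf("dynamic_summary: %d DMUs, %d interval(s), %d record(s) excluded\n",
              nrow(x$dmu_table), nrow(x$interval_table), x$n_excluded))
  cat("  overall means:",
      paste(sprintf("%s %.3f", names(x$overall_means), x$overall_means),
            collapse = ", "), "\n")
  cat(sprintf("  DMUs with mean TFPCH > 1: %d\n", x$n_tfpch_gt1))
  invisible(x)
}

#' Run the full scoring and reporting pipeline
#'
#' Loads or generates a panel, scores every period with the unified
#' super-efficiency SBM, computes all Malmquist records (skipped with a
#' logged notice when only one period exists), and writes scores, records
#' and four summary files as CSV, plus a run log recording seed, returns
#' to scale, tolerances, solver statuses and exclusions.
#'
#' Files written to `out_dir`: `panel.csv` (and `truth.csv` for synthetic
#' runs), `static_scores.csv`, `malmquist_records.csv`,
#' `static_summary.csv`, `static_effectiveness.csv`,
#' `dynamic_interval_means.csv`, `dynamic_dmu_means.csv`, `run_log.txt`.
#'
#' @param panel A [panel_dataset()], or `NULL` to use `panel_file` or
#'   `synthetic`.
#' @param panel_file Path to a panel CSV (needs `schema`).
#' @param schema Schema for [read_panel()].
#' @param synthetic A [synthetic_config()] used when no panel is given.
#' @param rts Returns to scale for the static scores.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the synthetic config seed.
#' @return Invisibly, a list with `panel`, `scores`, `records`,
#'   `static`, `dynamic` (NULL when T = 1) and `files`.
#' @export
run_pipeline <- function(panel = NULL, panel_file = NULL, schema = NULL,
                         synthetic = NULL, rts = "crs",
                         out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_ <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }
  rts <- .match_rts(rts)
  log_("sbmdea pipeline")
  log_("rts: %s", rts)
  log_("tolerances: score 1e-6, effectiveness 1e-9")

  files <- character(0)
  truth <- NULL
  if (is.null(panel)) {
    if (!is.null(panel_file)) {
      if (is.null(schema)) stop("panel_file requires a schema")
      panel <- read_panel(panel_file, schema)
      log_("panel: read from %s", panel_file)
    } else if (!is.null(synthetic)) {
      if (!is.null(seed)) synthetic$seed <- as.integer(seed)
      gp <- generate_panel(synthetic)
      panel <- gp$panel
      truth <- gp$truth
      log_("panel: synthetic, seed %d", synthetic$seed)
      utils::write.csv(panel_to_long(panel), file.path(out_dir, "panel.csv"),
                       row.names = FALSE)
      utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      files <- c(files, file.path(out_dir, c("panel.csv", "truth.csv")))
    } else {
      stop("pipeline stage 'input': provide panel, panel_file or synthetic")
    }
  }
  log_("panel: %d DMUs x %d periods, %d inputs, %d outputs",
       length(panel$dmu_ids), length(panel$periods),
       length(panel$input_names), length(panel$output_names))

  scores <- do.call(rbind, lapply(panel$periods, function(p) {
    score_period(panel, p, rts)
  }))
  bad <- scores$status != "optimal"
  log_("static scores: %d computed, %d non-optimal", nrow(scores), sum(bad))
  f <- file.path(out_dir, "static_scores.csv")
  write_scores(scores, f)
  files <- c(files, f)

  stat <- static_summary(scores[!bad, , drop = FALSE])
  M <- stat$score_matrix
  sm <- data.frame(dmu = rownames(M), M, mean = stat$dmu_means,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mean_row <- data.frame(dmu = "Mean", t(stat$period_means),
                         mean = stat$grand_mean,
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(mean_row) <- names(sm)
  sm <- rbind(sm, mean_row)
  f <- file.path(out_dir, "static_summary.csv")
  utils::write.csv(sm, f, row.names = FALSE)
  files <- c(files, f)
  se <- data.frame(period = names(stat$effective_counts),
                   effective_count = as.integer(stat$effective_counts),
                   effective_proportion_pct =
                     sprintf("%.2f", stat$effective_proportions),
                   stringsAsFactors = FALSE)
  f <- file.path(out_dir, "static_effectiveness.csv")
  utils::write.csv(se, f, row.names = FALSE)
  files <- c(files, f)

  records <- NULL
  dyn <- NULL
  if (length(panel$periods) < 2L) {
    log_("dynamic stage skipped: only one period, no interval exists")
  } else {
    records <- malmquist_panel(panel)
    log_("malmquist records: %d computed, %d incomplete (excluded from means)",
         nrow(records), sum(!records$complete))
    f <- file.path(out_dir, "malmquist_records.csv")
    write_scores(records, f)
    files <- c(files, f)
    dyn <- dynamic_summary(records)
    f <- file.path(out_dir, "dynamic_interval_means.csv")
    utils::write.csv(dyn$interval_table, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "dynamic_dmu_means.csv")
    utils::write.csv(dyn$dmu_table, f, row.names = FALSE)
    files <- c(files, f)
    log_("DMUs with mean TFPCH > 1: %d", dyn$n_tfpch_gt1)
  }

  log_file <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_file)
  files <- c(files, log_file)
  invisible(list(panel = panel, truth = truth, scores = scores,
                 records = records, static = stat, dynamic = dyn,
                 files = files))
}
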