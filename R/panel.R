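# Balanced input/output panels.
#
# A panel holds n decision-making units (DMUs) observed over T periods, with
# m strictly positive inputs and q strictly positive outputs per observation.
# Every downstream solver assumes the panel is balanced and validated, which
# is why validation lives in the constructor and nowhere else.

#' Construct a balanced DMU input/output panel
#'
#' Builds a validated panel from a long data frame with one row per
#' (DMU, period) observation. The panel is the common currency of the
#' package: efficiency scoring, Malmquist decomposition and reporting all
#' operate on it.
#'
#' Validation enforces the contract the solvers rely on: the panel must be
#' balanced (every DMU observed in every period, exactly once), all input and
#' output values must be strictly positive, and at least two DMUs are needed
#' so that every unit has a peer when it is excluded from its own frontier.
#' Incomplete DMUs are rejected, never imputed: a unit with a missing year
#' cannot be benchmarked against the others and silently dropping or filling
#' it would bias every frontier it touches.
#'
#' @param data Data frame in long format.
#' @param dmu Name of the column holding DMU labels.
#' @param period Name of the column holding period labels.
#' @param inputs Character vector of input indicator columns (m >= 1).
#' @param outputs Character vector of output indicator columns (q >= 1).
#' @return An object of class `panel_dataset` with elements `dmu_ids`,
#'   `periods`, `X` (n x T x m array), `Y` (n x T x q array),
#'   `input_names`, `output_names`.
#' @examples
#' d <- data.frame(dmu = c("A", "B"), period = 2016, x = c(1, 2), y = 1)
#' p <- panel_dataset(d, inputs = "x", outputs = "y")
#' p$dmu_ids
#' @export
panel_dataset <- function(data, dmu = "dmu", period = "period", inputs, outputs) {
  data <- as.data.frame(data)
  need <- c(dmu, period, inputs, outputs)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  if (length(inputs) < 1L || length(outputs) < 1L) {
    stop("need at least one input and one output indicator")
  }
  overlap <- intersect(inputs, outputs)
  if (length(overlap)) {
    stop("indicator roles must be disjoint; both input and output: ",
         paste(overlap, collapse = ", "))
  }

  dmu_v <- as.character(data[[dmu]])
  per_v <- as.character(data[[period]])
  dmu_ids <- unique(dmu_v)
  periods <- unique(per_v)
  suppressWarnings(pnum <- as.numeric(periods))
  if (!anyNA(pnum)) periods <- periods[order(pnum)]

  key <- paste(dmu_v, per_v, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    d1 <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicate record for (%s, %s)", d1[1], d1[2]))
  }
  want <- as.vector(outer(dmu_ids, periods, paste, sep = "\r"))
  gaps <- setdiff(want, key)
  if (length(gaps)) {
    g1 <- strsplit(gaps[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("unbalanced panel: missing record for (%s, %s)%s",
                 g1[1], g1[2],
                 if (length(gaps) > 1) sprintf(" and %d more", length(gaps) - 1L) else ""))
  }
  if (length(dmu_ids) < 2L) {
    stop("need at least 2 DMUs per period (super-efficiency requires a peer)")
  }

  for (col in c(inputs, outputs)) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("indicator column is not numeric: ", col)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("domain violation: non-positive value in column '%s' for (%s, %s)",
                   col, dmu_v[bad[1]], per_v[bad[1]]))
    }
  }

  n <- length(dmu_ids)
  Tn <- length(periods)
  m <- length(inputs)
  q <- length(outputs)
  idx_d <- match(dmu_v, dmu_ids)
  idx_t <- match(per_v, periods)
  X <- array(NA_real_, dim = c(n, Tn, m),
             dimnames = list(dmu_ids, periods, inputs))
  Y <- array(NA_real_, dim = c(n, Tn, q),
             dimnames = list(dmu_ids, periods, outputs))
  for (j in seq_len(m)) X[cbind(idx_d, idx_t, j)] <- data[[inputs[j]]]
  for (j in seq_len(q)) Y[cbind(idx_d, idx_t, j)] <- data[[outputs[j]]]

  structure(
    list(dmu_ids = dmu_ids, periods = periods, X = X, Y = Y,
         input_names = inputs, output_names = outputs),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d DMUs x %d periods, %d inputs, %d outputs\n",
              length(x$dmu_ids), length(x$periods),
              length(x$input_names), length(x$output_names)))
  cat("  periods:", paste(x$periods, collapse = ", "), "\n")
  cat("  inputs: ", paste(x$input_names, collapse = ", "), "\n")
  cat("  outputs:", paste(x$output_names, collapse = ", "), "\n")
  invisible(x)
}

.peer_matrix <- function(arr, period) {
  # arr is n x T x k; returns k x n matrix for the given period label
  n <- dim(arr)[1]
  k <- dim(arr)[3]
  M <- matrix(arr[, period, ], nrow = n, ncol = k,
              dimnames = list(dimnames(arr)[[1]], dimnames(arr)[[3]]))
  t(M)
}

.check_period <- function(panel, period) {
  period <- as.character(period)
  if (!period %in% panel$periods) {
    stop("period not present in panel: ", period)
  }
  period
}

.check_dmu <- function(panel, dmu) {
  dmu <- as.character(dmu)
  if (!dmu %in% panel$dmu_ids) {
    stop("DMU not present in panel: ", dmu)
  }
  dmu
}

#' Convert a panel back to long format
#'
#' @param panel A `panel_dataset`.
#' @return Long data frame with columns `dmu`, `period` and one column per
#'   indicator, ordered DMU-major as in the panel.
#' @export
panel_to_long <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  n <- length(panel$dmu_ids)
  Tn <- length(panel$periods)
  out <- data.frame(
    dmu = rep(panel$dmu_ids, each = Tn),
    period = rep(panel$periods, times = n),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(panel$input_names)) {
    out[[panel$input_names[j]]] <- as.vector(t(panel$X[, , j]))
  }
  for (j in seq_along(panel$output_names)) {
    out[[panel$output_names[j]]] <- as.vector(t(panel$Y[, , j]))
  }
  out
}

#' Read a balanced panel from a delimited file
#'
#' Reads a long-format CSV (header row; one row per DMU-period) and validates
#' it into a [panel_dataset()]. Column roles are supplied as a schema: either
#' a named character vector mapping each column name to one of `"dmu"`,
#' `"period"`, `"input"`, `"output"`, or the path to a YAML file of
#' `column: role` pairs. Every data column must be named in the schema.
#' Row order in the file never affects downstream scores.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector of column roles, or path to a YAML
#'   file with `column: role` entries.
#' @return A validated `panel_dataset`.
#' @export
read_panel <- function(path, schema) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema))) {
    if (!file.exists(schema)) stop("schema file not found: ", schema)
    schema <- unlist(yaml::read_yaml(schema))
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    stop("schema must be a named vector of column roles")
  }
  bad_roles <- setdiff(unique(schema), c("dmu", "period", "input", "output"))
  if (length(bad_roles)) {
    stop("unknown schema roles: ", paste(bad_roles, collapse = ", "))
  }
  data <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  uncovered <- setdiff(names(data), names(schema))
  if (length(uncovered)) {
    stop("schema does not name columns: ", paste(uncovered, collapse = ", "))
  }
  dmu_col <- names(schema)[schema == "dmu"]
  per_col <- names(schema)[schema == "period"]
  if (length(dmu_col) != 1L || length(per_col) != 1L) {
    stop("schema must name exactly one 'dmu' and one 'period' column")
  }
  panel_dataset(data,
                dmu = dmu_col, period = per_col,
                inputs = names(schema)[schema == "input"],
                outputs = names(schema)[schema == "output"])
}

#' Write a result table to CSV with full precision
#'
#' Writes scores or Malmquist records as delimited text. Numeric score
#' columns are written at full (17 significant digit) precision so that a
#' write-then-read round trip is lossless, and each score column gains a
#' companion `<name>_display` column rounded to 3 decimals, mirroring the
#' conventional presentation of DEA result tables.
#'
#' @param results Nonempty data frame of homogeneous results (e.g. from
#'   [score_period()] or [malmquist_panel()]).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_scores <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a nonempty data frame")
  }
  out <- results
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  for (col in num_cols) {
    out[[paste0(col, "_display")]] <- sprintf("%.3f", out[[col]])
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
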