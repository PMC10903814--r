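# Adjacent-period Malmquist total-factor-productivity index.
#
# The geometric-mean (Fare et al.) form is used. Writing D^a(z_b) for the
# distance of period-b data to the period-a frontier (CRS),
#   EFFCH = D^{t+1}(z_{t+1}) / D^t(z_t)
#   TECH  = sqrt[ (D^t(z_{t+1}) / D^{t+1}(z_{t+1})) * (D^t(z_t) / D^{t+1}(z_t)) ]
#   TFPCH = EFFCH * TECH
#           = sqrt[ (D^t(z_{t+1}) / D^t(z_t)) * (D^{t+1}(z_{t+1}) / D^{t+1}(z_t)) ]
# and, with VRS own-period distances V,
#   PECH = V^{t+1}(z_{t+1}) / V^t(z_t),   SECH = EFFCH / PECH,
# so TFPCH = EFFCH * TECH and EFFCH = PECH * SECH hold by construction on
# every complete record.
#
# Own-period distances are the plain (self-inclusive) SBM scores: with the
# conventional distance functions the single-input/single-output CRS case
# collapses to productivity ratios (TFPCH = p_{t+1}/p_t, TECH = p*_{t+1}/p*_t
# for every unit), which anchors the closed-form validation. Cross-period
# distances may exceed 1 when a unit lies beyond the other period's frontier.

#' Cross-period distance quadruple for one DMU
#'
#' Computes the four CRS distance values feeding one Malmquist ratio:
#' `d_t_t` and `d_t1_t1` are the own-period plain SBM scores, `d_t_t1` and
#' `d_t1_t` the cross-period scores of [cross_period_score()] (naming:
#' `d_a_b` is the distance of period-b data to the period-a frontier).
#' Infeasible components are flagged, never replaced by numbers.
#'
#' @param panel A [panel_dataset()].
#' @param dmu DMU label.
#' @param interval Length-2 vector of adjacent period labels `c(t, t1)`.
#' @param rts Returns to scale for the distances (CRS by convention; the
#'   scale-efficiency decomposition is only defined against a CRS
#'   technology).
#' @return A `distance_quad`: list with `dmu`, `interval`, the four
#'   distances, `statuses` and `feasible` flags.
#' @export
compute_distances <- function(panel, dmu, interval, rts = "crs") {
  stopifnot(inherits(panel, "panel_dataset"), length(interval) == 2L)
  rts <- .match_rts(rts)
  dmu <- .check_dmu(panel, dmu)
  t0 <- .check_period(panel, interval[1])
  t1 <- .check_period(panel, interval[2])
  if (identical(t0, t1)) stop("interval must span two distinct periods")

  own <- function(p) solve_sbm(panel, dmu, p, p, rts)
  cross <- function(eval_p, front_p) .cross_distance(panel, dmu, eval_p, front_p, rts)
  r_tt   <- own(t0)
  r_t1t1 <- own(t1)
  r_tt1  <- cross(t1, t0)
  r_t1t  <- cross(t0, t1)
  comp <- list(d_t_t = r_tt, d_t_t1 = r_tt1, d_t1_t = r_t1t, d_t1_t1 = r_t1t1)
  statuses <- vapply(comp, function(r) r$status, character(1))
  quad <- list(
    dmu = dmu, interval = c(t0, t1), rts = rts,
    d_t_t = r_tt$rho, d_t_t1 = r_tt1$rho,
    d_t1_t = r_t1t$rho, d_t1_t1 = r_t1t1$rho,
    statuses = statuses,
    feasible = all(statuses == "optimal")
  )
  class(quad) <- "distance_quad"
  quad
}

#' Decompose one Malmquist ratio
#'
#' Combines a [compute_distances()] quadruple with the two own-period VRS
#' scores into the five index components. The identities
#' `tfpch == effch * tech` and `effch == pech * sech` hold by construction
#' on complete records; an incomplete quadruple yields a record flagged
#' `complete = FALSE` with `NA` components.
#'
#' @param quad A `distance_quad`.
#' @param vrs_t,vrs_t1 Own-period VRS plain SBM scores of the DMU at the two
#'   periods (numbers or `efficiency_result` objects).
#' @return A `malmquist_record`: list with `dmu`, `interval`, `effch`,
#'   `tech`, `pech`, `sech`, `tfpch`, `complete`.
#' @export
malmquist_decompose <- function(quad, vrs_t, vrs_t1) {
  stopifnot(inherits(quad, "distance_quad"))
  as_score <- function(v) {
    if (inherits(v, "efficiency_result")) {
      if (v$status != "optimal") return(NA_real_)
      v$rho
    } else as.numeric(v)
  }
  v0 <- as_score(vrs_t)
  v1 <- as_score(vrs_t1)
  ok <- quad$feasible && is.finite(v0) && is.finite(v1) && v0 > 0
  if (!ok) {
    rec <- list(dmu = quad$dmu, interval = quad$interval,
                effch = NA_real_, tech = NA_real_, pech = NA_real_,
                sech = NA_real_, tfpch = NA_real_, complete = FALSE)
  } else {
    effch <- quad$d_t1_t1 / quad$d_t_t
    tech <- sqrt((quad$d_t_t1 / quad$d_t1_t1) * (quad$d_t_t / quad$d_t1_t))
    pech <- v1 / v0
    rec <- list(dmu = quad$dmu, interval = quad$interval,
                effch = effch, tech = tech, pech = pech,
                sech = effch / pech, tfpch = effch * tech, complete = TRUE)
  }
  class(rec) <- "malmquist_record"
  rec
}

#' @export
print.malmquist_record <- function(x, ...) {
  cat(sprintf("Malmquist record %s [%s-%s]: ", x$dmu,
              x$interval[1], x$interval[2]))
  if (x$complete) {
    cat(sprintf("effch %.4f tech %.4f pech %.4f sech %.4f tfpch %.4f\n",
                x$effch, x$tech, x$pech, x$sech, x$tfpch))
  } else cat("incomplete\n")
  invisible(x)
}

#' Malmquist records for every DMU and adjacent interval
#'
#' Runs the whole dynamic analysis on a panel: CRS distance quadruples and
#' VRS own-period scores for every DMU over every pair of adjacent periods,
#' decomposed into EFFCH, TECH, PECH, SECH and TFPCH.
#'
#' @param panel A [panel_dataset()] with at least two periods.
#' @return Data frame with columns `dmu`, `interval` (label `"t-t1"`),
#'   `period_from`, `period_to`, `effch`, `tech`, `pech`, `sech`, `tfpch`,
#'   `complete`; `n_dmu * (T - 1)` rows.
#' @export
malmquist_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  periods <- panel$periods
  if (length(periods) < 2L) {
    stop("Malmquist indices need at least two periods")
  }
  # cache own-period VRS scores once per (dmu, period)
  vrs <- matrix(NA_real_, length(panel$dmu_ids), length(periods),
                dimnames = list(panel$dmu_ids, periods))
  for (p in periods) {
    for (d in panel$dmu_ids) {
      r <- solve_sbm(panel, d, p, p, "vrs")
      vrs[d, p] <- if (r$status == "optimal") r$rho else NA_real_
    }
  }
  rows <- list()
  for (i in seq_len(length(periods) - 1L)) {
    t0 <- periods[i]; t1 <- periods[i + 1L]
    for (d in panel$dmu_ids) {
      quad <- compute_distances(panel, d, c(t0, t1), "crs")
      rec <- malmquist_decompose(quad, vrs[d, t0], vrs[d, t1])
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = d, interval = paste(t0, t1, sep = "-"),
        period_from = t0, period_to = t1,
        effch = rec$effch, tech = rec$tech, pech = rec$pech,
        sech = rec$sech, tfpch = rec$tfpch, complete = rec$complete,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify an index component as growth, unchanged or decline
#'
#' A component above 1 indicates positive growth or improvement, exactly 1
#' no change, and below 1 decline; a 1e-9 band around 1 absorbs numerical
#' noise.
#'
#' @param value Positive numeric vector of index components.
#' @return Character vector: `"growth"`, `"unchanged"` or `"decline"`.
#' @examples
#' classify_change(c(1.099, 0.766, 1))
#' @export
classify_change <- function(value) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("index components must be positive and finite")
  }
  ifelse(value > 1 + .TOL_EFFECTIVE, "growth",
         ifelse(value >= 1 - .TOL_EFFECTIVE, "unchanged", "decline"))
}

.mqt_components <- c("effch", "tech", "pech", "sech", "tfpch")

.complete_records <- function(records) {
  records <- as.data.frame(records)
  if ("tfp" %in% names(records) && !"tfpch" %in% names(records)) {
    names(records)[names(records) == "tfp"] <- "tfpch"
  }
  missing_cols <- setdiff(.mqt_components, names(records))
  if (length(missing_cols)) {
    stop("records lack component columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"complete" %in% names(records)) {
    records$complete <- stats::complete.cases(records[.mqt_components])
  }
  n_excluded <- sum(!records$complete)
  list(records = records[records$complete, , drop = FALSE],
       n_excluded = n_excluded)
}

.component_means <- function(records, by) {
  cc <- .complete_records(records)
  recs <- cc$records
  if (nrow(recs) == 0L) stop("no complete Malmquist records to aggregate")
  if (is.null(by)) {
    out <- as.data.frame(as.list(colMeans(recs[.mqt_components])))
    out$n <- nrow(recs)
  } else {
    out <- stats::aggregate(recs[.mqt_components], by = recs[by], FUN = mean)
    out$n <- stats::aggregate(recs[[by[1]]], by = recs[by], FUN = length)$x
  }
  attr(out, "n_excluded") <- cc$n_excluded
  out
}

#' Per-interval component means across DMUs
#'
#' Arithmetic mean of each index component over all DMUs, per interval —
#' the layout of the published interval tables. Arithmetic averaging is
#' deliberate (it matches how such tables are built), and the product
#' identities do *not* survive it: the mean TFPCH is generally not the
#' product of the mean EFFCH and mean TECH. Incomplete records are excluded
#' and their count reported via the `n_excluded` attribute.
#'
#' @param records Data frame of Malmquist records ([malmquist_panel()]
#'   output or anything with the five component columns).
#' @return Data frame of means per interval, with columns `interval`, the
#'   five components and `n`.
#' @export
aggregate_interval_means <- function(records) {
  if (!"interval" %in% names(as.data.frame(records))) {
    stop("records need an 'interval' column")
  }
  .component_means(records, "interval")
}

#' Per-DMU component means across intervals
#'
#' As [aggregate_interval_means()], but averaged over intervals within each
#' DMU — the layout of the published per-region tables.
#'
#' @inheritParams aggregate_interval_means
#' @return Data frame of means per DMU.
#' @export
aggregate_dmu_means <- function(records) {
  if (!"dmu" %in% names(as.data.frame(records))) {
    stop("records need a 'dmu' column")
  }
  .component_means(records, "dmu")
}
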