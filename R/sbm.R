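# Slacks-based measure (SBM) efficiency and super-efficiency scoring.
#
# Both programs are linear-fractional in their natural form and are solved
# exactly as single linear programs via the Charnes-Cooper transformation
# (t = 1/denominator; all variables scaled by t). No iterative fractional
# scheme is involved, so scores are deterministic.
#
# Plain SBM, DMU k against peers (X, Y), non-oriented:
#   min rho = [1 - (1/m) sum_i s-_i / x_ik] / [1 + (1/q) sum_r s+_r / y_rk]
#   s.t. X lambda + s- = x_k,  Y lambda - s+ = y_k,  lambda, s-, s+ >= 0
#   (VRS adds sum lambda = 1).
# rho lies in (0, 1] and equals 1 iff all slacks vanish at the optimum.
#
# Super-efficiency SBM (Tone 2002), DMU k against peers excluding k:
#   min delta = [(1/m) sum_i xbar_i / x_ik] / [(1/q) sum_r ybar_r / y_rk]
#   s.t. xbar >= X lambda, ybar <= Y lambda, xbar >= x_k, 0 < ybar <= y_k
# delta >= 1, strictly above 1 for units that lie beyond the frontier formed
# without them.

.TOL_SCORE <- 1e-6
.TOL_EFFECTIVE <- 1e-9

# Charnes-Cooper LP for the plain SBM.
# Variables: (t, Lambda[np], Sminus[m], Splus[q]), all >= 0.
.sbm_lp <- function(Xp, Yp, xk, yk, vrs) {
  m <- nrow(Xp); q <- nrow(Yp); np <- ncol(Xp)
  nv <- 1L + np + m + q
  c_obj <- c(1, rep(0, np), -1 / (m * xk), rep(0, q))
  nr <- 1L + m + q + vrs
  A <- matrix(0, nr, nv)
  b <- c(1, rep(0, m + q), if (vrs) 0)
  A[1, ] <- c(1, rep(0, np + m), 1 / (q * yk))
  for (i in seq_len(m)) {
    A[1L + i, ] <- c(-xk[i], Xp[i, ], as.numeric(seq_len(m) == i), rep(0, q))
  }
  for (r in seq_len(q)) {
    A[1L + m + r, ] <- c(-yk[r], Yp[r, ], rep(0, m), -as.numeric(seq_len(q) == r))
  }
  if (vrs) A[nr, ] <- c(-1, rep(1, np), rep(0, m + q))
  sol <- lp_solve(c_obj, A, b, rep("=", nr))
  if (sol$status != "optimal") {
    return(list(status = sol$status))
  }
  t_ <- sol$x[1]
  if (t_ < 1e-9) return(list(status = "degenerate"))
  list(status = "optimal",
       rho = sol$value,
       lambda = sol$x[1L + seq_len(np)] / t_,
       s_in = sol$x[1L + np + seq_len(m)] / t_,
       s_out = sol$x[1L + np + m + seq_len(q)] / t_)
}

# Charnes-Cooper LP for the super-efficiency (expansion) SBM.
# Variables: (t, Lambda[np], Xbar[m], Ybar[q]), all >= 0.
.super_lp <- function(Xp, Yp, xk, yk, vrs) {
  m <- nrow(Xp); q <- nrow(Yp); np <- ncol(Xp)
  nv <- 1L + np + m + q
  c_obj <- c(0, rep(0, np), 1 / (m * xk), rep(0, q))
  A_eq <- matrix(0, 1L + vrs, nv)
  b_eq <- c(1, if (vrs) 0)
  A_eq[1, ] <- c(0, rep(0, np + m), 1 / (q * yk))
  if (vrs) A_eq[2, ] <- c(-1, rep(1, np), rep(0, m + q))
  A_le <- matrix(0, 2L * (m + q), nv)
  b_le <- rep(0, 2L * (m + q))
  for (i in seq_len(m)) {      # X Lambda <= Xbar
    A_le[i, ] <- c(0, Xp[i, ], -as.numeric(seq_len(m) == i), rep(0, q))
  }
  for (r in seq_len(q)) {      # Ybar <= Y Lambda
    A_le[m + r, ] <- c(0, -Yp[r, ], rep(0, m), as.numeric(seq_len(q) == r))
  }
  for (i in seq_len(m)) {      # t x_k <= Xbar
    A_le[m + q + i, ] <- c(xk[i], rep(0, np), -as.numeric(seq_len(m) == i), rep(0, q))
  }
  for (r in seq_len(q)) {      # Ybar <= t y_k
    A_le[m + q + m + r, ] <- c(-yk[r], rep(0, np + m), as.numeric(seq_len(q) == r))
  }
  A <- rbind(A_eq, A_le)
  b <- c(b_eq, b_le)
  dir <- c(rep("=", nrow(A_eq)), rep("<=", nrow(A_le)))
  sol <- lp_solve(c_obj, A, b, dir)
  if (sol$status != "optimal") {
    return(list(status = sol$status))
  }
  t_ <- sol$x[1]
  if (t_ < 1e-9) return(list(status = "degenerate"))
  xbar <- sol$x[1L + np + seq_len(m)] / t_
  ybar <- sol$x[1L + np + m + seq_len(q)] / t_
  list(status = "optimal",
       rho = sol$value,
       lambda = sol$x[1L + seq_len(np)] / t_,
       s_in = xbar - xk,    # input expansion needed to reach the frontier
       s_out = yk - ybar)   # output contraction needed to reach the frontier
}

.new_result <- function(dmu, eval_period, frontier_period, rts, model,
                        sol, peer_ids, input_names, output_names) {
  if (sol$status != "optimal") {
    res <- list(dmu = dmu, eval_period = eval_period,
                frontier_period = frontier_period, rts = rts, model = model,
                rho = NA_real_, input_slacks = NULL, output_slacks = NULL,
                lambdas = NULL, status = sol$status)
  } else {
    res <- list(dmu = dmu, eval_period = eval_period,
                frontier_period = frontier_period, rts = rts, model = model,
                rho = sol$rho,
                input_slacks = stats::setNames(sol$s_in, input_names),
                output_slacks = stats::setNames(sol$s_out, output_names),
                lambdas = stats::setNames(sol$lambda, peer_ids),
                status = "optimal")
  }
  class(res) <- "efficiency_result"
  res
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("%s score for %s [%s vs %s frontier, %s]: ",
              x$model, x$dmu, x$eval_period, x$frontier_period,
              toupper(x$rts)))
  if (x$status == "optimal") {
    cat(sprintf("rho = %.6f\n", x$rho))
  } else {
    cat("status =", x$status, "\n")
  }
  invisible(x)
}

.match_rts <- function(rts) match.arg(tolower(rts), c("crs", "vrs"))

#' Plain (non-oriented) SBM efficiency of one DMU
#'
#' Solves the non-oriented slacks-based measure for one DMU against the
#' frontier spanned by all DMUs of `frontier_period` (the evaluated unit is
#' included when the periods coincide). The score lies in (0, 1] and equals
#' 1 exactly when no input excess and no output shortfall remain at the
#' optimum. When evaluating against another period's frontier the program
#' can be infeasible: the unit lies beyond that frontier and no peer
#' combination envelops it; the result then carries `status = "infeasible"`
#' rather than an invented number.
#'
#' @param panel A [panel_dataset()].
#' @param dmu DMU label.
#' @param period Period whose data the DMU brings.
#' @param frontier_period Period whose peers span the frontier (defaults to
#'   `period`).
#' @param rts `"crs"` (constant returns) or `"vrs"` (adds the convexity
#'   constraint on the intensity weights).
#' @return An `efficiency_result` with fields `rho`, `input_slacks` (same
#'   units as the inputs), `output_slacks`, `lambdas` (intensity weights per
#'   peer) and `status`.
#' @export
solve_sbm <- function(panel, dmu, period, frontier_period = period,
                      rts = c("crs", "vrs")) {
  stopifnot(inherits(panel, "panel_dataset"))
  rts <- .match_rts(rts)
  dmu <- .check_dmu(panel, dmu)
  period <- .check_period(panel, period)
  frontier_period <- .check_period(panel, frontier_period)
  Xp <- .peer_matrix(panel$X, frontier_period)
  Yp <- .peer_matrix(panel$Y, frontier_period)
  xk <- panel$X[dmu, period, ]
  yk <- panel$Y[dmu, period, ]
  sol <- .sbm_lp(Xp, Yp, xk, yk, vrs = (rts == "vrs"))
  .new_result(dmu, period, frontier_period, rts, "sbm", sol,
              colnames(Xp), panel$input_names, panel$output_names)
}

#' Super-efficiency SBM score of one DMU
#'
#' Unified super-efficiency scoring: SBM-efficient units are re-scored
#' against the frontier formed *without* them (Tone's super-efficiency SBM),
#' which pushes their score above 1 and makes efficient units mutually
#' comparable; SBM-inefficient units keep their plain SBM score, which the
#' super-efficiency program alone cannot reproduce (its optimum is exactly 1
#' for any enveloped unit). Running this on every DMU therefore yields a
#' single ranking with values on both sides of 1, the convention used for
#' "comprehensive efficiency" tables.
#'
#' For super-scored units the `input_slacks`/`output_slacks` fields hold the
#' input expansion (`xbar - x_k`) and output contraction (`y_k - ybar`)
#' needed to reach the reduced frontier.
#'
#' @inheritParams solve_sbm
#' @return An `efficiency_result`; `rho > 1` for SBM-efficient units (CRS,
#'   feasible cases), `rho` equal to the plain SBM score otherwise.
#' @export
solve_super_sbm <- function(panel, dmu, period, rts = c("crs", "vrs")) {
  stopifnot(inherits(panel, "panel_dataset"))
  rts <- .match_rts(rts)
  dmu <- .check_dmu(panel, dmu)
  period <- .check_period(panel, period)
  base <- solve_sbm(panel, dmu, period, period, rts)
  if (base$status != "optimal") {
    base$model <- "super_sbm"
    return(base)
  }
  if (base$rho < 1 - .TOL_SCORE) {
    base$model <- "super_sbm"
    return(base)
  }
  keep <- setdiff(panel$dmu_ids, dmu)
  if (!length(keep)) stop("super-efficiency needs at least one peer")
  Xp <- .peer_matrix(panel$X, period)[, keep, drop = FALSE]
  Yp <- .peer_matrix(panel$Y, period)[, keep, drop = FALSE]
  xk <- panel$X[dmu, period, ]
  yk <- panel$Y[dmu, period, ]
  sol <- .super_lp(Xp, Yp, xk, yk, vrs = (rts == "vrs"))
  .new_result(dmu, period, period, rts, "super_sbm", sol,
              keep, panel$input_names, panel$output_names)
}

#' Score every DMU of one period
#'
#' Applies [solve_super_sbm()] to each DMU against its own period's
#' frontier. Deterministic given the panel; no DMU is dropped — solver
#' failures are carried in the `status` column with `rho = NA`.
#'
#' @inheritParams solve_sbm
#' @param period Period to score.
#' @return Data frame with columns `dmu`, `period`, `rts`, `model`, `rho`,
#'   `status`, one row per DMU in panel order.
#' @export
score_period <- function(panel, period, rts = c("crs", "vrs")) {
  stopifnot(inherits(panel, "panel_dataset"))
  rts <- .match_rts(rts)
  period <- .check_period(panel, period)
  rows <- lapply(panel$dmu_ids, function(d) {
    r <- solve_super_sbm(panel, d, period, rts)
    data.frame(dmu = d, period = period, rts = rts, model = r$model,
               rho = if (r$status == "optimal") r$rho else NA_real_,
               status = r$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Distance of (dmu, eval_period) data to frontier_period's frontier, full
# peer set. Enveloped points get the plain SBM score (<= 1); points beyond
# the frontier (plain program infeasible) get the expansion score (> 1).
.cross_distance <- function(panel, dmu, eval_period, frontier_period, rts) {
  base <- solve_sbm(panel, dmu, eval_period, frontier_period, rts)
  if (base$status == "optimal") return(base)
  if (base$status != "infeasible") return(base)
  Xp <- .peer_matrix(panel$X, frontier_period)
  Yp <- .peer_matrix(panel$Y, frontier_period)
  xk <- panel$X[dmu, eval_period, ]
  yk <- panel$Y[dmu, eval_period, ]
  sol <- .super_lp(Xp, Yp, xk, yk, vrs = (rts == "vrs"))
  .new_result(dmu, eval_period, frontier_period, rts, "super_sbm", sol,
              colnames(Xp), panel$input_names, panel$output_names)
}

#' Cross-period (distance-function) score
#'
#' Scores one DMU-period observation against the frontier of another
#' period, the building block of the Malmquist index. With
#' `frontier_period == eval_period` this is the unified own-period score of
#' [solve_super_sbm()]. Across periods the evaluated observation is not part
#' of the peer set; if it is enveloped by the other period's frontier the
#' plain SBM applies (score <= 1), and if it lies beyond that frontier —
#' where the plain program is infeasible — the super-efficiency expansion
#' program applies and the score exceeds 1.
#'
#' @inheritParams solve_sbm
#' @param eval_period Period whose data the DMU brings.
#' @param frontier_period Period whose peers span the frontier.
#' @return An `efficiency_result`.
#' @export
cross_period_score <- function(panel, dmu, eval_period, frontier_period,
                               rts = c("crs", "vrs")) {
  stopifnot(inherits(panel, "panel_dataset"))
  rts <- .match_rts(rts)
  dmu <- .check_dmu(panel, dmu)
  eval_period <- .check_period(panel, eval_period)
  frontier_period <- .check_period(panel, frontier_period)
  if (identical(eval_period, frontier_period)) {
    return(solve_super_sbm(panel, dmu, eval_period, rts))
  }
  .cross_distance(panel, dmu, eval_period, frontier_period, rts)
}

#' Classify scores as DEA-effective or not
#'
#' Under the super-efficiency convention a unit is in a relatively
#' effective state when its comprehensive efficiency is at least 1 and in a
#' relatively invalid (ineffective) state below 1. The boundary score of
#' exactly 1 counts as effective; a numerical tolerance of 1e-9 guards the
#' comparison.
#'
#' @param rho Numeric vector of efficiency scores from optimal results.
#' @param status Optional status vector; any non-`"optimal"` entry is
#'   refused rather than classified.
#' @return Character vector, `"effective"` or `"ineffective"`.
#' @examples
#' classify_effectiveness(c(1.248, 0.652, 1))
#' @export
classify_effectiveness <- function(rho, status = "optimal") {
  status <- rep_len(status, length(rho))
  if (any(status != "optimal")) {
    stop("refusing to classify non-optimal results (status: ",
         paste(unique(status[status != "optimal"]), collapse = ", "), ")")
  }
  if (any(!is.finite(rho))) stop("rho must be finite")
  ifelse(rho >= 1 - .TOL_EFFECTIVE, "effective", "ineffective")
}
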