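# Dense two-phase primal simplex.
#
# The DEA programs solved here are small (tens of variables, ~10 constraints)
# but frequently degenerate: several peers coincide with the evaluated unit's
# projection, so many basic solutions share the optimum. Bland's rule is used
# for both the entering and the leaving variable, which guarantees finite
# termination on degenerate bases at these problem sizes.

#' @keywords internal
#' @noRd
lp_solve <- function(c_obj, A, b, dir, tol = 1e-9, max_iter = 20000L) {
  m <- length(b)
  n <- length(c_obj)
  stopifnot(nrow(A) == m, ncol(A) == n, length(dir) == m,
            all(dir %in% c("<=", ">=", "=")))

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_slack <- sum(dir != "=")
  tab <- cbind(A, matrix(0, m, n_slack))
  basis <- integer(m)
  art_rows <- logical(m)
  sj <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sj <- sj + 1L
      tab[i, n + sj] <- 1
      basis[i] <- n + sj
    } else if (dir[i] == ">=") {
      sj <- sj + 1L
      tab[i, n + sj] <- -1
      art_rows[i] <- TRUE
    } else {
      art_rows[i] <- TRUE
    }
  }
  n_art <- sum(art_rows)
  if (n_art > 0L) {
    tab <- cbind(tab, matrix(0, m, n_art))
    aj <- 0L
    for (i in which(art_rows)) {
      aj <- aj + 1L
      tab[i, n + n_slack + aj] <- 1
      basis[i] <- n + n_slack + aj
    }
  }
  rhs <- b

  pivot <- function(tab, rhs, basis, i, j) {
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    rhs[i] <- rhs[i] / piv
    other <- setdiff(seq_len(nrow(tab)), i)
    f <- tab[other, j]
    tab[other, ] <- tab[other, , drop = FALSE] - outer(f, tab[i, ])
    rhs[other] <- rhs[other] - f * rhs[i]
    basis[i] <- j
    list(tab = tab, rhs = rhs, basis = basis)
  }

  run_phase <- function(tab, rhs, basis, cost) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit", tab = tab, rhs = rhs, basis = basis))
      }
      red <- cost - as.vector(crossprod(tab, cost[basis]))
      red[basis] <- 0
      entering <- which(red < -tol)
      if (!length(entering)) {
        return(list(status = "optimal", tab = tab, rhs = rhs, basis = basis))
      }
      j <- min(entering)
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", tab = tab, rhs = rhs, basis = basis))
      }
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]
      st <- pivot(tab, rhs, basis, i, j)
      tab <- st$tab; rhs <- st$rhs; basis <- st$basis
    }
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_phase(tab, rhs, basis, cost1)
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    if (sum(cost1[ph1$basis] * ph1$rhs) > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    tab <- ph1$tab; rhs <- ph1$rhs; basis <- ph1$basis
    # drive any artificial still basic (at level zero) out of the basis
    for (i in which(basis > n + n_slack)) {
      row <- tab[i, seq_len(n + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        st <- pivot(tab, rhs, basis, i, j[1])
        tab <- st$tab; rhs <- st$rhs; basis <- st$basis
      }
      # a row with no eligible pivot is redundant; its artificial stays at zero
    }
    keep <- seq_len(n + n_slack)
    tab <- tab[, keep, drop = FALSE]
  }

  cost2 <- c(c_obj, rep(0, n_slack))
  ph2 <- run_phase(tab, rhs, basis, cost2)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  x_full <- numeric(n + n_slack)
  ok <- ph2$basis <= n + n_slack
  x_full[ph2$basis[ok]] <- ph2$rhs[ok]
  x <- x_full[seq_len(n)]
  list(status = "optimal", x = x, value = sum(c_obj * x))
}
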