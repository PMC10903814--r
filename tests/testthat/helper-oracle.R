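# Independent oracle for the fractional SBM programs.
#
# Both the plain SBM and the super-efficiency SBM minimize a ratio of
# affine functions over a polyhedron, so the optimum is attained at a
# vertex. For tiny instances the oracle enumerates every vertex by brute
# force (all basis subsets) and evaluates the fractional objective
# directly — no linear programming and no Charnes-Cooper transformation,
# so it shares no code path with the solver it checks.

# vertices of {v : v >= 0, G v <= h}
enum_vertices <- function(G, h) {
  d <- ncol(G)
  Gall <- rbind(G, -diag(d))
  hall <- c(h, rep(0, d))
  combs <- utils::combn(nrow(Gall), d)
  out <- list()
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    M <- Gall[idx, , drop = FALSE]
    v <- tryCatch(solve(M, hall[idx]), error = function(e) NULL)
    if (is.null(v)) next
    if (all(Gall %*% v <= hall + 1e-8)) out[[length(out) + 1L]] <- v
  }
  out
}

# Plain SBM: min over lambda >= 0 with X l <= xk, Y l >= yk of
#   (1 - mean((xk - X l)/xk)) / (1 + mean((Y l - yk)/yk)).
# Returns NA when no feasible lambda exists (point beyond the frontier).
oracle_sbm <- function(X, Y, xk, yk, vrs = FALSE) {
  G <- rbind(X, -Y)
  h <- c(xk, -yk)
  if (vrs) {
    one <- rep(1, ncol(X))
    G <- rbind(G, one, -one)
    h <- c(h, 1, -1)
  }
  vs <- enum_vertices(G, h)
  if (!length(vs)) return(NA_real_)
  vals <- vapply(vs, function(l) {
    sm <- xk - as.vector(X %*% l)
    sp <- as.vector(Y %*% l) - yk
    (1 - mean(sm / xk)) / (1 + mean(sp / yk))
  }, numeric(1))
  min(vals)
}

# Super-efficiency SBM over (lambda, xbar, ybar):
#   min mean(xbar/xk) / mean(ybar/yk)
#   s.t. X l <= xbar, ybar <= Y l, xbar >= xk, ybar <= yk, all >= 0.
oracle_super <- function(X, Y, xk, yk, vrs = FALSE) {
  np <- ncol(X); m <- nrow(X); q <- nrow(Y)
  G <- rbind(
    cbind(X, -diag(m), matrix(0, m, q)),
    cbind(-Y, matrix(0, q, m), diag(q)),
    cbind(matrix(0, m, np), -diag(m), matrix(0, m, q)),
    cbind(matrix(0, q, np + m), diag(q)))
  h <- c(rep(0, m + q), -xk, yk)
  if (vrs) {
    row <- c(rep(1, np), rep(0, m + q))
    G <- rbind(G, row, -row)
    h <- c(h, 1, -1)
  }
  vs <- enum_vertices(G, h)
  vals <- vapply(vs, function(v) {
    xbar <- v[np + seq_len(m)]
    ybar <- v[np + m + seq_len(q)]
    den <- mean(ybar / yk)
    if (den <= 1e-10) return(Inf)
    mean(xbar / xk) / den
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  min(vals)
}

# Unified own-period score mirroring solve_super_sbm's contract:
# the plain SBM score below 1, the exclusion super score otherwise.
oracle_unified <- function(X, Y, k, vrs = FALSE) {
  plain <- oracle_sbm(X, Y, X[, k], Y[, k], vrs)
  if (is.finite(plain) && plain < 1 - 1e-6) return(plain)
  oracle_super(X[, -k, drop = FALSE], Y[, -k, drop = FALSE],
               X[, k], Y[, k], vrs)
}
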