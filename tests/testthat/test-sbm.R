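# Expected values below marked "frozen" were computed with the
# vertex-enumeration oracle in helper-oracle.R (exact arithmetic on the
# fractional program) and then fixed.

test_that("identical units are mutually efficient with zero slacks", {
  X <- matrix(1, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  Y <- matrix(1, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  p <- panel_from_mats(X, Y)
  for (d in c("A", "B", "C")) {
    r <- solve_sbm(p, d, "1")
    expect_equal(r$rho, 1, tolerance = 1e-9)
    expect_lt(max(abs(c(r$input_slacks, r$output_slacks))), 1e-9)
    # the identical peer keeps the unit on the frontier when it is excluded
    expect_equal(solve_super_sbm(p, d, "1")$rho, 1, tolerance = 1e-9)
  }
})

test_that("toy-pair scores match the frozen oracle values", {
  p <- toy_pair()
  expect_equal(solve_sbm(p, "B", "1")$rho, 0.5, tolerance = 1e-9)   # frozen
  expect_equal(solve_super_sbm(p, "A", "1")$rho, 2, tolerance = 1e-9) # frozen
  # super-efficiency equals plain SBM for the inefficient unit
  expect_equal(solve_super_sbm(p, "B", "1")$rho,
               solve_sbm(p, "B", "1")$rho, tolerance = 1e-9)
  sc <- score_period(p, "1")
  expect_equal(sc$rho, c(2, 0.5), tolerance = 1e-9)
  # two-input facet projection: mean input-slack ratio 0.25  (frozen: 0.75)
  X <- matrix(c(1, 2, 2, 1, 2, 2), 2, dimnames = list(NULL, c("A", "B", "C")))
  Y <- matrix(1, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  p3 <- panel_from_mats(X, Y)
  expect_equal(solve_sbm(p3, "C", "1")$rho, 0.75, tolerance = 1e-9)
})

test_that("LP scores agree with the fractional-program oracle on tiny instances", {
  set.seed(101)
  for (rep in 1:3) {
    for (n in 2:4) for (m in 1:2) for (q in 1:2) {
      inst <- random_instance(n, m, q)
      colnames(inst$X) <- colnames(inst$Y) <- LETTERS[seq_len(n)]
      p <- panel_from_mats(inst$X, inst$Y)
      for (rts in c("crs", "vrs")) {
        vrs <- rts == "vrs"
        for (k in seq_len(n)) {
          lbl <- LETTERS[k]
          got <- solve_sbm(p, lbl, "1", rts = rts)
          want <- oracle_sbm(inst$X, inst$Y, inst$X[, k], inst$Y[, k], vrs)
          expect_equal(got$rho, want, tolerance = 1e-6,
                       label = sprintf("sbm n=%d m=%d q=%d %s k=%d", n, m, q, rts, k))
          gu <- solve_super_sbm(p, lbl, "1", rts = rts)
          wu <- oracle_unified(inst$X, inst$Y, k, vrs)
          if (gu$status == "optimal" && is.finite(wu)) {
            expect_equal(gu$rho, wu, tolerance = 1e-6,
                         label = sprintf("super n=%d m=%d q=%d %s k=%d", n, m, q, rts, k))
          }
        }
      }
    }
  }
})

test_that("scores are invariant to rescaling any indicator column", {
  gp <- generate_panel(synthetic_config(n = 10, n_periods = 1, seed = 5))
  p <- gp$panel
  base <- score_period(p, "1")$rho
  long <- panel_to_long(p)
  set.seed(7)
  for (col in c("input_2", "output_1", "output_3")) {
    scaled <- long
    scaled[[col]] <- scaled[[col]] * stats::runif(1, 0.01, 100)
    p2 <- panel_dataset(scaled, inputs = paste0("input_", 1:3),
                        outputs = paste0("output_", 1:3))
    expect_lt(max(abs(score_period(p2, "1")$rho - base)), 1e-6)
  }
})

test_that("weakly decreasing an efficient unit's output never raises its score", {
  set.seed(31)
  for (rep in 1:5) {
    inst <- random_instance(6, 2, 2)
    colnames(inst$X) <- colnames(inst$Y) <- LETTERS[1:6]
    p <- panel_from_mats(inst$X, inst$Y)
    sc <- score_period(p, "1")
    k <- which.max(sc$rho)
    base <- sc$rho[k]
    worse <- inst$Y
    worse[1, k] <- worse[1, k] * stats::runif(1, 0.5, 0.99)
    p2 <- panel_from_mats(inst$X, worse)
    expect_lte(solve_super_sbm(p2, LETTERS[k], "1")$rho, base + 1e-9)
  }
})

test_that("plain SBM never exceeds 1 and adding a dominated unit changes nothing", {
  set.seed(17)
  for (rep in 1:5) {
    inst <- random_instance(6, 2, 2)
    colnames(inst$X) <- colnames(inst$Y) <- LETTERS[1:6]
    p <- panel_from_mats(inst$X, inst$Y)
    rhos <- vapply(LETTERS[1:6], function(d) solve_sbm(p, d, "1")$rho, numeric(1))
    expect_true(all(rhos <= 1 + 1e-9))
    base_super <- score_period(p, "1")$rho
    # super >= 1 exactly for the SBM-efficient units
    expect_true(all(base_super[rhos >= 1 - 1e-9] >= 1 - 1e-9))
    expect_equal(base_super[rhos < 1 - 1e-6], unname(rhos[rhos < 1 - 1e-6]),
                 tolerance = 1e-9)
    # a unit dominated by A (more input, less output) moves no other score;
    # A itself is exempt: its own exclusion frontier now contains the clone
    dom_x <- cbind(inst$X, G = inst$X[, 1] * 1.5)
    dom_y <- cbind(inst$Y, G = inst$Y[, 1] * 0.7)
    p2 <- panel_from_mats(dom_x, dom_y)
    after <- score_period(p2, "1")
    expect_lt(max(abs(after$rho[match(LETTERS[2:6], after$dmu)] -
                        base_super[2:6])), 1e-6)
  }
})

test_that("cross-period scores follow the single-ratio closed form", {
  # productivities p drawn either side of the period-1 best p* = 1.0
  Xs <- list(`1` = matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("A", "B", "C"))),
             `2` = matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("A", "B", "C"))))
  Ys <- list(`1` = matrix(c(1.0, 0.72, 0.5), 1, dimnames = list(NULL, c("A", "B", "C"))),
             `2` = matrix(c(1.2, 0.9, 0.4), 1, dimnames = list(NULL, c("A", "B", "C"))))
  p <- panel_from_mats(Xs, Ys)
  # enveloped case: p = 0.72 against p* = 1.0
  expect_equal(cross_period_score(p, "B", "2", "1")$rho, 0.9, tolerance = 1e-9)
  expect_equal(cross_period_score(p, "B", "1", "1")$rho,
               solve_super_sbm(p, "B", "1")$rho, tolerance = 1e-12)
  # beyond-frontier case: p = 1.2 against p* = 1.0 scores above 1
  expect_equal(cross_period_score(p, "A", "2", "1")$rho, 1.2, tolerance = 1e-9)
  # the plain program alone is infeasible there
  expect_equal(solve_sbm(p, "A", "2", "1")$status, "infeasible")
})

test_that("effectiveness classification uses the >= 1 rule and refuses failures", {
  expect_equal(classify_effectiveness(c(1.248, 0.652, 1)),
               c("effective", "ineffective", "effective"))
  expect_error(classify_effectiveness(0.9, status = "infeasible"),
               "refusing to classify")
})
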