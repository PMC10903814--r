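fixture_static_matrix <- function() {
  tab <- load_fixture("static-efficiency")
  tab <- tab[tab$region != "Mean", ]
  M <- as.matrix(tab[, !(names(tab) %in% c("region", "mean"))])
  rownames(M) <- tab$region
  M
}

test_that("static summary reproduces the printed means and counts", {
  s <- static_summary(fixture_static_matrix())
  expect_equal(round(s$grand_mean, 3), 0.975)
  expect_equal(round(unname(s$period_means), 3),
               c(0.961, 1.037, 1.021, 0.973, 0.883))
  expect_equal(unname(s$effective_counts), c(9, 13, 12, 11, 7))
  expect_equal(round(unname(s$effective_proportions), 2),
               c(60, 86.67, 80, 73.33, 46.67))
  expect_equal(round(unname(s$dmu_means["Haikou City"]), 3), 1.196)
  # balanced-panel identity: grand mean = mean of row means = mean of col means
  expect_equal(s$grand_mean, mean(s$dmu_means), tolerance = 1e-9)
  expect_equal(s$grand_mean, mean(s$period_means), tolerance = 1e-9)
})

test_that("persistent effectiveness finds the four always-effective regions", {
  M <- fixture_static_matrix()
  expect_equal(persistent_effective(M),
               c("Haikou City", "Wuzhishan City", "Tunchang County",
                 "Baoting County"))
  ones <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("1", "2")))
  s <- static_summary(ones)
  expect_equal(s$persistent_effective, c("a", "b", "c"))
  expect_equal(unname(s$effective_proportions), c(100, 100))
  expect_equal(s$grand_mean, 1)
  dip <- ones; dip["b", "2"] <- 0.999
  expect_equal(persistent_effective(dip), c("a", "c"))
})

test_that("static summary refuses matrices with missing cells", {
  M <- fixture_static_matrix()
  M["Sanya City", "2018"] <- NA
  expect_error(static_summary(M), "missing score cells.*Sanya City, 2018")
})

test_that("dynamic summary counts below-average and growth regions as printed", {
  tab <- load_fixture("dmu-indices")
  tab <- tab[tab$region != "Mean", ]
  names(tab)[names(tab) == "region"] <- "dmu"
  d <- dynamic_summary(tab)
  expect_equal(d$n_tfpch_gt1, 1L)
  expect_equal(d$tfpch_growth_dmus, "Chengmai County")
  expect_equal(unname(d$below_mean_counts["tech"]), 7L)
  expect_equal(unname(d$below_mean_counts["effch"]), 8L)
  expect_equal(round(unname(d$overall_means), 3),
               c(1.001, 0.935, 0.996, 1.005, 0.934))
  # all-ones record set: nothing below the mean, nothing above 1
  ones <- data.frame(dmu = letters[1:4], effch = 1, tech = 1, pech = 1,
                     sech = 1, tfpch = 1)
  d1 <- dynamic_summary(ones)
  expect_equal(unname(d1$below_mean_counts), rep(0L, 5))
  expect_equal(d1$n_tfpch_gt1, 0L)
  expect_error(dynamic_summary(ones[0, ]), "empty")
})

test_that("interval fixture means match the printed Mean row", {
  tab <- load_fixture("interval-indices")
  body <- tab[tab$interval != "Mean", ]
  printed <- tab[tab$interval == "Mean", -1]
  expect_equal(round(colMeans(body[, -1]), 3), unlist(printed))
  expect_equal(round(mean(body$tfp), 3), 0.934)
})

test_that("the overall mean row agrees between interval and DMU layouts", {
  rec <- malmquist_panel(generate_panel(synthetic_config(n = 8, n_periods = 3,
                                                         seed = 4))$panel)
  d <- dynamic_summary(rec)
  for (k in c("effch", "tech", "pech", "sech", "tfpch")) {
    expect_equal(unname(d$overall_means[k]), mean(d$interval_table[[k]]),
                 tolerance = 1e-9)
    expect_equal(unname(d$overall_means[k]), mean(d$dmu_table[[k]]),
                 tolerance = 1e-9)
  }
})

test_that("the pipeline writes the expected record counts and is deterministic", {
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  cfg <- synthetic_config(n = 15, n_periods = 5)
  res <- run_pipeline(synthetic = cfg, out_dir = out1, seed = 8)
  scores <- utils::read.csv(file.path(out1, "static_scores.csv"))
  expect_equal(nrow(scores), 75)  # 15 DMUs x 5 periods
  recs <- utils::read.csv(file.path(out1, "malmquist_records.csv"))
  expect_equal(nrow(recs), 60)    # 15 DMUs x 4 intervals
  expect_true(all(file.exists(file.path(out1,
    c("static_summary.csv", "static_effectiveness.csv",
      "dynamic_interval_means.csv", "dynamic_dmu_means.csv",
      "run_log.txt")))))
  run_pipeline(synthetic = cfg, out_dir = out2, seed = 8)
  for (f in c("static_scores.csv", "malmquist_records.csv",
              "dynamic_dmu_means.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("summaries recomputed from written score files match in-memory ones", {
  out <- file.path(tempdir(), "pipe3")
  res <- run_pipeline(synthetic = synthetic_config(n = 8, n_periods = 3),
                      out_dir = out, seed = 5)
  back <- utils::read.csv(file.path(out, "static_scores.csv"),
                          stringsAsFactors = FALSE)
  back$rho <- as.numeric(back$rho)
  back$period <- as.character(back$period)
  s2 <- static_summary(back[back$status == "optimal", ])
  expect_equal(s2$grand_mean, res$static$grand_mean, tolerance = 1e-12)
  expect_equal(s2$effective_counts, res$static$effective_counts)
  rec <- utils::read.csv(file.path(out, "malmquist_records.csv"),
                         stringsAsFactors = FALSE)
  for (k in c("effch", "tech", "pech", "sech", "tfpch")) {
    rec[[k]] <- as.numeric(rec[[k]])
  }
  d2 <- dynamic_summary(rec)
  expect_equal(unname(d2$overall_means),
               unname(res$dynamic$overall_means), tolerance = 1e-12)
  unlink(out, recursive = TRUE)
})

test_that("a single-period panel skips the dynamic stage with a logged notice", {
  out <- file.path(tempdir(), "pipe4")
  res <- run_pipeline(synthetic = synthetic_config(n = 5, n_periods = 1),
                      out_dir = out, seed = 2)
  expect_null(res$dynamic)
  expect_false(file.exists(file.path(out, "malmquist_records.csv")))
  expect_true(any(grepl("dynamic stage skipped",
                        readLines(file.path(out, "run_log.txt")))))
  unlink(out, recursive = TRUE)
})
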