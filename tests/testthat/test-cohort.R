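test_that("cohort configuration is validated", {
  expect_s3_class(cohort_config(seed = 3), "cohort_config")
  expect_error(cohort_config(n_per_arm = 1), "at least 2")
  expect_error(cohort_config(median_dfs = c(-1, 10)), "positive")
  expect_error(cohort_config(accrual_window = 50, followup_cutoff = 40),
               "exceed")
  expect_error(cohort_config(arms = c("A", "A")), "distinct")
})

test_that("the post-progression median solves the OS-median equation", {
  for (m in list(c(14, 22), c(15, 24), c(3, 30))) {
    p <- pps_median_for_os(m[1], m[2])
    expect_gt(p, 0)
    # oracle: the hypoexponential survival at the OS median is exactly 0.5
    a <- log(2) / m[1]
    b <- log(2) / p
    s <- (b * exp(-a * m[2]) - a * exp(-b * m[2])) / (b - a)
    expect_equal(s, 0.5, tolerance = 1e-9)
    # and the solved median is below the naive difference of medians
    expect_lt(p, m[2] - m[1])
  }
  expect_error(pps_median_for_os(10, 10), "satisfy")
})

test_that("generated records satisfy the structural invariants", {
  cfg <- cohort_config(n_per_arm = 500, seed = 21)
  rec <- generate_cohort(cfg)
  expect_equal(nrow(rec), 1000)
  expect_true(all(rec$t_os >= rec$t_dfs))
  expect_true(all(rec$t_dfs >= 0))
  expect_true(all(rec$direct_cost > 0))
  # a censored overall survival implies nothing was observed later
  expect_true(all(rec$t_os[!rec$os_event] <= cfg$followup_cutoff))
  # byte-identical regeneration under the same seed
  expect_identical(rec, generate_cohort(cfg))
  expect_false(identical(rec, generate_cohort(cohort_config(n_per_arm = 500,
                                                            seed = 22))))
})

test_that("a cutoff beyond all event times leaves no censoring", {
  cfg <- cohort_config(n_per_arm = 200, accrual_window = 1e-9,
                       followup_cutoff = 1e6, seed = 8)
  rec <- generate_cohort(cfg)
  expect_true(all(rec$dfs_event))
  expect_true(all(rec$os_event))
})

test_that("censoring increases monotonically as the cutoff shrinks", {
  frac_censored <- function(cutoff) {
    rec <- generate_cohort(cohort_config(n_per_arm = 2000,
                                         followup_cutoff = cutoff, seed = 9))
    mean(!rec$os_event)
  }
  fr <- vapply(c(87, 60, 50), frac_censored, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("km_median follows the product-limit definition", {
  expect_equal(km_median(1:5, rep(TRUE, 5)), 3)
  expect_true(is.na(km_median(c(2, 4, 9), c(FALSE, FALSE, FALSE))))
  expect_error(km_median(numeric(0), logical(0)), "at least one")
  expect_error(km_median(1:3, c(TRUE, FALSE)), "equal length")
  expect_error(km_median(c(-1, 2), c(TRUE, TRUE)), "non-negative")
  # large uncensored exponential sample recovers the latent median
  set.seed(31)
  x <- rexp(10000, rate = log(2) / 22)
  expect_lt(abs(km_median(x, rep(TRUE, 10000)) - 22) / 22, 0.03)
})

test_that("cohort summaries recover the generator's parameters", {
  rec <- generate_cohort(cohort_config(n_per_arm = 10000, seed = 14))
  s <- summarize_cohort(rec)
  expect_named(s, c("arm", "n", "median_dfs", "median_os", "mean_cost",
                    "dfs_median_defined", "os_median_defined"))
  expect_equal(s$n, c(10000, 10000))
  opd <- s[s$arm == "OPD", ]
  lpd <- s[s$arm == "LPD", ]
  expect_lt(abs(opd$median_dfs - 14) / 14, 0.05)
  expect_lt(abs(opd$median_os - 22) / 22, 0.05)
  expect_lt(abs(lpd$median_dfs - 15) / 15, 0.05)
  expect_lt(abs(lpd$median_os - 24) / 24, 0.05)
  expect_lt(abs(opd$mean_cost - 95994.18) / 95994.18, 0.03)
  expect_lt(abs(lpd$mean_cost - 100013.20) / 100013.20, 0.03)
  expect_true(all(s$median_os >= s$median_dfs))
})

test_that("degenerate single-arm summaries are exact", {
  rec <- data.frame(arm = "A", t_dfs = rep(7, 5), dfs_event = TRUE,
                    t_os = rep(7, 5), os_event = TRUE, direct_cost = 1234.5)
  s <- summarize_cohort(rec)
  expect_equal(s$median_dfs, 7)
  expect_equal(s$mean_cost, 1234.5)
  expect_error(summarize_cohort(rec[0, ]), "non-empty")
})

test_that("cohort CSV round-trips at the documented precision", {
  rec <- generate_cohort(cohort_config(n_per_arm = 50, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "arm,t_dfs,dfs_event,t_os,os_event,direct_cost")
  back <- read_cohort(path)
  expect_identical(back$dfs_event, rec$dfs_event)
  expect_equal(back$t_dfs, rec$t_dfs, tolerance = 1e-4)
  expect_true(all(back$t_os >= back$t_dfs))
})
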