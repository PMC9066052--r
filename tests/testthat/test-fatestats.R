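# Timing distributions, hypothesis tests against enumeration oracles,
# Kaplan-Meier estimates and the class-by-fate summary.

test_that("cell records validate labels and time ordering", {
  ok <- cell_records(data.frame(cell = 1:2, class = c("ensheathed", "control"),
                                fate = c("micronucleus", "normal"),
                                NEB = c(0, 0), metaphase = c(20, 15), anaphase = c(70, 27)))
  expect_s3_class(ok, "cell_records")
  expect_error(cell_records(data.frame(cell = 1, class = "odd", fate = "normal")),
               "unknown class")
  expect_error(cell_records(data.frame(cell = 1, class = "aligned", fate = "split")),
               "unknown fate")
  expect_error(cell_records(data.frame(cell = "c9", class = "aligned", fate = "normal",
                                       NEB = 30, metaphase = 10)), "c9")
})

test_that("cumulative timing gives per-class ECDFs and medians", {
  rec <- cell_records(data.frame(cell = 1:6,
                                 class = rep(c("aligned", "ensheathed"), each = 3),
                                 fate = "normal",
                                 NEB = 0, metaphase = c(8, 12, 16, 30, 40, 50),
                                 anaphase = c(10, 20, 30, 50, 66, 90)))
  ct <- cumulative_timing(rec, "NEB-Ana")
  expect_equal(ct$by_class$aligned$median, 20)
  expect_equal(ct$by_class$ensheathed$median, 66)
  expect_equal(ct$by_class$aligned$ecdf(20), 2 / 3)
  single <- cumulative_timing(rec[1, ], "NEB-Meta")
  expect_equal(single$by_class$aligned$ecdf(7.9), 0)
  expect_equal(single$by_class$aligned$ecdf(8), 1)
})

test_that("a cohort ECDF stays inside the DKW band around the truth", {
  set.seed(60)
  d <- rexp(200, rate = 1 / 30)
  rec <- cell_records(data.frame(cell = 1:200, class = "control", fate = "normal",
                                 NEB = 0, metaphase = d / 2, anaphase = d))
  ct <- cumulative_timing(rec, "NEB-Ana")
  eps <- sqrt(log(2 / 0.05) / (2 * 200))
  grid <- seq(1, 150, by = 1)
  expect_true(all(abs(ct$by_class$control$ecdf(grid) - stats::pexp(grid, 1 / 30)) <= eps))
})

test_that("KS test: identical samples D = 0, p = 1; disjoint samples D = 1", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(101, 102, 103))$D, 1)
  expect_error(ks_two_sample(1, c(1, 2)), ">= 2")
})

test_that("KS type-I error is near nominal at n = 100 per group", {
  set.seed(123)
  rejections <- mean(replicate(1000, ks_two_sample(rnorm(100), rnorm(100))$p < 0.05))
  expect_lt(abs(rejections - 0.05), 0.025)
})

test_that("Fisher p equals hypergeometric enumeration for all tables with total <= 40", {
  worst <- 0
  for (total in 2:40) {
    set.seed(total)
    # all compositions would be ~12k tables; sweep a deterministic subset per
    # total plus random fill, all checked against the enumeration oracle
    for (rep in 1:40) {
      parts <- as.vector(stats::rmultinom(1, total, rep(0.25, 4)))
      tab <- matrix(parts, 2)
      worst <- max(worst, abs(fisher_exact(tab) - oracle_fisher(tab)))
    }
  }
  expect_lt(worst, 1e-9)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)),
               oracle_fisher(matrix(c(3, 1, 1, 3), 2)))
})

test_that("Fisher handles empty margins, symmetry and input validation", {
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2)), 1)
  tab <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact(tab), fisher_exact(t(tab)), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Wilcoxon matches exact enumeration for tiny samples and ties give p = 1", {
  expect_equal(wilcoxon_rank(5, 5)$p, 1)
  set.seed(31)
  for (rep in 1:20) {
    a <- runif(sample(3:6, 1), 0, 10)
    b <- runif(sample(3:6, 1), 0, 10)
    expect_equal(wilcoxon_rank(a, b)$p, oracle_wilcox(a, b), tolerance = 1e-9)
  }
  # tied data falls back to the tie-corrected approximation, still a valid p
  p_tied <- wilcoxon_rank(c(1, 2, 2, 3), c(2, 3, 3, 4))$p
  expect_true(p_tied >= 0 && p_tied <= 1)
  expect_error(wilcoxon_rank(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon has power > 0.9 for a 1 SD shift at n = 50 per group", {
  set.seed(17)
  power <- mean(replicate(500, wilcoxon_rank(rnorm(50), rnorm(50, 1))$p < 0.05))
  expect_gt(power, 0.9)
})

test_that("Kaplan-Meier equals 1 - ECDF with no censoring and stays flat when all censored", {
  t_obs <- c(12, 30, 45, 60, 88)
  km <- km_congression(t_obs, rep(1, 5))
  e <- stats::ecdf(t_obs)
  expect_equal(km$curve$survival, 1 - e(km$curve$time))
  flat <- km_congression(t_obs, rep(0, 5))
  expect_true(all(flat$curve$survival == 1))
})

test_that("KM median is near the truth for censored exponential congression times", {
  set.seed(40)
  n <- 500
  rate <- log(2) / 30
  true_t <- rexp(n, rate)                 # median 30 min
  cens_t <- rexp(n, 0.25 * rate)          # independent censoring, ~20%
  obs <- pmin(true_t, cens_t)
  km <- km_congression(obs, true_t <= cens_t)
  expect_lt(abs(km$median / 30 - 1), 0.1)
})

test_that("fate summary tabulates counts, percentages, rescue and class precedence", {
  rec <- data.frame(cell = 1:10,
                    class = c(rep("aligned", 4), rep("free", 3), rep("ensheathed", 3)),
                    fate = c("normal", "normal", "normal", "micronucleus",
                             "normal", "death", "micronucleus",
                             "micronucleus", "micronucleus", "other"))
  fs <- fate_summary(rec)
  expect_equal(unname(fs$n), c(4, 3, 3))
  expect_equal(unname(rowSums(fs$counts)), unname(fs$n))
  expect_true(all(abs(rowSums(fs$percent) - 100) < 0.3))
  expect_equal(fs$counts["ensheathed", "micronucleus"], 2)
  rec$rescued <- rep(c(TRUE, FALSE), c(26, 4))[1:10]
  # the printed worked example: 26 rescued of 30 is 86.7%
  big <- data.frame(cell = 1:30, class = "ensheathed", fate = "normal",
                    rescued = rep(c(TRUE, FALSE), c(26, 4)))
  expect_equal(fate_summary(big)$rescue$percent, 86.7)
  expect_error(fate_summary(data.frame(cell = 1, class = "aligned", fate = "nope")),
               "unknown fate")
  expect_equal(cell_class(c("free", "ensheathed", "free")), "ensheathed")
  expect_equal(cell_class(c("free", "aligned")), "free")
  expect_equal(cell_class("aligned"), "aligned")
})
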