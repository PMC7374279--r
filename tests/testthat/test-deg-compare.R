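test_that("two-group ANOVA follows the hand computation and conventions", {
  a <- anova_two_group(c(1, 2, 3), c(4, 5, 6))
  expect_equal(a$F, 13.5)  # MSB = 13.5, MSW = 1
  expect_equal(a$df2, 4)

  same <- anova_two_group(c(2, 2), c(2, 2))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_warning(lim <- anova_two_group(c(1, 1), c(2, 2)),
                 "zero within-group variance")
  expect_equal(lim$p, .Machine$double.xmin)

  expect_error(anova_two_group(1, c(1, 2)), "at least 2")
})

test_that("the F statistic is the square of the pooled t statistic", {
  set.seed(81)
  for (rep in 1:200) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), 0.3)
    a <- anova_two_group(x, y)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Welch option matches the Welch t-test", {
  set.seed(82)
  x <- rnorm(10, 0, 3)
  y <- rnorm(25, 0, 0.5)
  a <- anova_two_group(x, y, variance = "welch")
  tt <- t.test(x, y, var.equal = FALSE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("null ANOVA p-values are uniform", {
  set.seed(83)
  p <- replicate(2000, anova_two_group(rnorm(8), rnorm(8))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the differential-expression rule needs both magnitude and significance", {
  # encode the three published outcome patterns as direct predicates
  rule <- function(lfc, p) (lfc >= 1 | lfc <= -1) & p < 0.05
  expect_false(rule(-1.30, 0.13))  # large but not significant
  expect_false(rule(-0.55, 0.02))  # significant but small
  expect_true(rule(1.2, 0.01))

  set.seed(84)
  stats_tab <- tibble::tibble(
    gene = c("BIGSIG", "SMALLSIG", "NULL"),
    mean_case = c(9, 5.2, 6), sd_case = c(0.3, 0.1, 1),
    mean_ctrl = c(6, 5.0, 6), sd_ctrl = c(0.3, 0.1, 1))
  st <- simulate_pbmc_groups(stats_tab, 12, 12, seed = 84)
  deg <- compare_groups(st)
  expect_true(deg$is_deg[deg$gene == "BIGSIG"])
  expect_false(deg$is_deg[deg$gene == "SMALLSIG"])
  expect_identical(deg$is_deg,
                   (deg$lfc >= 1 | deg$lfc <= -1) & deg$p < 0.05)
})

test_that("sex stratification runs per stratum and skips thin strata", {
  stats_tab <- pbmc_reference_stats("All")
  st <- simulate_pbmc_groups(stats_tab, 10, 10,
                             sex_case = rep(c("F", "M"), 5),
                             sex_ctrl = rep(c("F", "M"), 5), seed = 85)
  deg <- compare_groups(st, stratify_by_sex = TRUE)
  expect_setequal(unique(deg$comparison), c("All", "Female", "Male"))
  expect_equal(nrow(deg), 9)
  expect_true(all(deg$n_case[deg$comparison == "Female"] == 5))

  st2 <- simulate_pbmc_groups(stats_tab, 6, 6,
                              sex_case = c("F", rep("M", 5)),
                              sex_ctrl = rep("M", 6), seed = 85)
  expect_message(deg2 <- compare_groups(st2, stratify_by_sex = TRUE),
                 "Female.*skipped")
  expect_false("Female" %in% deg2$comparison)
})

test_that("group comparison recovers the parameterised LFCs", {
  stats_tab <- pbmc_reference_stats("All")
  st <- simulate_pbmc_groups(stats_tab, 19, 18, seed = 86)
  deg <- compare_groups(st)
  deg <- deg[match(stats_tab$gene, deg$gene), ]
  se <- sqrt(stats_tab$sd_case^2 / 19 + stats_tab$sd_ctrl^2 / 18)
  truth <- stats_tab$mean_case - stats_tab$mean_ctrl
  expect_true(all(abs(deg$lfc - truth) < 3 * se))
})

test_that("gene order permutes output rows only", {
  stats_tab <- pbmc_reference_stats("All")
  st <- simulate_pbmc_groups(stats_tab, 8, 8, seed = 87)
  fwd <- compare_groups(st, genes = c("PPARG", "PPARD", "PPARA"))
  rev <- compare_groups(st, genes = c("PPARA", "PPARD", "PPARG"))
  expect_equal(fwd[order(fwd$gene), ], rev[order(rev$gene), ])
})

test_that("power and sample size come from the noncentral t distribution", {
  # detectable shift of one LFC unit against a genome-wide SD of 0.5
  res <- sample_size_for_power(delta = 1, sd = 0.5, alpha = 0.05,
                               power = 0.80)
  expect_equal(res$n_per_group, 6)
  expect_gte(res$achieved_power, 0.80)
  expect_lt(power_two_sample_t(res$n_per_group - 1, 1, 0.5), 0.80)

  # an enormous shift needs only the minimum group size
  expect_equal(sample_size_for_power(delta = 100, sd = 0.5)$n_per_group, 2)

  # power is non-decreasing in n
  pw <- vapply(2:30, power_two_sample_t, numeric(1), delta = 0.5, sd = 1)
  expect_true(all(diff(pw) > 0))

  expect_error(sample_size_for_power(delta = 0, sd = 1), "delta")
  expect_error(sample_size_for_power(delta = 1, sd = 1, power = 1), "power")
  expect_error(sample_size_for_power(delta = 1e-4, sd = 1, n_max = 50),
               "not attainable")
})

test_that("exact power matches power.t.test", {
  # power.t.test drops the rejection mass in the opposite tail, so it
  # sits just below the exact two-sided power; the gap vanishes as the
  # noncentrality grows
  for (n in c(3, 6, 15, 40)) {
    exact <- power_two_sample_t(n, 0.8, 1, 0.05)
    approx <- power.t.test(n = n, delta = 0.8, sd = 1)$power
    expect_gte(exact, approx)
    expect_lt(exact - approx, 5e-3)
  }
  expect_equal(power_two_sample_t(40, 0.8, 1, 0.05),
               power.t.test(n = 40, delta = 0.8, sd = 1)$power,
               tolerance = 1e-4)
})

test_that("packaged group statistics expose the published comparisons", {
  tab <- pbmc_reference_stats()
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$comparison), c("All", "Female", "Male"))
  fem <- pbmc_reference_stats("Female")
  expect_equal(fem$lfc[fem$gene == "PPARG"], -1.30)
})
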