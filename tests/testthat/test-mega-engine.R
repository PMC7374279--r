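test_that("fixed-effect pooling follows inverse-variance arithmetic", {
  fem <- fixed_effect_pool(c(0.5, 1.0), c(0.1, 0.1))
  expect_equal(fem$pooled, 0.75)
  expect_equal(fem$var, 0.05)
  expect_equal(fem$weights, c(0.5, 0.5))

  one <- fixed_effect_pool(0.3, 0.2)
  expect_equal(one$pooled, 0.3)
  expect_equal(one$weights, 1)

  expect_error(fixed_effect_pool(numeric(0), numeric(0)), "at least one")
  expect_error(fixed_effect_pool(c(1, 2), c(0.1, 0)), "> 0")
})

test_that("heterogeneity statistics follow the clamped I-squared rule", {
  het <- heterogeneity(c(0.5, 1.0), c(0.1, 0.1))
  expect_equal(het$Q, 1.25)  # 10 * 0.25^2 + 10 * 0.25^2
  expect_equal(het$df, 1)
  expect_equal(het$ISq, 20)

  same <- heterogeneity(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(same$Q, 0)
  expect_equal(same$ISq, 0)
  expect_equal(same$p_Q, 1)

  # boundary of the clamping rule: Q exactly equal to df
  y <- c(-0.5, 0.5)
  v <- c(0.5, 0.5)  # Q = 2*(0.5^2)/0.5 = 1 = df
  b <- heterogeneity(y, v)
  expect_equal(b$Q, b$df)
  expect_equal(b$ISq, 0)

  k1 <- heterogeneity(0.2, 0.1)
  expect_equal(k1$Q, 0)
  expect_equal(k1$df, 0)
  expect_equal(k1$p_Q, 1)
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  rem <- random_effects_pool(c(0.5, 1.0), c(0.1, 0.1))
  expect_equal(rem$tau2, 0.025)  # (1.25 - 1) / (20 - 10)
  expect_equal(rem$pooled, 0.75)
  expect_equal(rem$var, 0.0625)

  # homogeneous input reduces exactly to the fixed-effect result
  y <- c(0.4, 0.41, 0.39)
  v <- c(0.5, 0.5, 0.5)
  expect_lte(heterogeneity(y, v)$Q, 2)
  expect_identical(random_effects_pool(y, v)$pooled,
                   fixed_effect_pool(y, v)$pooled)

  # equal variances make the REM pool the arithmetic mean
  set.seed(61)
  y2 <- rnorm(6)
  expect_equal(random_effects_pool(y2, rep(0.3, 6))$pooled, mean(y2))
})

test_that("model selection uses the Q <= df rule and assembles the result", {
  res <- mega_analyze(c(0.5, 1.0), v = c(0.1, 0.1))
  expect_equal(res$model, "REM")  # Q = 1.25 > df = 1
  expect_equal(res$pooled_lfc, 0.75)
  expect_equal(res$ci_low, 0.75 - 1.96 * 0.25)
  expect_equal(res$ci_high, 0.75 + 1.96 * 0.25)
  expect_equal(res$p_value, 2 * pnorm(3, lower.tail = FALSE))
  expect_equal(res$tau2, 0.025)

  hom <- mega_analyze(rep(0.4, 5), v = rep(0.2, 5))
  expect_equal(hom$model, "FEM")
  expect_equal(hom$ISq, 0)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$pooled_lfc, 0.4)

  k1 <- mega_analyze(0.3, v = 0.1)
  expect_equal(k1$model, "FEM")
  expect_equal(k1$k, 1)
})

test_that("mega_analyze accepts effect tables and skips missing effects", {
  eff <- tibble::tibble(study_id = c("a", "b", "c"), gene = "PPARG",
                        lfc = c(0.5, 1.0, NA), var = c(0.1, 0.1, NA))
  res <- mega_analyze(eff)
  expect_equal(res$k, 2)
  expect_equal(res$gene, "PPARG")
  expect_equal(res$pooled_lfc, 0.75)
})

test_that("engine matches the brute-force oracle on random problems", {
  set.seed(62)
  for (rep in 1:200) {
    k <- sample(1:10, 1)
    y <- rnorm(k)
    v <- runif(k, 0.01, 2)
    oracle <- meta_brute(y, v)
    fem <- fixed_effect_pool(y, v)
    het <- heterogeneity(y, v)
    rem <- random_effects_pool(y, v)
    expect_equal(fem$pooled, oracle$pooled_fem, tolerance = 1e-10)
    expect_equal(fem$var, oracle$var_fem, tolerance = 1e-10)
    expect_equal(het$Q, oracle$Q, tolerance = 1e-10)
    expect_equal(het$ISq, oracle$ISq, tolerance = 1e-10)
    expect_equal(het$p_Q, oracle$p_Q, tolerance = 1e-10)
    expect_equal(rem$tau2, oracle$tau2, tolerance = 1e-10)
    expect_equal(rem$pooled, oracle$pooled_rem, tolerance = 1e-10)
    expect_true(het$ISq >= 0 && het$ISq < 100)
    expect_equal(sum(fem$weights), 1, tolerance = 1e-9)
    expect_equal(sum(rem$weights), 1, tolerance = 1e-9)
  }
})

test_that("engine agrees with metafor's FE and DL fits", {
  skip_if_not_installed("metafor")
  set.seed(63)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0.2, 0.5)
    v <- runif(k, 0.02, 0.5)
    fe <- metafor::rma(yi = y, vi = v, method = "FE")
    dl <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(fixed_effect_pool(y, v)$pooled, as.numeric(fe$beta),
                 tolerance = 1e-8)
    expect_equal(random_effects_pool(y, v)$tau2, dl$tau2, tolerance = 1e-8)
    expect_equal(random_effects_pool(y, v)$pooled, as.numeric(dl$beta),
                 tolerance = 1e-8)
    expect_equal(heterogeneity(y, v)$Q, fe$QE, tolerance = 1e-8)
  }
})

test_that("pooling is location-equivariant", {
  set.seed(64)
  y <- rnorm(7)
  v <- runif(7, 0.05, 0.5)
  a <- mega_analyze(y, v = v)
  b <- mega_analyze(y + 2.5, v = v)
  expect_equal(b$pooled_lfc, a$pooled_lfc + 2.5)
  expect_equal(b$Q, a$Q)
  expect_equal(b$ISq, a$ISq)
  expect_equal(b$tau2, a$tau2)
  expect_equal(attr(b, "studies")$weight, attr(a, "studies")$weight)
})

test_that("simulated homogeneous 13-study data recovers the true effect", {
  for (seed in 1:5) {
    set.seed(seed)
    sim <- simulate_meta_effects(k = 13, n_per_group = 30, theta = 0.5)
    res <- mega_analyze(sim$y, v = sim$v)
    expect_lt(abs(res$pooled_lfc - 0.5), 3 * res$se)
  }
})

test_that("forest data carries per-study CIs, weights and the summary row", {
  res <- mega_analyze(c(0.5, 1.0), v = c(0.1, 0.3))
  fd <- forest_data(res)
  expect_equal(nrow(fd), 3)
  expect_equal(fd$ci_low[1], 0.5 - 1.96 * sqrt(0.1))
  expect_true(fd$is_summary[3])
  expect_equal(fd$lfc[3], res$pooled_lfc)
  expect_equal(fd$ci_low[3], res$ci_low)

  eqv <- forest_data(mega_analyze(c(0.2, 0.6), v = c(0.2, 0.2)))
  expect_equal(eqv$weight[1:2], c(0.5, 0.5))
  # unequal variances weight inversely: v = (0.1, 0.3) under FEM -> 3:1
  fem <- fixed_effect_pool(c(0.5, 1.0), c(0.1, 0.3))
  expect_equal(fem$weights, c(0.75, 0.25))
})
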