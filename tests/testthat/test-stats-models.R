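# Hierarchical regression, collinearity, quadratic age model, LSO-CV,
# Levene's test, impairment rate.

make_design <- function(n, seed = 1, beta3 = 0, noise = 1) {
  set.seed(seed)
  d <- data.frame(age = runif(n, 20, 60), gender = rbinom(n, 1, 0.4),
                  x_s = rnorm(n), x_f = rnorm(n), x_m = rnorm(n),
                  site = sample(LETTERS[1:5], n, replace = TRUE))
  d$y <- -0.02 * d$age - 0.3 * d$gender + beta3 * d$x_m +
    rnorm(n, 0, noise)
  d
}

blocks3 <- list(c("age", "gender"), c("x_s", "x_f"), "x_m")

test_that("coefficients match the normal-equations oracle on a tiny dataset", {
  d <- data.frame(age = c(31, 45, 28, 52, 39, 47),
                  gender = c(0, 1, 0, 1, 1, 0),
                  x_m = c(0.1, -0.4, 0.3, 0.2, -0.1, 0.5),
                  y = c(0.2, -1.1, 0.5, -0.9, -0.4, 0.8))
  res <- hierarchical_regression(d, list(c("age", "gender"), "x_m"), "y")
  oracle <- oracle_ols(as.matrix(d[, c("age", "gender", "x_m")]), d$y)
  expect_equal(res$coefficients$b_raw, oracle$beta, tolerance = 1e-10)
  expect_equal(res$blocks$r2[2], oracle$r2, tolerance = 1e-10)
  # standardized beta definition
  expect_equal(res$coefficients$b_std[2],
               oracle$beta[2] * sd(d$age) / sd(d$y), tolerance = 1e-10)
  expect_identical(res$n, 6L)
})

test_that("exact linear outcome in block 1 gives R2 = 1 throughout", {
  d <- make_design(50, seed = 11, noise = 0)
  res <- hierarchical_regression(d, blocks3, "y")
  # y is exactly linear in age, gender, x_m; by block 3 R2 = 1; a spec'd
  # block-1-only outcome saturates from block 1 onward:
  d$y <- 1 + 0.5 * d$age - 2 * d$gender
  res <- suppressWarnings(hierarchical_regression(d, blocks3, "y"))
  expect_equal(res$blocks$r2, rep(1, 3), tolerance = 1e-10)
  expect_equal(res$blocks$delta_r2[2:3], c(0, 0), tolerance = 1e-10)
})

test_that("R2 is non-decreasing and delta_r2 exact across random datasets", {
  for (seed in 1:6) {
    d <- make_design(40, seed = seed, beta3 = runif(1, -1, 1))
    res <- hierarchical_regression(d, blocks3, "y")
    expect_true(all(diff(res$blocks$r2) >= -1e-12))
    expect_equal(res$blocks$delta_r2, c(res$blocks$r2[1],
                                        diff(res$blocks$r2)),
                 tolerance = 1e-12)
    expect_true(all(res$blocks$adj_r2 <= res$blocks$r2 + 1e-12))
  }
})

test_that("single-predictor block: delta F equals the coefficient t squared", {
  d <- make_design(80, seed = 12, beta3 = 0.3)
  res <- hierarchical_regression(d, blocks3, "y")
  tval <- summary(res$fit)$coefficients["x_m", "t value"]
  expect_equal(res$blocks$delta_f[3], tval^2, tolerance = 1e-10)
  expect_equal(res$blocks$delta_f_p[3],
               summary(res$fit)$coefficients["x_m", 4], tolerance = 1e-10)
})

test_that("standardized beta invariant under predictor rescaling", {
  d <- make_design(60, seed = 13, beta3 = 0.4)
  res1 <- hierarchical_regression(d, blocks3, "y")
  d2 <- d; d2$x_m <- d$x_m * 7 + 3
  res2 <- hierarchical_regression(d2, blocks3, "y")
  i <- which(res1$coefficients$term == "x_m")
  expect_equal(res2$coefficients$b_std[i], res1$coefficients$b_std[i],
               tolerance = 1e-10)
  expect_equal(res2$coefficients$b_raw[i], res1$coefficients$b_raw[i] / 7,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  d <- make_design(30, seed = 14)
  d$dup <- d$x_m
  expect_error(
    hierarchical_regression(d, list(c("age", "gender"), c("x_m", "dup")),
                            "y"), "collinear")
  d$const <- 1
  expect_error(hierarchical_regression(d, list("const"), "y"), "constant")
  expect_error(hierarchical_regression(d[1:3, ], blocks3, "y"), "too small")
})

test_that("collinearity diagnostics: VIF closed forms", {
  set.seed(15)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  d <- data.frame(a = a, b = b, c = 0.8 * a + sqrt(1 - 0.64) * rnorm(n))
  diag1 <- collinearity_diagnostics(d, c("a", "b"))
  expect_equal(unname(diag1$vif), c(1, 1), tolerance = 0.02)

  r <- cor(d$a, d$c)
  diag2 <- collinearity_diagnostics(d, c("a", "c"))
  expect_equal(unname(diag2$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  d$a2 <- d$a
  diag3 <- collinearity_diagnostics(d, c("a", "a2"))
  expect_true(all(is.infinite(diag3$vif)))
})

test_that("quadratic age model: exact quadratic metric and rescaling invariance", {
  set.seed(16)
  age <- runif(120, 20, 60)
  metric <- (age - mean(age))^2
  res <- quadratic_age_model(metric, age)
  expect_equal(res$blocks$r2[2], 1, tolerance = 1e-10)
  expect_gt(res$blocks$delta_r2[2], 0)

  metric <- rnorm(120) + 0.01 * age
  r_a <- quadratic_age_model(metric, age)
  r_b <- quadratic_age_model(metric, (age - 40) / 10)
  expect_equal(r_b$blocks$delta_r2[2], r_a$blocks$delta_r2[2],
               tolerance = 1e-9)
  expect_equal(r_b$blocks$delta_f_p[2], r_a$blocks$delta_f_p[2],
               tolerance = 1e-9)
})

test_that("Levene test: degenerate case, oracle match, small groups dropped", {
  x <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  out <- levene_test(x, g)
  expect_equal(out$f_stat, 0)

  set.seed(17)
  x <- c(rnorm(12, sd = 1), rnorm(15, sd = 3))
  g <- c(rep("a", 12), rep("b", 15))
  out <- levene_test(x, g)
  expect_equal(out$f_stat, oracle_levene_w(x, g), tolerance = 1e-10)
  expect_identical(c(out$df1, out$df2), c(1L, 25L))

  expect_warning(out2 <- levene_test(c(x, 5), c(g, "c")), "dropping")
  expect_equal(out2$f_stat, out$f_stat, tolerance = 1e-12)
  # median-centred variant differs but stays finite
  expect_true(is.finite(levene_test(x, g, center = "median")$f_stat))
})

test_that("LSO-CV: fold structure, perfect model, noise model", {
  d <- make_design(100, seed = 18)
  d$y <- 1 + 0.1 * d$age - 0.5 * d$gender + 0.3 * d$x_m  # zero noise
  cv <- suppressWarnings(leave_site_out_cv(d, blocks3, "y"))
  expect_identical(nrow(cv$folds), length(unique(d$site)))
  expect_identical(sum(cv$folds$n_test), nrow(d))
  expect_equal(cv$folds$test_r2, rep(1, nrow(cv$folds)), tolerance = 1e-9)

  # pure-noise outcome with small per-site n: out-of-sample R2 goes negative
  set.seed(19)
  neg <- replicate(20, {
    d <- make_design(60, seed = sample.int(1e6, 1), beta3 = 0, noise = 1)
    d$y <- rnorm(60)
    leave_site_out_cv(d, blocks3, "y")$mean_r2
  })
  expect_lt(mean(neg), 0)
  expect_gt(mean(neg < 0), 0.6)
})

test_that("LSO-CV flags single-subject sites instead of failing", {
  d <- make_design(40, seed = 20)
  d$site <- c("solo", rep(c("A", "B", "C"), 13))
  expect_warning(cv <- leave_site_out_cv(d, blocks3, "y"), "dropping")
  expect_true(is.na(cv$folds$test_r2[cv$folds$held_out_site == "solo"]))
  expect_false(anyNA(cv$folds$test_r2[cv$folds$held_out_site != "solo"]))
})

test_that("impairment rate: counts and distributional check", {
  expect_equal(impairment_rate(rep(0, 10))$count, 0)
  out <- impairment_rate(c(-2, -1, 0, -1.6), threshold = -1.5)
  expect_identical(out$count, 2L)
  expect_equal(out$proportion, 0.5)
  # strictly-below convention
  expect_identical(impairment_rate(c(-1.5), threshold = -1.5)$count, 0L)

  set.seed(21)
  out <- impairment_rate(rnorm(40000))
  expect_lt(abs(out$proportion - pnorm(-1.5)), 0.005)
})
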