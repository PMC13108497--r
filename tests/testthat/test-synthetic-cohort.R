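# Synthetic cohort generator: determinism, structural guarantees, planted
# outcome model, disk round-trip.

small_config <- function(n_subjects = 15, seed = 1, ...) {
  suppressWarnings(cohort_config(
    n_subjects = n_subjects, n_regions = 20, n_sites = 4,
    ts_length = 60, seed = seed, ...))
}

test_that("identical config + seed gives bit-identical output", {
  cfg <- small_config(seed = 31)
  a <- generate_structural_matrix(cfg, 3)
  b <- generate_structural_matrix(cfg, 3)
  expect_identical(a$weights, b$weights)
  expect_identical(generate_functional_timeseries(cfg, 3),
                   generate_functional_timeseries(cfg, 3))

  parc <- synthetic_parcellation(20, 4)
  c1 <- generate_cohort(cfg, parc)
  c2 <- generate_cohort(cfg, parc)
  expect_identical(as.data.frame(c1$manifest), as.data.frame(c2$manifest))
  expect_identical(c1$structural[[5]]$weights, c2$structural[[5]]$weights)
  expect_identical(c1$functional[[5]]$weights, c2$functional[[5]]$weights)
  # different subjects / seeds differ
  expect_false(identical(a$weights,
                         generate_structural_matrix(cfg, 4)$weights))
  expect_false(identical(
    a$weights, generate_structural_matrix(small_config(seed = 32),
                                          3)$weights))
})

test_that("structural matrices honour density and are always connected", {
  cfg <- suppressWarnings(cohort_config(n_subjects = 1, n_regions = 5,
                                        structural_density = 1,
                                        ts_length = 20, seed = 33))
  W <- generate_structural_matrix(cfg, 1)$weights
  expect_identical(sum(W[upper.tri(W)] > 0), 10L)  # complete graph on 5

  for (i in 1:8) {
    cfg <- small_config(seed = 34)
    W <- generate_structural_matrix(cfg, i)$weights
    expect_true(oracle_connected(W > 0))
    expect_true(all(W >= 0))
    expect_identical(max(abs(W - t(W))), 0)
    frac <- mean(W[upper.tri(W)] > 0)
    expect_lt(abs(frac - cfg$structural_density), 0.1)
  }

  # even near the connectivity bound the graph is repaired to connected
  cfg <- suppressWarnings(cohort_config(n_subjects = 1, n_regions = 30,
                                        structural_density = 2 / 30,
                                        ts_length = 60, seed = 35))
  for (i in 1:5) {
    expect_true(oracle_connected(
      generate_structural_matrix(cfg, i)$weights > 0))
  }
  expect_error(suppressWarnings(cohort_config(
    n_subjects = 1, n_regions = 30, structural_density = 0.01)),
    "bound")
})

test_that("pure-noise time series decorrelate as ts_length grows", {
  mean_abs_r <- function(t_len) {
    cfg <- suppressWarnings(cohort_config(
      n_subjects = 1, n_regions = 15, ts_length = t_len,
      factor_loading = 0, seed = 36))
    r <- cor(t(generate_functional_timeseries(cfg, 1)))
    mean(abs(r[upper.tri(r)]))
  }
  r_short <- mean_abs_r(30)
  r_long <- mean_abs_r(1000)
  expect_lt(r_long, r_short)
  expect_lt(r_long, 0.06)  # ~ sqrt(2/pi)/sqrt(T) for T = 1000

  # nonzero loadings give visible within-community block structure
  cfg <- small_config(seed = 37)
  parc <- synthetic_parcellation(20, 4)
  panel <- generate_functional_timeseries(cfg, 1, parc)
  r <- cor(t(panel))
  same <- outer(parc$network, parc$network, `==`) & upper.tri(r)
  diff <- (!outer(parc$network, parc$network, `==`)) & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff]) + 0.1)
})

test_that("cohort structure: sites, manifest fields, planted zero-noise model", {
  parc <- synthetic_parcellation(20, 4)
  cfg <- suppressWarnings(cohort_config(
    n_subjects = 60, n_regions = 20, n_sites = 13, ts_length = 60,
    seed = 38))
  co <- generate_cohort(cfg, parc)
  expect_identical(length(unique(co$manifest$site)), 13L)
  expect_identical(nrow(co$manifest), 60L)
  expect_true(all(co$manifest$gender %in% c(0, 1)))
  expect_true(all(co$manifest$age >= cfg$age_range[1] &
                    co$manifest$age <= cfg$age_range[2]))
  expect_true(all(co$manifest$edss >= 0 & co$manifest$edss <= 7.5))
  expect_true(all(co$manifest$edss * 2 == round(co$manifest$edss * 2)))

  # zero noise + zero multiplex effect: block-1 regression saturates
  cfg0 <- small_config(
    n_subjects = 25, seed = 39, noise_sd = 0,
    effect_coeffs = list(intercept = -0.7, beta_age = -0.18,
                         beta_sex = -0.33, beta_mplex_ecfpn = 0))
  co0 <- generate_cohort(cfg0, parc)
  d <- assemble_design_table(co0$manifest, co0$metrics)
  res <- suppressWarnings(
    hierarchical_regression(d, default_blocks("ec_fpn"), "sdmt_z"))
  expect_equal(res$blocks$r2[1], 1, tolerance = 1e-9)
})

test_that("cohort round-trips through the TSV/JSON layout", {
  parc <- synthetic_parcellation(20, 4)
  co <- generate_cohort(small_config(n_subjects = 6, seed = 40), parc)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  expect_identical(cfg_back$seed, 40L)
  expect_identical(cfg_back$n_subjects, 6L)

  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$manifest), as.data.frame(co$manifest),
               tolerance = 1e-9)
  for (i in c(1, 6)) {
    expect_equal(back$structural[[i]]$weights, co$structural[[i]]$weights,
                 tolerance = 1e-12)
    expect_equal(back$functional[[i]]$weights, co$functional[[i]]$weights,
                 tolerance = 1e-12)
  }
})
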