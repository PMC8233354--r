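test_that("index formula matches hand values and handles degenerate input", {
  expect_equal(psf_index(10, 10), 0)
  expect_equal(psf_index(15, 10), 1 / 3)
  expect_equal(psf_index(5, 10), -0.5)
  expect_equal(psf_index(10, 0), 1)    # formula limit, growth only on self
  expect_warning(out <- psf_index(0, 0), "both zero")
  expect_equal(out, 0)
  expect_error(psf_index(-1, 5), "non-negative")
})

test_that("index is antisymmetric, scale invariant and bounded", {
  set.seed(101)
  S <- stats::rlnorm(500, 3, 1)
  O <- stats::rlnorm(500, 3, 1)
  p <- psf_index(S, O)
  expect_true(all(p >= -1 & p <= 1))
  expect_equal(psf_index(O, S), -p)
  for (c in c(0.01, 3, 1e6))
    expect_equal(psf_index(c * S, c * O), p)
})

test_that("bootstrap interval collapses without resampling variance", {
  expect_equal(psf_bootstrap_ci(rep(10, 5), rep(10, 7), n_boot = 200),
               c(ci_low = 0, ci_high = 0))
  expect_equal(psf_bootstrap_ci(rep(10, 5), rep(5, 7), n_boot = 200),
               c(ci_low = 0.5, ci_high = 0.5))
  expect_error(psf_bootstrap_ci(10, c(5, 6)), ">= 2 replicates")
})

test_that("bootstrap is seeded and its width shrinks with replicate noise", {
  set.seed(5)
  s <- stats::rlnorm(30, log(10), 0.4)
  o <- stats::rlnorm(7, log(12), 0.4)
  ci1 <- psf_bootstrap_ci(s, o, n_boot = 500, seed = 9)
  ci2 <- psf_bootstrap_ci(s, o, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  s2 <- stats::rlnorm(30, log(10), 0.02)
  o2 <- stats::rlnorm(7, log(12), 0.02)
  ci3 <- psf_bootstrap_ci(s2, o2, n_boot = 500, seed = 9)
  expect_lt(diff(ci3), diff(ci1))
})

test_that("matrix has one cell per ordered species-soil pair", {
  d <- default_design()
  m <- true_psf_model(seed = 2)
  rec <- generate_psf_experiment(m, d)
  mat <- psf_matrix(rec, year = 2018, n_boot = 0)
  expect_s3_class(mat, "psf_matrix")
  expect_equal(nrow(mat), 240)
  expect_false(any(mat$species == mat$soil_species))
  expect_true(all(mat$n_self >= 27 & mat$n_self <= 35))
  expect_true(all(mat$n_other >= 5 & mat$n_other <= 9))
  # records restricted to one focal species still give its 15 cells
  one <- psf_matrix(rec[rec$species == "Ag", ], year = 2018, n_boot = 0)
  expect_equal(nrow(one), 15)
  # a missing combination is flagged NA with a warning, not dropped silently
  drop <- rec[!(rec$species == "Ag" & rec$soil_type == "Sn"), ]
  expect_warning(mat2 <- psf_matrix(drop, year = 2018, n_boot = 0),
                 "missing")
  expect_true(is.na(mat2$psf[mat2$species == "Ag" & mat2$soil_species == "Sn"]))
  expect_equal(psf_summary(mat2)$n_cells, 239)
})

test_that("zero-noise cells give degenerate intervals flagged significant", {
  pool <- small_pool()
  m <- true_psf_model(pool, effect = diag_effect(pool, 0.9), noise_sigma = 0,
                      year_attenuation = 1, seed = 1)
  mat <- psf_matrix(generate_psf_experiment(m, small_design()), 2018,
                    n_boot = 200, seed = 4)
  expect_equal(mat$ci_low, rep(-0.1, nrow(mat)))
  expect_equal(mat$ci_high, rep(-0.1, nrow(mat)))
  expect_true(all(mat$significant))
})

test_that("summary statistics separate magnitude from direction", {
  mk <- function(v) {
    structure(data.frame(species = "a", soil_species = "b", psf = v),
              class = c("psf_matrix", "data.frame"))
  }
  expect_equal(psf_summary(mk(rep(-0.1, 4))),
               list(mean_abs_psf = 0.1, net_mean_psf = -0.1, n_cells = 4))
  # large opposite feedbacks cancel in the net mean but not in |PSF|
  expect_equal(psf_summary(mk(c(0.3, -0.3))),
               list(mean_abs_psf = 0.3, net_mean_psf = 0, n_cells = 2))
  expect_error(psf_summary(mk(NA_real_)), "no non-missing")
})

test_that("species-level summary matches a direct t-test", {
  d <- default_design()
  rec <- generate_psf_experiment(true_psf_model(seed = 6), d)
  mat <- psf_matrix(rec, 2018, n_boot = 0)
  ss <- psf_species_summary(mat)
  expect_equal(nrow(ss), 16)
  expect_equal(ss$n_soils, rep(15, 16))
  for (sp in c("Ac", "Sn")) {
    v <- mat$psf[mat$species == sp]
    tt <- t.test(v)
    row <- ss[ss$species == sp, ]
    expect_equal(row$mean_psf, mean(v))
    expect_equal(row$se, sd(v) / sqrt(15))
    expect_equal(row$t_stat, unname(tt$statistic))
    expect_equal(row$p_value, tt$p.value)
  }
})

test_that("year comparison pairs cells and survives degenerate input", {
  pool <- small_pool()
  d <- small_design()
  # identical years (attenuation 1, no noise): t = 0, p = 1, no crash
  m0 <- true_psf_model(pool, effect = diag_effect(pool, 0.9), noise_sigma = 0,
                       year_attenuation = 1, seed = 1)
  yc0 <- psf_year_comparison(generate_psf_experiment(m0, d))
  expect_equal(yc0$t, c(0, 0))
  expect_equal(yc0$p_value, c(1, 1))
  # attenuated first year: a constant shift, detected with p ~ 0 and the
  # sign of t reflecting the increase in feedback strength
  m1 <- true_psf_model(pool, effect = diag_effect(pool, 0.8), noise_sigma = 0,
                       year_attenuation = 0.5, seed = 1)
  yc1 <- psf_year_comparison(generate_psf_experiment(m1, d))
  net <- yc1[yc1$metric == "net", ]
  expect_equal(net$p_value, 0)
  expect_gt(net$t, 0)  # year-1 net minus year-2 net > 0 (feedbacks more negative later)
  # mismatched cell sets are an error naming the unmatched pair
  rec <- generate_psf_experiment(m1, d)
  rec <- rec[!(rec$year == 2017 & rec$species == "Aa"), ]
  expect_error(psf_year_comparison(rec), "Aa Bb")
})

test_that("group tests flag a shifted functional group", {
  pool <- small_pool()
  set.seed(8)
  cells <- expand.grid(species = pool$code, soil_species = pool$code,
                       stringsAsFactors = FALSE)
  cells <- cells[cells$species != cells$soil_species, ]
  cells$psf <- rnorm(nrow(cells), 0, 0.01)
  cells$psf[cells$species == "Aa"] <- rnorm(3, -0.2, 0.01)
  mat <- structure(cells, class = c("psf_matrix", "data.frame"))
  gt <- psf_group_tests(mat, pool)
  expect_lt(gt$group_tests$p_value[gt$group_tests$group == "C3"], 0.01)
  expect_lt(gt$anova$p_value, 0.01)
  expect_equal(gt$anova$df1, 3)
  # all-zero cells: every group mean is 0 and nothing is significant
  mat0 <- mat
  mat0$psf <- 0
  gt0 <- psf_group_tests(mat0, pool)
  expect_true(all(gt0$group_tests$p_value == 1))
})

test_that("distance regression recovers an exact linear dependence", {
  d <- default_design()
  rec <- generate_psf_experiment(true_psf_model(seed = 9), d)
  mat <- psf_matrix(rec, 2018, n_boot = 0)
  codes <- sort(unique(mat$species))
  set.seed(10)
  dm <- matrix(runif(256, 1, 100), 16, 16, dimnames = list(codes, codes))
  dm <- (dm + t(dm)) / 2
  # psf exactly linear in distance: r = 1 and the slope is recovered
  mat$psf <- 0.001 * dm[cbind(mat$species, mat$soil_species)] - 0.2
  fit <- suppressWarnings(psf_distance_test(mat, dm))  # exact fit
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.001, tolerance = 1e-9)
  # constant psf: no correlation by convention
  mat$psf <- -0.1
  expect_equal(psf_distance_test(mat, dm)$r, 0)
  # incomplete distance information is an error
  expect_error(psf_distance_test(mat, dm[-1, ]), "missing")
})
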