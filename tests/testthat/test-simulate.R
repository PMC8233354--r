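mk_psf_records <- function(df) {
  df$experiment <- "psf"
  if (is.null(df$year)) df$year <- 2018L
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}

test_that("rate derivation inverts one season of discrete growth", {
  rec <- mk_psf_records(data.frame(
    species = c("Aa", "Aa", "Aa", "Bb", "Bb", "Bb"),
    soil_type = c("self", "Bb", "control", "self", "Aa", "control"),
    biomass_g = c(1, 2^52, 8, 16, 4, 2)))
  r <- derive_growth_rates(rec, "per_soil", b0 = 1)
  expect_equal(r["Aa", "Aa"], 0)          # B_obs = b0 -> no net growth
  expect_equal(r["Aa", "Bb"], 1)          # 2^52 over 52 steps -> doubling
  expect_equal(r["Bb", "Bb"], 16^(1 / 52) - 1)
  expect_equal(r["Aa", "background"], 8^(1 / 52) - 1)  # from control plots
  # single-rate null parameterizations replicate one rate across soils
  rc <- derive_growth_rates(rec, "control")
  expect_true(all(rc["Aa", ] == 8^(1 / 52) - 1))
  rs <- derive_growth_rates(rec, "self")
  expect_true(all(rs["Bb", ] == 16^(1 / 52) - 1))
  # round trip: simulating one season with the derived rate recovers B_obs
  p <- one_species_params(r["Bb", "Bb"], code = "Bb")
  B <- simulate_community("Bb", p, sim_schedule(52, n_seasons = 1))
  expect_equal(unname(B), 16, tolerance = 1e-6)
})

test_that("rate derivation flags zero growth and missing combinations", {
  rec <- mk_psf_records(data.frame(
    species = c("Aa", "Aa"), soil_type = c("self", "control"),
    biomass_g = c(0, 5)))
  expect_warning(r <- derive_growth_rates(rec, "self"), "floored")
  expect_equal(unname(r["Aa", "Aa"]), -1 + 1e-8)
  rec2 <- mk_psf_records(data.frame(
    species = c("Aa", "Bb"), soil_type = c("self", "self"),
    biomass_g = c(5, 5)))
  expect_error(derive_growth_rates(rec2, "per_soil"), "no records")
})

test_that("the five carrying capacities match a brute-force scan", {
  m <- true_psf_model(small_pool(), seed = 21)
  d <- small_design()
  prec <- generate_psf_experiment(m, d)
  crec <- generate_community_experiment(m, d)
  Ks <- carrying_capacities(prec, crec)
  # independent scan of the raw tables
  plot_tot <- tapply(crec$biomass_g, paste(crec$community_id, crec$replicate),
                     sum)
  expect_equal(Ks$K1$K, max(plot_tot))
  comm_means <- sapply(split(crec, crec$community_id), function(x)
    mean(tapply(x$biomass_g, x$replicate, sum)))
  expect_equal(Ks$K2$K, max(comm_means))
  expect_lte(Ks$K2$K, Ks$K1$K)  # a community mean cannot beat the best plot
  for (sp in small_pool()$code) {
    expect_equal(unname(Ks$K3$K[sp]),
                 max(crec$biomass_g[crec$species == sp]))
    expect_equal(unname(Ks$K5$K[sp]),
                 max(prec$biomass_g[prec$species == sp]))
  }
  expect_equal(Ks$K4$K, max(prec$biomass_g))
  expect_equal(Ks$K1$mode, "constant_K")
  expect_equal(Ks$K3$mode, "species_K")
  # one-plot community experiment: K1 is that plot's total
  one <- data.frame(community_id = "C1", replicate = 1,
                    species = c("Aa", "Bb"), biomass_g = c(60, 40))
  expect_warning(K1 <- carrying_capacities(prec, one)$K1$K, "median")
  expect_equal(K1, 100)
})

test_that("a step grows exponentially far below K and stalls at K", {
  p <- one_species_params(0.1, K = 1e12, conversion = 0)
  st <- sim_init("Aa", p)
  for (i in 1:10) {
    st2 <- sim_step(st, p)
    expect_equal(unname(st2$B), unname(st$B) * 1.1, tolerance = 1e-9)
    st <- st2
  }
  # at the constant-K ceiling the logistic bracket is zero: a fixed point
  pK <- one_species_params(0.5, K = 30, K_mode = "constant_K")
  stK <- structure(list(t = 0L, B = c(Aa = 30),
                        f = c(Aa = 0, background = 1)), class = "sim_state")
  expect_equal(sim_step(stK, pK)$B, c(Aa = 30))
})

test_that("identical species stay identical through soil dynamics", {
  codes <- c("Aa", "Bb")
  r <- matrix(0.08, 2, 3, dimnames = list(codes, c(codes, "background")))
  p <- growth_params(r, K = 50, K_mode = "constant_K", conversion = 0.02)
  st <- sim_init(codes, p)
  for (i in 1:60) {
    st <- sim_step(st, p)
    expect_equal(st$B[["Aa"]], st$B[["Bb"]])
    expect_equal(st$f[["Aa"]], st$f[["Bb"]])
    expect_equal(sum(st$f), 1, tolerance = 1e-9)
    expect_true(all(st$f >= 0))
  }
})

test_that("zero rates leave only the between-season biomass reset", {
  codes <- c("Aa", "Bb")
  r <- matrix(0, 2, 3, dimnames = list(codes, c(codes, "background")))
  p <- growth_params(r, K = 100, K_mode = "constant_K", conversion = 0.01)
  B <- simulate_community(codes, p, sim_schedule(52, 2, 0.01))
  expect_equal(B, c(Aa = 0.5 * 0.01, Bb = 0.5 * 0.01))
  expect_error(simulate_community(character(0), p), "at least one species")
})

test_that("monoculture trajectories match the scalar logistic recurrence", {
  sched <- sim_schedule(52, 2, 0.01)
  for (case in list(c(r = 0.09, K = 80), c(r = 0.15, K = 40),
                    c(r = 0.02, K = 500))) {
    p <- one_species_params(case["r"], K = unname(case["K"]),
                            K_mode = "species_K", conversion = 0.01)
    B <- simulate_community("Aa", p, sched)
    oracle <- scalar_logistic(1, case["r"], case["K"], 52, 2, 0.01)
    expect_equal(unname(B), unname(oracle), tolerance = 1e-6)
  }
})

test_that("without conversion on one soil type the feedback model is the null model", {
  m <- true_psf_model(small_pool(), seed = 31)
  d <- small_design()
  prec <- generate_psf_experiment(m, d)
  r_psf <- derive_growth_rates(prec, "per_soil")
  r_null <- derive_growth_rates(prec, "control")
  # same background rates by construction; c = 0 keeps all soil background
  expect_identical(r_psf[, "background"], r_null[, "background"])
  K <- c(Aa = 70, Bb = 90, Cc = 60, Dd = 120)
  p_psf <- growth_params(r_psf, K, "species_K", conversion = 0)
  p_null <- growth_params(r_null, K, "species_K", conversion = 0)
  for (id in c("C05", "C08")) {
    sp <- d$membership$species[d$membership$community_id == id]
    expect_identical(simulate_community(sp, p_psf),
                     simulate_community(sp, p_null))
  }
})

test_that("raising every rate never lowers any final biomass", {
  set.seed(77)
  codes <- c("Aa", "Bb", "Cc")
  for (i in 1:5) {
    r <- matrix(runif(12, 0.01, 0.12), 3, 4,
                dimnames = list(codes, c(codes, "background")))
    p1 <- growth_params(r, K = 60, "constant_K", conversion = 0.01)
    p2 <- growth_params(r + 0.01, K = 60, "constant_K", conversion = 0.01)
    B1 <- simulate_community(codes, p1)
    B2 <- simulate_community(codes, p2)
    expect_true(all(B2 >= B1 - 1e-9))
  }
})

test_that("a null community of identical species shows no biodiversity effect", {
  codes <- paste0("S", 1:8)
  r <- matrix(0.1, 8, 9, dimnames = list(codes, c(codes, "background")))
  p <- growth_params(r, K = 90, "constant_K", conversion = 0)
  mono <- simulate_community(codes[1], p)
  for (N in c(2, 4, 8)) {
    B <- simulate_community(codes[1:N], p)
    part <- loreau_hector(rep(unname(mono), N), unname(B))
    expect_equal(part$net, 0, tolerance = 1e-9)
    expect_equal(part$complementarity, 0, tolerance = 1e-9)
    expect_equal(part$selection, 0, tolerance = 1e-9)
  }
})

test_that("ensembles average the documented number of member runs", {
  m <- true_psf_model(small_pool(), seed = 41)
  d <- small_design()
  prec <- generate_psf_experiment(m, d)
  crec <- generate_community_experiment(m, d)
  null <- run_ensemble(d, "null", prec, crec)
  psf <- run_ensemble(d, "psf", prec, crec)
  expect_equal(sort(unique(paste(null$runs$rate_mode, null$runs$K_variant))),
               sort(paste(rep(c("control", "self"), each = 5),
                          paste0("K", 1:5))))
  expect_equal(unique(psf$runs$rate_mode), "per_soil")
  expect_equal(sort(unique(psf$runs$K_variant)), paste0("K", 1:5))
  # the ensemble mean is the plain average over member runs
  key <- paste(psf$runs$community_id, psf$runs$species)
  manual <- tapply(psf$runs$biomass_g, key, mean)
  expect_equal(psf$mean$biomass_g,
               as.numeric(manual[paste(psf$mean$community_id,
                                       psf$mean$species)]))
  # totals add the per-species ensemble means within a community
  tot <- tapply(psf$mean$biomass_g, psf$mean$community_id, sum)
  expect_equal(psf$total$biomass_g,
               as.numeric(tot[psf$total$community_id]))
})

test_that("strong negative self-feedback depresses monocultures below mixtures", {
  pool <- small_pool()
  m <- true_psf_model(pool, effect = diag_effect(pool, 0.4), noise_sigma = 0,
                      seed = 5)
  prec <- generate_psf_experiment(m, small_design())
  r <- derive_growth_rates(prec, "per_soil")
  p <- growth_params(r, K = stats::setNames(rep(1e9, 4), pool$code),
                     "species_K", conversion = 0.05)
  mono <- simulate_community("Aa", p)
  bi <- simulate_community(c("Aa", "Bb"), p)
  # per-capita: half a biculture seed on mixed soils beats a full
  # monoculture seed stuck on self-trained soil
  expect_gt(2 * bi[["Aa"]], unname(mono))
})
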