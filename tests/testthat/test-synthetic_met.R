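test_that("simulation is deterministic and produces the stated design", {
  cfg <- sim_config(seed = 11)
  sim1 <- simulate_trial(cfg)
  expect_equal(nrow(sim1$plots), 23L * 15L * 3L)
  expect_equal(nrow(sim1$experiments), 15L)

  # byte-identical CSV outputs under the same (config, seed)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_outputs(sim1, d1)
  write_sim_outputs(simulate_trial(cfg), d2)
  for (f in c("plots.csv", "weather.csv", "experiments.csv", "genotypes.csv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # different seed changes the data
  sim2 <- simulate_trial(sim_config(seed = 12))
  expect_false(identical(sim1$plots$gy_g_m2, sim2$plots$gy_g_m2))

  # per-experiment streams: adding a year never perturbs existing experiments
  sim3 <- simulate_trial(sim_config(seed = 11,
                                    years = c(2007L, 2008L, 2010L, 2011L,
                                              2012L, 2013L)))
  old <- sim3$plots[sim3$plots$year != 2013L, ]
  expect_equal(old$gy_g_m2, sim1$plots$gy_g_m2, ignore_attr = TRUE)
  expect_equal(old$date_flowering, sim1$plots$date_flowering,
               ignore_attr = TRUE)
})

test_that("degenerate configurations collapse as forced by construction", {
  # zero noise and amplitude: constant site-mean temperature
  cfg <- sim_config(seed = 1)
  cfg$weather$tmean_amplitude <- 0
  cfg$weather$ar1_sd <- 0
  wx <- simulate_weather(cfg, sim_experiments(cfg)[1, ])
  expect_equal(unique(wx$tmean_c),
               cfg$weather$tmean_annual[cfg$weather$site == wx$site[1]])

  # all SDs and differential effects zero: every plot's yield identical, and
  # the downstream ANOVA concentrates all SS in the residual (all zero)
  null_cfg <- sim_config(
    seed = 2, sigma_eps_days = 0, sigma_flower_year = 0,
    sigma_flower_plot = 0, grain_fill_sd = 0, sigma_gw_genotype = 0,
    sigma_gw_block = 0, sigma_gw_plot = 0, sigma_gn_genotype = 0,
    sigma_gn_block = 0, sigma_gn_plot = 0, sigma_gy_block = 0,
    sigma_gy_plot = 0, slope_sd = 0, sigma_env_quality = 0,
    ac_flowering_effect = c(I0I = 0, I0S = 0, I5I = 0, I5S = 0, SS = 0,
                            SI = 0),
    gn_ac_effect = c(I0I = 0, I0S = 0, I5I = 0, I5S = 0, SS = 0, SI = 0),
    env_quality = c(Spain = 0, `Mexico-North` = 0, `Mexico-South` = 0))
  simn <- simulate_trial(null_cfg)
  expect_equal(length(unique(simn$plots$gy_g_m2)), 1L)
  av <- combined_anova(derive_traits(simn$plots), "gy_g_m2", simn$genotypes)
  expect_true(all(av$ss[av$source != "residual"] < 1e-16))

  # noiseless allele-combination contrast is reproduced exactly (9-day span)
  det_cfg <- null_cfg
  det_cfg$ac_flowering_effect <- c(I0I = 0, I0S = 1, I5I = 2, I5S = 5,
                                   SS = 7, SI = 9)
  simd <- simulate_trial(det_cfg)
  pl <- derive_traits(simd$plots)
  ac <- simd$genotypes$allele_combination[match(pl$genotype,
                                                simd$genotypes$genotype)]
  mfl <- tapply(pl$days_ef, ac, mean)
  expect_equal(unname(mfl[["SI"]] - mfl[["I0I"]]), 9)
})

test_that("weather generator has the stated seasonal structure", {
  cfg <- sim_config(seed = 21)
  ex <- sim_experiments(cfg)
  spain <- ex[ex$site == "Spain" & ex$year == 2007, ]
  wx <- simulate_weather(cfg, spain)
  expect_true(all(wx$tmin_c <= wx$tmean_c & wx$tmean_c <= wx$tmax_c))
  expect_true(all(wx$rad_mj_m2 >= 0))
  mo <- as.integer(format(wx$date, "%m"))
  winter <- mean(wx$tmean_c[mo %in% c(12, 1, 2, 3)])
  spring <- mean(wx$tmean_c[mo %in% 4:6])
  expect_lt(winter, spring)
  # gap-free daily coverage of the full season
  expect_equal(as.integer(diff(range(wx$date))) + 1L, nrow(wx))
})

test_that("marginal allele-combination flowering shifts are recovered", {
  # mean realised AC contrast over 20 seeds within 2 SE of the configured one
  eff <- c(I0I = 0, I0S = 1, I5I = 2, I5S = 5, SS = 7, SI = 9)
  contr <- sapply(1:20, function(s) {
    sim <- simulate_trial(sim_config(seed = 100 + s))
    pl <- derive_traits(sim$plots)
    ac <- sim$genotypes$allele_combination[match(pl$genotype,
                                                 sim$genotypes$genotype)]
    m <- tapply(pl$days_ef, ac, mean)
    m[c("I5I", "I5S", "SS", "SI")] - m[["I0I"]]
  })
  est <- rowMeans(contr)
  se <- apply(contr, 1, sd) / sqrt(ncol(contr))
  truth <- eff[c("I5I", "I5S", "SS", "SI")] - eff[["I0I"]]
  expect_true(all(abs(est - truth) <= 2 * se + 1e-9))
})

test_that("grain weight declines with flowering delay at the stated rate", {
  # pooled regression over 20 seeds recovers sign and magnitude within 20%
  slopes <- sapply(1:20, function(s) {
    sim <- simulate_trial(sim_config(seed = 200 + s))
    pl <- derive_traits(sim$plots)
    dev <- stats::ave(pl$days_ef, paste(pl$site, pl$year),
                      FUN = function(z) z - mean(z))
    stats::coef(stats::lm(pl$gw_mg ~ dev))[2]
  })
  pooled <- mean(slopes)
  expect_lt(pooled, 0)
  expect_lt(abs(pooled - (-0.5)) / 0.5, 0.2)
})

test_that("true joint-regression slopes are recovered by the estimator", {
  # pooled over 5 seeds: >= 90% of genotypes inside the slope's 95% CI
  cover <- integer(0)
  for (s in 1:5) {
    sim <- simulate_trial(sim_config(seed = s))
    pl <- derive_traits(sim$plots)
    tr <- sim$truth$genotype
    tr <- tr[tr$included, ]
    fw <- finlay_wilkinson(cell_means(pl, "genotype", "gy_g_m2",
                                      sim$genotypes))
    b <- fw$b[match(tr$genotype, fw$entity)]
    se <- fw$se[match(tr$genotype, fw$entity)]
    crit <- stats::qt(0.975, 13)  # q - 2 df, 15 environments
    cover <- c(cover, abs(b - tr$true_slope) <= crit * se)
  }
  expect_gte(mean(cover), 0.9)
})
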