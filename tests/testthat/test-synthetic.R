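test_that("the template connectome is dense at density 1 and seed-stable", {
  atlas <- default_atlas()
  full <- make_template_connectome(atlas, density = 1, seed = 81)
  off <- full$weights[upper.tri(full$weights)]
  expect_true(all(off > 0))
  t1 <- make_template_connectome(atlas, density = 0.3, seed = 82)
  t2 <- make_template_connectome(atlas, density = 0.3, seed = 82)
  expect_identical(t1$weights, t2$weights)
  expect_error(make_template_connectome(atlas, density = 0), "density")
})

test_that("within-lobe connections are stronger than between-lobe ones", {
  atlas <- default_atlas()
  same <- outer(atlas$group, atlas$group, "==")
  ut <- upper.tri(same)
  for (s in 1:20) {
    w <- make_template_connectome(atlas, density = 0.35, seed = 900 + s)$weights
    expect_gt(mean(w[ut][same[ut]]), mean(w[ut][!same[ut]]))
  }
})

test_that("template rescaling pins global efficiency to the requested value", {
  atlas <- default_atlas()
  tpl <- make_template_connectome(atlas, 0.35, seed = 83,
                                  target_eglob = 0.026)
  expect_equal(global_efficiency(tpl), 0.026, tolerance = 1e-10)
})

test_that("simulated cohorts have the configured size and demographics", {
  sim <- fixture_sim()
  subj <- sim$cohort$subjects
  expect_equal(nrow(subj), 90)
  expect_equal(length(sim$cohort$connectomes), 90)
  expect_true(all(subj$age >= 60 & subj$age <= 85))
  expect_true(all(subj$sex %in% 0:1))
  big <- simulate_cohort(simulation_params(n_subjects = 4000, seed = 84,
                                           edge_noise_sd = 0),
                         store = "none")
  s <- big$cohort$subjects
  # target mean of the *truncated* normal (closed form), not the
  # pre-truncation location parameter
  a <- (60 - 68.06) / 4.74; b <- (85 - 68.06) / 4.74
  trunc_mean <- 68.06 + 4.74 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(s$age) - trunc_mean), 0.25)
  expect_lt(abs(mean(s$education) - 18.06), 0.2)
  expect_lt(abs(mean(s$sex) - 32 / 84), 0.03)
})

test_that("generation is deterministic under a fixed seed", {
  p <- simulation_params(n_subjects = 6, seed = 85)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort$subjects, s2$cohort$subjects)
  expect_identical(s1$cohort$connectomes[[3]]$weights,
                   s2$cohort$connectomes[[3]]$weights)
  expect_identical(s1$truth$mediator, s2$truth$mediator)
})

test_that("a pure direct-path configuration plants the total effect", {
  p <- simulation_params(n_subjects = 5000, effect_age_on_weights = 0,
                         path_c_prime = -0.5, path_b = 0,
                         sex_effect = 0, edu_effect = 0,
                         noise_sd_ef = sqrt(1 - 0.25),
                         edge_noise_sd = 0, seed = 86)
  sim <- simulate_cohort(p, store = "none")
  expect_lt(abs(cor(sim$cohort$subjects$age, sim$truth$common_factor) + 0.5),
            0.03)
})

test_that("a negative age slope drives computed efficiency down with age", {
  sim <- fixture_sim()            # edge noise on, metrics from real matrices
  prof <- fixture_profiles()
  age <- sim$cohort$subjects$age
  expect_lt(cor(age, prof$e_glob), 0)
  expect_lt(cor(age, prof$e_loc), 0)
  # generator's mediator equals the graph code's e_loc on the same matrices
  expect_equal(sim$truth$mediator, prof$e_loc, tolerance = 1e-10)
})

test_that("the planted standardized age path is realized in the mediator", {
  big <- simulate_cohort(simulation_params(n_subjects = 4000, seed = 87,
                                           edge_noise_sd = 0),
                         store = "none")
  r <- cor(big$cohort$subjects$age, log(big$truth$mediator))
  expect_lt(abs(r - (-0.44)), 0.05)
})

test_that("recovery_report is calibrated under the null and unbiased under effects", {
  null_params <- simulation_params(path_a = -0.44, path_b = 0,
                                   path_c_prime = -0.5)
  rep_null <- recovery_report(null_params, n_replicates = 120, seed = 88,
                              n_boot = 400)
  expect_lt(rep_null$rejection_rate, 0.15)
  eff_params <- simulation_params(path_a = -0.44, path_b = 0.18,
                                  path_c_prime = -0.45)
  rep_eff <- recovery_report(eff_params, n_replicates = 120, seed = 89,
                             n_boot = 400)
  # mean ab within MC error of the planted product
  mc_se <- rep_eff$rmse_ab / sqrt(rep_eff$n_replicates)
  expect_lt(abs(rep_eff$mean_ab - rep_eff$true_ab), 4 * mc_se + 0.01)
  expect_gt(rep_eff$rejection_rate, rep_null$rejection_rate)
})

test_that("estimation uncertainty shrinks with sample size", {
  small_p <- simulation_params(n_subjects = 84)
  big_p <- simulation_params(n_subjects = 2000)
  rep_small <- recovery_report(small_p, n_replicates = 40, seed = 90,
                               n_boot = 300)
  rep_big <- recovery_report(big_p, n_replicates = 40, seed = 91,
                             n_boot = 300)
  expect_lt(rep_big$rmse_ab, rep_small$rmse_ab)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(template_density = 1.5), "density")
  expect_error(simulation_params(sex_p_female = -0.1), "sex_p_female")
  expect_error(simulation_params(noise_sd_ef = 0), "positive")
  expect_error(simulate_cohort(simulation_params(), store = "none"),
               "edge_noise_sd")
})
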