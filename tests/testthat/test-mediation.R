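test_that("the OLS decomposition c = c' + ab holds on random fixtures", {
  for (s in 1:30) {
    set.seed(600 + s)
    n <- sample(20:60, 1)
    covs <- if (s %% 2) data.frame(sex = rbinom(n, 1, 0.5),
                                   edu = rnorm(n, 18, 3)) else NULL
    iv <- rnorm(n); m <- 0.3 * iv + rnorm(n)
    dv <- 0.2 * m - 0.3 * iv + rnorm(n)
    f <- fit_mediation(iv, m, dv, covs)
    expect_lt(abs(f$beta_c - f$beta_c_prime - f$beta_ab), 1e-10)
  }
})

test_that("a null b-path yields a near-zero indirect effect at large n", {
  set.seed(61)
  n <- 10000
  iv <- rnorm(n)
  m <- -0.4 * iv + rnorm(n)
  dv <- -0.5 * iv + rnorm(n)     # independent of m given iv
  f <- fit_mediation(iv, m, dv)
  expect_lt(abs(f$beta_ab), 0.02)
})

test_that("degenerate mediation inputs raise errors", {
  set.seed(62)
  n <- 30
  iv <- rnorm(n)
  expect_error(fit_mediation(iv, rep(1, n), rnorm(n)), "zero variance")
  expect_error(fit_mediation(iv, rnorm(n), rnorm(n),
                             data.frame(a = iv, b = 2 * iv)),
               "rank-deficient")
})

test_that("a symmetric bootstrap distribution gives plain percentile bounds", {
  boot <- c(seq(-1, 1, length.out = 1001))  # symmetric about 0
  bc <- efmediate:::bc_interval(boot, 0, 0.95)
  plain <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  expect_equal(bc, plain, tolerance = 1e-12)
})

test_that("bootstrap CIs are seed-reproducible and seed-stable", {
  d <- simulate_mediation_data(84, -0.44, 0.18, -0.45, seed = 63)
  r1 <- bootstrap_ci(d$iv, d$m, d$dv, n_boot = 5000, seed = 64)
  r2 <- bootstrap_ci(d$iv, d$m, d$dv, n_boot = 5000, seed = 64)
  expect_identical(c(r1$ci_lower, r1$ci_upper), c(r2$ci_lower, r2$ci_upper))
  r3 <- bootstrap_ci(d$iv, d$m, d$dv, n_boot = 5000, seed = 65)
  expect_lt(abs(r1$ci_lower - r3$ci_lower), 0.01)
  expect_lt(abs(r1$ci_upper - r3$ci_upper), 0.01)
  expect_equal(r1$beta_c, r1$beta_c_prime + r1$beta_ab, tolerance = 1e-10)
})

test_that("sampled BC bounds agree with the exhaustive n = 7 enumeration", {
  # variables pre-standardized so the enumeration shares the
  # implementation's coefficient scale
  set.seed(37)
  iv <- as.numeric(scale(rnorm(7)))
  m <- as.numeric(scale(-0.6 * iv + 0.5 * rnorm(7)))
  dv <- as.numeric(scale(0.6 * m + 0.5 * rnorm(7)))
  enum <- enumerate_boot_ab(iv, m, dv)
  est <- fit_mediation(iv, m, dv)$beta_ab
  oracle <- bc_bounds_oracle(enum$ab, enum$prob, est)
  got <- bootstrap_ci(iv, m, dv, n_boot = 100000, seed = 67)
  # the exact distribution is discrete (1716 weighted atoms), so sampled
  # and exact bounds can only agree to within the local atom spacing;
  # the sharp comparison is on the probability scale: the exact CDF at
  # the two bounds must coincide to bootstrap Monte-Carlo accuracy
  expect_lt(abs(weighted_cdf(enum$ab, enum$prob, got$ci_lower) -
                  weighted_cdf(enum$ab, enum$prob, oracle[1])), 0.01)
  expect_lt(abs(weighted_cdf(enum$ab, enum$prob, got$ci_upper) -
                  weighted_cdf(enum$ab, enum$prob, oracle[2])), 0.01)
  # and on the value scale the bounds agree to within a few atom gaps
  expect_lt(abs(got$ci_lower - oracle[1]), 0.1)
  expect_lt(abs(got$ci_upper - oracle[2]), 0.1)
})

test_that("BC intervals cover a planted indirect effect at the nominal rate", {
  covered <- logical(150)
  truth <- (-0.44) * 0.35
  for (r in seq_len(150)) {
    d <- simulate_mediation_data(84, -0.44, 0.35, -0.3, seed = 7000 + r)
    res <- bootstrap_ci(d$iv, d$m, d$dv, n_boot = 600, seed = 7000 + r)
    covered[r] <- res$ci_lower <= truth && truth <= res$ci_upper
  }
  # 95% nominal; 150 replicates have MC sd ~1.8 points
  expect_gte(mean(covered), 0.89)
})

test_that("regional mediation runs on the screen intersection and flags a planted node", {
  atlas <- default_atlas()
  n <- 250
  set.seed(68)
  age <- runif(n, 60, 85)
  zage <- scale(age)[, 1]
  metric <- as.data.frame(matrix(rnorm(n * 84), n, 84,
                                 dimnames = list(NULL, node_names(atlas))),
                          check.names = FALSE)
  target_col <- node_names(atlas)[10]
  metric[[target_col]] <- -0.6 * zage + 0.7 * rnorm(n)
  ef <- 0.5 * scale(metric[[target_col]])[, 1] - 0.25 * zage + 0.8 * rnorm(n)
  age_scr <- node_screen(metric, age, NULL, atlas)
  ef_scr <- node_screen(metric, ef, NULL, atlas)
  tab <- regional_mediation(metric, age, ef, age_scr, ef_scr, atlas,
                            n_boot = 500, seed = 69)
  expect_s3_class(tab, "regional_mediation_table")
  expect_equal(nrow(tab), nrow(screen_intersection(age_scr, ef_scr)))
  planted <- tab[tab$region == atlas$label[10] &
                   tab$hemisphere == atlas$hemisphere[10], ]
  expect_equal(nrow(planted), 1)
  expect_true(planted$significant)
  expect_lt(planted$ci_upper, 0)
})

test_that("disjoint screens give an empty mediation table, not an error", {
  atlas <- default_atlas()
  a <- list(rows = data.frame(hemisphere = "left", region = "Precuneus"))
  class(a) <- "screen_report"
  b <- list(rows = data.frame(hemisphere = "right", region = "Cuneus"))
  class(b) <- "screen_report"
  metric <- as.data.frame(matrix(rnorm(50 * 84), 50, 84,
                                 dimnames = list(NULL, node_names(atlas))),
                          check.names = FALSE)
  tab <- regional_mediation(metric, rnorm(50), rnorm(50), a, b, atlas,
                            n_boot = 200, seed = 70)
  expect_equal(nrow(tab), 0)
})
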