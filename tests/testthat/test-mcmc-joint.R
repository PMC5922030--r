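# The Metropolis-within-Gibbs engine and the joint-model surface:
# determinism, conjugate updates, DIC wiring, hazard-ratio reporting.

test_that("identical seeds give identical draw streams", {
  co <- small_cohort(n = 60, seed = 3)
  s <- mcmc_settings(chains = 2, iter = 300, burn = 150, thin = 1,
                     seed = 17)
  f1 <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                   co$covariates, settings = s))
  f2 <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                   co$covariates, settings = s))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$mcmc$devs, f2$mcmc$devs)
})

test_that("the conjugate variance update matches the closed-form
           inverse-gamma posterior", {
  set.seed(5)
  n <- 400
  z <- rnorm(n, 0, sqrt(0.3))
  ss <- sum(z^2)
  a0 <- 0.01; b0 <- 0.01
  draws <- replicate(20000, jmcd4:::sample_ig_var(n, ss, a0, b0))
  a_post <- a0 + n / 2
  b_post <- b0 + ss / 2
  expect_lt(abs(mean(draws) - b_post / (a_post - 1)), 0.002)
  expect_lt(abs(var(draws) - b_post^2 / ((a_post - 1)^2 * (a_post - 2))),
            2e-4)
})

test_that("the inverse-Wishart sampler has the right mean", {
  set.seed(6)
  S <- matrix(c(2, 0.4, 0.4, 1), 2, 2)
  df <- 12
  M <- Reduce(`+`, replicate(4000, jmcd4:::rinvwishart(df, S),
                             simplify = FALSE)) / 4000
  expect_lt(max(abs(M - S / (df - 2 - 1))), 0.02)
})

test_that("a point-mass posterior has zero effective parameters", {
  co <- small_cohort(n = 50, seed = 9)
  fit <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                    co$covariates,
                                    settings = quick_mcmc(seed = 10,
                                                          iter = 500,
                                                          burn = 250)))
  dic <- suppressWarnings(compute_dic(fit))
  # freeze the chain at its posterior means: Dbar collapses onto D_hat
  frozen <- fit
  frozen$draws <- matrix(rep(colMeans(fit$draws), each = 5), nrow = 5,
                         dimnames = list(NULL, colnames(fit$draws)))
  frozen$summaries <- jmcd4:::summarize_draws(frozen$draws)
  frozen$mcmc$devs <- rep(dic$D_hat, 5)
  dic0 <- suppressWarnings(compute_dic(frozen))
  expect_equal(dic0$p_D, 0)
  expect_equal(dic0$DIC, dic0$D_hat)
})

test_that("a negative p_D is reported with a warning, not hidden", {
  co <- small_cohort(n = 50, seed = 9)
  fit <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                    co$covariates,
                                    settings = quick_mcmc(seed = 10,
                                                          iter = 750,
                                                          burn = 300)))
  broken <- fit
  broken$mcmc$devs <- rep(fit$dic$D_hat - 50, 5)
  expect_warning(dic <- compute_dic(broken), "p_D")
  expect_lt(dic$p_D, 0)
})

test_that("hazard ratios are the draw-wise exponential with equivariant
           quantiles", {
  draws <- matrix(0, nrow = 200, ncol = 1,
                  dimnames = list(NULL, "x"))
  hr0 <- hazard_ratio_table(draws)
  expect_equal(hr0$hr, 1)
  expect_equal(c(hr0$hr_lower, hr0$hr_upper), c(1, 1))

  set.seed(11)
  draws2 <- matrix(rnorm(500, 0.021, 1e-8), ncol = 1,
                   dimnames = list(NULL, "time"))
  hr2 <- hazard_ratio_table(draws2)
  expect_equal(hr2$hr, exp(0.021), tolerance = 1e-6)
  expect_equal(round(hr2$pct_change, 1), 2.1)

  draws3 <- matrix(rnorm(2000, 0.3, 0.4), ncol = 1,
                   dimnames = list(NULL, "z"))
  hr3 <- hazard_ratio_table(draws3)
  # exp is monotone, so HR interval endpoints = exp of coefficient ones
  expect_equal(hr3$hr_lower,
               exp(quantile(draws3[, 1], 0.025, type = 1)[[1]]))
  expect_equal(hr3$hr_upper,
               exp(quantile(draws3[, 1], 0.975, type = 1)[[1]]))
})

test_that("joint posterior means recover the generating fixed effects at
           modest size", {
  co <- small_cohort(n = 150, seed = 21)
  fit <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                    co$covariates,
                                    settings = quick_mcmc(seed = 22,
                                                          iter = 1600,
                                                          burn = 800)))
  sm <- fit$summaries
  ic <- sm[sm$parameter == "long_(Intercept)", ]
  expect_lt(abs(ic$mean - 4.13), 4 * ic$sd)
  age <- sm[sm$parameter == "long_age", ]
  expect_lt(abs(age$mean - (-0.036)), 4 * age$sd)
  v0 <- sm[sm$parameter == "var_nu0", ]
  expect_gt(v0$mean, 0.3); expect_lt(v0$mean, 2)
  expect_gt(mean(fit$draws[, "rho"]), 0.5)
  expect_lt(mean(fit$draws[, "rho"]), 1.4)
})

test_that("separability: with the link off, joint and separate fits
           agree", {
  par <- default_true_params()
  par$tau <- c(0, 0); par$tau_b <- 0; par$sigma_nu2 <- 0
  co <- simulate_cohort(n = 150, params = par, seed = 31, miss_prob = 0)
  terms_l <- c("(Intercept)", "age", "time")
  terms_s <- "age"
  joint <- suppressWarnings(fit_joint(
    co$longitudinal, co$survival, co$covariates,
    joint_spec("intercept_slope_frailty", TRUE, terms_l, terms_s),
    quick_mcmc(seed = 32, iter = 2000, burn = 1000)))
  sep_l <- suppressWarnings(fit_longitudinal(
    co$longitudinal, co$covariates,
    longitudinal_spec("poisson_lognormal_heterogeneous",
                      fixed_effects = terms_l,
                      random_effects = c("intercept", "slope")),
    quick_mcmc(seed = 33, iter = 2000, burn = 1000)))
  sep_s <- fit_parametric_survival(co$survival, co$covariates,
                                   terms = terms_s)
  js <- joint$summaries
  for (p in c("long_(Intercept)", "long_age", "long_time")) {
    jrow <- js[js$parameter == p, ]
    srow <- sep_l$summaries[sep_l$summaries$parameter == p, ]
    expect_lt(abs(jrow$mean - srow$mean),
              3 * sqrt(jrow$sd^2 + srow$sd^2))
  }
  jage <- js[js$parameter == "surv_age", ]
  expect_lt(abs(jage$mean - coef(sep_s)[["age"]]),
            3 * sqrt(jage$sd^2 + sep_s$coef$se[1]^2))
})

test_that("the ladder report has one row per requested rung and marks the
           smallest DIC", {
  co <- small_cohort(n = 80, seed = 41)
  lad <- suppressWarnings(run_ladder(
    co$longitudinal, co$survival, co$covariates,
    levels = "fixed_only",
    long_terms = c("(Intercept)", "time"), surv_terms = character(0),
    settings = quick_mcmc(seed = 42, iter = 500, burn = 250)))
  expect_equal(nrow(lad$table), 1L)
  expect_true(lad$table$selected[1])
  expect_equal(lad$table$status[1], "ok")
})

test_that("posterior-predictive replication reproduces the fitted
           cohort's scale", {
  co <- small_cohort(n = 100, seed = 51)
  fit <- suppressWarnings(fit_joint(co$longitudinal, co$survival,
                                    co$covariates,
                                    settings = quick_mcmc(seed = 52,
                                                          iter = 1200,
                                                          burn = 600)))
  reps <- simulate(fit, nsim = 2, seed = 53)
  expect_length(reps, 2)
  obs <- co$longitudinal[co$longitudinal$observed == 1, ]
  # replicated mean count within a factor of ~2 of the observed mean
  expect_lt(abs(log(mean(reps[[1]]$longitudinal$y) /
                      mean(obs$cd4_change))), log(2))
  expect_true(all(reps[[1]]$survival$time > 0))
  expect_identical(simulate(fit, nsim = 1, seed = 7),
                   simulate(fit, nsim = 1, seed = 7))
})

test_that("sampler settings are validated", {
  expect_error(mcmc_settings(iter = 100, burn = 100), "burn")
  expect_error(mcmc_settings(thin = 0), "invalid")
})
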