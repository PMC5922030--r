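# The synthetic cohort generator: covariate marginals, latent effects,
# longitudinal counts, default times, MCAR dropout.

test_that("covariate marginals are honoured and draws are reproducible", {
  cov <- generate_covariates(792, seed = 7)
  p_f <- mean(cov$sex == "female")
  # binomial 99% bounds around the requested female fraction
  half <- qnorm(0.995) * sqrt(0.506 * 0.494 / 792)
  expect_gt(p_f, 0.506 - half)
  expect_lt(p_f, 0.506 + half)
  expect_true(all(cov$age >= 18))
  expect_true(all(cov$baseline_cd4 > 0))
  expect_true(all(cov$weight > 0))

  big <- generate_covariates(100000, seed = 1)
  expect_lt(abs(mean(big$residence == "rural") - 0.409), 0.005)

  expect_identical(generate_covariates(50, seed = 9),
                   generate_covariates(50, seed = 9))

  one <- generate_covariates(1, marginals = list(sex = c(female = 1)),
                             seed = 1)
  expect_equal(as.character(one$sex), "female")
})

test_that("covariate marginal validation rejects bad inputs", {
  expect_error(generate_covariates(10, marginals = list(eye_colour =
    c(blue = 1))), "unknown variable")
  expect_error(generate_covariates(10, marginals = list(sex =
    c(male = 0.6, female = 0.6))), "sum to 1")
  expect_error(generate_covariates(0), "integer >= 1")
})

test_that("latent effects match the requested second moments", {
  par <- default_true_params()
  par$Sigma_nu <- matrix(c(0.88, -0.054, -0.054, 0.021), 2, 2)
  lat <- generate_latent_effects(50000, par, seed = 2)
  target <- -0.054 / sqrt(0.88 * 0.021)
  expect_lt(abs(cor(lat$nu0, lat$nu1) - target), 0.02)
  expect_lt(abs(var(lat$nu0) - 0.88), 0.02)
  expect_lt(abs(var(lat$log_b) - par$sigma_b2), 0.01)

  par0 <- null_params()
  lat0 <- generate_latent_effects(100, par0, seed = 3)
  expect_true(all(lat0$log_b == 0))
  expect_true(all(lat0$frailty == 0))

  expect_identical(generate_latent_effects(200, par, seed = 5),
                   generate_latent_effects(200, par, seed = 5))

  expect_error(true_params(beta1 = c(a = 1),
                           Sigma_nu = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
})

test_that("longitudinal counts reduce to Poisson when all variances vanish", {
  par <- null_params()
  cov <- generate_covariates(300, seed = 1)
  lat <- generate_latent_effects(300, par, seed = 2)
  long <- generate_longitudinal(cov, lat, par, seed = 3)
  expect_lt(abs(mean(long$cd4_change) - 16), 0.3)
  expect_lt(abs(var(long$cd4_change) / mean(long$cd4_change) - 1), 0.05)

  par1 <- null_params(beta1 = c("(Intercept)" = 0))
  long1 <- generate_longitudinal(cov, lat, par1, seed = 4)
  expect_lt(abs(mean(long1$cd4_change) - 1), 0.05)
  expect_lt(abs(var(long1$cd4_change) - 1), 0.06)
})

test_that("visit-level log-normal dispersion produces overdispersion at
           every visit", {
  par <- default_true_params()
  par$sigma_b2 <- 0.5
  cov <- generate_covariates(5000, seed = 11)
  lat <- generate_latent_effects(5000, par, seed = 12)
  long <- generate_longitudinal(cov, lat, par, seed = 13)
  prof <- mean_variance_profile(long)
  expect_true(all(prof$overdispersed))
  expect_true(all(prof$sd^2 > prof$mean))
})

test_that("longitudinal generator validates its schedule and is
           deterministic", {
  par <- default_true_params()
  cov <- generate_covariates(20, seed = 1)
  lat <- generate_latent_effects(20, par, seed = 2)
  expect_error(generate_longitudinal(cov, lat, par, schedule = c(3, 2, 1)),
               "strictly increasing")
  expect_identical(generate_longitudinal(cov, lat, par, seed = 9),
                   generate_longitudinal(cov, lat, par, seed = 9))
  # counts accumulate from baseline so successive differences recover the
  # generated changes
  long <- generate_longitudinal(cov, lat, par, seed = 9)
  ch <- compute_cd4_change(long)
  merged <- merge(ch, long, by = c("patient_id", "visit_index"))
  expect_equal(merged$cd4_change.x, merged$cd4_change.y)
})

test_that("default times follow the Weibull closed form", {
  par <- null_params()
  cov <- generate_covariates(20000, seed = 21)
  lat <- generate_latent_effects(20000, par, seed = 22)
  srv <- generate_survival(cov, lat, par, max_followups = 1000, seed = 23)
  # unit-rate exponential special case
  expect_lt(abs(mean(srv$time) - 1), 0.03)
  for (tq in c(0.5, 1, 2))
    expect_lt(abs(mean(srv$time > tq) - exp(-tq)), 0.015)

  par2 <- null_params()
  par2$rho <- 0.763
  srv2 <- generate_survival(cov, lat, par2, max_followups = 1e6, seed = 24)
  # empirical hazard (event counts over time at risk) decreasing in t
  br <- quantile(srv2$time, c(0, 0.25, 0.5, 0.75, 0.9))
  haz <- numeric(4)
  for (k in 1:4) {
    at_risk <- srv2$time > br[k]
    ev <- srv2$time <= br[k + 1] & at_risk
    exposure <- sum(pmin(srv2$time[at_risk], br[k + 1]) - br[k])
    haz[k] <- sum(ev) / exposure
  }
  expect_true(all(diff(haz) < 0))
})

test_that("survival generation respects proportional hazards", {
  n <- 20000
  par <- null_params()
  par$beta2 <- c(sex_female = 0.7)
  par$rho <- 0.9
  cov <- generate_covariates(n, seed = 31)
  lat <- generate_latent_effects(n, par, seed = 32)
  srv <- generate_survival(cov, lat, par, max_followups = 1e6, seed = 33)
  cx <- fit_cox(srv, cov, "sex_female")
  expect_lt(abs(coef(cx)[["sex_female"]] - 0.7), 0.05)
})

test_that("administrative censoring and truncation bookkeeping hold", {
  co <- small_cohort(n = 200, seed = 77, miss_prob = 0)
  expect_true(all(co$survival$time > 0))
  expect_true(all(co$survival$time[co$survival$event == 0] ==
                    length(co$schedule)))
  counts <- table(factor(co$longitudinal$patient_id, levels = 1:200))
  expected <- vapply(1:200, function(i)
    sum(seq_along(co$schedule) <= co$survival$time[i]), numeric(1))
  expect_equal(as.numeric(counts), expected)
  expect_error(generate_survival(co$covariates, co$latent, co$params,
                                 max_followups = 0), "integer >= 1")
})

test_that("MCAR dropout is uniform, seed-stable and spares the baseline
           visit", {
  par <- default_true_params()
  cov <- generate_covariates(5000, seed = 41)
  lat <- generate_latent_effects(5000, par, seed = 42)
  long <- generate_longitudinal(cov, lat, par, seed = 43)
  expect_identical(apply_mcar(long, 0, seed = 1), long)
  m <- apply_mcar(long, 0.1, seed = 44)
  eligible <- m$visit_index >= 2
  expect_lt(abs(mean(m$observed[eligible] == 0) - 0.1), 0.005)
  expect_true(all(m$observed[m$visit_index == 1] == 1))
  expect_error(apply_mcar(long, 1), "probability")
  expect_error(apply_mcar(long, -0.1), "probability")
})

test_that("cohort CSV round trip preserves the three tables", {
  co <- small_cohort(n = 30, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  expect_equal(back$covariates$age, co$covariates$age)
  expect_equal(back$longitudinal$cd4_change, co$longitudinal$cd4_change)
  expect_equal(back$survival$time, co$survival$time)
  expect_equal(as.character(back$covariates$adherence),
               as.character(co$covariates$adherence))
})
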