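# Separate time-to-default submodels: Weibull/exponential ML and Cox.

sim_weibull <- function(n, rho, phi, lp = 0, cmax = Inf, seed = 1) {
  set.seed(seed)
  u <- runif(n)
  t_raw <- (-log(u) / (phi * exp(lp)))^(1 / rho)
  data.frame(patient_id = seq_len(n), time = pmin(t_raw, cmax),
             event = as.integer(t_raw <= cmax))
}

test_that("the exponential fit matches its closed-form likelihood", {
  srv <- sim_weibull(300, rho = 1, phi = 0.5, cmax = 3, seed = 2)
  fit <- fit_parametric_survival(srv, baseline = "exponential")
  lam_hat <- sum(srv$event) / sum(srv$time)
  expect_lt(abs(fit$scale - lam_hat), 1e-6)
  closed <- sum(srv$event) * log(lam_hat) - lam_hat * sum(srv$time)
  expect_lt(abs(fit$loglik - closed), 1e-8)
  # exponential == Weibull with shape held at 1
  expect_lt(abs(fit$loglik -
                  weibull_loglik(srv$time, srv$event, 0, 1, fit$scale)),
            1e-6)
})

test_that("the Weibull shape is recovered and drives the monotone-hazard
           verdict", {
  srv <- sim_weibull(2000, rho = 1, phi = 1, cmax = 4, seed = 3)
  fit <- fit_parametric_survival(srv, baseline = "weibull")
  expect_gt(fit$shape[["estimate"]], 0.9)
  expect_lt(fit$shape[["estimate"]], 1.1)

  srv2 <- sim_weibull(2000, rho = 0.7, phi = 1, cmax = 6, seed = 4)
  fit2 <- fit_parametric_survival(srv2, baseline = "weibull")
  expect_equal(fit2$verdict, "decreasing")
  expect_true(fit2$hazard(2) < fit2$hazard(1))  # decreasing iff rho < 1
  srv3 <- sim_weibull(2000, rho = 1.5, phi = 0.5, cmax = 3, seed = 5)
  fit3 <- fit_parametric_survival(srv3, baseline = "weibull")
  expect_equal(fit3$verdict, "increasing")
  expect_true(fit3$hazard(2) > fit3$hazard(1))
})

test_that("the Weibull ML fit agrees with an independent AFT fit", {
  skip_if_not_installed("flexsurv")
  cov <- generate_covariates(500, seed = 6)
  lp <- 0.5 * (cov$sex == "female")
  srv <- sim_weibull(500, rho = 1.3, phi = 0.4, lp = lp, cmax = 3,
                     seed = 7)
  fit <- fit_parametric_survival(srv, cov, terms = "sex_female")
  ref <- flexsurv::flexsurvreg(
    survival::Surv(srv$time, srv$event) ~ I(cov$sex == "female"),
    dist = "weibullPH")
  expect_lt(abs(fit$loglik - ref$loglik), 1e-4)
  expect_lt(abs(fit$shape[["estimate"]] - ref$res["shape", "est"]), 1e-3)
  expect_lt(abs(fit$coef$estimate - ref$res[3, "est"]), 1e-3)
})

test_that("all-censored or non-positive inputs are rejected", {
  srv <- data.frame(patient_id = 1:5, time = 1:5, event = 0)
  expect_error(fit_parametric_survival(srv), "censored")
  srv2 <- data.frame(patient_id = 1:5, time = c(-1, 1:4), event = 1)
  expect_error(fit_parametric_survival(srv2), "positive")
})

test_that("the Cox fit matches a brute-force partial likelihood on
           hand-sized data", {
  srv <- data.frame(patient_id = 1:5,
                    time = c(1.1, 2.3, 3.2, 4.5, 6.1),
                    event = c(1, 1, 0, 1, 1))
  cov <- generate_covariates(5, seed = 8)
  cov$sex <- factor(c("male", "female", "male", "female", "male"),
                    levels = c("male", "female"))
  x <- as.numeric(cov$sex == "female")
  # Breslow partial log-likelihood, enumerated directly
  plik <- function(b) {
    ll <- 0
    for (i in which(srv$event == 1)) {
      rs <- srv$time >= srv$time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[rs])))
    }
    ll
  }
  grid <- optimize(plik, c(-5, 5), maximum = TRUE)
  fit <- fit_cox(srv, cov, "sex_female")
  expect_lt(abs(coef(fit)[["sex_female"]] - grid$maximum), 1e-4)
  expect_equal(fit$coef$hr, exp(fit$coef$estimate))
})

test_that("a constant covariate carries no information", {
  srv <- sim_weibull(60, rho = 1, phi = 0.5, cmax = 3, seed = 9)
  cov <- generate_covariates(60, seed = 9)
  cov$sex <- factor(rep("female", 60), levels = c("male", "female"))
  fit <- fit_cox(srv, cov, "sex_female")
  expect_equal(coef(fit)[["sex_female"]], 0)
})

test_that("model comparison prefers the Weibull on Weibull data and
           never fabricates criteria", {
  wins <- 0L
  for (r in 1:3) {
    cov <- generate_covariates(400, seed = 20 + r)
    lp <- 0.6 * (cov$residence == "rural")
    srv <- sim_weibull(400, rho = 0.8, phi = 0.3, lp = lp, cmax = 8,
                       seed = 30 + r)
    wf <- fit_parametric_survival(srv, cov, terms = "rural")
    cf <- fit_cox(srv, cov, "rural")
    cmp <- compare_survival_models(weibull = wf, cox = cf)
    wins <- wins + (cmp$winner[["aic"]] == "weibull")
    expect_true(is.na(cmp$criteria$pearson_ratio[cmp$criteria$model ==
                                                   "cox"]))
  }
  expect_gte(wins, 2L)
})

test_that("survival predictions follow the fitted survivor function", {
  srv <- sim_weibull(500, rho = 1.2, phi = 0.5, cmax = 4, seed = 40)
  fit <- fit_parametric_survival(srv, baseline = "weibull")
  S <- predict(fit, times = c(0.5, 1, 2))
  expect_equal(dim(S), c(1L, 3L))
  expect_true(all(diff(S[1, ]) < 0))
  expect_equal(S[1, 2],
               exp(-fit$scale * 1^fit$shape[["estimate"]]))
})
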