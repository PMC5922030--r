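# The model likelihoods: Poisson-log-normal records, censored Weibull,
# and their shared-parameter combination.

test_that("the Poisson-log-normal record density matches direct numeric
           integration", {
  for (cse in list(list(y = 3, m = 1.2, b = 0.4),
                   list(y = 0, m = -0.5, b = 1.1),
                   list(y = 25, m = 3.0, b = 0.2))) {
    direct <- integrate(function(e)
      dpois(cse$y, exp(cse$m + e)) * dnorm(e, 0, sqrt(cse$b)),
      -Inf, Inf, rel.tol = 1e-12)$value
    got <- jmcd4:::pln_record_loglik(cse$y, cse$m, cse$b, gh = 40)
    expect_equal(got, log(direct), tolerance = 1e-5)
  }
  # degenerate variance collapses to the Poisson mass
  expect_equal(jmcd4:::pln_record_loglik(4, 1, 0),
               dpois(4, exp(1), log = TRUE))
})

test_that("censored Weibull log-likelihood matches its closed form", {
  set.seed(1)
  tt <- rexp(40); ev <- rbinom(40, 1, 0.7)
  rho <- 1.4; phi <- 0.6; lp <- runif(40, -1, 1)
  manual <- sum(ev * log(phi * rho * tt^(rho - 1) * exp(lp)) -
                  phi * tt^rho * exp(lp))
  expect_equal(weibull_loglik(tt, ev, lp, rho, phi), manual,
               tolerance = 1e-12)
  expect_error(weibull_loglik(c(-1, 1), c(1, 1), 0, 1, 1), "positive")
  expect_error(weibull_loglik(tt, ev, lp, -1, 1), "> 0")
})

joint_toy <- function(n = 12, seed = 2) {
  set.seed(seed)
  id <- rep(seq_len(n), each = 3)
  X1 <- cbind("(Intercept)" = 1, x = rnorm(3 * n))
  tvec <- rep(c(-1, 0, 1), n)
  y <- rpois(3 * n, 5)
  X2 <- cbind(z = rbinom(n, 1, 0.5))
  list(long = list(y = y, X = X1, id = id, tvec = tvec),
       surv = list(time = rexp(n) + 0.1, event = rbinom(n, 1, 0.8),
                   X = X2))
}

test_that("joint likelihood separates into the submodel likelihoods when
           all loadings vanish", {
  data <- joint_toy()
  n <- 12
  set.seed(3)
  latents <- list(nu0 = rnorm(n, 0, 0.5), nu1 = rnorm(n, 0, 0.1),
                  log_b = rnorm(n, 0, 0.3), frailty = rep(0, n))
  params <- list(beta1 = c(1.4, 0.2), beta2 = c(z = 0.5),
                 tau = c(0, 0), tau_b = 0, rho = 1.2, phi = 0.7,
                 Sigma_nu = matrix(c(0.25, 0, 0, 0.01), 2, 2),
                 sigma_b2 = 0.09, sigma_nu2 = 0)
  jl <- joint_log_likelihood(params, latents, data)
  parts <- attr(jl, "parts")
  ll_long <- pln_loglik(data$long$y, data$long$X, params$beta1,
                        data$long$id, data$long$tvec,
                        nu0 = latents$nu0, nu1 = latents$nu1,
                        b = exp(latents$log_b))
  ll_surv <- weibull_loglik(data$surv$time, data$surv$event,
                            as.vector(data$surv$X %*% params$beta2),
                            rho = params$rho, phi = params$phi)
  expect_lt(abs(parts[["longitudinal"]] - ll_long), 1e-10)
  expect_lt(abs(parts[["survival"]] - ll_surv), 1e-10)
  expect_lt(abs(as.numeric(jl) - (ll_long + ll_surv +
                                    parts[["latent_prior"]])), 1e-10)
})

test_that("single-patient single-visit joint likelihood matches a hand
           expansion", {
  data <- list(long = list(y = 4, X = matrix(1, 1, 1), id = 1, tvec = 0),
               surv = list(time = 2.5, event = 1, X = NULL))
  latents <- list(nu0 = 0.3, nu1 = -0.1, log_b = log(0.5), frailty = 0.2)
  params <- list(beta1 = 1.1, beta2 = numeric(0),
                 tau = c(0.4, -1), tau_b = 0.2, rho = 0.8, phi = 0.3,
                 Sigma_nu = matrix(c(0.5, -0.02, -0.02, 0.02), 2, 2),
                 sigma_b2 = 0.25, sigma_nu2 = 0.1)
  jl <- as.numeric(joint_log_likelihood(params, latents, data, gh = 40))
  # every term written out by hand
  m <- 1.1 + 0.3
  ll_long <- log(integrate(function(e)
    dpois(4, exp(m + e)) * dnorm(e, 0, sqrt(0.5)), -Inf, Inf,
    rel.tol = 1e-12)$value)
  W2 <- 0.4 * 0.3 + (-1) * (-0.1) + 0.2 * log(0.5) + 0.2
  ll_surv <- log(0.3 * 0.8 * 2.5^(0.8 - 1) * exp(W2)) -
    0.3 * 2.5^0.8 * exp(W2)
  P <- solve(params$Sigma_nu)
  ll_lat <- -0.5 * (P[1, 1] * 0.3^2 + 2 * P[1, 2] * 0.3 * (-0.1) +
                      P[2, 2] * 0.1^2) -
    0.5 * log(det(params$Sigma_nu)) - log(2 * pi) +
    dnorm(log(0.5), 0, 0.5, log = TRUE) + dnorm(0.2, 0, sqrt(0.1),
                                                log = TRUE)
  expect_equal(jl, ll_long + ll_surv + ll_lat, tolerance = 1e-6)
})

test_that("association loadings touch only the survival term", {
  data <- joint_toy()
  set.seed(4)
  latents <- list(nu0 = rnorm(12, 0, 0.5), nu1 = rnorm(12, 0, 0.2),
                  log_b = rep(0, 12), frailty = rep(0, 12))
  params <- list(beta1 = c(1.4, 0.2), beta2 = c(z = 0.5),
                 tau = c(0, 0), tau_b = 0, rho = 1.2, phi = 0.7,
                 Sigma_nu = matrix(c(0.25, 0, 0, 0.04), 2, 2),
                 sigma_b2 = 0, sigma_nu2 = 0)
  base <- attr(joint_log_likelihood(params, latents, data), "parts")
  params$tau <- c(0, -1.5)
  pert <- attr(joint_log_likelihood(params, latents, data), "parts")
  expect_equal(base[["longitudinal"]], pert[["longitudinal"]])
  expect_equal(base[["latent_prior"]], pert[["latent_prior"]])
  expect_false(isTRUE(all.equal(base[["survival"]], pert[["survival"]])))
})
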