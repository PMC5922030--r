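## Model likelihoods shared by the separate submodels and the joint model:
## the Poisson-log-normal record density (marginal over the visit-level
## perturbation, by Gauss-Hermite quadrature), the censored Weibull
## proportional-hazards density, and their shared-parameter combination.

## Record-wise log density of y ~ Poisson(exp(m + eps)), eps ~ N(0, b),
## integrating eps out with a K-node Gauss-Hermite rule.  `b` is recycled.
pln_record_loglik <- function(y, m, b, gh = 15, cap = 30) {
  b <- rep_len(b, length(y))
  out <- numeric(length(y))
  degen <- b < 1e-12
  if (any(degen))
    out[degen] <- dpois(y[degen], exp(pmin(m[degen], cap)), log = TRUE)
  if (any(!degen)) {
    rule <- gauss_hermite_rule(gh)
    yy <- y[!degen]; mm <- m[!degen]; bb <- b[!degen]
    M <- outer(sqrt(2 * bb), rule$x) + mm          # N x K log-means
    L <- dpois(yy, exp(pmin(M, cap)), log = TRUE) +
      matrix(rule$logw, nrow = length(yy), ncol = gh, byrow = TRUE)
    out[!degen] <- logsumexp_rows(L)
  }
  out
}

#' Poisson-log-normal longitudinal log-likelihood
#'
#' Log-likelihood of the count outcomes given the patient latent effects:
#' the linear predictor is `X beta1 + nu0_i + nu1_i * time`, the
#' visit-level perturbation (variance `b_i`) is integrated out by
#' Gauss-Hermite quadrature.
#'
#' @param y Count vector (one entry per observed record).
#' @param X Fixed-effect design matrix (including any time column).
#' @param beta1 Fixed-effect vector.
#' @param id Patient index (1-based) per record.
#' @param tvec Standardized time per record (for the random slope).
#' @param nu0,nu1 Patient random intercept/slope vectors.
#' @param b Patient dispersion `b_i` (scalar or per-patient vector).
#' @param gh Number of quadrature nodes.
#' @return Total log-likelihood (a scalar).
#' @export
pln_loglik <- function(y, X, beta1, id, tvec, nu0 = NULL, nu1 = NULL,
                       b = 0, gh = 15) {
  n <- max(id)
  if (is.null(nu0)) nu0 <- rep(0, n)
  if (is.null(nu1)) nu1 <- rep(0, n)
  m <- as.vector(X %*% beta1) + nu0[id] + nu1[id] * tvec
  bb <- if (length(b) == 1) rep(b, length(y)) else b[id]
  sum(pln_record_loglik(y, m, bb, gh = gh))
}

#' Censored Weibull proportional-hazards log-likelihood
#'
#' `sum_i [ delta_i * log h_i(t_i) - H_i(t_i) ]` with hazard
#' `h_i(t) = phi * rho * t^(rho-1) * exp(lp_i)` and cumulative hazard
#' `H_i(t) = phi * t^rho * exp(lp_i)`; `lp` carries both fixed effects and
#' any shared latent term `W2`.
#'
#' @param time Positive event/censoring times.
#' @param event 1 = event observed, 0 = censored.
#' @param lp Log relative hazard per subject (default 0).
#' @param rho,phi Positive shape and scale.
#' @return Total log-likelihood (a scalar).
#' @export
weibull_loglik <- function(time, event, lp = 0, rho, phi) {
  if (any(time <= 0)) stop_validation("times must be positive")
  if (rho <= 0 || phi <= 0) stop_validation("rho and phi must be > 0")
  lp <- rep_len(lp, length(time))
  sum(event * (log(phi) + log(rho) + (rho - 1) * log(time) + lp) -
        phi * time^rho * exp(lp))
}

## Per-subject censored Weibull log-density with the patient frailty
## integrated out by Gauss-Hermite quadrature: lp0 excludes the frailty,
## which is N(0, sigma_nu2) on the log-hazard scale.  Used by the DIC,
## whose focus conditions on the shared effects but marginalizes each
## submodel's local perturbation (eps longitudinally, the frailty here).
weibull_frailty_records <- function(time, event, lp0, rho, phi,
                                    sigma_nu2, gh = 9) {
  base <- event * (log(phi) + log(rho) + (rho - 1) * log(time))
  if (sigma_nu2 < 1e-12)
    return(base + event * lp0 - phi * time^rho * exp(lp0))
  rule <- gauss_hermite_rule(gh)
  z <- sqrt(2 * sigma_nu2) * rule$x
  L <- outer(event, z) + event * lp0 -
    (phi * time^rho) * exp(outer(lp0, z, `+`)) +
    matrix(rule$logw, nrow = length(time), ncol = gh, byrow = TRUE)
  base + logsumexp_rows(L)
}

#' Joint shared-parameter log-likelihood
#'
#' Sum over patients of (a) the Poisson-log-normal longitudinal log-density
#' given `(nu_i, b_i)`, (b) the censored Weibull log-density with
#' log-hazard `x' beta2 + W2_i`,
#' `W2_i = tau0 nu0_i + tau1 nu1_i + tau_b log b_i + frailty_i`, and
#' (c) the latent-effect log-priors (bivariate normal for `(nu0, nu1)`,
#' normal for `log b` and the frailty — each only when its variance is
#' positive).
#'
#' @param params List with `beta1`, `beta2`, `tau` (length 2), `tau_b`,
#'   `rho`, `phi`, `Sigma_nu`, `sigma_b2`, `sigma_nu2` (a [true_params()]
#'   object works).
#' @param latents List/data frame with `nu0`, `nu1`, `log_b`, `frailty`.
#' @param data List with `long = list(y, X, id, tvec)` and
#'   `surv = list(time, event, X)` (survival `X` may be `NULL`).
#' @param gh Quadrature nodes for the longitudinal part.
#' @return Scalar log-likelihood with attribute `parts` =
#'   `c(longitudinal, survival, latent_prior)`.
#' @export
joint_log_likelihood <- function(params, latents, data, gh = 15) {
  lng <- data$long; srv <- data$surv
  n <- length(latents$nu0)
  ll_long <- pln_loglik(lng$y, lng$X, params$beta1, lng$id, lng$tvec,
                        nu0 = latents$nu0, nu1 = latents$nu1,
                        b = exp(latents$log_b), gh = gh)
  lp <- rep(0, length(srv$time))
  if (!is.null(srv$X) && length(params$beta2))
    lp <- as.vector(srv$X %*% params$beta2)
  W2 <- params$tau[1] * latents$nu0 + params$tau[2] * latents$nu1 +
    params$tau_b * latents$log_b + latents$frailty
  ll_surv <- weibull_loglik(srv$time, srv$event, lp + W2,
                            rho = params$rho, phi = params$phi)
  ll_lat <- 0
  S <- params$Sigma_nu
  if (any(abs(S) > 1e-14)) {
    P <- chol2inv(chol(S))
    q <- P[1, 1] * latents$nu0^2 + 2 * P[1, 2] * latents$nu0 * latents$nu1 +
      P[2, 2] * latents$nu1^2
    ll_lat <- ll_lat - 0.5 * sum(q) - n / 2 * determinant(S)$modulus[1] -
      n * log(2 * pi)
  }
  if (params$sigma_b2 > 0)
    ll_lat <- ll_lat + sum(stats::dnorm(latents$log_b, 0,
                                        sqrt(params$sigma_b2), log = TRUE))
  if (params$sigma_nu2 > 0)
    ll_lat <- ll_lat + sum(stats::dnorm(latents$frailty, 0,
                                        sqrt(params$sigma_nu2), log = TRUE))
  total <- ll_long + ll_surv + ll_lat
  if (!is.finite(total)) {
    bad <- "longitudinal"
    if (!is.finite(ll_surv)) bad <- "survival"
    if (!is.finite(ll_lat)) bad <- "latent prior"
    stop("non-finite joint log-likelihood in the ", bad, " term")
  }
  structure(total, parts = c(longitudinal = ll_long, survival = ll_surv,
                             latent_prior = ll_lat))
}
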