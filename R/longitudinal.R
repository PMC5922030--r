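## Separate longitudinal submodels: Poisson-log-normal GLMM (homogeneous or
## patient-specific dispersion) by MCMC, and marginal count-family fits
## (Poisson-log-normal vs negative binomial) by maximum likelihood for the
## information-criteria comparison.

#' Longitudinal model specification
#'
#' @param family One of `"poisson_lognormal_homogeneous"`,
#'   `"poisson_lognormal_heterogeneous"`, `"negative_binomial"`.
#' @param fixed_effects Design-column names (see [build_design()]; `"time"`
#'   adds the standardized visit time).
#' @param random_effects Subset of `c("intercept", "slope")`; a slope
#'   requires the intercept.  Random effects are not supported for the
#'   negative binomial family (its role is the marginal criteria
#'   comparison).
#' @param engine `"auto"` (MCMC when random effects present, otherwise
#'   marginal ML), `"mcmc"`, or `"ml"`.
#' @param sigma_eps2 `NULL` to estimate the visit-level variance, or a
#'   fixed non-negative value (0 pins the model at its Poisson limit;
#'   ML engine only).
#' @return A validated list of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(family = "poisson_lognormal_heterogeneous",
                              fixed_effects = c("(Intercept)", "time"),
                              random_effects = c("intercept", "slope"),
                              engine = "auto", sigma_eps2 = NULL) {
  family <- match.arg(family, c("poisson_lognormal_homogeneous",
                                "poisson_lognormal_heterogeneous",
                                "negative_binomial"))
  engine <- match.arg(engine, c("auto", "mcmc", "ml"))
  if (!all(random_effects %in% c("intercept", "slope")))
    stop_validation("random_effects must be a subset of intercept/slope")
  if ("slope" %in% random_effects && !("intercept" %in% random_effects))
    stop_validation("a random slope requires the random intercept")
  if (family == "poisson_lognormal_heterogeneous" &&
      !("intercept" %in% random_effects))
    stop_validation("the heterogeneous family requires at least the ",
                    "random intercept")
  if (family == "negative_binomial" && length(random_effects))
    stop_validation("random effects are not supported for the negative ",
                    "binomial family")
  if (engine == "ml" && length(random_effects))
    stop_validation("the ML engine supports no patient random effects; ",
                    "use the MCMC engine")
  if (engine == "auto") engine <- if (length(random_effects)) "mcmc" else "ml"
  if (!is.null(sigma_eps2)) {
    if (engine != "ml" || sigma_eps2 < 0)
      stop_validation("a fixed sigma_eps2 requires the ML engine and a ",
                      "non-negative value")
  }
  structure(list(family = family, fixed_effects = fixed_effects,
                 random_effects = random_effects, engine = engine,
                 link = "log", sigma_eps2 = sigma_eps2),
            class = "longitudinal_spec")
}

## Marginal ML fit of the Poisson-log-normal (or pure Poisson) family.
## `sigma_fix` pins the visit-level variance (0 = pure Poisson ML).
fit_pln_ml <- function(y, X, sigma_floor = 1e-6, gh = 21,
                       sigma_fix = NULL) {
  p <- ncol(X)
  nll_pois <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - exp(eta) - lgamma(y + 1))
  }
  gr_pois <- function(b) {
    eta <- as.vector(X %*% b)
    -as.vector(crossprod(X, y - exp(eta)))
  }
  b_start <- c(log(mean(y) + 0.5), rep(0, p - 1))
  if (!"(Intercept)" %in% colnames(X)) b_start <- rep(0, p)
  pois <- optim(b_start, nll_pois, gr_pois, method = "BFGS",
                control = list(reltol = 1e-15, maxit = 500))
  if (!is.null(sigma_fix)) {
    if (sigma_fix == 0)
      return(list(beta = setNames(pois$par, colnames(X)), sigma2 = 0,
                  loglik = -pois$value, k = p))
    nll_fix <- function(b)
      -sum(pln_record_loglik(y, as.vector(X %*% b), sigma_fix, gh = gh))
    fx <- optim(pois$par, nll_fix, method = "BFGS",
                control = list(reltol = 1e-12, maxit = 500))
    return(list(beta = setNames(fx$par, colnames(X)), sigma2 = sigma_fix,
                loglik = -fx$value, k = p))
  }
  nll_pln <- function(par) {
    b <- par[seq_len(p)]; s2 <- par[p + 1]
    m <- as.vector(X %*% b)
    -sum(pln_record_loglik(y, m, s2, gh = gh))
  }
  ## sigma2 is bounded below by 0 so the Poisson boundary is attainable
  mom <- var(y) / max(mean(y), 1e-8) - 1          # moment-based start
  fit <- optim(c(pois$par, max(mom, 1e-3)), nll_pln,
               method = "L-BFGS-B",
               lower = c(rep(-Inf, p), 0),
               control = list(factr = 1e4, maxit = 500))
  s2 <- fit$par[p + 1]
  if (s2 < sigma_floor || -fit$value <= -pois$value + 1e-9) {
    ## boundary: the data are effectively Poisson
    list(beta = setNames(pois$par, colnames(X)), sigma2 = 0,
         loglik = -pois$value, k = p)
  } else {
    list(beta = setNames(fit$par[seq_len(p)], colnames(X)), sigma2 = s2,
         loglik = -fit$value, k = p + 1)
  }
}

fit_criteria <- function(loglik, k, N, y, mean_hat, var_hat) {
  pearson <- sum((y - mean_hat)^2 / var_hat)
  dof <- N - k
  structure(list(pearson_chi2 = pearson, dof = dof,
                 pearson_ratio = pearson / dof, loglik = loglik,
                 k = k, n_obs = N,
                 aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(N)),
            class = "fit_criteria")
}

#' @export
print.fit_criteria <- function(x, ...) {
  cat(sprintf(
    "Pearson chi2 %.1f / %d df = %.3f | loglik %.1f | AIC %.1f | BIC %.1f\n",
    x$pearson_chi2, x$dof, x$pearson_ratio, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Fit a separate longitudinal count submodel
#'
#' Fits the CD4-change submodel on its own.  For the Poisson-log-normal
#' families with patient random effects the engine is the package's
#' Metropolis-within-Gibbs sampler (the survival block disabled); without
#' random effects a marginal maximum-likelihood fit (Gauss-Hermite) is
#' used; the negative binomial is fitted by ML via [MASS::glm.nb()].
#'
#' @param long Longitudinal table (rows with `observed == 0` are dropped).
#' @param covariates Covariate table covering every patient.
#' @param spec A [longitudinal_spec()].
#' @param settings Sampler settings ([mcmc_settings()]), used by the MCMC
#'   engine.
#' @return Object of class `longitudinal_fit`: coefficient summaries,
#'   variance components, per-patient latent-effect estimates, fit
#'   criteria, convergence diagnostics and a `status` field (`"ok"` or
#'   `"failed"`, the latter carrying diagnostics rather than silent
#'   partial output).
#' @export
fit_longitudinal <- function(long, covariates,
                             spec = longitudinal_spec(),
                             settings = mcmc_settings()) {
  stopifnot(inherits(spec, "longitudinal_spec"))
  obs <- if (!is.null(long$observed)) long[long$observed == 1, , drop = FALSE]
    else long
  if (spec$family == "negative_binomial") {
    dat <- prepare_jm_data(obs, NULL, covariates, spec$fixed_effects, NULL)
    nb <- MASS::glm.nb(dat$y ~ 0 + dat$X1_raw)
    beta <- setNames(coef(nb), colnames(dat$X1_raw))
    m <- exp(as.vector(dat$X1_raw %*% beta))
    v <- m + m^2 / nb$theta
    crit <- fit_criteria(as.numeric(stats::logLik(nb)),
                         length(beta) + 1, dat$N, dat$y, m, v)
    out <- list(spec = spec, engine = "ml",
                coef = data.frame(term = names(beta), estimate = beta,
                                  se = summary(nb)$coefficients[, 2],
                                  row.names = NULL),
                theta = nb$theta, varcomps = NULL, criteria = crit,
                per_patient_effects = NULL, convergence = NULL,
                status = "ok")
    class(out) <- "longitudinal_fit"
    return(out)
  }
  heterogeneous <- spec$family == "poisson_lognormal_heterogeneous"
  if (spec$engine == "ml") {
    dat <- prepare_jm_data(obs, NULL, covariates, spec$fixed_effects, NULL)
    ml <- fit_pln_ml(dat$y, dat$X1_raw, sigma_fix = spec$sigma_eps2)
    m <- exp(as.vector(dat$X1_raw %*% ml$beta) + ml$sigma2 / 2)
    v <- m + m^2 * (exp(ml$sigma2) - 1)
    crit <- fit_criteria(ml$loglik, ml$k, dat$N, dat$y, m, v)
    out <- list(spec = spec, engine = "ml",
                coef = data.frame(term = names(ml$beta),
                                  estimate = as.numeric(ml$beta),
                                  row.names = NULL),
                varcomps = c(sigma_eps2 = ml$sigma2),
                criteria = crit, per_patient_effects = NULL,
                convergence = NULL, status = "ok")
    class(out) <- "longitudinal_fit"
    return(out)
  }
  level <- if ("slope" %in% spec$random_effects) "full"
    else if ("intercept" %in% spec$random_effects) "intercept" else "fixed"
  dat <- prepare_jm_data(obs, NULL, covariates, spec$fixed_effects, NULL)
  res <- jm_mcmc(dat, level = level, heterogeneous = heterogeneous,
                 include_surv = FALSE, settings = settings)
  finish_mcmc_longfit(res, dat, spec, settings)
}

finish_mcmc_longfit <- function(res, dat, spec, settings) {
  summ <- summarize_draws(res$draws)
  conv <- convergence_diagnostics(res)
  lat <- res$latent_means
  bn <- paste0("long_", colnames(dat$X1))
  beta_hat <- summ$mean[match(bn, summ$parameter)]
  names(beta_hat) <- colnames(dat$X1)
  b_hat <- exp(lat$log_b)
  m_lat <- as.vector(dat$X1_raw %*% beta_hat) + lat$nu0[dat$id] +
    lat$nu1[dat$id] * dat$tvec
  ll_hat <- sum(pln_record_loglik(dat$y, m_lat, b_hat[dat$id],
                                  gh = settings$gh))
  vc_names <- intersect(c("sigma_b2", "sigma_eps2", "var_nu0", "var_nu1",
                          "cov_nu01", "corr_nu01"), summ$parameter)
  k <- ncol(dat$X1) + sum(vc_names != "corr_nu01")
  mc <- exp(m_lat + b_hat[dat$id] / 2)           # conditional mean given RE
  vcnd <- mc + mc^2 * (exp(b_hat[dat$id]) - 1)
  crit <- fit_criteria(ll_hat, k, dat$N, dat$y, mc, vcnd)
  status <- if (all(conv$ok)) "ok" else "failed"
  out <- list(spec = spec, engine = "mcmc", summaries = summ,
              coef = summ[match(bn, summ$parameter), , drop = FALSE],
              varcomps = setNames(summ$mean[match(vc_names,
                                                  summ$parameter)],
                                  vc_names),
              criteria = crit,
              per_patient_effects = data.frame(
                patient_id = seq_len(dat$n), nu0 = lat$nu0, nu1 = lat$nu1,
                log_b = lat$log_b),
              convergence = conv, draws = res$draws, mcmc = res,
              dat = dat, status = status)
  class(out) <- "longitudinal_fit"
  if (status == "failed")
    warning("longitudinal MCMC fit did not meet the convergence criterion ",
            "(Geweke |z| < 2 and ESS >= 200); status set to 'failed'")
  out
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat("Longitudinal count submodel:", x$spec$family,
      sprintf("[engine %s, status %s]\n", x$engine, x$status))
  print(x$coef, digits = 4)
  if (!is.null(x$varcomps)) {
    cat("Variance components:\n")
    print(round(x$varcomps, 4))
  }
  print(x$criteria)
  invisible(x)
}

#' @export
coef.longitudinal_fit <- function(object, ...) {
  if (!is.null(object$coef$estimate))
    setNames(object$coef$estimate, object$coef$term)
  else setNames(object$coef$mean, sub("^long_", "", object$coef$parameter))
}

#' @export
summary.longitudinal_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$convergence)) {
    cat("\nConvergence diagnostics:\n")
    print(object$convergence, digits = 3)
  }
  invisible(object)
}

#' @export
residuals.longitudinal_fit <- function(object, ...) {
  if (is.null(object$dat))
    stop("Pearson residuals are available for MCMC fits only")
  dat <- object$dat
  beta_hat <- coef(object)
  lat <- object$per_patient_effects
  b_hat <- exp(lat$log_b)
  m <- exp(as.vector(dat$X1_raw %*% beta_hat[colnames(dat$X1_raw)]) +
             lat$nu0[dat$id] + lat$nu1[dat$id] * dat$tvec +
             b_hat[dat$id] / 2)
  v <- m + m^2 * (exp(b_hat[dat$id]) - 1)
  (dat$y - m) / sqrt(v)
}

#' Compare the quasi-Poisson-type and negative binomial count families
#'
#' Fits the marginal Poisson-log-normal model (the generative realization
#' of the quasi-Poisson mean-variance inflation) and the negative binomial
#' to the same design by maximum likelihood, and ranks them by AIC, BIC
#' and Pearson chi-square per degree of freedom ("the smaller is the
#' better").  Disagreements among the criteria are reported, not resolved.
#'
#' @param long Longitudinal table.
#' @param covariates Covariate table.
#' @param terms Fixed-effect design columns shared by both fits.
#' @return Object of class `family_comparison`: `criteria` (two-row data
#'   frame), `winner` per criterion, `overall` (`NA` on disagreement),
#'   `tie` flag.
#' @export
compare_count_families <- function(long, covariates,
                                   terms = c("(Intercept)", "time")) {
  pln <- fit_longitudinal(long, covariates,
                          longitudinal_spec("poisson_lognormal_homogeneous",
                                            fixed_effects = terms,
                                            random_effects = character(0),
                                            engine = "ml"))
  nb <- tryCatch(
    fit_longitudinal(long, covariates,
                     longitudinal_spec("negative_binomial",
                                       fixed_effects = terms,
                                       random_effects = character(0))),
    error = function(e) e)
  if (inherits(nb, "error"))
    stop("family comparison aborted: negative binomial fit failed (",
         conditionMessage(nb), ")")
  crit <- data.frame(
    family = c("poisson_lognormal", "negative_binomial"),
    pearson_ratio = c(pln$criteria$pearson_ratio, nb$criteria$pearson_ratio),
    loglik = c(pln$criteria$loglik, nb$criteria$loglik),
    aic = c(pln$criteria$aic, nb$criteria$aic),
    bic = c(pln$criteria$bic, nb$criteria$bic))
  pick <- function(v) {
    if (isTRUE(all.equal(v[1], v[2]))) "tie" else crit$family[which.min(v)]
  }
  winner <- c(aic = pick(crit$aic), bic = pick(crit$bic),
              pearson_ratio = pick(crit$pearson_ratio))
  tie <- all(winner == "tie")
  if (tie) message("count family comparison: criteria identical, tie")
  agreed <- unique(winner[winner != "tie"])
  overall <- if (length(agreed) == 1) agreed else NA_character_
  if (length(agreed) > 1)
    message("count family criteria disagree: ",
            paste(names(winner), winner, sep = "=", collapse = ", "))
  structure(list(criteria = crit, winner = winner, overall = overall,
                 tie = tie, fits = list(poisson_lognormal = pln,
                                        negative_binomial = nb)),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("Count family comparison (smaller is better):\n")
  print(x$criteria, digits = 5)
  cat("Winner by criterion:",
      paste(names(x$winner), x$winner, sep = "=", collapse = ", "), "\n")
  cat("Overall:", ifelse(is.na(x$overall), "disagreement", x$overall), "\n")
  invisible(x)
}
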