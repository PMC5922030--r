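## The joint shared-parameter model: MCMC fit, DIC, the random-effects
## ladder, and hazard-ratio reporting.

#' Joint model specification
#'
#' @param ladder_level One of `"fixed_only"` (no random effects),
#'   `"random_intercept"` (random intercept in the longitudinal submodel,
#'   no latent link), `"intercept_slope_frailty"` (random intercept and
#'   slope shared into the survival log-hazard through loadings
#'   `tau0`/`tau1`, plus a patient frailty).
#' @param heterogeneous_variance Share a patient-specific log-dispersion
#'   `log b_i` (loaded into the hazard via `tau_b` at the top ladder
#'   level); otherwise a pooled visit-level variance is used.
#' @param long_terms,surv_terms Design columns of the two submodels
#'   (`"time"` allowed in `long_terms` only).
#' @return A validated list of class `joint_spec`.
#' @export
joint_spec <- function(ladder_level = "intercept_slope_frailty",
                       heterogeneous_variance = TRUE,
                       long_terms = c("(Intercept)", "age", "sex_female",
                                      "adherence_fair", "adherence_poor",
                                      "time"),
                       surv_terms = c("age", "sex_female",
                                      "adherence_fair", "adherence_poor")) {
  ladder_level <- match.arg(ladder_level,
                            c("fixed_only", "random_intercept",
                              "intercept_slope_frailty"))
  if ("time" %in% surv_terms)
    stop_validation("'time' is not a survival design column")
  structure(list(ladder_level = ladder_level,
                 heterogeneous_variance = isTRUE(heterogeneous_variance),
                 long_terms = long_terms, surv_terms = surv_terms),
            class = "joint_spec")
}

ladder_to_level <- function(ladder_level) {
  switch(ladder_level, fixed_only = "fixed",
         random_intercept = "intercept",
         intercept_slope_frailty = "full")
}

#' Fit the Bayesian shared-parameter joint model
#'
#' Runs the Metropolis-within-Gibbs sampler over the longitudinal
#' Poisson-log-normal GLMM and the Weibull proportional-hazards submodel,
#' linked (at the top ladder level) through the shared latent term
#' `W2 = tau0 nu0 + tau1 nu1 + tau_b log b + frailty` in the log-hazard.
#' Marginal convergence diagnostics produce a warning, not a failure.
#'
#' @param long Longitudinal table (rows with `observed == 0` dropped).
#' @param surv Survival table.
#' @param covariates Covariate table covering every patient.
#' @param spec A [joint_spec()].
#' @param settings Sampler settings ([mcmc_settings()]).
#' @return Object of class `joint_fit`: posterior `summaries`, raw
#'   `draws`, per-patient `latent_means`, `dic` components,
#'   `hazard_ratios`, `convergence` diagnostics and acceptance rates.
#' @export
fit_joint <- function(long, surv, covariates, spec = joint_spec(),
                      settings = mcmc_settings()) {
  stopifnot(inherits(spec, "joint_spec"))
  dat <- prepare_jm_data(long, surv, covariates, spec$long_terms,
                         spec$surv_terms)
  res <- jm_mcmc(dat, level = ladder_to_level(spec$ladder_level),
                 heterogeneous = spec$heterogeneous_variance,
                 include_surv = TRUE, settings = settings)
  summ <- summarize_draws(res$draws)
  conv <- convergence_diagnostics(res)
  if (!all(conv$ok))
    warning("joint MCMC: marginal convergence diagnostics for ",
            paste(conv$parameter[!conv$ok], collapse = ", "),
            " (Geweke |z| >= 2 or ESS < 200)")
  out <- structure(list(spec = spec, settings = settings,
                        summaries = summ, draws = res$draws,
                        chain_id = res$chain_id,
                        latent_means = res$latent_means,
                        convergence = conv, mcmc = res, dat = dat),
                   class = "joint_fit")
  out$dic <- compute_dic(out)
  cn <- colnames(out$draws)
  out$hazard_ratios <- if (any(grepl("^surv_", cn) |
                                cn %in% c("tau0", "tau1", "tau_b")))
    hazard_ratio_table(out) else NULL
  out
}

posterior_mean_params <- function(fit) {
  summ <- fit$summaries
  g <- function(nm) {
    i <- match(nm, summ$parameter)
    ifelse(is.na(i), 0, summ$mean[i])
  }
  X1n <- colnames(fit$dat$X1)
  X2n <- colnames(fit$dat$X2)
  list(beta1 = setNames(vapply(paste0("long_", X1n), g, 0), X1n),
       beta2 = setNames(vapply(paste0("surv_", X2n), g, 0), X2n),
       tau = c(g("tau0"), g("tau1")), tau_b = g("tau_b"),
       rho = max(g("rho"), 1e-8), phi = max(g("phi"), 1e-8))
}

#' Deviance Information Criterion of a joint fit
#'
#' `Dbar` is the posterior mean of the deviance (-2 x the data
#' log-likelihood, marginal over the visit-level perturbation but
#' conditional on the patient latent effects), evaluated along the chain;
#' `D_hat` is the deviance at the posterior means of the parameters with
#' the latent effects plugged in at their posterior means;
#' `p_D = Dbar - D_hat` and `DIC = Dbar + p_D`.  A negative `p_D` is
#' reported with a warning (a known DIC pathology), never hidden.
#'
#' @param fit A `joint_fit` (or a `longitudinal_fit` from the MCMC
#'   engine, for which the survival terms are absent).
#' @return List `(Dbar, D_hat, p_D, DIC)`.
#' @export
compute_dic <- function(fit) {
  res <- fit$mcmc
  if (is.null(res)) stop("compute_dic needs an MCMC fit")
  if (nrow(res$draws) < 200)
    warning("fewer than 200 post-burn-in draws; DIC is unreliable")
  Dbar <- mean(res$devs)
  dat <- fit$dat
  lat <- res$latent_means
  pm <- posterior_mean_params(fit)
  m <- as.vector(dat$X1_raw %*% pm$beta1) + lat$nu0[dat$id] +
    lat$nu1[dat$id] * dat$tvec
  b_hat <- exp(lat$log_b)
  Dhat <- -2 * sum(pln_record_loglik(dat$y, m, b_hat[dat$id],
                                     gh = fit$settings$gh))
  if (res$flags$include_surv) {
    lp0 <- if (ncol(dat$X2) > 0) as.vector(dat$X2_raw %*% pm$beta2) else
      numeric(dat$n)
    if (res$flags$use_link)
      lp0 <- lp0 + pm$tau[1] * lat$nu0 + pm$tau[2] * lat$nu1 +
        pm$tau_b * lat$log_b
    summ <- fit$summaries
    s2u <- if (res$flags$use_u)
      summ$mean[match("sigma_nu2", summ$parameter)] else 0
    Dhat <- Dhat - 2 * sum(weibull_frailty_records(
      dat$tt, dat$delta, lp0, pm$rho, pm$phi, s2u,
      gh = fit$settings$gh))
  }
  pD <- Dbar - Dhat
  if (pD < 0)
    warning("negative effective number of parameters (p_D = ",
            round(pD, 2), "); known DIC pathology")
  list(Dbar = Dbar, D_hat = Dhat, p_D = pD, DIC = Dbar + pD)
}

#' Fit the ladder of random-effect structures and rank by DIC
#'
#' Fits the joint model at each requested ladder rung (fixed effects
#' only; + random intercept; + random slope and frailty with the shared
#' link), tabulates the DIC, and marks the smallest-DIC rung as selected.
#' A failing rung is marked failed and the ladder continues.
#'
#' @param long,surv,covariates Data tables.
#' @param levels Ladder rungs to fit.
#' @param heterogeneous_variance Passed to [joint_spec()].
#' @param long_terms,surv_terms Passed to [joint_spec()].
#' @param settings Sampler settings.
#' @return Object of class `jm_ladder`: `table` (level, Dbar, p_D, DIC,
#'   status, selected) and the per-rung `fits`.
#' @export
run_ladder <- function(long, surv, covariates,
                       levels = c("fixed_only", "random_intercept",
                                  "intercept_slope_frailty"),
                       heterogeneous_variance = TRUE,
                       long_terms = c("(Intercept)", "age", "sex_female",
                                      "adherence_fair", "adherence_poor",
                                      "time"),
                       surv_terms = c("age", "sex_female",
                                      "adherence_fair", "adherence_poor"),
                       settings = mcmc_settings()) {
  fits <- vector("list", length(levels))
  names(fits) <- levels
  rows <- lapply(levels, function(lv) {
    f <- tryCatch(suppressWarnings(
      fit_joint(long, surv, covariates,
                joint_spec(lv, heterogeneous_variance, long_terms,
                           surv_terms),
                settings)),
      error = function(e) e)
    if (inherits(f, "error"))
      return(data.frame(level = lv, Dbar = NA_real_, p_D = NA_real_,
                        DIC = NA_real_, status = conditionMessage(f)))
    fits[[lv]] <<- f
    data.frame(level = lv, Dbar = f$dic$Dbar, p_D = f$dic$p_D,
               DIC = f$dic$DIC, status = "ok")
  })
  tab <- do.call(rbind, rows)
  tab$selected <- FALSE
  if (any(!is.na(tab$DIC)))
    tab$selected[which.min(tab$DIC)] <- TRUE
  structure(list(table = tab, fits = fits), class = "jm_ladder")
}

#' @export
print.jm_ladder <- function(x, ...) {
  cat("DIC ladder over random-effect structures:\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Hazard ratios with 95 percent credible intervals
#'
#' Applies `exp` draw-wise to the survival coefficients (and association
#' loadings, when present) and summarizes on the hazard-ratio scale:
#' posterior mean and 2.5/97.5 percent quantiles, plus the per-unit
#' percentage change implied by the posterior-mean coefficient.
#'
#' @param x A `joint_fit`, or a matrix of coefficient draws (columns =
#'   terms).
#' @return Data frame (`term`, `coef_mean`, `hr`, `hr_lower`, `hr_upper`,
#'   `pct_change`).
#' @export
hazard_ratio_table <- function(x) {
  if (inherits(x, "joint_fit")) {
    cn <- colnames(x$draws)
    keep <- grepl("^surv_", cn) | cn %in% c("tau0", "tau1", "tau_b")
    if (!any(keep))
      stop("no survival coefficient draws in this fit")
    draws <- x$draws[, keep, drop = FALSE]
    colnames(draws) <- sub("^surv_", "", colnames(draws))
  } else {
    draws <- as.matrix(x)
    if (!nrow(draws)) stop("no draws supplied")
  }
  hr <- exp(draws)
  ## order-statistic quantiles (type 1): exactly equivariant under the
  ## monotone map exp, so the HR interval is exp of the coefficient one
  data.frame(term = colnames(draws),
             coef_mean = colMeans(draws),
             hr = colMeans(hr),
             hr_lower = apply(hr, 2, quantile, 0.025, type = 1),
             hr_upper = apply(hr, 2, quantile, 0.975, type = 1),
             pct_change = 100 * (exp(colMeans(draws)) - 1),
             row.names = NULL)
}

#' Percentage change in hazard (or mean) per unit of a covariate
#'
#' The exp-scale effect of a log-linear coefficient expressed as a
#' percentage: `100 * (exp(coef) - 1)`.
#'
#' @param coef Coefficient(s) on the log scale.
#' @return Percentage change per unit increase.
#' @export
hazard_pct_change <- function(coef) 100 * (exp(coef) - 1)

#' @export
print.joint_fit <- function(x, ...) {
  cat("Shared-parameter joint fit:", x$spec$ladder_level,
      if (x$spec$heterogeneous_variance) "(heterogeneous variance)" else
        "(homogeneous variance)", "\n")
  cat(sprintf("  %d chains x %d kept draws\n",
              x$settings$chains, sum(x$chain_id == 1)))
  print(x$summaries, digits = 4)
  cat(sprintf("DIC %.1f (Dbar %.1f, p_D %.1f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$p_D))
  invisible(x)
}

#' @export
summary.joint_fit <- function(object, ...) {
  print(object)
  cat("\nHazard ratios:\n")
  print(object$hazard_ratios, digits = 4)
  cat("\nConvergence diagnostics:\n")
  print(object$convergence, digits = 3)
  invisible(object)
}

#' @export
coef.joint_fit <- function(object, ...) {
  setNames(object$summaries$mean, object$summaries$parameter)
}

#' Posterior-predictive replication of the fitted cohort
#'
#' Draws new longitudinal counts and default times for the fitted
#' cohort's design, using the posterior means of the global parameters
#' and freshly sampled latent effects — a posterior-predictive check of
#' the joint generative model.
#'
#' @param object A `joint_fit`.
#' @param nsim Number of replicated datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` lists, each with `longitudinal`
#'   (`patient_id`, `visit`, `y`) and `survival` (`patient_id`, `time`,
#'   `event`) tables on the fitted design.
#' @export
simulate.joint_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  dat <- object$dat
  pm <- posterior_mean_params(object)
  summ <- object$summaries
  g <- function(nm, default = 0) {
    i <- match(nm, summ$parameter)
    if (is.na(i)) default else summ$mean[i]
  }
  S <- matrix(c(g("var_nu0"), g("cov_nu01"), g("cov_nu01"),
                g("var_nu1")), 2, 2)
  xb1 <- as.vector(dat$X1_raw %*% pm$beta1)
  lp2 <- if (ncol(dat$X2_raw) > 0)
    as.vector(dat$X2_raw %*% pm$beta2) else numeric(dat$n)
  tmax <- max(dat$tt)
  replicate(nsim, simplify = FALSE, {
    nu <- if (any(S != 0))
      matrix(rnorm(2 * dat$n), ncol = 2) %*% chol(S + diag(1e-12, 2))
      else matrix(0, dat$n, 2)
    het <- "sigma_b2" %in% summ$parameter
    logb <- if (het) rnorm(dat$n, 0, sqrt(max(g("sigma_b2"), 0))) else
      numeric(dat$n)
    b <- if (het) exp(logb) else rep(g("sigma_eps2", default = 1), dat$n)
    u <- rnorm(dat$n, 0, sqrt(max(g("sigma_nu2"), 0)))
    eps <- rnorm(dat$N, 0, sqrt(pmax(b[dat$id], 0)))
    mu <- exp(pmin(xb1 + nu[dat$id, 1] + nu[dat$id, 2] * dat$tvec + eps,
                   object$settings$cap))
    W2 <- g("tau0") * nu[, 1] + g("tau1") * nu[, 2] + g("tau_b") * logb +
      u
    t_raw <- (-log(runif(dat$n)) /
                (pm$phi * exp(lp2 + W2)))^(1 / pm$rho)
    list(longitudinal = data.frame(patient_id = dat$id,
                                   time_std = dat$tvec,
                                   y = rpois(dat$N, mu)),
         survival = data.frame(patient_id = seq_len(dat$n),
                               time = pmin(t_raw, tmax),
                               event = as.integer(t_raw <= tmax)))
  })
}

#' @export
plot.joint_fit <- function(x, pars = NULL, ...) {
  cn <- colnames(x$draws)
  if (is.null(pars)) pars <- utils::head(cn, 6)
  pars <- intersect(pars, cn)
  old <- graphics::par(mfrow = c(length(pars), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "l", ylab = p, xlab = "",
                   col = x$chain_id, ...)
  }
  invisible(x)
}
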