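## Separate time-to-default submodels: parametric Weibull (and its
## exponential special case) proportional hazards fitted by maximizing the
## package's censored Weibull likelihood, and the semi-parametric Cox model
## via survival::coxph with Breslow tie handling.

#' Fit a parametric (Weibull or exponential) time-to-default model
#'
#' Maximizes the censored Weibull proportional-hazards likelihood
#' `prod h(t_i)^delta_i S(t_i)` with hazard
#' `phi rho t^(rho-1) exp(x' beta2)`.  The exponential model is the
#' Weibull with shape fixed at 1.  A shape estimate below 1 is reported as
#' a "decreasing" default-rate verdict, above 1 as "increasing".
#'
#' @param surv Survival table (`patient_id`, `time`, `event`).
#' @param covariates Covariate table (only needed when `terms` nonempty).
#' @param terms Survival design columns (no intercept; the scale `phi`
#'   plays that role).
#' @param baseline `"weibull"` or `"exponential"`.
#' @param frailty Must be `FALSE` here: the patient frailty is estimated
#'   within the joint model ([fit_joint()]), not by the separate
#'   maximum-likelihood fit.
#' @param conf_level Confidence level for Wald intervals (log-scale for
#'   `rho` and `phi`).
#' @return Object of class `parametric_survival_fit` with `coef` (with
#'   hazard ratios `exp(coef)`), `shape` (`rho`, CI), `scale` (`phi`),
#'   `loglik`, `criteria`, a baseline `hazard(t)` function and the
#'   monotonicity `verdict`.
#' @export
fit_parametric_survival <- function(surv, covariates = NULL,
                                    terms = character(0),
                                    baseline = "weibull",
                                    frailty = FALSE,
                                    conf_level = 0.95) {
  baseline <- match.arg(baseline, c("weibull", "exponential"))
  if (isTRUE(frailty))
    stop_validation("the patient frailty is estimated within the joint ",
                    "model (fit_joint); use ladder_level = ",
                    "'intercept_slope_frailty'")
  tt <- surv$time; delta <- surv$event
  if (any(tt <= 0)) stop_validation("non-positive survival times")
  if (sum(delta) < 1) stop("all observations censored: cannot fit")
  p <- length(terms)
  X <- if (p > 0) build_design(covariates, terms) else
    matrix(numeric(0), length(tt), 0)
  est_rho <- baseline == "weibull"
  nll <- function(par) {
    par <- pmin(pmax(par, -30), 30)     # keep exp() away from 0/Inf
    phi <- exp(par[1])
    rho <- if (est_rho) exp(par[2]) else 1
    beta <- if (p > 0) par[(1 + est_rho) + seq_len(p)] else numeric(0)
    lp <- if (p > 0) as.vector(X %*% beta) else 0
    -weibull_loglik(tt, delta, lp, rho, phi)
  }
  gr <- function(par) {
    par <- pmin(pmax(par, -30), 30)
    phi <- exp(par[1])
    rho <- if (est_rho) exp(par[2]) else 1
    beta <- if (p > 0) par[(1 + est_rho) + seq_len(p)] else numeric(0)
    lp <- if (p > 0) as.vector(X %*% beta) else rep(0, length(tt))
    H <- phi * tt^rho * exp(lp)
    g1 <- -sum(delta - H)                                 # d/dlog(phi)
    g <- g1
    if (est_rho) {
      g2 <- -rho * sum(delta * (1 / rho + log(tt)) - H * log(tt))
      g <- c(g, g2)
    }
    if (p > 0) g <- c(g, -as.vector(crossprod(X, delta - H)))
    g
  }
  start <- c(log(sum(delta) / sum(tt)), if (est_rho) 0, rep(0, p))
  opt <- optim(start, nll, gr, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  if (opt$convergence != 0)
    stop("parametric survival fit did not converge (code ",
         opt$convergence, ")")
  H <- optimHess(opt$par, nll, gr)
  vc <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  se <- sqrt(pmax(diag(vc), 0))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  phi <- exp(opt$par[1])
  rho <- if (est_rho) exp(opt$par[2]) else 1
  rho_ci <- if (est_rho) rho * exp(c(-1, 1) * zc * se[2]) else c(1, 1)
  cf <- NULL
  if (p > 0) {
    idx <- (1 + est_rho) + seq_len(p)
    cf <- data.frame(term = terms, estimate = opt$par[idx], se = se[idx],
                     lower = opt$par[idx] - zc * se[idx],
                     upper = opt$par[idx] + zc * se[idx],
                     hr = exp(opt$par[idx]), row.names = NULL)
  }
  loglik <- -opt$value
  k <- length(opt$par)
  crit <- list(loglik = loglik, k = k, n_obs = length(tt),
               aic = -2 * loglik + 2 * k,
               bic = -2 * loglik + k * log(length(tt)),
               pearson_chi2 = NA_real_, pearson_ratio = NA_real_,
               pearson_note = "unavailable for censored parametric fits")
  structure(list(baseline = baseline, coef = cf,
                 shape = c(estimate = rho, lower = rho_ci[1],
                           upper = rho_ci[2]),
                 scale = phi, vcov = vc, loglik = loglik, criteria = crit,
                 hazard = local({
                   phi0 <- phi; rho0 <- rho
                   function(t) phi0 * rho0 * t^(rho0 - 1)
                 }),
                 verdict = if (rho < 1) "decreasing" else "increasing",
                 terms = terms),
            class = "parametric_survival_fit")
}

#' @export
print.parametric_survival_fit <- function(x, ...) {
  cat(sprintf("%s proportional-hazards fit (loglik %.2f)\n",
              x$baseline, x$loglik))
  cat(sprintf("  shape rho = %.3f (%.3f, %.3f) -> %s default rate\n",
              x$shape["estimate"], x$shape["lower"], x$shape["upper"],
              x$verdict))
  cat(sprintf("  scale phi = %.4f\n", x$scale))
  if (!is.null(x$coef)) print(x$coef, digits = 4)
  invisible(x)
}

#' @export
coef.parametric_survival_fit <- function(object, ...) {
  if (is.null(object$coef)) return(numeric(0))
  setNames(object$coef$estimate, object$coef$term)
}

#' @export
predict.parametric_survival_fit <- function(object, times,
                                            newdata = NULL, ...) {
  lp <- 0
  if (!is.null(object$coef) && !is.null(newdata))
    lp <- as.vector(build_design(newdata, object$terms) %*%
                      object$coef$estimate)
  outer(exp(lp), times, function(e, t)
    exp(-object$scale * t^object$shape[["estimate"]] * e))
}

#' Fit the semi-parametric Cox proportional-hazards model
#'
#' Maximizes the Breslow-tie partial likelihood via [survival::coxph()].
#' No baseline parameters are reported; monotone-likelihood (complete
#' separation) is raised as an error with a diagnostic.
#'
#' @param surv Survival table.
#' @param covariates Covariate table.
#' @param terms Design columns (at least one).
#' @return Object of class `cox_fit` with `coef` (and hazard ratios),
#'   partial-likelihood `criteria` (BIC flagged approximate, Pearson
#'   chi-square unavailable), and the underlying `coxph` object.
#' @export
fit_cox <- function(surv, covariates, terms) {
  if (!length(terms)) stop_validation("fit_cox requires >= 1 covariate")
  if (sum(surv$event) < 1) stop("all observations censored: cannot fit")
  X <- build_design(covariates, terms)
  keep <- apply(X, 2, function(z) sd(z) > 0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ X,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("monotone partial likelihood (complete separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  cf[is.na(cf)] <- 0                      # constant columns carry no signal
  names(cf) <- terms
  se <- sqrt(diag(fit$var))
  se <- c(se, rep(0, length(cf) - length(se)))[seq_along(cf)]
  if (!all(keep)) se[!keep] <- NA_real_
  loglik <- fit$loglik[2]
  k <- sum(keep)
  nev <- sum(surv$event)
  crit <- list(loglik = loglik, k = k, n_obs = nrow(surv),
               aic = -2 * loglik + 2 * k,
               bic = -2 * loglik + k * log(nev),
               bic_note = "approximate: partial likelihood, n = events",
               pearson_chi2 = NA_real_, pearson_ratio = NA_real_,
               pearson_note = "unavailable for the partial likelihood")
  structure(list(coef = data.frame(term = terms, estimate = as.numeric(cf),
                                   se = se, hr = exp(as.numeric(cf)),
                                   row.names = NULL),
                 loglik = loglik, criteria = crit, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (partial loglik %.2f)\n",
              x$loglik))
  print(x$coef, digits = 4)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$coef$estimate, object$coef$term)
}

#' Rank survival fits by information criteria
#'
#' Tabulates log-likelihood, AIC and BIC (and availability notes) for a
#' set of survival fits and marks the smaller-is-better winner per
#' criterion, flagging disagreements.  Criteria a fit cannot supply
#' (e.g., Pearson chi-square for a partial likelihood) are marked
#' unavailable, never fabricated.
#'
#' @param ... Named fits (`parametric_survival_fit` or `cox_fit`), or a
#'   single list of them.
#' @return Object of class `survival_comparison`.
#' @export
compare_survival_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && is.null(fits[[1]]$criteria))
    fits <- fits[[1]]
  if (length(fits) < 2) stop_validation("need >= 2 fits to compare")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  crit <- do.call(rbind, lapply(names(fits), function(nm) {
    cc <- fits[[nm]]$criteria
    data.frame(model = nm, loglik = cc$loglik, aic = cc$aic, bic = cc$bic,
               pearson_ratio = cc$pearson_ratio)
  }))
  pick <- function(v) {
    if (all(is.na(v))) return(NA_character_)
    vv <- v; vv[is.na(vv)] <- Inf
    if (isTRUE(all.equal(min(vv), max(vv)))) "tie" else
      crit$model[which.min(vv)]
  }
  winner <- c(aic = pick(crit$aic), bic = pick(crit$bic),
              pearson_ratio = pick(crit$pearson_ratio))
  agreed <- unique(winner[!is.na(winner) & winner != "tie"])
  structure(list(criteria = crit, winner = winner,
                 overall = if (length(agreed) == 1) agreed else
                   NA_character_,
                 disagreement = length(agreed) > 1),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Survival model comparison (smaller is better):\n")
  print(x$criteria, digits = 5)
  cat("Winner by criterion:",
      paste(names(x$winner), x$winner, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
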