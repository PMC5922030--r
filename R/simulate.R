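## Synthetic cohort generator: covariates, latent effects, longitudinal
## counts, default times, and MCAR dropout.  Every generator is a pure
## function of (arguments, seed).

## Log-normal parameters matched to a (median, q1, q3) summary.
lnorm_from_quartiles <- function(q) {
  mu <- log(q[["median"]])
  sigma <- (log(q[["q3"]]) - log(q[["q1"]])) / (2 * qnorm(0.75))
  c(mu = mu, sigma = sigma)
}

#' Generate baseline covariate profiles
#'
#' Draws a synthetic cohort of adult patients whose categorical marginals
#' match the requested frequencies and whose continuous variables (age,
#' weight, baseline CD4) are log-normal with the requested
#' median/quartiles.  Age is truncated below at 18 years.
#'
#' @param n Cohort size.
#' @param marginals Per-variable frequency map as in [table1_marginals()];
#'   variables omitted from the map keep their defaults, and partial
#'   categorical maps are rejected unless they sum to one.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Data frame with one row per patient (`patient_id`, `sex`, `age`,
#'   `weight`, `baseline_cd4`, `residence`, `marital`, `education`,
#'   `income`, `who_stage`, `cellphone`, `disclosure`, `adherence`).
#' @export
generate_covariates <- function(n, marginals = table1_marginals(), seed = 1) {
  n <- check_count(n, "n")
  defaults <- table1_marginals()
  unknown <- setdiff(names(marginals), names(defaults))
  if (length(unknown))
    stop_validation("unknown variable name(s) in marginals: ",
                    paste(unknown, collapse = ", "))
  m <- defaults
  m[names(marginals)] <- marginals
  lev <- covariate_levels()
  for (v in names(lev)) {
    p <- m[[v]]
    if (is.null(names(p)) || !all(names(p) %in% lev[[v]]))
      stop_validation("marginals for '", v, "' must be named with levels ",
                      paste(lev[[v]], collapse = "/"))
    if (abs(sum(p) - 1) > 1e-9)
      stop_validation("marginals for '", v, "' must sum to 1 (got ",
                      format(sum(p)), ")")
    if (any(p < 0)) stop_validation("negative frequency for '", v, "'")
  }
  set.seed(seed)
  draw_cat <- function(v) {
    p <- m[[v]]
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = lev[[v]])
  }
  draw_lnorm <- function(v, lower = 0) {
    par <- lnorm_from_quartiles(m[[v]])
    x <- exp(rnorm(n, par["mu"], par["sigma"]))
    while (any(x < lower)) {                       # truncation by redraw
      i <- which(x < lower)
      x[i] <- exp(rnorm(length(i), par["mu"], par["sigma"]))
    }
    x
  }
  data.frame(
    patient_id = seq_len(n),
    sex = draw_cat("sex"),
    age = draw_lnorm("age", lower = 18),
    weight = draw_lnorm("weight"),
    baseline_cd4 = draw_lnorm("baseline_cd4"),
    residence = draw_cat("residence"),
    marital = draw_cat("marital"),
    education = draw_cat("education"),
    income = draw_cat("income"),
    who_stage = draw_cat("who_stage"),
    cellphone = draw_cat("cellphone"),
    disclosure = draw_cat("disclosure"),
    adherence = draw_cat("adherence")
  )
}

#' Generate patient-level latent effects
#'
#' Draws, independently of the covariates, the correlated random
#' intercept/slope `(nu0, nu1) ~ N(0, Sigma_nu)`, the log-dispersion
#' `log_b ~ N(0, sigma_b2)` (so the patient-specific variance
#' `b = exp(log_b)` is log-normal with median 1), and the frailty
#' `frailty ~ N(0, sigma_nu2)`.
#'
#' @param n Number of patients.
#' @param params A [true_params()] object.
#' @param seed Integer seed.
#' @return Data frame (`patient_id`, `nu0`, `nu1`, `log_b`, `frailty`).
#' @export
generate_latent_effects <- function(n, params, seed = 1) {
  n <- check_count(n, "n")
  stopifnot(inherits(params, "true_params"))
  set.seed(seed)
  S <- params$Sigma_nu
  if (all(abs(S) < 1e-14)) {
    nu <- matrix(0, n, 2)
  } else {
    L <- t(chol(S))
    nu <- t(L %*% matrix(rnorm(2 * n), 2, n))
  }
  log_b <- if (params$sigma_b2 > 0) rnorm(n, 0, sqrt(params$sigma_b2)) else
    rep(0, n)
  frailty <- if (params$sigma_nu2 > 0) rnorm(n, 0, sqrt(params$sigma_nu2)) else
    rep(0, n)
  data.frame(patient_id = seq_len(n), nu0 = nu[, 1], nu1 = nu[, 2],
             log_b = log_b, frailty = frailty)
}

#' Generate the longitudinal CD4 change table
#'
#' For patient i at scheduled visit j with standardized time t_j the
#' log-mean is `x_i' beta1 + nu0_i + nu1_i t_j + eps_ij` with visit-level
#' perturbation `eps_ij ~ N(0, b_i)`; the CD4 change outcome is Poisson
#' with that mean (a Poisson-log-normal count, overdispersed whenever
#' `b_i > 0`).  CD4 counts are accumulated from the baseline CD4 covariate
#' so that successive differences recover the generated changes; the first
#' on-treatment visit is referenced against the pre-treatment baseline.
#'
#' @param profiles Covariate data frame ([generate_covariates()]).
#' @param effects Latent-effect data frame ([generate_latent_effects()]).
#' @param params A [true_params()] object; `beta1` names select design
#'   columns, with `time` the standardized visit time.
#' @param schedule Strictly increasing visit times in months.
#' @param seed Integer seed.
#' @param cap Cap on |log mean|; values beyond it are truncated with a
#'   warning (overflow guard).
#' @return Long-format data frame (`patient_id`, `visit_index`,
#'   `visit_time`, `time_std`, `cd4_count`, `cd4_change`, `observed`) with
#'   the schedule carried in `attr(, "schedule")`.
#' @export
generate_longitudinal <- function(profiles, effects, params,
                                  schedule = default_schedule(), seed = 1,
                                  cap = 20) {
  stopifnot(inherits(params, "true_params"))
  if (nrow(profiles) != nrow(effects))
    stop_validation("profiles and effects must have one row per patient")
  if (!length(schedule) || any(diff(schedule) <= 0))
    stop_validation("schedule must be nonempty and strictly increasing")
  set.seed(seed)
  n <- nrow(profiles)
  J <- length(schedule)
  t_std <- standardize_time(schedule, schedule)
  bnames <- names(params$beta1)
  X <- build_design(profiles, bnames)              # time excluded
  xb_base <- as.vector(X %*% params$beta1[colnames(X)])
  b_time <- if ("time" %in% bnames) params$beta1[["time"]] else 0

  id <- rep(seq_len(n), each = J)
  vis <- rep(seq_len(J), times = n)
  tt <- schedule[vis]
  ts <- t_std[vis]
  b_i <- params$sigma_eps2 * exp(effects$log_b)
  eps <- rnorm(n * J, 0, sqrt(b_i[id]))
  eta <- xb_base[id] + b_time * ts + effects$nu0[id] + effects$nu1[id] * ts +
    eps
  over <- abs(eta) > cap
  if (any(over)) {
    warning(sum(over), " linear predictor value(s) exceeded |cap| = ", cap,
            " and were truncated")
    eta <- pmin(pmax(eta, -cap), cap)
  }
  y <- rpois(n * J, exp(eta))
  long <- data.frame(patient_id = id, visit_index = vis, visit_time = tt,
                     time_std = ts, cd4_count = NA_real_, cd4_change = y,
                     observed = 1L)
  ## counts accumulate from the pre-treatment baseline CD4
  base <- profiles$baseline_cd4[id]
  long$cd4_count <- base + as.vector(
    unlist(tapply(y, id, cumsum, simplify = FALSE), use.names = FALSE))
  attr(long, "schedule") <- schedule
  long
}

#' Generate time-to-default and apply administrative censoring
#'
#' Event times are drawn by inverse-CDF from the Weibull
#' proportional-hazards model with hazard
#' `phi * rho * t^(rho-1) * exp(x' beta2 + W2)`, where the shared latent
#' term `W2 = tau0 nu0 + tau1 nu1 + tau_b log_b + frailty` enters the
#' log-hazard.  Time is measured in follow-up-visit units and kept
#' continuous; times beyond `max_followups` are administratively censored.
#'
#' @param profiles,effects,params As in [generate_longitudinal()].
#' @param max_followups Administrative horizon in visit units (>= 1).
#' @param seed Integer seed.
#' @return Data frame (`patient_id`, `time`, `event`) with `event = 1` for
#'   observed default, 0 for censoring.
#' @export
generate_survival <- function(profiles, effects, params,
                              max_followups = 20, seed = 1) {
  stopifnot(inherits(params, "true_params"))
  max_followups <- check_count(max_followups, "max_followups")
  if (nrow(profiles) != nrow(effects))
    stop_validation("profiles and effects must have one row per patient")
  set.seed(seed)
  n <- nrow(profiles)
  lp <- rep(0, n)
  if (length(params$beta2)) {
    X2 <- build_design(profiles, names(params$beta2))
    lp <- as.vector(X2 %*% params$beta2[colnames(X2)])
  }
  W2 <- params$tau[1] * effects$nu0 + params$tau[2] * effects$nu1 +
    params$tau_b * effects$log_b + effects$frailty
  u <- runif(n)
  t_raw <- (-log(u) / (params$phi * exp(lp + W2)))^(1 / params$rho)
  event <- as.integer(t_raw <= max_followups)
  data.frame(patient_id = profiles$patient_id,
             time = pmin(t_raw, max_followups),
             event = event)
}

#' Drop longitudinal records after default or censoring
#'
#' Keeps, for each patient, only the scheduled visits whose visit index
#' does not exceed the (continuous) default/censoring time in visit units.
#'
#' @param long Longitudinal table.
#' @param surv Survival table from [generate_survival()].
#' @return The truncated longitudinal table.
#' @export
truncate_longitudinal <- function(long, surv) {
  tmax <- surv$time[match(long$patient_id, surv$patient_id)]
  out <- long[long$visit_index <= tmax, , drop = FALSE]
  attr(out, "schedule") <- attr(long, "schedule")
  rownames(out) <- NULL
  out
}

#' Apply MCAR dropout to a longitudinal table
#'
#' Flags each post-baseline record (visit index >= 2) as unobserved with
#' probability `miss_prob`, independently of every outcome and covariate;
#' the first visit is never removed.
#'
#' @param table Longitudinal table.
#' @param miss_prob Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The table with its `observed` column updated.
#' @export
apply_mcar <- function(table, miss_prob, seed = 1) {
  check_prob(miss_prob, "miss_prob", upper_open = TRUE)
  if (miss_prob == 0) return(table)
  set.seed(seed)
  eligible <- table$visit_index >= 2
  drop <- rbinom(nrow(table), 1, miss_prob) == 1 & eligible
  table$observed <- as.integer(table$observed == 1 & !drop)
  table
}

#' Simulate a complete joint cohort
#'
#' Composes the generator stages: covariates, latent effects, longitudinal
#' counts, default times (with truncation of post-default visits), and
#' MCAR dropout.  Stage seeds are derived deterministically from `seed`.
#'
#' @param n Cohort size (default 792).
#' @param params Generating parameters ([default_true_params()] preset).
#' @param marginals Covariate marginals.
#' @param schedule Visit schedule (months).
#' @param max_followups Administrative horizon in visit units.
#' @param miss_prob MCAR missingness probability.
#' @param seed Integer seed.
#' @return List of class `jm_cohort`: `covariates`, `longitudinal`,
#'   `survival`, `latent`, `params`, `schedule`, `seed`.
#' @export
simulate_cohort <- function(n = 792, params = default_true_params(),
                            marginals = table1_marginals(),
                            schedule = default_schedule(),
                            max_followups = length(schedule),
                            miss_prob = 0.1, seed = 1) {
  covariates <- generate_covariates(n, marginals, seed = seed)
  latent <- generate_latent_effects(n, params, seed = seed + 1)
  long <- generate_longitudinal(covariates, latent, params,
                                schedule = schedule, seed = seed + 2)
  surv <- generate_survival(covariates, latent, params,
                            max_followups = max_followups, seed = seed + 3)
  long <- truncate_longitudinal(long, surv)
  long <- apply_mcar(long, miss_prob, seed = seed + 4)
  structure(list(covariates = covariates, longitudinal = long,
                 survival = surv, latent = latent, params = params,
                 schedule = schedule, seed = seed),
            class = "jm_cohort")
}

#' @export
print.jm_cohort <- function(x, ...) {
  cat("Synthetic joint cohort:", nrow(x$covariates), "patients\n")
  cat("  longitudinal records:", nrow(x$longitudinal),
      sprintf("(%.1f%% flagged missing)",
              100 * mean(x$longitudinal$observed == 0)), "\n")
  cat("  defaults observed:", sum(x$survival$event), "of",
      nrow(x$survival), "\n")
  invisible(x)
}

#' Write a cohort to the three-CSV schema
#'
#' Writes `covariates.csv`, `longitudinal.csv` (long format) and
#' `survival.csv` into `dir`, with missing entries as empty fields.
#'
#' @param cohort A `jm_cohort` (or a bare list with the same tables).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("covariates.csv", "longitudinal.csv",
                            "survival.csv"))
  write.csv(cohort$covariates, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$longitudinal, paths[2], row.names = FALSE, na = "")
  write.csv(cohort$survival, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory holding the three CSV files.
#' @return List with `covariates`, `longitudinal`, `survival`.
#' @export
read_cohort <- function(dir) {
  cov <- read.csv(file.path(dir, "covariates.csv"),
                  stringsAsFactors = FALSE)
  lev <- covariate_levels()
  for (v in names(lev)) cov[[v]] <- factor(cov[[v]], levels = lev[[v]])
  list(covariates = cov,
       longitudinal = read.csv(file.path(dir, "longitudinal.csv")),
       survival = read.csv(file.path(dir, "survival.csv")))
}
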