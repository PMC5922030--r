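## Cohort presets: covariate marginals, visit schedule, and the default
## generating parameters used throughout the package's simulation studies.

#' Default covariate marginals for the synthetic cohort
#'
#' Category frequencies and median/quartile summaries matching the published
#' descriptive statistics of the 792-patient HAART cohort the package's
#' models were developed for (50.6\% female, 40.9\% rural, 68.2\% good
#' adherence, 72.6\% disclosed, etc.).  Continuous variables are summarised
#' by \code{c(median, q1, q3)} and simulated log-normally from those
#' quartiles; age is truncated at 18 years (adult cohort).
#'
#' @return A named list: each categorical entry is a named probability
#'   vector (summing to 1), each continuous entry a numeric
#'   \code{c(median, q1, q3)}.
#' @export
table1_marginals <- function() {
  list(
    sex        = c(male = 0.494, female = 0.506),
    residence  = c(urban = 0.591, rural = 0.409),
    marital    = c(without_partner = 0.552, with_partner = 0.448),
    education  = c(none = 0.202, primary = 0.259, secondary = 0.345,
                   tertiary = 0.194),
    income     = c(low = 0.448, middle = 0.437, high = 0.115),
    who_stage  = c(stage1 = 0.128, stage2 = 0.326, stage3 = 0.251,
                   stage4 = 0.295),
    cellphone  = c(yes = 0.505, no = 0.495),
    disclosure = c(yes = 0.726, no = 0.274),
    adherence  = c(good = 0.682, fair = 0.202, poor = 0.116),
    age          = c(median = 36, q1 = 28, q3 = 48),
    weight       = c(median = 62, q1 = 58, q3 = 70),
    baseline_cd4 = c(median = 150, q1 = 113, q3 = 198)
  )
}

#' Default follow-up visit schedule
#'
#' Visit times in months on therapy: monthly for the first six months, then
#' quarterly to an administrative horizon of `n_visits` scheduled visits
#' (default 20, roughly a four-year study window).
#'
#' @param n_visits Number of scheduled visits (>= 1).
#' @return Numeric vector of strictly increasing visit times (months).
#' @export
default_schedule <- function(n_visits = 20) {
  n_visits <- check_count(n_visits, "n_visits")
  times <- c(1:6, seq(9, by = 3, length.out = max(0, n_visits - 6)))
  times[seq_len(n_visits)]
}

## Standardize visit times against a reference schedule so that the "time"
## coefficient has a stable meaning across generation and fitting.
standardize_time <- function(times, schedule) {
  (times - mean(schedule)) / sd(schedule)
}

#' Construct (and validate) a set of true generating parameters
#'
#' Bundles the parameters of the joint generating model: fixed effects of
#' the longitudinal log-mean (`beta1`, named after design columns, with
#' `time` the standardized visit time), fixed effects of the survival
#' log-hazard (`beta2`), the covariance of the random intercept/slope
#' (`Sigma_nu`), the variance of the patient log-dispersion (`sigma_b2`),
#' the frailty variance (`sigma_nu2`), association loadings `tau`
#' (on the random intercept and slope) and `tau_b` (on the log-dispersion),
#' and the Weibull shape `rho` and scale `phi`.
#'
#' @param beta1,beta2 Named numeric vectors of fixed effects.
#' @param Sigma_nu 2x2 symmetric positive-definite covariance matrix.
#' @param sigma_b2,sigma_nu2 Non-negative variances.
#' @param sigma_eps2 Baseline visit-level variance scale: patient i's
#'   dispersion is `b_i = sigma_eps2 * exp(log_b_i)`.  The default 1 is
#'   the reference heterogeneous model (log-dispersion centred at 0); 0
#'   switches the visit-level perturbation off entirely (pure Poisson
#'   limit).
#' @param tau Length-2 numeric: loadings on (intercept, slope).
#' @param tau_b Loading on the patient log-dispersion.
#' @param rho,phi Positive Weibull shape and scale.
#' @return An object of class `true_params` (a validated list).
#' @export
true_params <- function(beta1, beta2 = numeric(0),
                        Sigma_nu = diag(c(0, 0)),
                        sigma_b2 = 0, sigma_nu2 = 0, sigma_eps2 = 1,
                        tau = c(0, 0), tau_b = 0,
                        rho = 1, phi = 1) {
  if (is.null(names(beta1)) || any(!nzchar(names(beta1))))
    stop_validation("beta1 must be a fully named numeric vector")
  if (length(beta2) && (is.null(names(beta2)) || any(!nzchar(names(beta2)))))
    stop_validation("beta2 must be named when non-empty")
  Sigma_nu <- as.matrix(Sigma_nu)
  if (!identical(dim(Sigma_nu), c(2L, 2L)))
    stop_validation("Sigma_nu must be 2x2")
  zero <- all(abs(Sigma_nu) < 1e-14)
  if (!zero && !is_pd(Sigma_nu))
    stop_validation("Sigma_nu must be symmetric positive-definite (or all zero)")
  if (sigma_b2 < 0 || sigma_nu2 < 0 || sigma_eps2 < 0)
    stop_validation("sigma_b2, sigma_nu2 and sigma_eps2 must be >= 0")
  if (rho <= 0 || phi <= 0) stop_validation("rho and phi must be > 0")
  if (length(tau) != 2) stop_validation("tau must have length 2")
  structure(list(beta1 = beta1, beta2 = beta2, Sigma_nu = Sigma_nu,
                 sigma_b2 = sigma_b2, sigma_nu2 = sigma_nu2,
                 sigma_eps2 = sigma_eps2,
                 tau = as.numeric(tau), tau_b = as.numeric(tau_b),
                 rho = rho, phi = phi),
            class = "true_params")
}

#' Default true-parameter preset
#'
#' The package-wide simulation preset.  Values reported by the reference
#' joint analysis are used where available: longitudinal intercept 4.13,
#' age slope -0.036, female effect 0.023, fair/poor adherence -0.552/-0.483,
#' time slope 0.121; Var(nu0) = 0.862, Var(nu1) = 0.011, Cov = -0.064;
#' association loadings tau1 = -2.324 (random slope) and tau_b = 0.051
#' (log-dispersion); Weibull shape rho = 0.864.  Remaining quantities
#' (survival fixed effects, tau0, sigma_b2, sigma_nu2, phi) are unreported
#' and fixed once at realistic values; see the methods vignette.
#'
#' @return A `true_params` object.
#' @export
default_true_params <- function() {
  true_params(
    beta1 = c("(Intercept)" = 4.13, age = -0.036, sex_female = 0.023,
              adherence_fair = -0.552, adherence_poor = -0.483,
              time = 0.121),
    beta2 = c(age = -0.02, sex_female = -0.1,
              adherence_fair = 0.25, adherence_poor = 0.35),
    Sigma_nu = matrix(c(0.862, -0.064, -0.064, 0.011), 2, 2),
    sigma_b2 = 0.25, sigma_nu2 = 0.1,
    tau = c(-0.25, -2.324), tau_b = 0.051,
    rho = 0.864, phi = 0.25
  )
}

## Names of the categorical covariates and their level sets.
covariate_levels <- function() {
  list(sex = c("male", "female"),
       residence = c("urban", "rural"),
       marital = c("without_partner", "with_partner"),
       education = c("none", "primary", "secondary", "tertiary"),
       income = c("low", "middle", "high"),
       who_stage = c("stage1", "stage2", "stage3", "stage4"),
       cellphone = c("yes", "no"),
       disclosure = c("yes", "no"),
       adherence = c("good", "fair", "poor"))
}

#' Fixed-effect design matrix for the cohort covariates
#'
#' Builds the reference-coded design columns used by both the generator and
#' the fitting functions.  Available columns: `(Intercept)`, `age`,
#' `weight`, `baseline_cd4`, `sex_female`, `rural`, `with_partner`,
#' `edu_none`, `edu_primary`, `edu_secondary` (ref tertiary), `income_low`,
#' `income_middle` (ref high), `who_stage1`..`who_stage3` (ref stage 4),
#' `no_cellphone`, `no_disclosure`, `adherence_fair`, `adherence_poor`
#' (ref good).
#'
#' @param covariates Covariate data frame as produced by
#'   [generate_covariates()].
#' @param terms Character vector of column names to build ("time" entries
#'   are ignored here; visit time is appended by the callers that need it).
#' @return Numeric matrix with one row per patient.
#' @export
build_design <- function(covariates, terms) {
  terms <- setdiff(terms, "time")
  n <- nrow(covariates)
  cols <- list(
    "(Intercept)"   = function(d) rep(1, n),
    age             = function(d) d$age,
    weight          = function(d) d$weight,
    baseline_cd4    = function(d) d$baseline_cd4,
    sex_female      = function(d) as.numeric(d$sex == "female"),
    rural           = function(d) as.numeric(d$residence == "rural"),
    with_partner    = function(d) as.numeric(d$marital == "with_partner"),
    edu_none        = function(d) as.numeric(d$education == "none"),
    edu_primary     = function(d) as.numeric(d$education == "primary"),
    edu_secondary   = function(d) as.numeric(d$education == "secondary"),
    income_low      = function(d) as.numeric(d$income == "low"),
    income_middle   = function(d) as.numeric(d$income == "middle"),
    who_stage1      = function(d) as.numeric(d$who_stage == "stage1"),
    who_stage2      = function(d) as.numeric(d$who_stage == "stage2"),
    who_stage3      = function(d) as.numeric(d$who_stage == "stage3"),
    no_cellphone    = function(d) as.numeric(d$cellphone == "no"),
    no_disclosure   = function(d) as.numeric(d$disclosure == "no"),
    adherence_fair  = function(d) as.numeric(d$adherence == "fair"),
    adherence_poor  = function(d) as.numeric(d$adherence == "poor")
  )
  unknown <- setdiff(terms, names(cols))
  if (length(unknown))
    stop_validation("unknown design terms: ", paste(unknown, collapse = ", "))
  X <- vapply(terms, function(tm) cols[[tm]](covariates), numeric(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, terms))
  X
}
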