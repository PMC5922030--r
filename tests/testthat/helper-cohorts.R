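# Shared fixtures, built in code at test time.

# Small preset cohort for fitting tests.
small_cohort <- function(n = 150, seed = 42, miss_prob = 0.1,
                         params = default_true_params()) {
  simulate_cohort(n = n, params = params, miss_prob = miss_prob, seed = seed)
}

# Parameters with every latent source switched off (pure Poisson counts).
null_params <- function(beta1 = c("(Intercept)" = log(16))) {
  true_params(beta1 = beta1, Sigma_nu = diag(c(0, 0)), sigma_b2 = 0,
              sigma_nu2 = 0, sigma_eps2 = 0, tau = c(0, 0), tau_b = 0,
              rho = 1, phi = 1)
}

# Fast sampler settings for smoke-level MCMC tests.
quick_mcmc <- function(seed = 1, iter = 1200, burn = 600) {
  mcmc_settings(chains = 1, iter = iter, burn = burn, thin = 2, seed = seed)
}
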