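# Random intake profiles over the 14 PHD components, for property tests.
random_intake_profiles <- function(n, seed = 1, energy_range = c(1200, 3500)) {
  set.seed(seed)
  comps <- phd_components()
  d <- as.data.frame(matrix(stats::rlnorm(n * length(comps),
                                          log(60), 1.2),
                            n, length(comps),
                            dimnames = list(NULL, comps)))
  d$energy <- stats::runif(n, energy_range[1], energy_range[2])
  d
}

# Small right-censored dataset with continuous (untied) times.
random_survival_data <- function(n, p, seed, beta = NULL,
                                 censor_max = 12) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- stats::runif(p, -0.6, 0.6)
  eta <- drop(X %*% beta)
  t <- stats::rexp(n, 0.12 * exp(eta))
  cens <- stats::runif(n, 0, censor_max)
  d <- as.data.frame(X)
  d$fu <- pmin(t, cens)
  d$ev <- as.integer(t < cens)
  d
}

# Compact synthetic study shared by suite-level tests.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(n_participants = 8000, seed = 301,
                             effect_set = "phd")
      cache <<- simulate_study(cfg, with_genotypes = TRUE)
    }
    cache
  }
})
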