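# Builders and independent oracles shared across test files.

make_samples <- function(soil_cd, soil_ph, soybean_cd,
                         area = "low", id_prefix = "S") {
  n <- length(soil_cd)
  data.frame(
    sample_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    area = rep_len(area, n),
    soil_cd = soil_cd, soil_ph = soil_ph, soybean_cd = soybean_cd,
    stringsAsFactors = FALSE
  )
}

# random but physically valid cohort for plumbing tests
random_samples <- function(n = 20, seed = 1, area = "low") {
  set.seed(seed)
  make_samples(runif(n, 0.4, 3), runif(n, 4.5, 8), runif(n, 0.03, 0.9),
               area = area)
}

# Maximum standard deviation attainable by any distribution of the
# truncated-normal closure (exponentially tilted uniform) on [a, b] with a
# prescribed mean. Independent oracle: the tilt exp(theta * x) / Z has
# mean m(theta) and variance m'(theta); solve m(theta) = mean by uniroot
# and differentiate numerically.
tilted_uniform_sd_max <- function(mean, a, b) {
  m_of <- function(theta) {
    if (abs(theta) < 1e-8) return((a + b) / 2)
    # mean of density proportional to exp(theta x) on [a, b]
    num <- stats::integrate(function(x) x * exp(theta * (x - b)), a, b)$value
    den <- stats::integrate(function(x) exp(theta * (x - b)), a, b)$value
    num / den
  }
  theta <- stats::uniroot(function(t) m_of(t) - mean,
                          lower = -500 / (b - a),
                          upper = 500 / (b - a), tol = 1e-12)$root
  h <- 1e-4 / (b - a)
  sqrt((m_of(theta + h) - m_of(theta - h)) / (2 * h))
}

# concentration at which CR crosses the 1e-4 acceptability threshold
cr_threshold_conc <- function(params = exposure_params(),
                              target = 1e-4) {
  target * params$BW / (params$IR * params$mass_conversion * params$SF)
}
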