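# Truncated-normal utilities used by the synthetic-cohort generator.
#
# A marginal is specified by its truncated mean/sd on [lower, upper]; the
# generator needs the untruncated (mu, sigma) whose truncated moments match.
# Internally everything is parameterized by the standardized bounds
# alpha = (lower - mu)/sigma, beta = (upper - mu)/sigma, which stay
# well-conditioned even when the matching solution degenerates towards an
# exponentially tilted uniform (|mu| large, sigma large).

# Mean and sd of a normal(mu, sigma) truncated to [a, b].
tn_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  # reflect into the lower tail where pnorm/dnorm keep precision
  if (al + be > 0) {
    m <- tn_moments(-mu, sigma, -b, -a)
    return(c(mean = -m[["mean"]], sd = m[["sd"]]))
  }
  Z <- pnorm(be) - pnorm(al)
  h <- (dnorm(al) - dnorm(be)) / Z
  v <- 1 + (al * dnorm(al) - be * dnorm(be)) / Z - h^2
  c(mean = mu + sigma * h, sd = sigma * sqrt(max(v, 0)))
}

# Quantile function of the truncated normal, vectorized over p.
tn_quantile <- function(p, mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  if (al + be > 0) {
    return(-tn_quantile(1 - p, -mu, sigma, -b, -a))
  }
  pa <- pnorm(al)
  pb <- pnorm(be)
  q <- mu + sigma * qnorm(pa + p * (pb - pa))
  pmin(pmax(q, a), b)
}

# Solve for (mu, sigma) whose truncated moments best match (mean, sd) on
# [a, b]. Printed small-sample moments can exceed what any distribution
# confined to [a, b] can attain (the tilted-uniform variance bound), so the
# solve is weighted least squares rather than exact root finding: the mean
# residual is weighted 10x because every downstream dose quantity is linear
# in concentration, while sd only shapes the spread. Returns the attained
# moments and an `exact` flag.
tn_match <- function(mean, sd, a, b) {
  stopifnot(a < b, sd > 0, mean > a, mean < b)
  w <- b - a
  obj <- function(par) {
    al <- par[1]
    be <- al + exp(par[2])
    if (al < -33 || be > 33) return(1e6 + al^2 + be^2)
    sigma <- w / (be - al)
    mu <- a - al * sigma
    m <- tn_moments(mu, sigma, a, b)
    if (any(!is.finite(m))) return(1e6)
    10 * ((m[["mean"]] - mean) / w)^2 + ((m[["sd"]] - sd) / w)^2
  }
  sigma0 <- 1.5 * sd
  start <- c((a - mean) / sigma0,
             log((b - a) / sigma0))
  start[1] <- max(start[1], -30)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  al <- fit$par[1]
  be <- al + exp(fit$par[2])
  sigma <- w / (be - al)
  mu <- a - al * sigma
  got <- tn_moments(mu, sigma, a, b)
  list(mu = mu, sigma = sigma, lower = a, upper = b,
       target = c(mean = mean, sd = sd),
       attained = got,
       exact = abs(got[["mean"]] - mean) < 1e-5 * w &&
               abs(got[["sd"]] - sd) < 1e-5 * w)
}
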