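# Independent grid-integration oracle for the fixed-effects two-treatment
# model: every study has arms (A, B), logit p_i1 = mu_i, logit p_i2 = mu_i + d.
# The posterior of d marginalizes each mu_i by 1-D quadrature, so the oracle
# shares no code with the sampler.

grid_posterior_d <- function(data, mu_sd = 100, d_sd = 100,
                             d_grid = seq(-3, 3, length.out = 1201),
                             mu_grid = seq(-6, 6, length.out = 601)) {
  lbin <- function(r, n, theta) {
    p <- stats::plogis(theta)
    stats::dbinom(r, n, p, log = TRUE) # integer counts only in the oracle
  }
  studies <- split(data, data$study)
  log_post <- stats::dnorm(d_grid, 0, d_sd, log = TRUE)
  dmu <- diff(mu_grid[1:2])
  for (s in studies) {
    s <- s[order(s$treatment), ]
    # integrate the study baseline out for every d value
    contrib <- vapply(d_grid, function(d) {
      lk <- lbin(s$events[1], s$n[1], mu_grid) +
        lbin(s$events[2], s$n[2], mu_grid + d) +
        stats::dnorm(mu_grid, 0, mu_sd, log = TRUE)
      m <- max(lk)
      m + log(sum(exp(lk - m)) * dmu)
    }, numeric(1))
    log_post <- log_post + contrib
  }
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  cdf <- cumsum(w)
  qfun <- function(p) d_grid[which.min(abs(cdf - p))]
  list(grid = d_grid, weight = w,
       mean = sum(w * d_grid),
       sd = sqrt(sum(w * d_grid^2) - sum(w * d_grid)^2),
       q = qfun)
}

# Monte Carlo standard error of an empirical quantile: batch-means error of
# the exceedance indicator scaled by the estimated density at the quantile
mc_error_quantile <- function(x, p, batches = 50) {
  qhat <- stats::quantile(x, p, names = FALSE)
  ind <- as.numeric(x <= qhat)
  bs <- length(ind) %/% batches
  bm <- colMeans(matrix(ind[seq_len(bs * batches)], nrow = bs))
  se_cdf <- stats::sd(bm) / sqrt(batches)
  f <- stats::density(x, n = 512)
  fq <- max(stats::approx(f$x, f$y, xout = qhat)$y, 1e-8)
  se_cdf / fq
}

# plain batch-means standard error of a mean, independent of the package code
batch_se <- function(x, batches = 50) {
  bs <- length(x) %/% batches
  bm <- colMeans(matrix(x[seq_len(bs * batches)], nrow = bs))
  stats::sd(bm) / sqrt(batches)
}
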