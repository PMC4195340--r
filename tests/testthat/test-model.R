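test_that("log-likelihood matches closed-form binomial masses", {
  one <- nma_data(data.frame(study = "s", treatment = c("A", "B"),
                             events = c(1, 1), n = c(2, 2)))
  arr <- nma_arrays(one)
  fe <- nma_model("fixed")
  state <- list(mu = 0, d = 0) # p = 0.5 in both arms
  expect_equal(log_likelihood(arr, state, fe), 2 * log(0.5), tolerance = 1e-12)

  # full network, all parameters zero: independent binomials at p = 0.5
  arrT <- nma_arrays(hf_data())
  st0 <- list(mu = rep(0, arrT$ns), d = rep(0, arrT$nt - 1))
  direct <- sum(unlist(lapply(seq_len(arrT$ns), function(i) {
    k <- seq_len(arrT$na[i])
    dbinom(arrT$r[i, k], arrT$n[i, k], 0.5, log = TRUE)
  })))
  expect_equal(log_likelihood(arrT, st0, fe), direct, tolerance = 1e-9)

  # boundary guard: p -> 0 with events observed stays finite, never -Inf
  expect_lt(log_likelihood(arr, list(mu = -800, d = 0), fe), -700)
  ll <- log_likelihood(arr, list(mu = -Inf, d = 0), fe)
  expect_true(is.finite(ll) && ll < -1e9)

  # fractional corrected counts are accepted
  corr <- nma_arrays(correct_zero_cells(nma_data(data.frame(
    study = "s", treatment = c("A", "B"), events = c(0, 1), n = c(29, 29)))))
  expect_true(is.finite(log_likelihood(corr, list(mu = 0, d = 0), fe)))

  expect_error(log_likelihood(arr, list(mu = c(0, 0), d = 0), fe),
               "one entry per study")
})

test_that("multi-arm conditional decomposition has the exchangeable moments", {
  tri <- nma_data(data.frame(study = "s", treatment = c("A", "B", "C"),
                             events = c(5, 6, 7), n = 50))
  arr <- nma_arrays(tri)
  re <- nma_model("random")
  st <- list(mu = 0.1, d = c(-0.3, 0.2),
             delta = matrix(c(0, -0.3, 0.2), 1), sigma = 1)
  c2 <- conditional_delta(arr, st, re, 1, 2)
  expect_equal(c2$var, 1)         # two-arm case: unconditional variance
  expect_equal(c2$mean, -0.3)
  c3 <- conditional_delta(arr, st, re, 1, 3)
  expect_equal(c3$var, 0.75)      # sigma^2 * k/(2(k-1)) at k = 3
  expect_equal(c3$mean, 0.2)      # delta_2 at its mean: correction vanishes
  st$delta[1, 2] <- -0.3 + 0.4    # deviate delta_2 by +0.4
  expect_equal(conditional_delta(arr, st, re, 1, 3)$mean, 0.2 + 0.4 / 2)
  # matches the conditional of the joint exchangeable normal computed directly
  Sg <- matrix(c(1, 0.5, 0.5, 1), 2)
  cond_mean <- 0.2 + Sg[2, 1] / Sg[1, 1] * (st$delta[1, 2] - (-0.3))
  cond_var <- Sg[2, 2] - Sg[2, 1]^2 / Sg[1, 1]
  expect_equal(conditional_delta(arr, st, re, 1, 3)$mean, cond_mean)
  expect_equal(conditional_delta(arr, st, re, 1, 3)$var, cond_var)
  expect_error(conditional_delta(arr, st, re, 1, 1), "non-baseline")
  expect_error(conditional_delta(arr, st, nma_model("fixed"), 1, 2),
               "random-effects")
})

test_that("log-prior densities follow the configured priors", {
  toy <- toy2_data()
  arr <- nma_arrays(toy)
  re <- nma_model("random")
  st0 <- list(mu = rep(0, 2), d = 0, delta = matrix(0, 2, 2), sigma = 1)
  # all-zero state under vague priors: S + (K-1) normal log-densities at zero
  # + uniform sd density + two delta densities at their zero means
  expected <- 3 * dnorm(0, 0, 100, log = TRUE) + log(1 / 2) +
    2 * dnorm(0, 0, 1, log = TRUE)
  expect_equal(log_prior(st0, re, arr), expected, tolerance = 1e-12)
  # sd outside the uniform support
  st_out <- st0; st_out$sigma <- 2.5
  expect_identical(log_prior(st_out, re, arr), -Inf)
  # lognormal heterogeneity prior evaluates the transformed density
  ln <- nma_model("random", priors = nma_priors(het = het_lognormal(-2, 1)))
  st_ln <- st0; st_ln$sigma <- sqrt(exp(-2))
  got <- log_prior(st_ln, ln, arr)
  manual <- 3 * dnorm(0, 0, 100, log = TRUE) +
    dlnorm(exp(-2), -2, 1, log = TRUE) + log(2 * sqrt(exp(-2))) +
    sum(dnorm(0, 0, st_ln$sigma, log = TRUE) * 2)
  expect_equal(got, manual, tolerance = 1e-12)
  # log-posterior finite at interior states
  expect_true(is.finite(log_posterior(arr, st0, re)))
})

test_that("UME parameterization enumerates baseline-relative comparisons", {
  comps <- ume_comparisons(hf_data())
  ab <- function(lab) {
    m <- match(strsplit(lab, ":", fixed = TRUE)[[1]], hf_treatments)
    paste(LETTERS[m], collapse = "")
  }
  expect_setequal(vapply(comps$label, ab, character(1)),
                  c("AB", "AD", "AC", "AE", "CE", "CD")) # never BD
  single <- nma_data(data.frame(study = "s", treatment = c("A", "B"),
                                events = 1, n = 10))
  expect_equal(nrow(ume_comparisons(single)), 1L)
  twice <- nma_data(data.frame(study = c("s", "s", "z", "z"),
                               treatment = c("A", "B", "A", "B"),
                               events = 1, n = 10))
  expect_equal(nrow(ume_comparisons(twice)), 1L) # shared parameter
})

test_that("Turner prior lookup resolves configured category pairs", {
  pr <- turner_prior("all-cause mortality", "pharmacological vs placebo")
  expect_s3_class(pr, "nma_het_prior")
  expect_equal(pr$type, "lognormal")
  expect_error(turner_prior("nope", "nope"), "no unique prior")
  own <- data.frame(outcome = "x", comparison = "y",
                    meanlog = -3, sdlog = 1.2)
  expect_equal(turner_prior("x", "y", table = own)$meanlog, -3)
})

test_that("RE posterior degenerates to FE as the heterogeneity bound shrinks", {
  toy <- toy2_data()
  fe <- nma_mcmc(toy, nma_model("fixed"), quick_settings(seed = 5))
  re0 <- nma_mcmc(toy, nma_model("random",
                                 priors = nma_priors(het = het_uniform(0.001))),
                  quick_settings(seed = 5))
  m_fe <- mean(fit_draws(fe, "d[B]"))
  m_re <- mean(fit_draws(re0, "d[B]"))
  tol <- 3 * sqrt(batch_se(fit_draws(fe, "d[B]"))^2 +
                  batch_se(fit_draws(re0, "d[B]"))^2) + 0.01
  expect_lt(abs(m_fe - m_re), tol)
})

test_that("UME equals consistency comparison-wise on a loop-free network", {
  # two studies A-B and B-C: no closed loop, so no indirect pooling to differ
  ds <- nma_data(data.frame(study = rep(c("s1", "s2"), each = 2),
                            treatment = c("A", "B", "B", "C"),
                            events = c(10, 14, 12, 9), n = 60))
  cons <- nma_mcmc(ds, nma_model("fixed"), quick_settings(seed = 3))
  ume <- nma_mcmc(ds, nma_model("fixed", "ume"), quick_settings(seed = 4))
  # AB comparison
  ab_c <- fit_draws(cons, "d[B]")
  ab_u <- fit_draws(ume, "d[A:B]")
  expect_lt(abs(mean(ab_c) - mean(ab_u)),
            3 * sqrt(batch_se(ab_c)^2 + batch_se(ab_u)^2) + 0.01)
  # BC comparison: consistency d_C - d_B vs the UME B:C parameter
  bc_c <- fit_draws(cons, "d[C]") - fit_draws(cons, "d[B]")
  bc_u <- fit_draws(ume, "d[B:C]")
  expect_lt(abs(mean(bc_c) - mean(bc_u)),
            3 * sqrt(batch_se(bc_c)^2 + batch_se(bc_u)^2) + 0.01)
})
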