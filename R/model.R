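#' Prior configuration for the binomial-logit NMA models
#'
#' Vague normal priors on per-study baseline log-odds and on the basic
#' (log-odds-ratio) parameters, and a heterogeneity prior on the
#' between-study standard deviation: either uniform on sd (the customary
#' vague choice, `sd ~ Uniform(0, 2)`) or a lognormal prior on the
#' between-study *variance* for informative use.
#'
#' The vague normal priors default to mean 0 and variance 1e4 (sd 100).
#'
#' @param mu_var variance of the normal prior on study baselines \eqn{\mu_i}.
#' @param d_var variance of the normal prior on basic parameters \eqn{d_k}
#'   (and, under the inconsistency model, on each per-comparison mean effect).
#' @param het heterogeneity prior, from [het_uniform()] or [het_lognormal()].
#' @return A list of class `nma_priors`.
#' @export
nma_priors <- function(mu_var = 1e4, d_var = 1e4, het = het_uniform(2)) {
  stopifnot(mu_var > 0, d_var > 0, inherits(het, "nma_het_prior"))
  structure(list(mu_var = mu_var, d_var = d_var, het = het),
            class = "nma_priors")
}

#' @rdname nma_priors
#' @param upper upper bound of the uniform prior on the between-study sd.
#' @export
het_uniform <- function(upper = 2) {
  stopifnot(upper > 0)
  structure(list(type = "uniform", upper = upper), class = "nma_het_prior")
}

#' @rdname nma_priors
#' @param meanlog,sdlog parameters of the lognormal prior on the
#'   between-study variance \eqn{\sigma^2}.
#' @export
het_lognormal <- function(meanlog, sdlog) {
  stopifnot(is.finite(meanlog), sdlog > 0)
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "nma_het_prior")
}

#' Informative heterogeneity priors by outcome and comparison type
#'
#' Returns a lognormal prior on the between-study variance for a given
#' (outcome category, comparison category) pair, looked up from the table
#' shipped in `inst/extdata/turner_heterogeneity_priors.csv`. The table
#' carries predictive-distribution values for heterogeneity of log odds
#' ratios derived from the large empirical meta-epidemiological study of
#' Turner and colleagues; the shipped numbers are representative
#' transcriptions and the file is plain CSV so users can verify them against
#' the publication or substitute their own.
#'
#' @param outcome one of the outcome categories in the table
#'   (e.g. `"all-cause mortality"`, `"semi-objective"`, `"subjective"`).
#' @param comparison one of the comparison categories
#'   (e.g. `"pharmacological vs placebo"`).
#' @param table optional replacement table (data frame with columns
#'   `outcome`, `comparison`, `meanlog`, `sdlog`).
#' @return An `nma_het_prior` from [het_lognormal()].
#' @export
turner_prior <- function(outcome, comparison, table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "turner_heterogeneity_priors.csv",
                        package = "nmabayes")
    table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  hit <- table$outcome == outcome & table$comparison == comparison
  if (sum(hit) != 1L)
    stop("no unique prior for outcome '", outcome, "' / comparison '",
         comparison, "'; available: ",
         paste(unique(paste(table$outcome, table$comparison, sep = " / ")),
               collapse = "; "))
  het_lognormal(table$meanlog[hit], table$sdlog[hit])
}

#' Specify an NMA model
#'
#' The model family is the standard binomial-logit NMA:
#' \deqn{r_{ik} \sim \mathrm{Binomial}(p_{ik}, n_{ik}), \quad
#'       \mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}, \quad
#'       \delta_{i,\mathrm{baseline}} = 0,}
#' with fixed effects \eqn{\delta_{ik} = d_{t_{ik}} - d_{t_{i1}}} or random
#' effects \eqn{\delta_{ik}} drawn around those means with between-study sd
#' \eqn{\sigma} and pairwise within-study covariance \eqn{\sigma^2/2}
#' (multi-arm correlation). The consistency framework expresses every
#' contrast through basic parameters \eqn{d_2..d_K} (with \eqn{d_1 = 0});
#' the inconsistency (unrelated mean effects, UME) framework gives each
#' observed baseline-relative comparison its own independent mean effect.
#'
#' @param effect `"random"` or `"fixed"` treatment-effect structure.
#' @param framework `"consistency"` or `"ume"` (unrelated mean effects).
#' @param priors an [nma_priors] configuration.
#' @param direction is the outcome `"bad"` (e.g. death — lower odds better)
#'   or `"good"`? Affects ranking and reporting only, never the likelihood.
#' @return A list of class `nma_model`.
#' @export
nma_model <- function(effect = c("random", "fixed"),
                      framework = c("consistency", "ume"),
                      priors = nma_priors(),
                      direction = c("bad", "good")) {
  effect <- match.arg(effect)
  framework <- match.arg(framework)
  direction <- match.arg(direction)
  stopifnot(inherits(priors, "nma_priors"))
  if (effect == "fixed" && priors$het$type == "lognormal")
    warning("informative heterogeneity prior has no effect in a fixed-effects model")
  structure(list(effect = effect, framework = framework, priors = priors,
                 direction = direction), class = "nma_model")
}

#' @export
print.nma_model <- function(x, ...) {
  het <- if (x$priors$het$type == "uniform")
    sprintf("sd ~ Uniform(0, %g)", x$priors$het$upper)
  else
    sprintf("var ~ Lognormal(%g, %g^2)", x$priors$het$meanlog, x$priors$het$sdlog)
  cat(sprintf("Binomial-logit NMA model: %s effects, %s framework\n",
              x$effect, x$framework))
  cat(sprintf("  priors: mu ~ N(0, %g), d ~ N(0, %g)%s\n",
              x$priors$mu_var, x$priors$d_var,
              if (x$effect == "random") paste0(", ", het) else ""))
  cat("  outcome direction:", x$direction, "\n")
  invisible(x)
}

#' Enumerate unrelated-mean-effects comparison parameters
#'
#' One independent mean-effect parameter per distinct (study-baseline
#' treatment, non-baseline treatment) pair observed in the data; multi-arm
#' trials contribute parameters relative to their own baseline arm, so pairs
#' never observed baseline-relative get no parameter.
#'
#' @param x an [nma_data] or `nma_arrays` object.
#' @return A data frame with columns `base`, `trt` (treatment labels) and
#'   `label` (`"base:trt"`), one row per UME parameter, ordered by treatment
#'   index.
#' @export
ume_comparisons <- function(x) {
  arr <- if (inherits(x, "nma_arrays")) x else nma_arrays(x)
  pairs <- unique(do.call(rbind, lapply(seq_len(arr$ns), function(i) {
    k <- 2:arr$na[i]
    cbind(arr$t[i, 1], arr$t[i, k])
  })))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  data.frame(base = arr$treatments[pairs[, 1]],
             trt = arr$treatments[pairs[, 2]],
             label = paste(arr$treatments[pairs[, 1]],
                           arr$treatments[pairs[, 2]], sep = ":"),
             stringsAsFactors = FALSE)
}

# integer matrix mapping (study, arm>=2) -> 1-based UME parameter index
ume_cmap <- function(arr, comps = ume_comparisons(arr)) {
  key <- paste(match(comps$base, arr$treatments),
               match(comps$trt, arr$treatments), sep = ":")
  cmap <- matrix(0L, arr$ns, ncol(arr$t))
  for (i in seq_len(arr$ns))
    for (k in 2:arr$na[i])
      cmap[i, k] <- match(paste(arr$t[i, 1], arr$t[i, k], sep = ":"), key)
  cmap
}

# number of mean-effect parameters for a model on given arrays
n_effect_pars <- function(arr, model) {
  if (model$framework == "ume") nrow(ume_comparisons(arr)) else arr$nt - 1L
}

# labels of the mean-effect parameters
effect_par_labels <- function(arr, model) {
  if (model$framework == "ume") paste0("d[", ume_comparisons(arr)$label, "]")
  else paste0("d[", arr$treatments[-1], "]")
}

# linear predictor matrix theta[i,k] for a given state
state_theta <- function(arrays, state, model) {
  th <- matrix(NA_real_, arrays$ns, ncol(arrays$t))
  cmap <- if (model$framework == "ume") ume_cmap(arrays) else NULL
  dfull <- c(0, state$d) # consistency: d of treatment 1 is 0
  for (i in seq_len(arrays$ns)) {
    for (k in seq_len(arrays$na[i])) {
      off <- 0
      if (k > 1L) {
        if (model$effect == "random") off <- state$delta[i, k]
        else if (model$framework == "ume") off <- state$d[cmap[i, k]]
        else off <- dfull[arrays$t[i, k]] - dfull[arrays$t[i, 1]]
      }
      th[i, k] <- state$mu[i] + off
    }
  }
  th
}

#' Model log-likelihood
#'
#' Sum of binomial log-masses over all data points at the fitted
#' probabilities implied by a parameter state, using the log-Gamma continuous
#' extension of the binomial coefficient so fractional continuity-corrected
#' counts are well defined. Probabilities at the numerical boundary are
#' guarded to a large negative finite value rather than `-Inf`.
#'
#' @param arrays an `nma_arrays` object from [nma_arrays()].
#' @param state list with elements `mu` (length `ns`), `d` (length K-1 under
#'   consistency, or one per UME comparison), and for random-effects models
#'   `delta` (`ns` x max-arms matrix, baseline column ignored) and `sigma`.
#' @param model an [nma_model].
#' @return Finite scalar log-likelihood.
#' @export
log_likelihood <- function(arrays, state, model) {
  check_state(arrays, state, model)
  th <- state_theta(arrays, state, model)
  ll <- 0
  for (i in seq_len(arrays$ns)) {
    k <- seq_len(arrays$na[i])
    r <- arrays$r[i, k]; n <- arrays$n[i, k]; theta <- th[i, k]
    lp <- ifelse(theta > 0, -log1p(exp(-theta)), theta - log1p(exp(theta)))
    lq <- ifelse(theta > 0, -theta - log1p(exp(-theta)), -log1p(exp(theta)))
    lc <- lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
    contrib <- lc + r * lp + (n - r) * lq
    contrib[!is.finite(contrib)] <- -1e10
    ll <- ll + sum(contrib)
  }
  ll
}

check_state <- function(arrays, state, model) {
  if (length(state$mu) != arrays$ns)
    stop("state$mu must have one entry per study")
  nd <- n_effect_pars(arrays, model)
  if (length(state$d) != nd)
    stop("state$d must have length ", nd, " for this model")
  if (model$effect == "random") {
    if (is.null(state$delta) || is.null(state$sigma))
      stop("random-effects state requires delta and sigma")
    if (!all(dim(state$delta) >= c(arrays$ns, max(arrays$na))))
      stop("state$delta dimension mismatch")
  }
  invisible(TRUE)
}

#' Model log-prior
#'
#' Sum of log prior densities at a parameter state: normal on each study
#' baseline and each mean-effect parameter, plus (random effects) the
#' trial-specific-effect densities under the exchangeable multi-arm
#' decomposition and the heterogeneity prior on \eqn{\sigma}. States outside
#' the heterogeneity-prior support return `-Inf`.
#'
#' @inheritParams log_likelihood
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(state, model, arrays) {
  check_state(arrays, state, model)
  pr <- model$priors
  lp <- sum(stats::dnorm(state$mu, 0, sqrt(pr$mu_var), log = TRUE)) +
        sum(stats::dnorm(state$d, 0, sqrt(pr$d_var), log = TRUE))
  if (model$effect == "random") {
    sg <- state$sigma
    lp <- lp + if (pr$het$type == "uniform") {
      if (sg >= 0 && sg <= pr$het$upper) -log(pr$het$upper) else -Inf
    } else {
      if (sg > 0)
        stats::dlnorm(sg^2, pr$het$meanlog, pr$het$sdlog, log = TRUE) +
          log(2 * sg)
      else -Inf
    }
    if (is.finite(lp)) {
      cmap <- if (model$framework == "ume") ume_cmap(arrays) else NULL
      dfull <- c(0, state$d)
      for (i in seq_len(arrays$ns)) {
        cum <- 0
        for (k in 2:arrays$na[i]) {
          m <- if (model$framework == "ume") state$d[cmap[i, k]]
               else dfull[arrays$t[i, k]] - dfull[arrays$t[i, 1]]
          if (model$framework == "ume") {
            v <- sg^2
          } else {
            cd <- conditional_moments(m, cum, k - 1L, sg)
            m <- cd$mean; v <- cd$var
          }
          lp <- lp + stats::dnorm(state$delta[i, k], m, sqrt(v), log = TRUE)
          if (model$framework != "ume")
            cum <- cum + state$delta[i, k] -
              (dfull[arrays$t[i, k]] - dfull[arrays$t[i, 1]])
        }
      }
    }
  }
  lp
}

# conditional mean/variance of delta at arm position p = j + 1 given the
# previous j - 1 non-baseline deltas (cum = running sum of their deviations)
conditional_moments <- function(basic_mean, cum, j, sigma) {
  list(mean = basic_mean + cum / j,
       var = sigma^2 * (j + 1) / (2 * j))
}

#' Log-posterior (up to a constant)
#'
#' @inheritParams log_likelihood
#' @return `log_likelihood + log_prior`.
#' @export
log_posterior <- function(arrays, state, model) {
  lp <- log_prior(state, model, arrays)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(arrays, state, model)
}

#' Conditional distribution of a trial-specific effect
#'
#' Under the homogeneous-variance exchangeable random-effects model the
#' trial-specific log odds ratios of a multi-arm study are jointly normal
#' with variance \eqn{\sigma^2} and pairwise covariance \eqn{\sigma^2/2}.
#' This returns the normal conditional for the effect at arm position `k`
#' (\eqn{k \ge 2}) given the effects at positions 2..k-1:
#' mean \eqn{(d_{t_{ik}} - d_{t_{i1}}) + \frac{1}{k-1}\sum_{j<k}
#' [\delta_{ij} - (d_{t_{ij}} - d_{t_{i1}})]} and variance
#' \eqn{\sigma^2 k / (2(k-1))}. At `k = 2` it reduces to the unconditional
#' \eqn{N(d_{t_{i2}} - d_{t_{i1}}, \sigma^2)}.
#'
#' @inheritParams log_likelihood
#' @param study study index (row of the arrays).
#' @param arm arm position within the study, 2-based (never the baseline).
#' @return List with elements `mean` and `var`.
#' @export
conditional_delta <- function(arrays, state, model, study, arm) {
  if (model$effect != "random")
    stop("conditional_delta applies to random-effects models")
  if (arm < 2L || arm > arrays$na[study])
    stop("arm must be a non-baseline arm position of the study")
  dfull <- c(0, state$d)
  bm <- function(k) dfull[arrays$t[study, k]] - dfull[arrays$t[study, 1]]
  cum <- 0
  if (arm > 2L)
    for (j in 2:(arm - 1L)) cum <- cum + state$delta[study, j] - bm(j)
  conditional_moments(bm(arm), cum, arm - 1L, state$sigma)
}
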