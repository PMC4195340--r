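#' Potential scale reduction factor (Brooks-Gelman-Rubin)
#'
#' Classic PSRF comparing within-chain and between-chain variances on the
#' retained draws:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \cdot W + B/n}{W}}}
#' with `W` the mean within-chain variance and `B/n` the variance of the
#' chain means. Values close to 1 indicate approximate convergence.
#'
#' @param fit an `nma_fit` (needs >= 2 chains with >= 4 retained draws).
#' @param parameters parameter names; defaults to the mean-effect parameters
#'   plus `sigma` when present.
#' @return Named numeric vector of PSRF values.
#' @export
psrf <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  parameters <- default_diag_pars(fit, parameters)
  vapply(parameters, function(p) {
    m <- fit_draws(fit, p, pooled = FALSE)
    n <- nrow(m)
    if (ncol(m) < 2L || n < 4L) stop("PSRF needs >= 2 chains of >= 4 draws")
    W <- mean(apply(m, 2, stats::var))
    if (W == 0) stop("zero within-chain variance for '", p,
                     "': degenerate constant chains")
    B_over_n <- stats::var(colMeans(m))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
}

#' Monte Carlo standard error (batch means)
#'
#' Chains are concatenated and split into `batches` equal batches (a
#' trailing remainder is dropped); the MC error is
#' `sd(batch means) / sqrt(batches)`. The conventional adequacy rule asks
#' the MC error to be below 5% of the posterior sd.
#'
#' @inheritParams psrf
#' @param batches number of batches (default 50).
#' @return Named numeric vector of MC errors.
#' @export
mc_error <- function(fit, parameters = NULL, batches = 50) {
  stopifnot(inherits(fit, "nma_fit"))
  parameters <- default_diag_pars(fit, parameters)
  vapply(parameters, function(p) {
    x <- fit_draws(fit, p)
    if (length(x) < 100L) stop("MC error needs >= 100 retained draws")
    bs <- length(x) %/% batches
    x <- x[seq_len(bs * batches)]
    bm <- colMeans(matrix(x, nrow = bs))
    stats::sd(bm) / sqrt(batches)
  }, numeric(1))
}

default_diag_pars <- function(fit, parameters) {
  if (!is.null(parameters)) return(parameters)
  pars <- dimnames(fit$draws)[[2]]
  c(grep("^d\\[", pars, value = TRUE), intersect("sigma", pars))
}

#' Convergence report
#'
#' Per-parameter PSRF, posterior sd, MC error and the 5%-of-sd rule; the
#' overall flag passes only when every monitored effect estimate (and the
#' between-study sd, when present) satisfies the rule.
#'
#' @inheritParams mc_error
#' @return Object of class `nma_convergence`: data frame (`parameter`,
#'   `psrf`, `sd`, `mc_error`, `mc_rule_pass`) with attribute
#'   `overall_pass`.
#' @export
convergence <- function(fit, parameters = NULL, batches = 50) {
  parameters <- default_diag_pars(fit, parameters)
  sds <- vapply(parameters, function(p) stats::sd(fit_draws(fit, p)),
                numeric(1))
  mce <- mc_error(fit, parameters, batches)
  rep <- data.frame(parameter = parameters, psrf = psrf(fit, parameters),
                    sd = sds, mc_error = mce,
                    mc_rule_pass = mce < 0.05 * sds,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(rep, overall_pass = all(rep$mc_rule_pass),
            class = c("nma_convergence", "data.frame"))
}

#' @export
print.nma_convergence <- function(x, ...) {
  cat("Convergence diagnostics (MC-error rule: mc_error < 5% of sd)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Residual deviance of binomial data points
#'
#' Saturated-model deviance contribution of each data point,
#' \deqn{dev = 2[r \ln(r/\hat r) + (n-r)\ln((n-r)/(n-\hat r))]}
#' with \eqn{\hat r = n p} and the convention \eqn{0 \ln 0 = 0}. A
#' well-fitting point contributes about 1.
#'
#' @param r observed events (vectorized).
#' @param n sample sizes.
#' @param p fitted probabilities, strictly inside (0, 1).
#' @return Numeric vector of deviance contributions.
#' @export
residual_deviance <- function(r, n, p) {
  if (any(p <= 0 | p >= 1)) stop("fitted probabilities must lie in (0, 1)")
  m <- max(length(r), length(n), length(p))
  r <- rep_len(r, m); n <- rep_len(n, m); p <- rep_len(p, m)
  rhat <- n * p
  t1 <- ifelse(r > 0, r * log(r / rhat), 0)
  t2 <- ifelse(n - r > 0, (n - r) * log((n - r) / (n - rhat)), 0)
  2 * (t1 + t2)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the total residual deviance; `Dhat` the
#' deviance at the posterior means of the fitted probabilities; `pD = Dbar -
#' Dhat` the effective number of parameters; `DIC = Dbar + pD`. Per-point
#' posterior mean deviances (which sum to `Dbar`) are returned labeled by
#' (study, treatment) for model criticism.
#'
#' @param fit an `nma_fit` whose monitors include the fitted probabilities.
#' @return Object of class `nma_dic`: list with `Dbar`, `pD`, `DIC`, and
#'   `points` (data frame `study`, `treatment`, `dev`).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  arrays <- fit$arrays
  pars <- dimnames(fit$draws)[[2]]
  ppar <- grep("^p\\[", pars, value = TRUE)
  if (length(ppar) != arrays$nobs)
    stop("fit does not monitor the per-data-point fitted probabilities")
  if (arrays$corrected)
    warning("fit statistics computed on continuity-corrected data can look ",
            "artificially favorable; interpret with caution")
  r <- unlist(lapply(seq_len(arrays$ns), function(i)
    arrays$r[i, seq_len(arrays$na[i])]))
  n <- unlist(lapply(seq_len(arrays$ns), function(i)
    arrays$n[i, seq_len(arrays$na[i])]))
  lab <- do.call(rbind, lapply(seq_len(arrays$ns), function(i)
    data.frame(study = arrays$study[i],
               treatment = arrays$treatments[arrays$t[i, seq_len(arrays$na[i])]],
               stringsAsFactors = FALSE)))
  # pooled draws matrix: (iterations*chains) x data points
  pm <- do.call(rbind, lapply(seq_len(dim(fit$draws)[3]), function(ch)
    fit$draws[, ppar, ch, drop = TRUE]))
  dev_draws <- sapply(seq_along(ppar), function(j)
    residual_deviance(r[j], n[j], pm[, j]))
  per_point <- colMeans(dev_draws)
  Dbar <- sum(per_point)
  Dhat <- sum(residual_deviance(r, n, colMeans(pm)))
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, pD = pD, DIC = Dbar + pD,
                 points = cbind(lab, dev = per_point)),
            class = "nma_dic")
}

#' @export
print.nma_dic <- function(x, ...) {
  cat(sprintf("Dbar = %.2f  pD = %.2f  DIC = %.2f  (%d data points)\n",
              x$Dbar, x$pD, x$DIC, nrow(x$points)))
  invisible(x)
}

#' Dev-dev inconsistency table
#'
#' Pairs the per-data-point posterior mean deviances of a consistency fit
#' and an inconsistency (UME) fit of the same data — the numbers behind the
#' customary dev-dev scatter, where points that fit clearly better under the
#' inconsistency model (bottom-right of the plot) flag potential
#' inconsistency. Every point is labeled with its study and treatment so it
#' can be identified.
#'
#' @param fit_cons consistency-model `nma_fit` (or its [dic()]).
#' @param fit_incons inconsistency-model `nma_fit` (or its [dic()]) over the
#'   same data.
#' @param margin flag a point when its consistency deviance exceeds its
#'   inconsistency deviance by more than this many deviance units.
#' @return Data frame of class `nma_devdev` with columns `study`,
#'   `treatment`, `dev_consistency`, `dev_inconsistency`, `flag`.
#' @export
devdev_table <- function(fit_cons, fit_incons, margin = 1) {
  dc <- if (inherits(fit_cons, "nma_dic")) fit_cons else dic(fit_cons)
  di <- if (inherits(fit_incons, "nma_dic")) fit_incons else dic(fit_incons)
  if (!identical(dc$points[c("study", "treatment")],
                 di$points[c("study", "treatment")]))
    stop("fits cover different data-point sets")
  out <- data.frame(study = dc$points$study, treatment = dc$points$treatment,
                    dev_consistency = dc$points$dev,
                    dev_inconsistency = di$points$dev,
                    stringsAsFactors = FALSE)
  out$flag <- out$dev_consistency - out$dev_inconsistency > margin
  class(out) <- c("nma_devdev", "data.frame")
  out
}
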