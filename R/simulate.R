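#' Design a synthetic NMA simulation
#'
#' Describes a forward simulation from the random-effects consistency model:
#' per study a baseline log-odds drawn uniformly from
#' `baseline_logodds_range`, trial-specific log odds ratios drawn *jointly*
#' from the exchangeable multivariate normal (variance `true_sigma^2`,
#' pairwise covariance `true_sigma^2 / 2`) around the consistency means, and
#' binomial event counts at the implied probabilities. Drawing the effects
#' jointly (rather than via the sequential conditionals the sampler uses)
#' makes recovery tests an independent check of that decomposition.
#'
#' @param K number of treatments.
#' @param S number of studies.
#' @param true_d true basic parameters (length K-1; `d` of treatment 1 is 0).
#' @param true_sigma true between-study sd.
#' @param design list of per-study treatment-index vectors. Default: each
#'   study compares treatment 1 with one non-reference treatment, cycling so
#'   the network is connected.
#' @param baseline_logodds_range interval for study baseline log-odds.
#' @param arm_size_range integer interval for per-arm sample sizes.
#' @param seed RNG seed; the simulated dataset is deterministic given it.
#' @param inconsistency_bump scalar added to the trial-specific effects of
#'   non-baseline-vs-baseline comparisons in studies whose baseline is not
#'   treatment 1 — a simple way to inject loop inconsistency for dev-dev
#'   testing. Default 0 (consistent network).
#' @return List of class `nma_design`.
#' @export
nma_design <- function(K, S, true_d, true_sigma,
                       design = NULL,
                       baseline_logodds_range = c(-2, -0.5),
                       arm_size_range = c(200, 400),
                       seed = 1, inconsistency_bump = 0) {
  stopifnot(K >= 2, S >= 1, length(true_d) == K - 1, true_sigma >= 0)
  if (is.null(design))
    design <- lapply(seq_len(S), function(i) c(1L, 2L + (i - 1L) %% (K - 1L)))
  stopifnot(length(design) == S)
  if (!all(sort(unique(unlist(design))) %in% seq_len(K)))
    stop("design references unknown treatments")
  if (length(unique(unlist(design))) < K)
    stop("design does not use all K treatments")
  structure(list(K = K, S = S, true_d = true_d, true_sigma = true_sigma,
                 design = design,
                 baseline_logodds_range = baseline_logodds_range,
                 arm_size_range = arm_size_range, seed = seed,
                 inconsistency_bump = inconsistency_bump),
            class = "nma_design")
}

#' Simulate an NMA dataset with known truth
#'
#' @param design an [nma_design].
#' @return An [nma_data] object with treatments labeled `T1..TK` and
#'   attributes `"true_d"`, `"true_sigma"` and `"true_delta"` (the simulated
#'   trial-specific effects, studies in rows).
#' @export
#' @examples
#' des <- nma_design(K = 3, S = 6, true_d = c(-0.5, 0.2), true_sigma = 0.2,
#'                   seed = 7)
#' simulate_nma(des)
simulate_nma <- function(design) {
  stopifnot(inherits(design, "nma_design"))
  set.seed(design$seed)
  dfull <- c(0, design$true_d)
  trts <- paste0("T", seq_len(design$K))
  maxa <- max(lengths(design$design))
  true_delta <- matrix(NA_real_, design$S, maxa)
  rows <- vector("list", design$S)
  for (i in seq_len(design$S)) {
    ts <- sort(design$design[[i]])
    A <- length(ts)
    mu <- stats::runif(1, design$baseline_logodds_range[1],
                       design$baseline_logodds_range[2])
    means <- dfull[ts[-1]] - dfull[ts[1]]
    if (design$inconsistency_bump != 0 && ts[1] != 1L)
      means <- means + design$inconsistency_bump
    delta <- c(0, draw_exchangeable(means, design$true_sigma))
    true_delta[i, seq_len(A)] <- delta
    n <- round(stats::runif(A, design$arm_size_range[1],
                            design$arm_size_range[2]))
    p <- stats::plogis(mu + delta)
    r <- stats::rbinom(A, n, p)
    rows[[i]] <- data.frame(study = sprintf("sim%02d", i),
                            treatment = trts[ts], events = r, n = n,
                            stringsAsFactors = FALSE)
  }
  out <- nma_data(do.call(rbind, rows), treatments = trts, reference = 1,
                  warn_limits = FALSE)
  attr(out, "true_d") <- design$true_d
  attr(out, "true_sigma") <- design$true_sigma
  attr(out, "true_delta") <- true_delta
  out
}

# joint draw from N(means, Sigma) with Sigma = sigma^2 on the diagonal and
# sigma^2/2 off-diagonal (exchangeable compound symmetry); uses the
# common-factor representation u + e rather than sequential conditionals
draw_exchangeable <- function(means, sigma) {
  m <- length(means)
  if (m == 0L) return(numeric(0))
  if (sigma == 0) return(means)
  u <- stats::rnorm(1, 0, sigma * sqrt(1 / 2))
  means + u + stats::rnorm(m, 0, sigma * sqrt(1 / 2))
}
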