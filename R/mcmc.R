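#' MCMC settings
#'
#' @param n_chains number of independent chains (at least 2; convergence
#'   diagnostics need multiple chains). Default 3.
#' @param n_burnin burn-in iterations discarded per chain (adaptation happens
#'   here only).
#' @param n_sample post-burn-in iterations per chain.
#' @param thin retention stride (>= 1); retained length is `n_sample / thin`.
#' @param init_range_mu interval for uniform random initial baseline
#'   log-odds.
#' @param init_range_d interval for uniform random initial log odds ratios.
#' @param seed base seed; chain `c` uses `seed + c`, making every draw
#'   reproducible.
#' @return List of class `nma_settings`.
#' @export
nma_settings <- function(n_chains = 3, n_burnin = 20000, n_sample = 40000,
                         thin = 1, init_range_mu = c(-2, 2),
                         init_range_d = c(-2, 2), seed = 1) {
  stopifnot(n_chains >= 2, n_burnin >= 0, n_sample >= thin, thin >= 1,
            length(init_range_mu) == 2, diff(init_range_mu) > 0,
            length(init_range_d) == 2, diff(init_range_d) > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_sample = as.integer(n_sample), thin = as.integer(thin),
                 init_range_mu = init_range_mu, init_range_d = init_range_d,
                 seed = as.integer(seed)),
            class = "nma_settings")
}

#' Random initial values for one chain
#'
#' Baselines and mean-effect parameters are drawn uniformly from the
#' configured ranges; trial-specific effects start at their conditional
#' means; the between-study sd starts uniformly over the central half of its
#' prior mass. Deterministic given `(seed, chain)` — the function seeds R's
#' RNG itself.
#'
#' @param arrays an `nma_arrays` object.
#' @param model an [nma_model].
#' @param chain chain index (1-based).
#' @param settings an [nma_settings] object.
#' @return A parameter-state list (`mu`, `d`, and for random effects `delta`,
#'   `sigma`) usable with [log_posterior()].
#' @export
nma_init <- function(arrays, model, chain, settings = nma_settings()) {
  set.seed(settings$seed + chain)
  draw_state(arrays, model, settings)
}

draw_state <- function(arrays, model, settings) {
  nd <- n_effect_pars(arrays, model)
  state <- list(
    mu = stats::runif(arrays$ns, settings$init_range_mu[1],
                      settings$init_range_mu[2]),
    d = stats::runif(nd, settings$init_range_d[1], settings$init_range_d[2]))
  if (model$effect == "random") {
    het <- model$priors$het
    qs <- if (het$type == "uniform") c(0.25, 0.75) * het$upper
          else sqrt(stats::qlnorm(c(0.25, 0.75), het$meanlog, het$sdlog))
    state$sigma <- stats::runif(1, qs[1], qs[2])
    state$delta <- matrix(0, arrays$ns, ncol(arrays$t))
    cmap <- if (model$framework == "ume") ume_cmap(arrays) else NULL
    dfull <- c(0, state$d)
    for (i in seq_len(arrays$ns))
      for (k in 2:arrays$na[i])
        state$delta[i, k] <- if (model$framework == "ume") state$d[cmap[i, k]]
          else dfull[arrays$t[i, k]] - dfull[arrays$t[i, 1]]
  }
  state
}

#' Run one MCMC chain
#'
#' Adaptive random-walk Metropolis-within-Gibbs over parameter blocks (each
#' study baseline, each mean-effect parameter, each trial-specific effect,
#' the heterogeneity sd). Per-parameter step sizes adapt toward ~0.44
#' acceptance during burn-in and are frozen afterwards, so the retained
#' kernel is non-adaptive and stationarity-preserving.
#'
#' @inheritParams nma_init
#' @return List with `draws` (retained-iterations x monitored-parameters
#'   matrix), `accept` (named post-burn-in acceptance rates by block group)
#'   and `steps` (frozen step sizes).
#' @export
nma_run_chain <- function(arrays, model, chain, settings = nma_settings()) {
  set.seed(settings$seed + chain)
  state <- draw_state(arrays, model, settings)
  for (try in seq_len(50)) {
    if (is.finite(log_posterior(arrays, state, model))) break
    if (try == 50) stop("could not find finite starting state after 50 tries")
    state <- draw_state(arrays, model, settings)
  }
  random <- model$effect == "random"
  ume <- model$framework == "ume"
  cmap <- if (ume) ume_cmap(arrays) else matrix(0L, arrays$ns, ncol(arrays$t))
  het <- model$priors$het
  res <- nma_chain_cpp(
    t = arrays$t, r = arrays$r, n = arrays$n, na = arrays$na, nt = arrays$nt,
    random = random, ume = ume, cmap = cmap, nd = length(state$d),
    mu_sd = sqrt(model$priors$mu_var), d_sd = sqrt(model$priors$d_var),
    het_type = if (het$type == "uniform") 0L else 1L,
    het_p1 = if (het$type == "uniform") het$upper else het$meanlog,
    het_p2 = if (het$type == "uniform") 0 else het$sdlog,
    mu0 = state$mu, d0 = state$d,
    sigma0 = if (random) state$sigma else 1,
    n_burnin = settings$n_burnin, n_sample = settings$n_sample,
    thin = settings$thin)
  colnames(res$draws) <- monitor_names(arrays, model)
  nb <- c(mu = arrays$ns, d = length(state$d),
          delta = if (random) res$n_delta else 0L,
          sigma = if (random) 1L else 0L)
  grp <- rep(names(nb), nb)
  res$accept <- vapply(split(res$accept, factor(grp, names(nb)[nb > 0])),
                       mean, numeric(1))
  res[c("draws", "accept", "steps")]
}

monitor_names <- function(arrays, model) {
  pnames <- unlist(lapply(seq_len(arrays$ns), function(i)
    paste0("p[", arrays$study[i], ":",
           arrays$treatments[arrays$t[i, seq_len(arrays$na[i])]], "]")))
  c(paste0("mu[", arrays$study, "]"),
    effect_par_labels(arrays, model),
    if (model$effect == "random") "sigma",
    pnames)
}

#' Fit an NMA model by multi-chain MCMC
#'
#' Runs [nma_run_chain()] for each of `n_chains` independent chains (chain
#' `c` is seeded with `seed + c`) and assembles the retained draws.
#'
#' @param data an [nma_data] object (or `nma_arrays`).
#' @param model an [nma_model].
#' @param settings an [nma_settings] object.
#' @param monitors which quantities to retain: any of `"mu"`, `"d"`,
#'   `"sigma"`, `"p"` (per-data-point fitted probabilities, needed for
#'   deviance-based criticism). Defaults to all.
#' @return An object of class `nma_fit`: list with `draws` (3-D array
#'   retained-iterations x parameters x chains, with dimnames), `accept`
#'   (block acceptance rates per chain), `model`, `arrays`, `settings`.
#' @export
#' @examples
#' d <- data.frame(study = rep(c("s1", "s2"), each = 2),
#'                 treatment = rep(c("A", "B"), 2),
#'                 events = c(12, 8, 20, 14), n = c(50, 50, 80, 80))
#' fit <- nma_mcmc(nma_data(d), nma_model(effect = "fixed"),
#'                 nma_settings(n_burnin = 500, n_sample = 1000, seed = 42))
#' posterior_summary(fit, "d[B]")
nma_mcmc <- function(data, model = nma_model(), settings = nma_settings(),
                     monitors = c("mu", "d", "sigma", "p")) {
  arrays <- if (inherits(data, "nma_arrays")) data else nma_arrays(data)
  stopifnot(inherits(model, "nma_model"), inherits(settings, "nma_settings"))
  monitors <- match.arg(monitors, several.ok = TRUE)
  if (arrays$corrected)
    message("note: data carry zero-cell continuity corrections; ",
            "interpret model-fit statistics with caution")
  chains <- lapply(seq_len(settings$n_chains), function(ch)
    nma_run_chain(arrays, model, ch, settings))
  all_names <- colnames(chains[[1]]$draws)
  keep <- vapply(all_names, function(nm)
    sub("\\[.*", "", nm) %in% monitors, logical(1))
  n_ret <- nrow(chains[[1]]$draws)
  draws <- array(NA_real_, c(n_ret, sum(keep), settings$n_chains),
                 dimnames = list(NULL, all_names[keep],
                                 paste0("chain", seq_len(settings$n_chains))))
  for (ch in seq_len(settings$n_chains))
    draws[, , ch] <- chains[[ch]]$draws[, keep, drop = FALSE]
  structure(list(draws = draws,
                 accept = t(vapply(chains, `[[`, chains[[1]]$accept, "accept")),
                 model = model, arrays = arrays, settings = settings),
            class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("NMA fit: %s effects, %s framework; %d chains x %d retained draws\n",
              x$model$effect, x$model$framework, dm[3], dm[1]))
  eff <- grep("^d\\[", dimnames(x$draws)[[2]], value = TRUE)
  if (length(eff)) print(posterior_summary(x, c(eff,
    if ("sigma" %in% dimnames(x$draws)[[2]]) "sigma")), row.names = FALSE)
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param fit an `nma_fit`.
#' @param parameter parameter name (see `dimnames(fit$draws)[[2]]`).
#' @param pooled if `TRUE` (default) concatenate chains into one vector;
#'   otherwise return the retained-draws x chains matrix.
#' @return Numeric vector or matrix of draws.
#' @export
fit_draws <- function(fit, parameter, pooled = TRUE) {
  stopifnot(inherits(fit, "nma_fit"))
  if (!parameter %in% dimnames(fit$draws)[[2]])
    stop("unknown parameter '", parameter, "'")
  m <- fit$draws[, parameter, ]
  if (pooled) as.vector(m) else m
}

#' Long-format draws table
#'
#' Plain-text interoperable export: one row per (chain, iteration,
#' parameter).
#'
#' @param fit an `nma_fit`.
#' @param parameters optional subset of parameter names.
#' @return Data frame with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
draws_table <- function(fit, parameters = NULL) {
  pars <- dimnames(fit$draws)[[2]]
  if (!is.null(parameters)) {
    stopifnot(all(parameters %in% pars))
    pars <- parameters
  }
  n_ret <- dim(fit$draws)[1]; n_ch <- dim(fit$draws)[3]
  do.call(rbind, lapply(seq_len(n_ch), function(ch)
    data.frame(chain = ch, iteration = rep(seq_len(n_ret), length(pars)),
               parameter = rep(pars, each = n_ret),
               value = as.vector(fit$draws[, pars, ch]),
               stringsAsFactors = FALSE)))
}
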