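#' Posterior summary of monitored parameters
#'
#' Mean, sd, median and equal-tailed 95% credible interval from the pooled
#' chains. Quantiles use R's default (type 7) continuous convention.
#'
#' @param fit an `nma_fit` with at least 100 retained draws overall.
#' @param parameters parameter names; defaults to mean effects plus `sigma`.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  parameters <- default_diag_pars(fit, parameters)
  rows <- lapply(parameters, function(p) {
    x <- fit_draws(fit, p)
    if (length(x) < 100L) stop("posterior summary needs >= 100 draws")
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               median = q[2], lower = q[1], upper = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled draws of a pairwise odds ratio
#'
#' Under the consistency framework every contrast derives from the basic
#' parameters: the odds ratio of `treatment` versus `vs` is
#' \eqn{\exp(d_{treatment} - d_{vs})} draw by draw (with the reference's
#' `d = 0`). Identical treatments give exactly 1, and reciprocity
#' `OR(a, b) * OR(b, a) = 1` and the consistency identity
#' `OR(a, b) * OR(b, c) = OR(a, c)` hold per draw by construction.
#'
#' @param fit a consistency-framework `nma_fit`.
#' @param treatment,vs treatment labels (or indices).
#' @return Numeric vector of pooled odds-ratio draws.
#' @export
or_draws <- function(fit, treatment, vs) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$model$framework != "consistency")
    stop("pairwise odds ratios require the consistency framework")
  trts <- fit$arrays$treatments
  ix <- function(t) {
    if (is.character(t)) t <- match(t, trts)
    if (is.na(t) || t < 1 || t > length(trts)) stop("unknown treatment")
    t
  }
  i <- ix(treatment); j <- ix(vs)
  dcol <- function(k) {
    if (k == 1L) return(0)
    fit_draws(fit, paste0("d[", trts[k], "]"))
  }
  exp(dcol(i) - dcol(j))
}

#' Rank probabilities and SUCRA
#'
#' For each pooled posterior draw the treatments are ranked by their basic
#' parameter: rank 1 is the lowest log-odds effect when the outcome is
#' `"bad"` (fewer events is better) and the highest when `"good"`; exact
#' ties break by treatment index. `P[treatment, rank]` collects the
#' empirical frequencies and
#' \deqn{SUCRA_t = \frac{1}{K-1} \sum_{r=1}^{K-1} \mathrm{cum}P_{t,r}}
#' summarizes them: 1 when a treatment is certain to be best, 0 when certain
#' to be worst.
#'
#' @param fit a consistency `nma_fit` monitoring the full `d` vector.
#' @param direction override the model's outcome direction.
#' @return Object of class `nma_ranks`: list with `P` (K x K matrix), `sucra`
#'   (named vector) and `direction`.
#' @export
rank_probabilities <- function(fit, direction = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$model$framework != "consistency")
    stop("treatment ranking requires the consistency framework")
  direction <- if (is.null(direction)) fit$model$direction
               else match.arg(direction, c("bad", "good"))
  trts <- fit$arrays$treatments
  K <- length(trts)
  dmat <- cbind(0, vapply(trts[-1], function(tr)
    fit_draws(fit, paste0("d[", tr, "]")), numeric(length(fit_draws(fit,
    paste0("d[", trts[2], "]"))))))
  eff <- if (direction == "bad") dmat else -dmat
  P <- matrix(0, K, K, dimnames = list(trts, paste0("rank", seq_len(K))))
  # rank of each treatment per draw; ties broken by treatment index
  for (tix in seq_len(K)) {
    rk <- rowSums(eff < eff[, tix]) +
      rowSums(eff[, seq_len(K) < tix, drop = FALSE] == eff[, tix]) + 1
    P[tix, ] <- tabulate(rk, nbins = K) / nrow(eff)
  }
  cum <- t(apply(P, 1, cumsum))
  sucra <- rowSums(cum[, seq_len(K - 1), drop = FALSE]) / (K - 1)
  structure(list(P = P, sucra = sucra, direction = direction),
            class = "nma_ranks")
}

#' @export
print.nma_ranks <- function(x, ...) {
  cat("Rank probabilities (rank 1 = best, outcome direction:",
      x$direction, ")\n")
  print(round(x$P, 3))
  cat("\nSUCRA:\n")
  print(round(sort(x$sucra, decreasing = TRUE), 3))
  invisible(x)
}

#' League table of all pairwise comparisons
#'
#' K x K grid with the treatments on the diagonal ordered by descending
#' SUCRA (best first, top left). Cell (row, column) holds the posterior
#' median and 95% CrI of the odds ratio of the *row* treatment versus the
#' *column* treatment — read from top to bottom and left to right, as stated
#' in the object's header; medians satisfy cell(i,j) x cell(j,i) = 1.
#'
#' @param fit a consistency `nma_fit`.
#' @param ranks optional precomputed [rank_probabilities()] result.
#' @return Object of class `nma_league`: list with `order` (treatment labels,
#'   best first), matrices `median`, `lower`, `upper`, and `convention`.
#' @export
league_table <- function(fit, ranks = NULL) {
  if (is.null(ranks)) ranks <- rank_probabilities(fit)
  ord <- names(sort(ranks$sucra, decreasing = TRUE))
  K <- length(ord)
  med <- lo <- up <- matrix(NA_real_, K, K, dimnames = list(ord, ord))
  diag(med) <- diag(lo) <- diag(up) <- 1
  # each unordered pair is summarized once; the mirror cell is filled with
  # the exact reciprocals so median reciprocity holds identically
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    x <- or_draws(fit, ord[i], ord[j])
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    lo[i, j] <- q[1]; med[i, j] <- q[2]; up[i, j] <- q[3]
    lo[j, i] <- 1 / q[3]; med[j, i] <- 1 / q[2]; up[j, i] <- 1 / q[1]
  }
  structure(list(order = ord, median = med, lower = lo, upper = up,
                 convention = paste("cell(row, column) = OR of row treatment",
                                    "vs column treatment")),
            class = "nma_league")
}

#' @export
print.nma_league <- function(x, digits = 2, ...) {
  cat("League table (diagonal ordered by descending SUCRA)\n")
  cat(x$convention, "\n\n")
  K <- length(x$order)
  cells <- matrix("", K, K, dimnames = list(x$order, x$order))
  for (i in seq_len(K)) for (j in seq_len(K))
    cells[i, j] <- if (i == j) x$order[i] else
      sprintf("%.*f (%.*f-%.*f)", digits, x$median[i, j],
              digits, x$lower[i, j], digits, x$upper[i, j])
  print(cells, quote = FALSE)
  invisible(x)
}

#' Forest-plot data
#'
#' One record per (comparison, model): the posterior median and 95% CrI of
#' the odds ratio, ready for plotting. Reference-versus-reference rows are
#' excluded.
#'
#' @param fits a single consistency `nma_fit` or a named list of them (names
#'   become model tags, e.g. `list(FE = ..., RE = ...)`).
#' @param comparisons `"reference"` (each treatment vs the network reference,
#'   the default) or `"all"` (all unordered pairs).
#' @return Data frame with columns `model`, `treatment`, `vs`, `label`,
#'   `median`, `lower`, `upper`.
#' @export
forest_data <- function(fits, comparisons = c("reference", "all")) {
  comparisons <- match.arg(comparisons)
  if (inherits(fits, "nma_fit")) fits <- list(model = fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "nma_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  do.call(rbind, lapply(names(fits), function(tag) {
    fit <- fits[[tag]]
    trts <- fit$arrays$treatments
    ref <- fit$arrays$reference
    pairs <- if (comparisons == "reference")
      cbind(setdiff(seq_along(trts), ref), ref)
    else t(utils::combn(seq_along(trts), 2))[, 2:1, drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(rix) {
      i <- pairs[rix, 1]; j <- pairs[rix, 2]
      q <- stats::quantile(or_draws(fit, i, j), c(0.025, 0.5, 0.975),
                           names = FALSE)
      data.frame(model = tag, treatment = trts[i], vs = trts[j],
                 label = paste(trts[i], "vs", trts[j]),
                 median = q[2], lower = q[1], upper = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Evidence-network diagram layout
#'
#' Deterministic circular layout: nodes equally spaced on the unit circle in
#' registry order, node radius proportional to the square root of the
#' participant count (so node *area* is proportional to participants), edge
#' width proportional to the number of trials making the comparison.
#'
#' @param net an `nma_network` from [nma_network()].
#' @param labels optional named character vector overriding node labels.
#' @param max_radius radius of the largest node in plot units.
#' @return List of class `nma_layout` with data frames `nodes` (`treatment`,
#'   `label`, `x`, `y`, `radius`, `participants`) and `edges` (`t1`, `t2`,
#'   `x1`, `y1`, `x2`, `y2`, `width`, `trials`).
#' @export
network_layout <- function(net, labels = NULL, max_radius = 0.15) {
  stopifnot(inherits(net, "nma_network"))
  K <- nrow(net$nodes)
  ang <- pi / 2 - 2 * pi * (seq_len(K) - 1) / K
  lab <- net$nodes$treatment
  if (!is.null(labels)) {
    hit <- match(lab, names(labels))
    lab[!is.na(hit)] <- labels[hit[!is.na(hit)]]
  }
  nodes <- data.frame(
    treatment = net$nodes$treatment, label = lab,
    x = cos(ang), y = sin(ang),
    radius = max_radius * sqrt(net$nodes$participants /
                                 max(net$nodes$participants)),
    participants = net$nodes$participants, stringsAsFactors = FALSE)
  ix <- match(net$edges$t1, nodes$treatment)
  jx <- match(net$edges$t2, nodes$treatment)
  edges <- data.frame(
    t1 = net$edges$t1, t2 = net$edges$t2,
    x1 = nodes$x[ix], y1 = nodes$y[ix], x2 = nodes$x[jx], y2 = nodes$y[jx],
    width = net$edges$trials, trials = net$edges$trials,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "nma_layout")
}

#' @export
plot.nma_network <- function(x, labels = NULL, ...) {
  lay <- network_layout(x, labels = labels)
  graphics::plot.new()
  graphics::plot.window(c(-1.4, 1.4), c(-1.4, 1.4), asp = 1)
  with(lay$edges, graphics::segments(x1, y1, x2, y2, lwd = width * 2,
                                     col = "grey60"))
  graphics::symbols(lay$nodes$x, lay$nodes$y, circles = lay$nodes$radius,
                    inches = FALSE, add = TRUE, bg = "steelblue",
                    fg = "grey20")
  off <- 1.18
  graphics::text(lay$nodes$x * off, lay$nodes$y * off, lay$nodes$label)
  invisible(lay)
}

#' @export
plot.nma_ranks <- function(x, ...) {
  graphics::barplot(t(x$P), beside = FALSE, legend.text = colnames(x$P),
                    ylab = "probability", las = 2,
                    main = "Rankogram", ...)
  invisible(x)
}

#' Export a full analysis report bundle
#'
#' Writes a JSON report plus CSV tables (league, rank probabilities, forest
#' data, per-point deviances, optional dev-dev table) into a directory. The
#' JSON is written with stable key order and full precision, so re-exporting
#' an unchanged analysis is byte-identical. Convergence failures are flagged
#' in the report but never block the export.
#'
#' @param path output directory (created if needed).
#' @param data the [nma_data] analyzed.
#' @param fits named list of `nma_fit` objects.
#' @param devdev optional [devdev_table()] result.
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(path, data, fits, devdev = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(fits, "nma_fit")) fits <- list(model = fits)
  written <- character()
  wf <- function(df, name) {
    f <- file.path(path, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  net <- nma_network(data)
  report <- list(dataset = unclass(summary(data)),
                 network = list(nodes = net$nodes, edges = net$edges),
                 models = list())
  for (tag in names(fits)) {
    fit <- fits[[tag]]
    conv <- convergence(fit)
    fstat <- tryCatch(suppressWarnings(dic(fit)), error = function(e) NULL)
    report$models[[tag]] <- list(
      effect = fit$model$effect, framework = fit$model$framework,
      direction = fit$model$direction,
      summaries = posterior_summary(fit),
      convergence = as.data.frame(conv),
      overall_pass = attr(conv, "overall_pass"),
      fit_statistics = if (!is.null(fstat))
        fstat[c("Dbar", "pD", "DIC")] else NULL)
    if (fit$model$framework == "consistency") {
      rk <- rank_probabilities(fit)
      lg <- league_table(fit, rk)
      wf(data.frame(treatment = rownames(rk$P), rk$P,
                    sucra = rk$sucra, check.names = FALSE),
         paste0("ranks_", tag, ".csv"))
      lgdf <- data.frame(treatment = lg$order, round(lg$median, 6),
                         check.names = FALSE)
      wf(lgdf, paste0("league_median_", tag, ".csv"))
      wf(forest_data(stats::setNames(list(fit), tag)),
         paste0("forest_", tag, ".csv"))
      report$models[[tag]]$sucra <- as.list(rk$sucra)
    }
    if (!is.null(fstat)) wf(fstat$points, paste0("deviance_", tag, ".csv"))
  }
  if (!is.null(devdev)) wf(as.data.frame(devdev), "devdev.csv")
  f <- file.path(path, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, f)
  invisible(written)
}
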