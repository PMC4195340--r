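#' Construct an arm-level network-meta-analysis dataset
#'
#' Builds a validated `nma_data` object from long-format arm-level records of
#' a dichotomous outcome: one row per (study, treatment arm) carrying the
#' number of events and the number of randomized patients. Treatments are
#' indexed 1..K; treatment 1 is the network reference against which basic
#' parameters are expressed.
#'
#' @param data data frame with columns `study`, `treatment`, `events`, `n`.
#' @param treatments optional character vector fixing the treatment registry
#'   order (and hence indices). Defaults to order of first appearance.
#' @param reference reference treatment, as label or index. Defaults to the
#'   treatment appearing in the most studies (ties broken by registry order),
#'   the usual recommendation for the network reference.
#' @param warn_limits emit a warning beyond 15 treatments or 50 studies
#'   (a common tool limit for spreadsheet-hosted NMA; statistically harmless).
#' @return An object of class `nma_data`: a list with elements `data` (long
#'   data frame with an integer treatment index column `t`, arms sorted
#'   baseline-first within study), `treatments`, `reference` (index) and
#'   `corrected` (logical, set by [correct_zero_cells()]).
#' @details Validation rejects malformed counts (`events < 0`, `events > n`,
#'   `n <= 0`), duplicated (study, treatment) pairs, single-arm studies, and
#'   networks whose treatment graph is disconnected (no path of shared-arm
#'   studies links every pair of treatments). The first arm of each study is
#'   the baseline arm: the arm whose treatment has the lowest index.
#' @seealso [read_nma_long()], [read_nma_wide()], [correct_zero_cells()],
#'   [nma_network()]
#' @export
#' @examples
#' d <- data.frame(study = c("s1", "s1", "s2", "s2"),
#'                 treatment = c("A", "B", "A", "C"),
#'                 events = c(5, 3, 10, 8), n = c(50, 50, 100, 100))
#' nma_data(d)
nma_data <- function(data, treatments = NULL, reference = NULL,
                     warn_limits = TRUE) {
  req <- c("study", "treatment", "events", "n")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  data <- as.data.frame(data)[req]
  data$study <- as.character(data$study)
  data$treatment <- as.character(data$treatment)
  data$events <- as.numeric(data$events)
  data$n <- as.numeric(data$n)
  if (nrow(data) == 0L) stop("empty dataset")
  if (anyNA(data)) stop("malformed rows: missing values")
  if (any(data$n <= 0)) stop("arm sizes must be positive")
  if (any(data$events < 0)) stop("event counts must be non-negative")
  if (any(data$events > data$n)) stop("events exceed sample size")
  if (anyDuplicated(data[c("study", "treatment")]))
    stop("duplicate (study, treatment) pairs")

  if (is.null(treatments)) {
    treatments <- unique(data$treatment)
  } else {
    treatments <- as.character(treatments)
    missing_t <- setdiff(data$treatment, treatments)
    if (length(missing_t))
      stop("treatments argument omits: ", paste(missing_t, collapse = ", "))
    treatments <- treatments[treatments %in% data$treatment]
  }
  data$t <- match(data$treatment, treatments)

  arms_per_study <- table(data$study)
  if (any(arms_per_study < 2L))
    stop("single-arm study: ",
         paste(names(arms_per_study)[arms_per_study < 2L], collapse = ", "))

  # baseline-first ordering: studies by first appearance, arms by index
  study_order <- unique(data$study)
  data <- data[order(match(data$study, study_order), data$t), ]
  rownames(data) <- NULL

  if (!network_connected(data, length(treatments)))
    stop("disconnected network: not all treatments are linked by studies")

  if (warn_limits) {
    if (length(treatments) > 15L)
      warning("more than 15 treatments; exceeds the common spreadsheet-tool cap")
    if (length(study_order) > 50L)
      warning("more than 50 studies; exceeds the common spreadsheet-tool cap")
  }

  if (is.null(reference)) {
    n_stud <- vapply(treatments, function(tr)
      length(unique(data$study[data$treatment == tr])), integer(1))
    reference <- which.max(n_stud) # ties -> earliest registry entry
  } else if (is.character(reference)) {
    reference <- match(reference, treatments)
    if (is.na(reference)) stop("unknown reference treatment")
  } else {
    reference <- as.integer(reference)
    if (reference < 1L || reference > length(treatments))
      stop("reference index out of range")
  }

  structure(list(data = data, treatments = treatments,
                 reference = as.integer(reference), corrected = FALSE),
            class = "nma_data")
}

network_connected <- function(data, K) {
  if (K == 1L) return(TRUE)
  # union-find over treatments joined by co-occurrence in a study
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (s in split(data$t, data$study)) {
    r1 <- find(s[1])
    for (t2 in s[-1]) { r2 <- find(t2); if (r1 != r2) parent[r2] <- r1 }
  }
  length(unique(vapply(seq_len(K), find, integer(1)))) == 1L
}

#' Read a long-format NMA dataset from CSV
#'
#' Canonical serialization: UTF-8 comma-separated file with header columns
#' `study`, `treatment`, `events`, `n`, one row per arm.
#'
#' @inheritParams nma_data
#' @param path path to the CSV file.
#' @return An [nma_data] object.
#' @export
read_nma_long <- function(path, treatments = NULL, reference = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nma_data(df, treatments = treatments, reference = reference)
}

#' Read a wide-format NMA dataset from CSV
#'
#' Wide layout mirrors the familiar trial-table presentation: a `study` column
#' followed by one (events, patients) column pair per treatment, left to
#' right in treatment-index order. A blank pair means the treatment was absent
#' from that study. The treatment label is taken from the events column of
#' each pair (any ` events`/`_events`/`.events` suffix is stripped).
#'
#' @inheritParams read_nma_long
#' @return An [nma_data] object identical to the one produced by
#'   [read_nma_long()] on the equivalent long file.
#' @export
read_nma_wide <- function(path, reference = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 3L) stop("empty or malformed wide file")
  if (names(df)[1] != "study") stop("first column must be 'study'")
  body <- df[-1]
  if (ncol(body) %% 2L != 0L)
    stop("odd column count: expected (events, n) pairs after 'study'")
  k <- ncol(body) / 2L
  labels <- sub("[ ._](events|r)$", "", names(body)[2L * seq_len(k) - 1L])
  long <- do.call(rbind, lapply(seq_len(k), function(j) {
    ev <- suppressWarnings(as.numeric(body[[2L * j - 1L]]))
    nn <- suppressWarnings(as.numeric(body[[2L * j]]))
    keep <- !(is.na(ev) & is.na(nn))
    data.frame(study = df$study[keep], treatment = labels[j],
               events = ev[keep], n = nn[keep], stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$study, df$study)), ]
  nma_data(long, treatments = labels, reference = reference)
}

#' @export
print.nma_data <- function(x, ...) {
  s <- summary(x)
  cat("Arm-level NMA dataset:", s$n_studies, "studies,",
      s$n_treatments, "treatments\n")
  cat("  ", s$n_events, "events in", s$n_patients, "patients\n")
  cat("  reference:", x$treatments[x$reference],
      sprintf("(in %d studies)\n", s$n_studies_with_reference))
  if (x$corrected) cat("  zero-cell continuity correction applied\n")
  invisible(x)
}

#' Summarize an NMA dataset
#'
#' Totals shown alongside the data-entry sheet of spreadsheet NMA tools:
#' study, treatment, patient and event counts, and the number of studies
#' that include the reference treatment.
#'
#' @param object an [nma_data] object.
#' @param ... unused.
#' @return A list of class `nma_summary` with elements `n_studies`,
#'   `n_treatments`, `n_patients`, `n_events`, `n_studies_with_reference`.
#' @export
summary.nma_data <- function(object, ...) {
  d <- object$data
  ref <- object$treatments[object$reference]
  structure(list(
    n_studies = length(unique(d$study)),
    n_treatments = length(object$treatments),
    n_patients = sum(d$n),
    n_events = sum(d$events),
    n_studies_with_reference =
      length(unique(d$study[d$treatment == ref]))
  ), class = "nma_summary")
}

#' @export
print.nma_summary <- function(x, ...) {
  cat("Studies:                 ", x$n_studies, "\n")
  cat("Treatments:              ", x$n_treatments, "\n")
  cat("Patients:                ", x$n_patients, "\n")
  cat("Events:                  ", x$n_events, "\n")
  cat("Studies with reference:  ", x$n_studies_with_reference, "\n")
  invisible(x)
}

#' Zero-cell continuity correction
#'
#' Applies an adjusted continuity correction, centered around 0.5 and
#' accounting for differences in arm sizes, to every study that contains at
#' least one zero-event or all-event arm. Within such a study each arm `a`
#' receives a correction \eqn{c_a} added to its event count and \eqn{2 c_a}
#' added to its sample size, with \eqn{c_a} proportional to the reciprocal of
#' the mean size of the *other* arms of the study and normalized so that the
#' corrections sum to (number of arms)/2 — i.e. they average exactly 0.5.
#' With equal arm sizes every \eqn{c_a = 0.5}, the classical correction.
#' Studies without zero/all-event cells are untouched, and no study is ever
#' dropped. Corrected counts are fractional and handled exactly by the
#' log-Gamma binomial likelihood.
#'
#' @param x an [nma_data] object.
#' @return A corrected `nma_data` object with `corrected = TRUE` and an
#'   attribute `"corrections"` (data frame of per-arm corrections). A warning
#'   is raised for studies whose arms are *all* zero-event, which cannot
#'   contribute to relative-effect estimation.
#' @export
correct_zero_cells <- function(x) {
  stopifnot(inherits(x, "nma_data"))
  d <- x$data
  corr <- data.frame(study = character(), treatment = character(),
                     c = numeric(), stringsAsFactors = FALSE)
  for (s in unique(d$study)) {
    idx <- which(d$study == s)
    ev <- d$events[idx]; nn <- d$n[idx]
    if (!any(ev == 0 | ev == nn)) next
    if (all(ev == 0))
      warning("study '", s, "' has zero events in every arm; it does not ",
              "contribute to relative effect estimation")
    A <- length(idx)
    w <- vapply(seq_len(A), function(a) 1 / mean(nn[-a]), numeric(1))
    ca <- w / sum(w) * (A / 2)
    d$events[idx] <- ev + ca
    d$n[idx] <- nn + 2 * ca
    corr <- rbind(corr, data.frame(study = s, treatment = d$treatment[idx],
                                   c = ca, stringsAsFactors = FALSE))
  }
  x$data <- d
  x$corrected <- TRUE
  attr(x, "corrections") <- corr
  x
}

#' Build the evidence network of an NMA dataset
#'
#' Nodes are treatments weighted by their cumulative number of randomized
#' participants; edges are unordered treatment pairs weighted by the number of
#' trials in which both treatments appear — the quantities that drive node
#' size and edge width in the customary evidence-network diagram.
#'
#' @param x an [nma_data] object.
#' @return An object of class `nma_network`: list with `nodes` (data frame
#'   `treatment`, `participants`) and `edges` (data frame `t1`, `t2`,
#'   `trials`, with `t1` before `t2` in registry order).
#' @export
nma_network <- function(x) {
  stopifnot(inherits(x, "nma_data"))
  d <- x$data
  nodes <- data.frame(
    treatment = x$treatments,
    participants = vapply(x$treatments, function(tr)
      sum(d$n[d$treatment == tr]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pair_keys <- unlist(lapply(split(d$t, d$study), function(ts) {
    ts <- sort(ts)
    cmb <- utils::combn(ts, 2)
    paste(cmb[1, ], cmb[2, ], sep = ":")
  }))
  tab <- table(pair_keys)
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  edges <- data.frame(
    t1 = x$treatments[as.integer(parts[, 1])],
    t2 = x$treatments[as.integer(parts[, 2])],
    trials = as.integer(tab), row.names = NULL, stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$t1, x$treatments),
                       match(edges$t2, x$treatments)), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "nma_network")
}

#' @export
print.nma_network <- function(x, ...) {
  cat("Evidence network:", nrow(x$nodes), "treatments,",
      nrow(x$edges), "direct comparisons\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Rectangular model arrays for the sampler
#'
#' Restructures an [nma_data] object into the per-study rectangular arrays
#' the likelihood works on: treatment indices, event counts, sizes, and arm
#' counts, baseline arm first, remaining arms in ascending treatment index.
#'
#' @param x an [nma_data] object.
#' @return A list of class `nma_arrays`: `ns`, `nt`, `na` (arms per study),
#'   matrices `t`, `r`, `n` (`ns` x max arms; `t` is 0 where a study has no
#'   such arm), `study` labels, `treatments`, `reference`, `nobs` (total data
#'   points = total arms) and `corrected`.
#' @export
nma_arrays <- function(x) {
  stopifnot(inherits(x, "nma_data"))
  d <- x$data
  studies <- unique(d$study)
  ns <- length(studies)
  byst <- split(d, match(d$study, studies))
  na <- vapply(byst, nrow, integer(1))
  maxa <- max(na)
  tm <- matrix(0L, ns, maxa); rm_ <- matrix(0, ns, maxa); nm <- matrix(0, ns, maxa)
  for (i in seq_len(ns)) {
    b <- byst[[i]]
    o <- order(b$t) # baseline (lowest treatment index) first
    tm[i, seq_len(na[i])] <- b$t[o]
    rm_[i, seq_len(na[i])] <- b$events[o]
    nm[i, seq_len(na[i])] <- b$n[o]
  }
  structure(list(ns = ns, nt = length(x$treatments), na = na,
                 t = tm, r = rm_, n = nm, study = studies,
                 treatments = x$treatments, reference = x$reference,
                 nobs = sum(na), corrected = isTRUE(x$corrected)),
            class = "nma_arrays")
}

#' Rebuild an NMA dataset from model arrays
#'
#' Inverse of [nma_arrays()]; useful for round-trip checks and for exporting
#' corrected data.
#'
#' @param arrays an `nma_arrays` object.
#' @return An [nma_data] object.
#' @export
nma_data_from_arrays <- function(arrays) {
  stopifnot(inherits(arrays, "nma_arrays"))
  rows <- do.call(rbind, lapply(seq_len(arrays$ns), function(i) {
    k <- seq_len(arrays$na[i])
    data.frame(study = arrays$study[i],
               treatment = arrays$treatments[arrays$t[i, k]],
               events = arrays$r[i, k], n = arrays$n[i, k],
               stringsAsFactors = FALSE)
  }))
  out <- nma_data(rows, treatments = arrays$treatments,
                  reference = arrays$reference, warn_limits = FALSE)
  out$corrected <- arrays$corrected
  out
}

#' Write dataset summary and evidence network as JSON
#'
#' @param x an [nma_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_json <- function(x, path) {
  net <- nma_network(x)
  obj <- list(summary = unclass(summary(x)),
              network = list(nodes = net$nodes, edges = net$edges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a dataset back to canonical long CSV
#'
#' @param x an [nma_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nma_long <- function(x, path) {
  stopifnot(inherits(x, "nma_data"))
  utils::write.csv(x$data[c("study", "treatment", "events", "n")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
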