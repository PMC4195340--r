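# shared fixtures, built in code or loaded from the shipped plain-text data

table1_wide_path <- function()
  system.file("extdata", "heart_failure_mortality_wide.csv",
              package = "nmabayes")

table1_long_path <- function()
  system.file("extdata", "heart_failure_mortality_long.csv",
              package = "nmabayes")

# canonical treatment order of the heart-failure network (A..E)
hf_treatments <- c("Medical therapy", "Cardiac resynchronization",
                   "Implantable defibrillator",
                   "Combined resynchronization and defibrillator",
                   "Amiodarone")

hf_data <- function() read_nma_wide(table1_wide_path())

# two-arm two-study toy with moderate counts, used with the grid oracle
toy2_data <- function() {
  nma_data(data.frame(
    study = rep(c("t1", "t2"), each = 2),
    treatment = rep(c("A", "B"), 2),
    events = c(10, 15, 20, 14), n = c(50, 50, 80, 80),
    stringsAsFactors = FALSE))
}

# minimal fit stub carrying hand-constructed draws; enough structure for the
# reporting and diagnostic functions that only touch draws + labels
stub_fit <- function(draws_by_chain, treatments = NULL, reference = 1,
                     effect = "fixed", framework = "consistency",
                     direction = "bad") {
  stopifnot(is.list(draws_by_chain))
  n_ret <- nrow(draws_by_chain[[1]])
  pars <- colnames(draws_by_chain[[1]])
  arr <- array(NA_real_, c(n_ret, length(pars), length(draws_by_chain)),
               dimnames = list(NULL, pars,
                               paste0("chain", seq_along(draws_by_chain))))
  for (ch in seq_along(draws_by_chain)) arr[, , ch] <- draws_by_chain[[ch]]
  model <- nma_model(effect, framework, direction = direction)
  structure(list(draws = arr, model = model,
                 arrays = list(treatments = treatments, reference = reference)),
            class = "nma_fit")
}

quick_settings <- function(seed = 1, n_burnin = 2000, n_sample = 4000, ...)
  nma_settings(n_burnin = n_burnin, n_sample = n_sample, seed = seed, ...)
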