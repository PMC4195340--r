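test_that("long and wide readers agree on the heart-failure network", {
  wide <- read_nma_wide(table1_wide_path())
  long <- read_nma_long(table1_long_path(), treatments = hf_treatments)
  expect_identical(wide$treatments, hf_treatments)
  expect_identical(long$data, wide$data)
  expect_identical(long$reference, wide$reference)
  expect_equal(wide$treatments[wide$reference], "Medical therapy")
  ms <- wide$data[wide$data$study == "MUSTIC-SR", ]
  expect_equal(ms$events, c(0, 1))
  expect_equal(ms$n, c(29, 29))
})

test_that("dataset summary reproduces the published evidence-base totals", {
  s <- summary(hf_data())
  expect_identical(s$n_studies, 12L)
  expect_identical(s$n_treatments, 5L)
  expect_equal(s$n_patients, 8307)
  expect_equal(s$n_events, 1616)
  expect_identical(s$n_studies_with_reference, 8L)
})

test_that("summary totals are direct sums and invariant to row order", {
  d <- data.frame(study = c("s1", "s1"), treatment = c("A", "B"),
                  events = c(1, 2), n = c(10, 10))
  s <- summary(nma_data(d))
  expect_equal(unclass(s)[c("n_studies", "n_treatments", "n_patients",
                            "n_events", "n_studies_with_reference")],
               list(n_studies = 1L, n_treatments = 2L, n_patients = 20,
                    n_events = 3, n_studies_with_reference = 1L),
               ignore_attr = TRUE)
  long <- utils::read.csv(table1_long_path(), stringsAsFactors = FALSE)
  shuffled <- long[rev(seq_len(nrow(long))), ]
  expect_equal(unclass(summary(nma_data(shuffled))),
               unclass(summary(hf_data())))
})

test_that("validation rejects malformed inputs", {
  base <- data.frame(study = c("s1", "s1"), treatment = c("A", "B"),
                     events = c(1, 2), n = c(10, 10))
  expect_error(nma_data(base[1, ]), "single-arm")
  bad <- base; bad$events[1] <- 11
  expect_error(nma_data(bad), "exceed")
  dup <- rbind(base, base[1, ])
  expect_error(nma_data(dup), "duplicate")
  disc <- data.frame(study = rep(c("s1", "s2"), each = 2),
                     treatment = c("A", "B", "C", "D"),
                     events = 1, n = 10)
  expect_error(nma_data(disc), "disconnected")
  expect_error(nma_data(base[0, ]), "empty")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("study,A events,A n,B events", tmp)
  expect_error(read_nma_wide(tmp), "empty|odd")
  writeLines(c("study,A events,A n,B events", "s1,1,10,2"), tmp)
  expect_error(read_nma_wide(tmp), "odd")
})

test_that("treatment/study caps warn but do not block", {
  big <- do.call(rbind, lapply(1:51, function(i)
    data.frame(study = paste0("s", i), treatment = c("A", "B"),
               events = c(1, 1), n = c(10, 10))))
  expect_warning(nma_data(big), "50 studies")
  expect_silent(nma_data(big, warn_limits = FALSE))
})

test_that("evidence network has the published edges and node weights", {
  net <- nma_network(hf_data())
  key <- paste(match(net$edges$t1, hf_treatments),
               match(net$edges$t2, hf_treatments), sep = "")
  got <- stats::setNames(net$edges$trials, key)
  expect_equal(got[c("12", "14", "24", "13", "15", "35", "34")],
               c("12" = 4, "14" = 1, "24" = 1, "13" = 4, "15" = 1,
                 "35" = 2, "34" = 3))
  expect_equal(nrow(net$edges), 7L)
  expect_equal(net$nodes$participants[1], 2586)
  expect_true(all(net$edges$trials >= 1))
})

test_that("network edge weights decompose over studies", {
  ds <- hf_data()
  full <- nma_network(ds)
  drop <- ds$data[ds$data$study != "COMPANION", ]
  smaller <- nma_network(nma_data(drop, treatments = hf_treatments))
  key <- function(net) paste(net$edges$t1, net$edges$t2)
  for (k in key(smaller)) {
    dec <- full$edges$trials[key(full) == k] -
      smaller$edges$trials[key(smaller) == k]
    pair_in_dropped <- k %in% c(
      "Medical therapy Cardiac resynchronization",
      "Medical therapy Combined resynchronization and defibrillator",
      "Cardiac resynchronization Combined resynchronization and defibrillator")
    expect_equal(dec, as.numeric(pair_in_dropped))
  }
  # the single 2-arm-study network has one edge of weight 1
  one <- nma_network(nma_data(data.frame(
    study = "s", treatment = c("A", "B"), events = 1, n = 10)))
  expect_equal(one$edges$trials, 1L)
})

test_that("continuity correction is centered at 0.5 and size-adjusted", {
  ds <- hf_data()
  cor <- suppressMessages(correct_zero_cells(ds))
  ms <- cor$data[cor$data$study == "MUSTIC-SR", ]
  expect_equal(ms$events, c(0.5, 1.5)) # equal arms force exactly 0.5
  expect_equal(ms$n, c(30, 30))
  # only MUSTIC-SR has a zero cell; everything else untouched
  other <- cor$data$study != "MUSTIC-SR"
  expect_equal(cor$data[other, ], ds$data[other, ])
  expect_equal(sum(cor$data$events), sum(ds$data$events) + 1)
  expect_true(cor$corrected)

  # unequal arms: corrections proportional to 1 / (mean size of other arms)
  uneq <- nma_data(data.frame(study = "z", treatment = c("T", "C"),
                              events = c(0, 3), n = c(100, 50)))
  cz <- correct_zero_cells(uneq)$data
  expect_equal(cz$events, c(0 + 2 / 3, 3 + 1 / 3))
  expect_equal(cz$n, c(100 + 4 / 3, 50 + 2 / 3))
})

test_that("correction scope, normalization and degenerate cases", {
  # all-event cell triggers correction too; per-study corrections sum to A/2
  allev <- nma_data(data.frame(study = "s", treatment = c("A", "B", "C"),
                               events = c(10, 3, 2), n = c(10, 20, 40)))
  ca <- attr(correct_zero_cells(allev), "corrections")
  expect_equal(sum(ca$c), 3 / 2)
  expect_true(all(diff(ca$c[order(c(30, 25, 15))]) <= 0)) # bigger others -> smaller c
  # no zero / all-event cells: identity
  clean <- nma_data(data.frame(study = "s", treatment = c("A", "B"),
                               events = c(1, 2), n = c(10, 10)))
  expect_identical(correct_zero_cells(clean)$data, clean$data)
  # all-zero study warns but is kept
  az <- nma_data(data.frame(study = rep(c("s1", "s2"), each = 2),
                            treatment = rep(c("A", "B"), 2),
                            events = c(0, 0, 3, 4), n = 20))
  expect_warning(cz <- correct_zero_cells(az), "not contribute")
  expect_equal(length(unique(cz$data$study)), 2L)
  # ordering invariant 0 <= events <= size still holds on the full fixture
  cf <- suppressWarnings(correct_zero_cells(hf_data()))$data
  expect_true(all(cf$events >= 0 & cf$events <= cf$n))
})

test_that("model arrays are rectangular, baseline-first, and round-trip", {
  ds <- hf_data()
  arr <- nma_arrays(ds)
  expect_equal(arr$nobs, 26)
  expect_equal(sum(arr$na), 26)
  comp <- which(arr$study == "COMPANION")
  expect_equal(arr$t[comp, 1:3], c(1L, 2L, 4L)) # A, B, D ascending, baseline first
  expect_equal(arr$r[comp, 1:3], c(77, 131, 105))
  back <- nma_data_from_arrays(arr)
  expect_equal(back$data, ds$data)
  expect_identical(back$treatments, ds$treatments)
})

test_that("reference defaults to the treatment in the most studies", {
  ds <- nma_data(data.frame(
    study = rep(c("s1", "s2", "s3"), each = 2),
    treatment = c("X", "Y", "Y", "Z", "Y", "X"),
    events = 1, n = 10))
  expect_equal(ds$treatments[ds$reference], "Y")
  ds2 <- nma_data(ds$data[, 1:4], reference = "Z")
  expect_equal(ds2$treatments[ds2$reference], "Z")
})

test_that("JSON and long-CSV exports round-trip", {
  ds <- hf_data()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_dataset_json(ds, tmp)
  j <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(j$summary$n_events, 1616)
  expect_equal(nrow(j$network$edges), 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_nma_long(ds, csv)
  again <- read_nma_long(csv, treatments = hf_treatments)
  expect_equal(again$data, ds$data)
})
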