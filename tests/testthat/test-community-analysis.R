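make_table <- function(n, seed = 1, treatment = rep(c("00", "0M", "F0", "FM"),
                                                    length.out = n)) {
  withr::with_seed(seed, {
    params <- tibble::tibble(sod_id = sprintf("s%02d", seq_len(n)))
    for (p in parameter_names()) params[[p]] <- rnorm(n)
    labels <- tibble::tibble(
      sod_id = params$sod_id,
      region = factor(rep(paste0("region_", 1:3), length.out = n)),
      treatment = treatment
    )
    aggregate_parameters(params, labels)
  })
}

test_that("aggregation derives factorial flags and rejects inconsistencies", {
  tab <- make_table(12)
  expect_identical(nrow(tab), 12L)
  expect_identical(as.character(tab$mown[tab$treatment == "0M"][1]), "Y")
  expect_identical(as.character(tab$fertilized[tab$treatment == "0M"][1]), "N")
  expect_identical(as.character(tab$mown[tab$treatment == "FM"][1]), "Y")
  expect_identical(as.character(tab$fertilized[tab$treatment == "F0"][1]), "Y")

  params <- tibble::tibble(sod_id = c("a", "a"), height = c(1, 2))
  labels <- tibble::tibble(sod_id = "a", region = "r1", treatment = "00")
  expect_error(aggregate_parameters(params, labels), "duplicate")

  params2 <- tibble::tibble(sod_id = "a", height = 1)
  labels2 <- tibble::tibble(sod_id = "a", region = "r1", treatment = "FM",
                            fertilized = "N")
  expect_error(aggregate_parameters(params2, labels2), "contradiction")
})

test_that("specific leaf area divides area by dry mass in mm^2/mg", {
  expect_equal(specific_leaf_area(300, 10), 30)
  expect_equal(specific_leaf_area(0, 5), 0)
  expect_error(specific_leaf_area(100, 0), "dry_mass")
})

test_that("the standard fertilizer dose corresponds to ~99 kg N per ha and year", {
  expect_equal(nitrogen_application_rate(), 98.88)
  expect_lt(abs(nitrogen_application_rate() - 99), 0.5)
  # double application doubles the annual rate
  expect_equal(nitrogen_application_rate(applications_per_year = 2), 2 * 98.88)
})

test_that("community-weighted means match brute-force weighted means", {
  abund <- tibble::tibble(
    sod_id = c("s1", "s1", "s2", "s3", "s3"),
    species = c("A", "B", "A", "A", "B"),
    cover = c(50, 50, 30, 75, 25)
  )
  traits <- tibble::tibble(
    species = c("A", "B"),
    leaf_length = c(10, 20),
    sla = c(8, 16)
  )
  cwm <- community_weighted_mean(abund, traits)
  expect_equal(cwm$leaf_length[cwm$sod_id == "s1"], 15)
  expect_equal(cwm$leaf_length[cwm$sod_id == "s2"], 10) # single species
  expect_equal(cwm$sla[cwm$sod_id == "s3"], (75 * 8 + 25 * 16) / 100) # 10

  # species missing a trait drop out of both sums for that trait
  traits_na <- traits
  traits_na$sla[2] <- NA
  cwm2 <- community_weighted_mean(abund, traits_na)
  expect_equal(cwm2$sla[cwm2$sod_id == "s1"], 8)

  # a sod with no usable species is missing, not 0
  traits_none <- tibble::tibble(species = "C", sla = 5)
  cwm3 <- community_weighted_mean(abund, traits_none)
  expect_true(all(is.na(cwm3$sla)))
})

test_that("CWM is cover-rescaling invariant and bounded by trait range", {
  withr::with_seed(5, {
    abund <- tibble::tibble(
      sod_id = rep(sprintf("s%d", 1:6), each = 4),
      species = rep(letters[1:4], 6),
      cover = runif(24, 1, 60)
    )
    traits <- tibble::tibble(species = letters[1:4], t1 = runif(4, 5, 50))
  })
  cwm <- community_weighted_mean(abund, traits)
  scaled <- abund
  scaled$cover <- scaled$cover * 7.3
  expect_equal(community_weighted_mean(scaled, traits)$t1, cwm$t1)
  expect_true(all(cwm$t1 >= min(traits$t1) & cwm$t1 <= max(traits$t1)))
})

test_that("classification separates separable data and is seed-reproducible", {
  tab <- make_table(40, seed = 2)
  tab$height <- ifelse(tab$mown == "Y", 20, 300) + rnorm(40)
  cl <- classify(tab, "mown", n_trees = 300, seed = 7)
  expect_gte(cl$accuracy, 0.99)
  expect_identical(cl$accuracy, sum(diag(cl$confusion)) / sum(cl$confusion))
  expect_identical(cl$top_variables[1], "height")

  cl2 <- classify(tab, "mown", n_trees = 300, seed = 7)
  expect_identical(cl2$accuracy, cl$accuracy)
  expect_identical(tidy(cl2), tidy(cl))
  expect_identical(nrow(tidy(cl)), 14L)
  expect_identical(glance(cl)$n, 40L)
})

test_that("label-independent predictors classify at chance level", {
  tab <- make_table(60, seed = 3) # predictors independent of labels
  accs <- vapply(1:5, function(s) {
    classify(tab, "mown", n_trees = 300, seed = s)$accuracy
  }, numeric(1))
  band <- 1.96 * sqrt(0.25 / 60)
  expect_lt(abs(mean(accs) - 0.5), band)
})

test_that("duplicating predictors leaves accuracy within OOB noise", {
  tab <- make_table(40, seed = 4)
  tab$height <- ifelse(tab$fertilized == "Y", 1, 0) + rnorm(40, sd = 0.7)
  base_acc <- classify(tab, "fertilized", n_trees = 500, seed = 1)$accuracy
  dup <- tab
  for (p in parameter_names()) dup[[paste0(p, "_copy")]] <- dup[[p]]
  dup_acc <- classify(dup, "fertilized", n_trees = 500, seed = 1,
                      predictors = c(parameter_names(),
                                     paste0(parameter_names(), "_copy")))$accuracy
  expect_lt(abs(dup_acc - base_acc), 0.15)
})

test_that("classification guards: single class, too few rows, missing data", {
  tab <- make_table(12)
  single <- tab
  single$mown <- factor("N", levels = c("N", "Y"))
  expect_error(classify(single, "mown", n_trees = 50), "single class")
  expect_error(classify(tab[1:8, ], "mown", n_trees = 50), "at least 10")

  tab$ndvi[1:2] <- NA
  cl <- classify(tab, "mown", n_trees = 50, seed = 1)
  expect_identical(cl$n_dropped, 2L)
  expect_identical(cl$n_used, 10L)
})

test_that("cross-validated accuracy broadly agrees with out-of-bag", {
  tab <- make_table(48, seed = 6)
  tab$height <- ifelse(tab$mown == "Y", 0, 3) + rnorm(48)
  oob <- classify(tab, "mown", n_trees = 300, seed = 2, method = "oob")
  cv <- classify(tab, "mown", n_trees = 300, seed = 2, method = "cv")
  expect_lt(abs(oob$accuracy - cv$accuracy), 0.15)
})

test_that("per-event accuracies are deterministic and propagate failures", {
  tab <- make_table(24, seed = 8)
  tab$height <- ifelse(tab$mown == "Y", 0, 5) + rnorm(24, sd = 0.5)
  two <- dplyr::bind_rows(
    dplyr::mutate(tab, scan_event = 1),
    dplyr::mutate(tab, scan_event = 2)
  )
  acc <- accuracy_timeseries(two, "mown", n_trees = 200, seed = 3)
  expect_identical(nrow(acc), 2L)
  expect_identical(acc$accuracy[1], acc$accuracy[2]) # identical data, same seed

  # an event with a single class fails alone, the other proceeds
  broken <- two
  broken$mown[broken$scan_event == 2] <- factor("N", levels = c("N", "Y"))
  acc2 <- accuracy_timeseries(broken, "mown", n_trees = 200, seed = 3)
  expect_false(is.na(acc2$accuracy[1]))
  expect_true(is.na(acc2$accuracy[2]))
  expect_match(acc2$note[2], "single class")
})

test_that("mowing is easier to classify after the treatment than before", {
  ex <- generate_experiment(n_sods = 24, n_events = 2, seed = 12)
  ph <- phenotype_experiment(ex, scanner_model(grid_resolution = 5, xy_jitter = 0.3))
  acc <- accuracy_timeseries(ph$table, "mown", n_trees = 300, seed = 1)
  expect_gt(acc$accuracy[acc$scan_event == 2], acc$accuracy[acc$scan_event == 1])
  expect_gte(acc$accuracy[acc$scan_event == 2], 0.9)
})

test_that("group tests reproduce textbook t and F statistics", {
  tab <- tibble::tibble(
    sod_id = sprintf("s%d", 1:6),
    height = c(1, 2, 3, 4, 5, 6),
    mown = factor(c("N", "N", "N", "Y", "Y", "Y"))
  )
  res <- group_difference_tests(tab, "mown", parameters = "height")
  # Welch two-sample t for {1,2,3} vs {4,5,6}
  expect_equal(res$statistic, -3 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  expect_identical(res$test, "t")

  # three identical groups: F ~ 0
  tab3 <- tibble::tibble(
    sod_id = sprintf("s%d", 1:9),
    ndvi = rep(c(0.4, 0.5, 0.6), 3),
    region = factor(rep(c("a", "b", "c"), each = 3))
  )
  res3 <- group_difference_tests(tab3, "region", parameters = "ndvi")
  expect_identical(res3$test, "F")
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_identical(res3$df, 2)
  expect_identical(res3$df2, 6)

  # equal means, large n: |t| small
  withr::with_seed(9, {
    big <- tibble::tibble(
      sod_id = sprintf("s%d", 1:400),
      psri = rnorm(400),
      fertilized = factor(rep(c("N", "Y"), 200))
    )
  })
  resb <- group_difference_tests(big, "fertilized", parameters = "psri")
  expect_lt(abs(resb$statistic), 3)

  # degenerate group handled with a note
  degen <- tibble::tibble(sod_id = c("a", "b", "c"), hue = c(1, 2, 3),
                          mown = factor(c("N", "N", "Y")))
  resd <- group_difference_tests(degen, "mown", parameters = "hue")
  expect_true(is.na(resd$statistic))
  expect_match(resd$note, "degenerate")
})
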