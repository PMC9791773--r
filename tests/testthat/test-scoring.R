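test_that("the three published worked examples score exactly", {
  expect_equal(score_density(200, "dairy", "4-5"), 8)
  expect_equal(score_density(150, "cereals", "2-3"), 5)
  expect_equal(score_density(45, "snacks", "4-5"), 2.75)
})

test_that("adequacy scoring is proportional below and capped above", {
  expect_equal(score_adequacy(0, 250), 0)
  expect_equal(score_adequacy(300, 250), 10)        # capped at recommendation
  expect_equal(score_adequacy(250, 250), 10)        # inclusive at the cutoff
  expect_equal(score_density(41.5, "fruits", "2-3"), 41.5 / 83 * 10)
  d <- seq(0, 500, length.out = 101)
  s <- score_adequacy(d, 250)
  expect_true(all(diff(s) >= 0))                    # nondecreasing
})

test_that("moderation scoring follows the nearest-bound linear rule", {
  expect_equal(score_moderation(20, 18, 21), 10)    # inside interval
  expect_equal(score_moderation(0, 18, 21), 0)      # zero intake
  expect_equal(score_density(35.5, "cereals", "2-3"),
               (1 - abs(1 - 35.5 / 71)) * 10)
  expect_equal(score_density(250, "cereals", "2-3"), 0)  # > twice upper
  # continuity at the interval bounds and exact zero at twice the upper bound
  expect_equal(score_moderation(71, 71, 100), 10)
  expect_equal(score_moderation(100, 71, 100), 10)
  expect_equal(score_moderation(200, 71, 100), 0)
  expect_gt(score_moderation(200 - 1e-9, 71, 100), 0)
  expect_equal(score_moderation(200 + 1e-9, 71, 100), 0)
  # monotone on each side of the plateau
  below <- score_moderation(seq(1e-6, 71, length.out = 50), 71, 100)
  above <- score_moderation(seq(100, 250, length.out = 50), 71, 100)
  expect_true(all(diff(below) >= 0))
  expect_true(all(diff(above) <= 0))
  expect_error(score_moderation(10, 71, 100, zero_above_density = 150),
               "2 \\* upper_density")
})

test_that("limitation scoring decays linearly from full score to the limit", {
  expect_equal(score_limitation(0, 100), 5)
  expect_equal(score_limitation(150, 100), 0)
  expect_equal(score_limitation(100, 100), 0)       # zero at the limit itself
  d <- seq(0, 200, length.out = 101)
  expect_true(all(diff(score_limitation(d, 100)) <= 0))
})

test_that("score_density validates its component and age-group lookup", {
  expect_error(score_density(10, "chocolate", "2-3"), "no component")
  expect_error(score_density(10, "dairy", "6-7"), "no component")
  expect_error(score_adequacy(-1, 100), "finite and >= 0")
})

test_that("densities are the ratio of daily means, scaled to 1000 kcal", {
  rec <- tibble::tibble(subject_id = "a", day = 1:3,
                        energy_kcal = c(1000, 1200, 1400),
                        dairy = c(150, 253, 250))
  d <- densify(rec)
  expect_equal(d$mean_energy, 1200)
  expect_equal(d$n_days_used, 3L)
  expect_equal(d$dairy, (653 / 3) / 1200 * 1000, tolerance = 1e-12)

  one <- tibble::tibble(subject_id = "b", day = 1, energy_kcal = 1000,
                        dairy = 200)
  expect_equal(densify(one)$dairy, 200)             # identity at 1000 kcal

  zero <- tibble::tibble(subject_id = "c", day = 1:2, energy_kcal = c(0, 0),
                         dairy = c(1, 2))
  expect_error(densify(zero), "densities are undefined")
})

test_that("implausible mean energies are excluded with strict bounds", {
  rec <- tibble::tibble(
    subject_id = rep(c("low", "edge", "ok", "high"), each = 2),
    day = rep(1:2, 4),
    energy_kcal = c(280, 320, 400, 400, 1100, 1200, 4500, 4100))
  res <- filter_plausible_energy(rec)
  expect_setequal(unique(res$kept$subject_id), c("edge", "ok"))
  expect_equal(nrow(res$excluded), 2)
  expect_equal(res$excluded$reason[res$excluded$subject_id == "low"],
               "energy_below_minimum")
  expect_equal(res$excluded$reason[res$excluded$subject_id == "high"],
               "energy_above_maximum")
})

test_that("a subject meeting every max-score criterion totals 90", {
  dens <- c(vegetables = 179, fruits = 107, dairy = 250, soybeans = 11,
            aquatic = 14, cereals = 100, eggs = 20, red_meat_poultry = 25,
            vitamin_a = 500, iron = 10, snacks = 0)
  fix <- targeted_subject(5, dens)
  res <- score_subject(fix$profile, fix$records)
  expect_equal(res$total, 90)
})

test_that("zero consumption of everything scores 5 (the limitation points)", {
  dens <- stats::setNames(rep(0, 11), component_ids(cpdi_standard()))
  fix <- targeted_subject(3, dens)
  res <- score_subject(fix$profile, fix$records)
  expect_equal(res$total, 5)
  expect_equal(res$snacks, 5)
})

test_that("the worked-example densities embedded in one subject total 85.75", {
  dens <- c(vegetables = 179, fruits = 107, dairy = 200, soybeans = 11,
            aquatic = 14, cereals = 100, eggs = 20, red_meat_poultry = 25,
            vitamin_a = 500, iron = 10, snacks = 45)
  fix <- targeted_subject(4, dens)
  res <- score_subject(fix$profile, fix$records)
  expect_equal(res$dairy, 8)
  expect_equal(res$snacks, 2.75)
  expect_equal(res$total, 90 - (10 - 8) - (5 - 2.75))
})

test_that("score_cohort collects rejects without failing the run", {
  coh <- demo_cohort(n = 6)
  coh$profiles$age_years[2] <- 7
  orphan <- coh$records[1:3, ]
  orphan$subject_id <- "GHOST"
  records <- dplyr::bind_rows(coh$records, orphan)
  res <- score_cohort(records, coh$profiles)
  expect_equal(nrow(res), 5)
  rej <- rejects(res)
  expect_setequal(rej$reason, c("no_profile", "age_outside_2_5"))
  expect_true("GHOST" %in% rej$subject_id)
  expect_equal(res$subject_id, sort(res$subject_id))  # deterministic order

  empty <- score_cohort(coh$records[0, ], coh$profiles[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("components missing from the records score as zero consumption", {
  fix <- targeted_subject(5, c(dairy = 250))
  expect_warning(res <- score_cohort(fix$records, fix$profile),
                 "scored as 0 consumption")
  expect_equal(res$dairy, 10)
  expect_equal(res$vegetables, 0)
  expect_equal(res$snacks, 5)
  expect_true("vegetables" %in% attr(res, "missing_components"))
})

test_that("totals are the sum of subscores and stay within [0, 90]", {
  coh <- demo_cohort(n = 80, seed = 11)
  res <- score_cohort(coh$records, coh$profiles)
  ids <- component_ids(cpdi_standard())
  expect_equal(res$total, rowSums(as.data.frame(res)[ids]))
  expect_true(all(res$total >= 0 & res$total <= 90))
  for (id in ids) {
    ms <- cpdi_standard()$components$max_score[
      cpdi_standard()$components$component_id == id][1]
    expect_true(all(res[[id]] >= 0 & res[[id]] <= ms))
  }
})

test_that("rescaling a subject's intakes and energy leaves scores unchanged", {
  coh <- demo_cohort(n = 40, seed = 3)
  res1 <- score_cohort(coh$records, coh$profiles)
  set.seed(99)
  scale_by <- stats::setNames(stats::runif(40, 0.2, 5),
                              unique(coh$records$subject_id))
  rec2 <- coh$records
  cols <- c("energy_kcal", component_ids(cpdi_standard()))
  for (col in cols) {
    rec2[[col]] <- rec2[[col]] * scale_by[rec2$subject_id]
  }
  res2 <- score_cohort(rec2, coh$profiles)
  expect_equal(res2$total, res1$total, tolerance = 1e-9)
})
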