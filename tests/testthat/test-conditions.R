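test_that("stored reward sequences have the right length and composition", {
  seqs <- reward_sequences()
  expect_named(seqs, c("0.2", "0.3", "0.5", "0.7", "0.8"))
  expect_true(all(lengths(seqs) == 20))
  # proportion of rewarded pokes over one cycle equals the nominal label
  for (lab in names(seqs)) {
    expect_identical(sum(seqs[[lab]]), as.integer(20 * as.numeric(lab)))
  }
  expect_equal(sum(sequence_outcome(0.8, 0:19)) / 20, 0.8)
  expect_identical(sum(sequence_outcome(0.5, 0:19)), 10L)
})

test_that("sequence outcomes repeat cyclically and reject unknown labels", {
  for (lab in c(0.2, 0.5, 0.8)) {
    expect_identical(sequence_outcome(lab, 20), sequence_outcome(lab, 0))
    expect_identical(sequence_outcome(lab, 0:19),
                     sequence_outcome(lab, 40:59))
  }
  expect_error(sequence_outcome(0.35, 0), "valid labels")
  expect_error(sequence_outcome(0.5, -1))
})

test_that("relative intensity matches the difference/mean ratio", {
  expect_equal(round(relative_intensity(4, 20), 2), 1.33)
  expect_equal(relative_intensity(0.2, 0.5), 0.857, tolerance = 1e-3)
  expect_equal(round(relative_intensity(4.7, 9.4), 2), 0.67)
  expect_equal(relative_intensity(3.7, 3.7), 0)
  # symmetric, and the 4 vs 10 uL pair matches the probability pair
  expect_equal(relative_intensity(4, 20), relative_intensity(20, 4))
  expect_equal(relative_intensity(4, 10), relative_intensity(0.2, 0.5),
               tolerance = 1e-12)
  expect_error(relative_intensity(0, 5))
  expect_error(relative_intensity(4, -1))
})

test_that("expected value is volume times probability", {
  expect_equal(expected_value(reward_option(20, 0.2)), 4)
  expect_equal(expected_value(4, 1.0), 4)
  # the experiment-2 incongruent pair is equally profitable
  i2 <- condition_row(2, "I")
  expect_equal(i2$relative_value, 1)
  expect_gt(i2$volume_a, i2$volume_b) # scored toward the higher volume
})

test_that("catalogue has the documented conditions per experiment", {
  expect_identical(nrow(condition_catalogue(1)), 6L)
  expect_identical(nrow(condition_catalogue(2)), 5L)
  expect_identical(nrow(condition_catalogue(3)), 8L)
  expect_false("BVLP" %in% condition_catalogue(2)$label)
  expect_identical(condition_catalogue(4)$label, condition_catalogue(1)$label)
  c1 <- condition_catalogue(1); c4 <- condition_catalogue(4)
  expect_equal(c1[, c("volume_a", "prob_a", "volume_b", "prob_b")],
               c4[, c("volume_a", "prob_a", "volume_b", "prob_b")])
  expect_error(condition_catalogue(5), "1, 2, 3, 4")
})

test_that("congruent conditions are dominated, incongruent ones split", {
  for (e in c(1, 2, 4)) {
    cc <- condition_row(e, "C")
    expect_true(cc$volume_a > cc$volume_b && cc$prob_a > cc$prob_b)
    ci <- condition_row(e, "I")
    expect_true((ci$volume_a > ci$volume_b) != (ci$prob_a > ci$prob_b))
  }
  # baselines differ on exactly one dimension
  for (e in 1:4) {
    cat_e <- condition_catalogue(e)
    base <- cat_e[cat_e$relevant_dimension != "both", ]
    differs <- (abs(base$volume_a - base$volume_b) > 1e-9) +
      (abs(base$prob_a - base$prob_b) > 1e-9)
    expect_true(all(differs == 1))
  }
})

test_that("cohort-2 variant substitutes the delivered volumes", {
  c2 <- condition_catalogue(1, "cohort2")
  expect_setequal(unique(c(c2$volume_a, c2$volume_b)), c(4.7, 20.3))
  c3fig <- condition_catalogue(3, "cohort2")
  vol_rel <- c3fig[c3fig$relevant_dimension == "volume", ]
  expect_setequal(unique(c(vol_rel$volume_a, vol_rel$volume_b)), c(4.7, 9.4))
  c3txt <- condition_catalogue(3, "cohort2", cohort2_exp3_source = "text")
  vol_rel <- c3txt[c3txt$relevant_dimension == "volume", ]
  expect_setequal(unique(c(vol_rel$volume_a, vol_rel$volume_b)), c(4.8, 9.6))
  # background volumes use the delivered values in both variants
  expect_setequal(c3fig$background_value[c3fig$background_dimension == "volume"],
                  c(4.7, 9.4, 14.0, 20.3))
})

test_that("background levels normalize to the maximum tested value", {
  expect_equal(background_level(15, c(4, 10, 15, 20)), 0.75)
  expect_equal(background_level(20, c(4, 10, 15, 20)), 1)
  expect_equal(background_level(4, c(4, 10, 15, 20)), 0.2)
  expect_error(background_level(12, c(4, 10, 15, 20)), "not among")
  c3 <- condition_catalogue(3)
  expect_setequal(c3$background_level[c3$background_dimension == "volume"],
                  c(0.2, 0.5, 0.75, 1))
})

test_that("the full schedule spans 50 days of acquisition/reversal pairs", {
  expect_identical(schedule_days(1:4), 50L)
  plan <- session_plan(n_mice = 4, experiments = 1, seed = 3)
  expect_identical(max(plan$day), 12L) # 6 conditions x 2 days
  # each condition appears exactly twice per mouse: acquisition then reversal
  per_cond <- split(plan, interaction(plan$mouse_id, plan$condition_label))
  for (p in per_cond) {
    expect_identical(nrow(p), 2L)
    expect_identical(sort(p$reversal), 0:1)
    # reversal swaps the two rewarding dispensers only
    expect_identical(p$dispenser_a[p$reversal == 0],
                     p$dispenser_b[p$reversal == 1])
    expect_identical(p$dispenser_b[p$reversal == 0],
                     p$dispenser_a[p$reversal == 1])
  }
})

test_that("catalogue round-trips through a flat file", {
  cat1 <- condition_catalogue(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(cat1, path)
  expect_equal(read_catalogue(path), cat1)
})
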