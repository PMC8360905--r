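test_that("bootstrap CIs collapse on constant data and nest by construction", {
  ci <- bootstrap_mean_ci(rep(0.3, 10), seed = 1)
  expect_equal(ci$estimate, 0.3)
  expect_equal(ci$ci90, c(0.3, 0.3))
  expect_equal(ci$ci95, c(0.3, 0.3))
  for (s in 1:10) {
    x <- rnorm(24, 0.2, 0.1)
    ci <- bootstrap_mean_ci(x, seed = s)
    expect_true(ci$ci95[1] <= ci$ci90[1] && ci$ci90[2] <= ci$ci95[2])
  }
  expect_error(bootstrap_mean_ci(1), "two finite")
  expect_error(bootstrap_mean_ci(c(1, NA)), "finite")
})

test_that("bootstrap CIs are deterministic given a seed and well calibrated", {
  x <- rnorm(24, 0.3, 0.05)
  expect_identical(bootstrap_mean_ci(x, seed = 3),
                   bootstrap_mean_ci(x, seed = 3))
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(24, 0.3, 0.05)
    ci <- bootstrap_mean_ci(x, seed = 1000 + s)
    hits <- hits + (abs(ci$estimate - 0.3) < 0.03 && ci$ci95[1] > 0)
  }
  expect_gte(hits, 48) # a clear effect is detected in almost every sample
})

test_that("TOST outcomes follow the four-way CI logic", {
  expect_identical(tost_classify(rep(0, 12), seed = 1)$outcome, "equivalent")
  expect_identical(tost_classify(rep(0.05, 12), seed = 1)$outcome,
                   "trivial_difference")
  for (s in 1:20) {
    set.seed(s)
    expect_identical(
      tost_classify(rnorm(24, 0.3, 0.05), seed = 2000 + s)$outcome,
      "different")
  }
  # a wide, zero-centred sample is inconclusive
  set.seed(8)
  x <- rnorm(8, 0, 0.4)
  x <- x - mean(x)
  expect_identical(tost_classify(x, seed = 5)$outcome, "inconclusive")
  # exactly one of the four outcomes, always
  for (s in 1:20) {
    set.seed(100 + s)
    out <- tost_classify(rnorm(10, 0, 0.15), seed = s)$outcome
    expect_true(out %in% c("equivalent", "trivial_difference",
                           "inconclusive", "different"))
  }
})

test_that("familywise alpha divides by k^2/4 and never inflates", {
  expect_equal(familywise_alpha(0.05, 2), 0.05)
  expect_equal(familywise_alpha(0.05, 0), 0.05)
  expect_equal(familywise_alpha(0.05, 8), 0.003125)
  a <- vapply(0:10, familywise_alpha, numeric(1), alpha = 0.05)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a <= 0.05))
  expect_error(familywise_alpha(0.05, 2.5))
})

test_that("problematic cases are counted from supported near-bound CIs", {
  near <- tost_classify(rep(0.095, 20), seed = 1)  # CI at 0.095, bound 0.1
  far <- tost_classify(rep(0.01, 20), seed = 1)
  diff <- tost_classify(rep(0.5, 20), seed = 1)
  expect_identical(count_problematic_cases(list(near, far, diff)), 1L)
})

test_that("background slopes recover hand-built effects", {
  levels <- c(0.2, 0.5, 0.75, 1)
  cat3 <- condition_catalogue(3)
  perf <- do.call(rbind, lapply(1:3, function(m) {
    do.call(rbind, lapply(seq_len(nrow(cat3)), function(i) {
      lvl <- cat3$background_level[i]
      p <- if (cat3$relevant_dimension[i] == "probability") {
        0.7                      # flat: no background effect
      } else {
        0.6 + 0.1 * (lvl - 0.2) / 0.8  # rises by 0.1 from level 0.2 to 1
      }
      perf_row(m, 3, cat3$label[i], p)
    }))
  }))
  res <- background_slopes(perf, seed = 3)
  flat <- res$slopes$slope[res$slopes$relevant_dimension == "probability"]
  rising <- res$slopes$slope[res$slopes$relevant_dimension == "volume"]
  expect_lt(max(abs(flat)), 1e-9)
  # a 0.1 rise across the background range is exactly the sesoi slope
  expect_lt(max(abs(rising - 0.125)), 1e-9)
  # flat slopes are zero up to least-squares rounding, so the group test
  # must support equivalence (a degenerate CI at ~1e-17 may exclude 0)
  expect_true(res$tost$probability$outcome %in%
                c("equivalent", "trivial_difference"))
  expect_error(background_slopes(perf[-1, ], seed = 3), "4 background")
})

test_that("contrast tables build the eight contrasts with re-scoring", {
  vals <- c(BPLV = 0.75, BPHV = 0.72, BVLP = 0.68, BVHP = 0.74,
            C = 0.85, I = 0.25)
  perf <- do.call(rbind, lapply(1:8, function(m) {
    do.call(rbind, lapply(names(vals), function(lab) {
      perf_row(m, 1, lab, vals[[lab]])
    }))
  }))
  ct <- contrast_table(perf, 1, seed = 7)
  expect_identical(nrow(ct), 8L)
  expect_setequal(ct$contrast,
                  c("C-BPLV", "C-BPHV", "C-BVLP", "C-BVHP",
                    "I-BPLV", "I-BPHV", "I-BVLP", "I-BVHP"))
  # I is re-scored toward probability against the probability baselines
  expect_equal(ct$mean_difference[ct$contrast == "I-BPLV"],
               (1 - 0.25) - 0.75)
  expect_equal(ct$mean_difference[ct$contrast == "I-BVHP"], 0.25 - 0.74)
  expect_equal(ct$mean_difference[ct$contrast == "C-BPLV"], 0.85 - 0.75)
  expect_true(all(ct$outcome %in% c("equivalent", "trivial_difference",
                                    "inconclusive", "different")))
  # constant per-mouse differences give degenerate, decisive outcomes:
  # (1 - 0.25) - 0.75 = 0 exactly, (1 - 0.25) - 0.72 = 0.03
  expect_identical(ct$outcome[ct$contrast == "I-BPLV"], "equivalent")
  expect_identical(ct$outcome[ct$contrast == "I-BPHV"], "trivial_difference")
})

test_that("experiment 2 reuses the experiment-1 volume baseline", {
  labs2 <- c("BPLV", "BPHV", "BVHP", "C", "I")
  perf <- do.call(rbind, lapply(1:6, function(m) {
    rbind(
      do.call(rbind, lapply(labs2, function(lab) perf_row(m, 2, lab, 0.6))),
      perf_row(m, 1, "BVLP", 0.6)
    )
  }))
  ct <- contrast_table(perf, 2, seed = 9)
  expect_identical(nrow(ct), 8L)
  # a condition contrasted with an identical one is equivalent
  expect_identical(ct$outcome[ct$contrast == "C-BVLP"], "equivalent")
  # without the reused baseline the contrast cannot be built
  expect_error(contrast_table(perf[perf$experiment != 1, ], 2, seed = 9),
               "BVLP")
  expect_error(contrast_table(perf, 3), "experiments 1, 2 and 4")
})
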