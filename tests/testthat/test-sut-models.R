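test_that("salience is (max - min)/mean and matches relative intensity", {
  expect_equal(round(salience(c(4, 20)), 2), 1.33)
  expect_equal(salience(c(0.2, 0.5)), 0.857, tolerance = 1e-3)
  expect_equal(salience(c(7, 7)), 0)
  expect_equal(salience(c(4, 20)), relative_intensity(4, 20))
  expect_error(salience(5), "two option values")
})

test_that("dimension selection follows each rule's criterion", {
  vols_eq <- c(4, 4); probs <- c(0.2, 0.5)     # BPLV: s(v)=0, s(p)=0.857
  vols <- c(4, 20); probs_eq <- c(0.5, 0.5)    # BVHP: s(v)=1.33, s(p)=0
  expect_identical(
    decision_dimension(sut_model("vfirst", 0.5), vols_eq, probs),
    "probability")
  expect_identical(
    decision_dimension(sut_model("pfirst", 0.95), vols, probs_eq),
    "volume")
  # wta with theta = 1 always picks the higher-salience dimension
  wta <- sut_model("wta", 0.7, theta = 1)
  dims <- replicate(20, decision_dimension(wta, c(4, 20), c(0.2, 0.5)))
  expect_true(all(dims == "volume")) # s(v)=1.33 > s(p)=0.857
  # below both thresholds the lexicographic rules revert to random choice
  expect_identical(
    decision_dimension(sut_model("pfirst", 0.95), c(10, 12), c(0.5, 0.6)),
    "random")
  expect_error(decision_dimension(sut_model("sev", 1), vols, probs),
               "non-compensatory")
})

test_that("rnonc selects volume with probability theta_v", {
  set.seed(42)
  m <- sut_model("rnonc", 0.05, theta_v = 0.3)
  dims <- replicate(4000, decision_dimension(m, c(4, 20), c(0.2, 0.5)))
  expect_equal(mean(dims == "volume"), 0.3, tolerance = 0.03)
})

test_that("remembered-value samples have the construction's mean", {
  # gamma -> 0 degenerates to the point estimate pi * v
  m0 <- sut_model("sev", 1e-9)
  expect_equal(sample_remembered_value(m0, 20, 0.5), 10, tolerance = 1e-6)
  set.seed(7)
  n <- 1e5
  sev <- sample_remembered_value(sut_model("sev", 1.05), 20, 0.5, n = n)
  expect_lt(abs(mean(sev) - 10), 3 * 1.05 * 10 / sqrt(n))
  # independence of the two-scalar traces: E(XY) = E(X)E(Y) = 10
  ts <- sample_remembered_value(sut_model("2scal", 0.65), 20, 0.5, n = n)
  expect_lt(abs(mean(ts) - 10), 3 * sd(ts) / sqrt(n))
  expect_error(sample_remembered_value(sut_model("wta", 0.7), 20, 0.5),
               "dimension")
})

test_that("truncated sampling never returns negative values", {
  set.seed(1)
  m <- sut_model("sev", 2, truncate_at_zero = TRUE)
  x <- sample_remembered_value(m, 4, 0.2, n = 5000)
  expect_true(all(x >= 0))
  expect_true(is.na(choice_probability(m, opt(4, 0.5), opt(4, 0.2))))
})

test_that("closed-form choice probabilities match their normal algebra", {
  sev <- sut_model("sev", 1.05)
  expect_equal(choice_probability(sev, opt(4, 0.5), opt(4, 0.2)),
               pnorm(0.3 / (1.05 * sqrt(0.5^2 + 0.2^2))))
  expect_equal(round(choice_probability(sev, opt(4, 0.5), opt(4, 0.2)), 3),
               0.702)
  wta <- sut_model("wta", 0.7, theta = 1)
  expect_equal(round(choice_probability(wta, opt(20, 0.5), opt(4, 0.5)), 3),
               0.869) # pnorm(16 / (0.7 * sqrt(416)))
  # equal options are a coin flip; the gamma -> 0 limit is deterministic
  expect_equal(choice_probability(sev, opt(4, 0.2), opt(4, 0.2)), 0.5)
  expect_equal(choice_probability(sut_model("sev", 1e-12),
                                  opt(4, 0.5), opt(4, 0.2)), 1,
               tolerance = 1e-9)
  expect_true(is.na(choice_probability(sut_model("2scal", 0.65),
                                       opt(4, 0.5), opt(4, 0.2))))
})

test_that("choice probabilities of the two options sum to one", {
  pairs <- list(c(4, 0.5, 4, 0.2), c(20, 0.5, 4, 0.5),
                c(20, 0.5, 4, 0.2), c(20, 0.2, 4, 0.5))
  for (kind in setdiff(model_kinds(), "2scal")) {
    for (pr in pairs) {
      m <- sut_model(kind, 0.7, theta_v = 0.3, theta = 0.8)
      a <- opt(pr[1], pr[2]); b <- opt(pr[3], pr[4])
      expect_equal(choice_probability(m, a, b) + choice_probability(m, b, a),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("simulated choice frequencies agree with the closed forms", {
  pairs <- list(c(4, 0.5, 4, 0.2), c(20, 0.5, 4, 0.5), c(20, 0.2, 4, 0.5))
  n <- 2e4
  i <- 0
  for (kind in c("sev", "rnonc", "wta", "pfirst", "vfirst")) {
    for (g in c(0.5, 1.05)) {
      for (pr in pairs) {
        i <- i + 1
        m <- sut_model(kind, g, theta_v = 0.4, theta = 0.85)
        a <- opt(pr[1], pr[2]); b <- opt(pr[3], pr[4])
        p <- choice_probability(m, a, b)
        expect_lt(abs(choice_freq(m, a, b, n, seed = 100 + i) - p),
                  three_se(p, n))
      }
    }
  }
})

test_that("rnonc reduces to single-dimension rules at extreme theta_v", {
  a <- opt(20, 0.2); b <- opt(4, 0.5)
  g <- 0.6
  expect_equal(
    choice_probability(sut_model("rnonc", g, theta_v = 1), a, b),
    pnorm(16 / (g * sqrt(416))))
  expect_equal(
    choice_probability(sut_model("rnonc", g, theta_v = 0), a, b),
    pnorm(-0.3 / (g * sqrt(0.29))))
  # the mixture at theta_v = 0.5 sits midway, verified by simulation
  m <- sut_model("rnonc", g, theta_v = 0.5)
  p <- choice_probability(m, a, b)
  expect_equal(p, 0.5 * pnorm(16 / (g * sqrt(416))) +
                 0.5 * pnorm(-0.3 / (g * sqrt(0.29))))
  expect_lt(abs(choice_freq(m, a, b, 2e4, seed = 9) - p),
            three_se(p, 2e4))
})

test_that("sev preference for the better option weakens as gamma grows", {
  a <- opt(20, 0.5); b <- opt(4, 0.2)
  probs <- vapply(gamma_grid(),
                  function(g) choice_probability(sut_model("sev", g), a, b),
                  numeric(1))
  expect_true(all(diff(probs) <= 0))
  expect_true(all(probs > 0.5))
})

test_that("wta reverts to a fair coin when saliences are equal", {
  # 4 vs 10 uL has the same relative intensity as 0.2 vs 0.5
  m <- sut_model("wta", 0.7)
  a <- opt(10, 0.2); b <- opt(4, 0.5)
  expect_equal(choice_probability(m, a, b), 0.5)
  f <- choice_freq(m, a, b, 2e4, seed = 4)
  expect_lt(abs(f - 0.5), three_se(0.5, 2e4))
})

test_that("2scal sampling is reproducible and dimension-order invariant", {
  m <- sut_model("2scal", 0.65)
  a <- opt(20, 0.2); b <- opt(4, 0.5)
  expect_identical(choice_freq(m, a, b, 1e4, seed = 5),
                   choice_freq(m, a, b, 1e4, seed = 5))
  # oracle drawing the volume trace before the probability trace
  swapped_freq <- function(n, seed) {
    set.seed(seed)
    sa <- rnorm(n, 20, 0.65 * 20) * rnorm(n, 0.2, 0.65 * 0.2)
    sb <- rnorm(n, 4, 0.65 * 4) * rnorm(n, 0.5, 0.65 * 0.5)
    mean(sa > sb)
  }
  n <- 1e5
  f1 <- choice_freq(m, a, b, n, seed = 6)
  f2 <- swapped_freq(n, seed = 7)
  expect_lt(abs(f1 - f2), 3 * sqrt(2 * 0.25 / n) + 2 / n)
})

test_that("identical options yield chance-level choice for every rule", {
  a <- opt(10, 0.5)
  n <- 2e4
  for (kind in model_kinds()) {
    m <- sut_model(kind, 0.7)
    f <- choice_freq(m, a, a, n, seed = 11 + match(kind, model_kinds()))
    expect_lt(abs(f - 0.5), three_se(0.5, n))
  }
})

test_that("model specification validates its parameters", {
  expect_error(sut_model("sev", -1), "gamma")
  expect_error(sut_model("sev", 1, theta_v = 2), "theta_v")
  expect_error(sut_model("nope", 1))
  expect_identical(reference_models()[["rnonc"]]$gamma, 0.05)
  expect_identical(names(reference_models()), model_kinds())
})
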