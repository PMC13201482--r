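test_that("profiles parse from strings and vectors, and reject bad levels", {
  p <- eq5d_profile("21321")
  expect_s3_class(p, "eq5d_profile")
  expect_identical(unclass(p),
                   c(mo = 2L, sc = 1L, ua = 3L, pd = 2L, ad = 1L))
  expect_identical(format(p), "21321")
  expect_identical(unclass(eq5d_profile(c(5, 4, 3, 2, 1))),
                   c(mo = 5L, sc = 4L, ua = 3L, pd = 2L, ad = 1L))
  expect_error(eq5d_profile("1111"), "five digits")
  expect_error(eq5d_profile("11161"), "five digits")
  expect_error(eq5d_profile(c(1, 2, 3, 4, 6)), "1..5")
})

test_that("scoring is additive: intercept minus the per-dimension decrements", {
  # full health scores to the intercept, no decrements apply
  expect_identical(score_profile("11111", toy), toy$intercept)
  # one worsened dimension subtracts exactly its decrement
  expect_equal(score_profile("21111", toy), 1.0 - 0.05)
  # worst state: independent oracle sums the tariff file rows directly
  tab <- read.csv(system.file("extdata", "toy_tariff.csv",
                              package = "hearcua"))
  intercept <- tab$decrement[tab$dimension == "intercept"]
  worst <- sum(tab$decrement[tab$dimension != "intercept" & tab$level == 5])
  expect_equal(score_profile("55555", toy), intercept - worst)
  expect_equal(score_profile("55555", toy), toy$floor)
})

test_that("loaded tariffs validate: intercept conformance, level-1 zeros, monotone warning", {
  path <- system.file("extdata", "toy_tariff.csv", package = "hearcua")
  t <- load_tariff(path)
  expect_identical(score_profile("11111", t), t$intercept)
  expect_true(all(t$decrement[, 1] == 0))
  # scoring never exceeds the intercept; worsening one level never helps
  set.seed(42)
  for (i in 1:25) {
    lv <- sample(1:5, 5, replace = TRUE)
    u <- score_profile(eq5d_profile(lv), t)
    expect_lte(u, t$intercept)
    d <- sample(1:5, 1)
    if (lv[d] < 5) {
      worse <- lv; worse[d] <- worse[d] + 1L
      expect_lte(score_profile(eq5d_profile(worse), t), u)
    }
  }
  # a decrement that shrinks with level is flagged but tolerated
  tmp <- tempfile(fileext = ".csv")
  bad <- read.csv(path)
  bad$decrement[bad$dimension == "mo" & bad$level == 5] <- 0.01
  write.csv(bad, tmp, row.names = FALSE)
  expect_warning(load_tariff(tmp), "non-decreasing")
  # a missing (dimension, level) key names itself
  gap <- read.csv(path)
  gap <- gap[!(gap$dimension == "pd" & gap$level == 3), ]
  write.csv(gap, tmp, row.names = FALSE)
  expect_error(load_tariff(tmp), "pd, level 3")
})

test_that("mean_utility composes filters and matches a brute-force group oracle", {
  rec <- tiny_cohort()
  expect_equal(mean_utility(rec), mean(rec$utility))
  expect_equal(mean_utility(rec, arm = "user"), mean(c(0.9, 0.8, 0.7)))
  expect_equal(mean_utility(rec, arm = "user", severity = "mild"), 0.9)
  expect_error(mean_utility(rec[0, ]), "empty selection")
  expect_error(mean_utility(rec, arm = "user", severity = "none"),
               "empty selection")

  # independent oracle: tapply over arm x severity
  big <- generate_cohort(survey_cohort_spec(), seed = 7)
  oracle <- tapply(big$utility, list(big$arm, big$severity), mean)
  for (a in rownames(oracle)) {
    for (s in colnames(oracle)) {
      expect_equal(mean_utility(big, arm = a, severity = s), oracle[a, s])
    }
  }
})

test_that("union of disjoint strata recovers the count-weighted mean", {
  rec <- generate_cohort(survey_cohort_spec(), seed = 3)
  for (a in c("user", "non_user")) {
    n <- table(rec$severity[rec$arm == a])
    m <- vapply(names(n), function(s) mean_utility(rec, a, s), numeric(1))
    expect_equal(mean_utility(rec, arm = a),
                 sum(as.numeric(n) * m) / sum(n))
  }
})

test_that("severity grading partitions [20, Inf) with half-open boundaries", {
  expect_identical(as.character(classify_severity(25)), "mild")
  expect_identical(as.character(classify_severity(65)), "severe")
  expect_identical(as.character(classify_severity(c(34.9, 35.0))),
                   c("mild", "moderate"))
  expect_identical(as.character(classify_severity(c(20, 34, 64, 64.9, 120))),
                   c("mild", "mild", "moderate", "moderate", "severe"))
  expect_error(classify_severity(19.9), "below")
  expect_error(classify_severity(-3), "non-negative")
  expect_error(classify_severity(Inf), "finite")
  # total on [20, Inf): every draw gets exactly one grade
  set.seed(1)
  x <- 20 + rexp(200, 1 / 30)
  g <- classify_severity(x)
  expect_false(anyNA(g))
  expect_identical(levels(g), severity_levels())
})

test_that("records score profiles through the tariff and validate costs", {
  rec <- participant_records(
    id = c("a", "b"), arm = c("user", "non_user"),
    better_ear_db = c(40, 70),
    profile = c("21111", NA), utility = c(NA, 0.55),
    tariff = toy
  )
  expect_equal(rec$utility, c(0.95, 0.55))
  expect_identical(as.character(rec$severity), c("moderate", "severe"))
  expect_error(
    participant_records("a", "user", severity = "mild"),
    "utility"
  )
  expect_error(
    participant_records("a", "user", severity = "mild", utility = 0.5,
                        cost_consultation = -1),
    "non-negative"
  )
})
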