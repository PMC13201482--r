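test_that("transition matrices validate structure and name each violation", {
  expect_no_error(validate_transition_matrix(diag(3)))
  expect_no_error(validate_transition_matrix(rbind(
    c(0.8, 0.15, 0.05), c(0, 0.9, 0.1), c(0, 0, 1))))
  expect_error(validate_transition_matrix(rbind(
    c(0.8, 0.1, 0.05), c(0, 0.9, 0.1), c(0, 0, 1))), "row 1 sums")
  expect_error(validate_transition_matrix(rbind(
    c(1.2, -0.2, 0), c(0, 1, 0), c(0, 0, 1))), "outside \\[0,1\\]")
  expect_error(validate_transition_matrix(rbind(
    c(0.9, 0.1, 0), c(0.1, 0.9, 0), c(0, 0, 1))), "improvement")
  expect_error(validate_transition_matrix(matrix(1, 2, 2)), "3x3")
})

test_that("traces follow the matrix-power oracle on random valid matrices", {
  set.seed(17)
  mat_pow <- function(m, t) Reduce(`%*%`, replicate(t, m, simplify = FALSE))
  for (i in 1:100) {
    m <- random_valid_matrix()
    init <- random_initial()
    tr <- run_cohort_trace(m, init, horizon = 15)
    t <- sample(1:15, 1)
    expect_equal(unname(tr[t + 1, ]), as.numeric(init %*% mat_pow(m, t)),
                 tolerance = 1e-12)
    # conservation at every cycle
    expect_true(all(abs(rowSums(tr) - 1) <= 1e-12))
    # monotone structure: severe never shrinks, mild never grows
    expect_true(all(diff(tr[, "severe"]) >= -1e-15))
    expect_true(all(diff(tr[, "mild"]) <= 1e-15))
  }
})

test_that("degenerate matrices give the expected traces", {
  init <- c(1, 0, 0)
  expect_true(all(run_cohort_trace(diag(3), c(0.2, 0.3, 0.5), 10) ==
                    rep(c(0.2, 0.3, 0.5), each = 11)))
  m <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
  tr <- run_cohort_trace(m, init, 2)
  expect_equal(unname(tr["cycle1", ]), c(0, 1, 0))
  expect_error(run_cohort_trace(diag(3), c(0.5, 0.5, 0.5), 5), "sum to 1")
})

test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0, 0:20), rep(1, 21))
  expect_equal(discount_factor(0.05, 3), 1.05^-3)
  expect_error(discount_factor(-0.01, 1))
})

test_that("zero-rate, full-utility accumulation conserves person-years", {
  set.seed(23)
  for (i in 1:10) {
    m <- random_valid_matrix()
    tr <- run_cohort_trace(m, random_initial(), 15)
    spec <- markov_spec(horizon = 15, discount_rate = 0,
                        state_utility = c(1, 1, 1), cohort_size = 40)
    out <- accumulate_outcomes(tr, spec)
    expect_equal(out$qalys, 40 * 15, tolerance = 1e-9)
    expect_equal(out$cost, 0)
  }
})

test_that("single-state constant cost matches the closed-form annuity", {
  tr <- run_cohort_trace(diag(3), c(0, 1, 0), 15)
  r <- 0.03; c_ann <- 1200
  spec <- markov_spec(horizon = 15, discount_rate = r,
                      state_utility = c(0.8, 0.6, 0.4),
                      state_cost = c(0, c_ann, 0))
  out <- accumulate_outcomes(tr, spec)
  annuity <- (1 - (1 + r)^-15) / r
  expect_equal(out$cost, c_ann * annuity, tolerance = 1e-12)
  expect_equal(out$qalys, 0.6 * annuity, tolerance = 1e-12)
  # discounting only shrinks totals
  spec0 <- markov_spec(horizon = 15, discount_rate = 0,
                       state_utility = c(0.8, 0.6, 0.4),
                       state_cost = c(0, c_ann, 0))
  out0 <- accumulate_outcomes(tr, spec0)
  expect_lt(out$cost, out0$cost)
  expect_lt(out$qalys, out0$qalys)
})

test_that("device purchases land at fitting and 3-yearly replacement cycles", {
  tr <- run_cohort_trace(diag(3), c(1, 0, 0), 15)
  r <- 0.03
  spec <- markov_spec(horizon = 15, discount_rate = r,
                      state_utility = c(1, 1, 1), state_cost = c(0, 0, 0),
                      device_price_per_ear = 8000, ears = 1)
  out <- accumulate_outcomes(tr, spec)
  v <- 1 / (1 + r)
  expect_equal(out$cost, 8000 * sum(v^c(0, 3, 6, 9, 12)), tolerance = 1e-12)
  # bilateral doubles the device stream
  spec2 <- markov_spec(horizon = 15, discount_rate = r,
                       state_utility = c(1, 1, 1),
                       device_price_per_ear = 8000, ears = 2)
  expect_equal(accumulate_outcomes(tr, spec2)$cost, 2 * out$cost)
})

test_that("re-evaluation cost charges the newly-progressed fraction", {
  m <- rbind(c(0.5, 0.5, 0), c(0, 1, 0), c(0, 0, 1))
  tr <- run_cohort_trace(m, c(1, 0, 0), 3)
  spec <- markov_spec(horizon = 3, discount_rate = 0,
                      state_utility = c(1, 1, 1),
                      reevaluation_cost = 100)
  # moved fractions by hand: 0.5, 0.25, 0.125
  out <- accumulate_outcomes(tr, spec, m)
  expect_equal(out$cost, 100 * (0.5 + 0.25 + 0.125), tolerance = 1e-12)
  expect_error(accumulate_outcomes(tr, spec), "transition matrix")
})

test_that("two-arm comparison wires up increments and trivial ties", {
  mats <- synthetic_transition_matrices()
  su <- markov_spec(state_utility = c(0.763, 0.807, 0.904),
                    state_cost = c(1456, 1456, 1456), ears = 1)
  sn <- markov_spec(state_utility = c(0.592, 0.598, 0.614),
                    state_cost = c(528, 528, 528), ears = 0)
  res <- markov_ce(su, sn, mats$user, mats$non_user,
                   c(0.2, 0.4, 0.4), c(0.4, 0.4, 0.2),
                   wtp_threshold = 1e5)
  expect_s3_class(res, "ce_result")
  expect_equal(res$delta_cost, res$cost_intervention - res$cost_comparator)
  expect_gt(res$delta_qaly, 0)
  expect_identical(res$icer$label, "icer")
  # identical arms tie exactly
  tie <- markov_ce(sn, sn, mats$non_user, mats$non_user,
                   c(1, 0, 0), c(1, 0, 0))
  expect_equal(tie$delta_cost, 0)
  expect_equal(tie$delta_qaly, 0)
  expect_identical(tie$icer$label, "tie")
})

test_that("half-cycle correction averages adjacent occupancies", {
  m <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
  tr <- run_cohort_trace(m, c(1, 0, 0), 2)
  spec <- markov_spec(horizon = 2, discount_rate = 0,
                      state_utility = c(1, 0, 0),
                      half_cycle_correction = TRUE)
  # occupancy in mild: 1, 0, 0 -> averaged cycle values 0.5, 0
  expect_equal(accumulate_outcomes(tr, spec)$qalys, 0.5)
})
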