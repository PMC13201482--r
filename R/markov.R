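#' Validate an annual transition-probability matrix
#'
#' The three-state hearing-severity model orders states (mild, moderate,
#' severe). In each annual cycle a cohort member remains in their state or
#' progresses to a worse one -- never improves -- so a valid matrix is
#' row-stochastic (each row sums to 1 within 1e-12), has entries in [0, 1],
#' and is upper-triangular (all below-diagonal entries exactly 0).
#'
#' @param m 3x3 numeric matrix of annual transition probabilities.
#' @return the matrix, with state dimnames attached, or an error naming
#'   every violated constraint.
#' @examples
#' validate_transition_matrix(rbind(c(0.8, 0.15, 0.05),
#'                                  c(0,   0.9,  0.1),
#'                                  c(0,   0,    1)))
#' @export
validate_transition_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L))) {
    stop("transition matrix must be 3x3 numeric", call. = FALSE)
  }
  problems <- character()
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > 1e-12)
  if (length(off)) {
    problems <- c(problems, sprintf("row %d sums to %.12g, not 1", off,
                                    rs[off]))
  }
  neg <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(neg)) {
    problems <- c(problems,
                  sprintf("entry [%d,%d] = %g outside [0,1]",
                          neg[, 1L], neg[, 2L], m[neg]))
  }
  low <- which(lower.tri(m) & m != 0, arr.ind = TRUE)
  if (nrow(low)) {
    problems <- c(problems,
                  sprintf("improvement entry [%d,%d] = %g must be 0 (%s -> %s)",
                          low[, 1L], low[, 2L], m[low],
                          severity_levels()[low[, 1L]],
                          severity_levels()[low[, 2L]]))
  }
  if (length(problems)) {
    stop("invalid transition matrix:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  dimnames(m) <- list(severity_levels(), severity_levels())
  m
}

#' Run the cohort through the transition matrix
#'
#' Computes the cohort trace: occupancy fractions per state at cycles
#' 0..horizon, with occupancy[t] = occupancy[t-1] %*% m. Row t therefore
#' equals initial %*% m^t.
#'
#' @param m transition matrix (validated with
#'   [validate_transition_matrix()]).
#' @param initial length-3 initial state distribution, summing to 1.
#' @param horizon number of annual cycles (default 15).
#' @return matrix of class \code{cohort_trace}, (horizon + 1) x 3, rows
#'   \code{cycle0..cycleH}, columns the states.
#' @export
run_cohort_trace <- function(m, initial, horizon = 15) {
  m <- validate_transition_matrix(m)
  initial <- as.numeric(initial)
  stopifnot(length(initial) == 3L, all(initial >= 0))
  if (abs(sum(initial) - 1) > 1e-12) {
    stop("initial distribution must sum to 1", call. = FALSE)
  }
  stopifnot(horizon >= 0, horizon == round(horizon))
  trace <- matrix(0, nrow = horizon + 1L, ncol = 3L,
                  dimnames = list(paste0("cycle", 0:horizon),
                                  severity_levels()))
  trace[1L, ] <- initial
  for (t in seq_len(horizon)) {
    trace[t + 1L, ] <- trace[t, ] %*% m
  }
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' Present-value discount factor
#'
#' \code{1 / (1 + rate)^cycle}: the weight applied to costs and QALYs
#' occurring \code{cycle} years in the future.
#'
#' @param rate annual discount rate, >= 0 (the reference-case value for
#'   India is 0.03 on both costs and outcomes).
#' @param cycle cycle index/indices, non-negative integers.
#' @return discount factor(s) in (0, 1].
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 0), all(cycle == round(cycle)))
  1 / (1 + rate)^cycle
}

#' Markov run settings for one arm
#'
#' Everything [accumulate_outcomes()] needs besides the trace: the state
#' utilities and annual state costs for the arm, discounting, device
#' schedule, and the re-evaluation cost charged when hearing status changes.
#'
#' @param horizon annual cycles (default 15).
#' @param discount_rate applied to both costs and QALYs (default 0.03).
#' @param state_utility length-3 utilities for (mild, moderate, severe).
#' @param state_cost length-3 annual INR per person in each state.
#' @param device_price_per_ear INR (default 8000); set \code{ears = 0} for
#'   the non-user arm.
#' @param ears 0, 1 or 2.
#' @param replacement_interval years between device purchases for continued
#'   users (default 3, the device warranty/lifespan).
#' @param reevaluation_cost INR charged per expected newly-progressed cohort
#'   fraction each cycle (default 0).
#' @param cohort_size persons (default 1: per-person results).
#' @param timing \code{"cycle_end"} (default) discounts cycle-t outcomes by
#'   \code{1/(1+r)^t}; \code{"cycle_start"} by \code{1/(1+r)^(t-1)}.
#' @param half_cycle_correction average adjacent cycle occupancies before
#'   accumulating (default FALSE).
#' @return object of class \code{markov_spec}.
#' @export
markov_spec <- function(horizon = 15, discount_rate = 0.03,
                        state_utility, state_cost = c(0, 0, 0),
                        device_price_per_ear = 8000, ears = 0,
                        replacement_interval = 3,
                        reevaluation_cost = 0, cohort_size = 1,
                        timing = c("cycle_end", "cycle_start"),
                        half_cycle_correction = FALSE) {
  timing <- match.arg(timing)
  stopifnot(horizon >= 1, horizon == round(horizon),
            discount_rate >= 0,
            length(state_utility) == 3L, length(state_cost) == 3L,
            all(state_cost >= 0), device_price_per_ear >= 0,
            ears %in% c(0, 1, 2),
            replacement_interval >= 1,
            reevaluation_cost >= 0, cohort_size > 0)
  structure(
    list(horizon = horizon, discount_rate = discount_rate,
         state_utility = as.numeric(state_utility),
         state_cost = as.numeric(state_cost),
         device_price_per_ear = device_price_per_ear, ears = ears,
         replacement_interval = replacement_interval,
         reevaluation_cost = reevaluation_cost, cohort_size = cohort_size,
         timing = timing, half_cycle_correction = half_cycle_correction),
    class = "markov_spec"
  )
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' QALYs: \code{cohort * sum_t df(t) * sum_s occupancy[t,s] * utility[s]}
#' over cycles 1..horizon. Costs: the same accumulation of annual state
#' costs, plus the device purchases -- the initial fitting at cycle 0
#' (undiscounted) and replacements every \code{replacement_interval} years
#' while the horizon still has cycles to serve (t = 3, 6, 9, 12 for the
#' 15-year defaults), each discounted at its cycle -- plus the re-evaluation
#' cost times the expected fraction of the cohort that progressed to a worse
#' state during each cycle.
#'
#' @param trace a [run_cohort_trace()] result.
#' @param spec a [markov_spec()].
#' @param m the transition matrix used for the trace; required only when
#'   \code{spec$reevaluation_cost > 0} (to attribute newly-progressed
#'   fractions).
#' @return named list: \code{cost} (discounted INR) and \code{qalys}
#'   (discounted), both scaled by \code{spec$cohort_size}.
#' @export
accumulate_outcomes <- function(trace, spec, m = NULL) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(spec, "markov_spec"))
  h <- spec$horizon
  if (nrow(trace) != h + 1L) {
    stop("trace has ", nrow(trace) - 1L, " cycles but spec horizon is ", h,
         call. = FALSE)
  }
  occ <- unclass(trace)
  if (spec$half_cycle_correction) {
    occ_eff <- (occ[1:h, , drop = FALSE] + occ[2:(h + 1L), , drop = FALSE]) / 2
  } else {
    occ_eff <- occ[2:(h + 1L), , drop = FALSE]  # end-of-cycle occupancy
  }
  t_idx <- seq_len(h)
  df_cycle <- if (spec$timing == "cycle_end") {
    discount_factor(spec$discount_rate, t_idx)
  } else {
    discount_factor(spec$discount_rate, t_idx - 1L)
  }
  qalys <- sum(df_cycle * (occ_eff %*% spec$state_utility))
  cost <- sum(df_cycle * (occ_eff %*% spec$state_cost))
  if (spec$ears > 0) {
    device <- spec$ears * spec$device_price_per_ear
    buy_at <- seq(0, h - 1e-9, by = spec$replacement_interval)
    cost <- cost + sum(device * discount_factor(spec$discount_rate, buy_at))
  }
  if (spec$reevaluation_cost > 0) {
    if (is.null(m)) {
      stop("the transition matrix is needed to attribute re-evaluation ",
           "costs", call. = FALSE)
    }
    m <- validate_transition_matrix(m)
    # expected fraction changing state during cycle t: 1 - sum_s occ[t-1,s]*m[s,s]
    stay <- diag(m)
    moved <- 1 - as.numeric(occ[1:h, , drop = FALSE] %*% stay)
    cost <- cost + sum(df_cycle * spec$reevaluation_cost * moved)
  }
  list(cost = spec$cohort_size * cost, qalys = spec$cohort_size * qalys)
}

#' Two-arm Markov cost-utility comparison
#'
#' Runs the user and non-user arms over their transition matrices and
#' initial distributions, accumulates discounted costs and QALYs per arm,
#' and forms the incremental comparison.
#'
#' @param user_spec,non_user_spec [markov_spec()] per arm (the user arm
#'   usually carries \code{ears} 1 or 2; the non-user arm \code{ears = 0}).
#' @param user_matrix,non_user_matrix annual transition matrices per arm.
#' @param user_initial,non_user_initial initial state distributions.
#' @param wtp_threshold optional INR/QALY.
#' @return a [ce_result()] with the per-arm traces attached as attributes
#'   \code{trace_user} and \code{trace_non_user}.
#' @export
markov_ce <- function(user_spec, non_user_spec,
                      user_matrix, non_user_matrix,
                      user_initial, non_user_initial,
                      wtp_threshold = NULL) {
  stopifnot(user_spec$horizon == non_user_spec$horizon)
  tu <- run_cohort_trace(user_matrix, user_initial, user_spec$horizon)
  tn <- run_cohort_trace(non_user_matrix, non_user_initial,
                         non_user_spec$horizon)
  ou <- accumulate_outcomes(tu, user_spec, user_matrix)
  on <- accumulate_outcomes(tn, non_user_spec, non_user_matrix)
  res <- ce_result(ou$cost, ou$qalys, on$cost, on$qalys, wtp_threshold)
  attr(res, "trace_user") <- tu
  attr(res, "trace_non_user") <- tn
  res
}

#' Synthetic default transition matrices
#'
#' Placeholder annual progression probabilities for the two arms, with
#' hearing-aid users progressing more slowly than non-users. These are
#' synthetic values for examples and smoke tests, not estimates from any
#' study; real analyses must supply their own matrices via configuration.
#'
#' @return named list with elements \code{user} and \code{non_user}.
#' @export
synthetic_transition_matrices <- function() {
  list(
    user = validate_transition_matrix(rbind(
      c(0.92, 0.06, 0.02),
      c(0.00, 0.94, 0.06),
      c(0.00, 0.00, 1.00))),
    non_user = validate_transition_matrix(rbind(
      c(0.85, 0.10, 0.05),
      c(0.00, 0.88, 0.12),
      c(0.00, 0.00, 1.00)))
  )
}
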