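# shared fixtures built in code

toy <- toy_tariff()

# a small hand-built cohort with known strata
tiny_cohort <- function() {
  participant_records(
    id = sprintf("T%02d", 1:6),
    arm = c("user", "user", "user", "non_user", "non_user", "non_user"),
    severity = c("mild", "moderate", "severe", "mild", "moderate", "severe"),
    utility = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
    cost_consultation = 100, cost_investigations = 1000
  )
}

# random valid (row-stochastic, upper-triangular) transition matrix
random_valid_matrix <- function() {
  r1 <- stats::rgamma(3, 1); r1 <- r1 / sum(r1)
  r2 <- stats::rgamma(2, 1); r2 <- r2 / sum(r2)
  rbind(c(r1), c(0, r2), c(0, 0, 1))
}

# random initial distribution over the three states
random_initial <- function() {
  p <- stats::rgamma(3, 1)
  p / sum(p)
}

paper_tree <- function(wtp = NULL) {
  evaluate_tree(list(
    tree_strategy("no_aid", 2669, 0.601),
    tree_strategy("unilateral", 11420, 0.832),
    tree_strategy("bilateral", 19420, 0.832)
  ), comparator = "no_aid", wtp_threshold = wtp)
}
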