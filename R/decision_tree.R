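#' QALYs accrued at a constant utility
#'
#' Utility weight times the years over which it is accrued; undiscounted
#' (the short-horizon tree reports undiscounted QALYs). The default accrual
#' horizon elsewhere in the package is 7 years, the remaining-life-expectancy
#' assumption under which the published utilities 0.832 and 0.601 convert to
#' 5.824 and 4.207 QALYs exactly.
#'
#' @param utility utility weight(s).
#' @param accrual_years years of accrual, > 0.
#' @return QALYs.
#' @examples
#' qalys_from_utility(0.832, 7)  # 5.824
#' @export
qalys_from_utility <- function(utility, accrual_years) {
  if (any(accrual_years <= 0)) {
    stop("accrual_years must be positive", call. = FALSE)
  }
  utility * accrual_years
}

#' Define a decision-tree strategy
#'
#' A strategy is a pathway of the short-horizon tree: a name, a total
#' per-person cost over the tree horizon, a mean utility, and the accrual
#' horizon converting utility to QALYs. A strategy may instead carry
#' probability-weighted sub-branches (each with probability, cost and
#' utility); its expected cost and utility are then the probability-weighted
#' means. The published tree is effectively deterministic per arm, so the
#' default is a single branch of probability 1.
#'
#' @param name strategy name, e.g. \code{"no_aid"}, \code{"unilateral"},
#'   \code{"bilateral"}.
#' @param total_cost per-person INR over the tree horizon (ignored when
#'   \code{branches} given).
#' @param mean_utility mean utility (ignored when \code{branches} given).
#' @param accrual_years QALY accrual horizon, default 7.
#' @param branches optional data.frame with columns \code{probability},
#'   \code{cost}, \code{utility}; probabilities must sum to 1.
#' @return object of class \code{tree_strategy}.
#' @export
tree_strategy <- function(name, total_cost = NULL, mean_utility = NULL,
                          accrual_years = 7, branches = NULL) {
  if (is.null(branches)) {
    stopifnot(!is.null(total_cost), !is.null(mean_utility))
    branches <- data.frame(probability = 1, cost = total_cost,
                           utility = mean_utility)
  } else {
    need <- c("probability", "cost", "utility")
    stopifnot(all(need %in% names(branches)))
    if (abs(sum(branches$probability) - 1) > 1e-9) {
      stop("branch probabilities must sum to 1", call. = FALSE)
    }
    if (any(branches$probability < 0)) {
      stop("branch probabilities must be non-negative", call. = FALSE)
    }
  }
  if (any(branches$cost < 0)) {
    stop("strategy costs must be non-negative", call. = FALSE)
  }
  structure(
    list(name = as.character(name),
         total_cost = sum(branches$probability * branches$cost),
         mean_utility = sum(branches$probability * branches$utility),
         accrual_years = accrual_years, branches = branches),
    class = "tree_strategy"
  )
}

#' Evaluate the decision tree
#'
#' Computes expected cost and QALYs for each strategy (probability-weighted
#' over branches, QALYs via [qalys_from_utility()]) and incremental results
#' -- delta cost, delta QALYs, ICER -- of every other strategy against the
#' comparator.
#'
#' @param strategies list of [tree_strategy()] objects with unique names.
#' @param comparator name of the comparator strategy (default
#'   \code{"no_aid"}).
#' @param wtp_threshold optional INR/QALY for cost-effectiveness
#'   classification of each comparison.
#' @return object of class \code{tree_result}: list with \code{strategies}
#'   (data.frame name/cost/qalys) and \code{comparisons} (named list of
#'   [ce_result()] objects, one per non-comparator strategy).
#' @examples
#' tree <- evaluate_tree(list(
#'   tree_strategy("no_aid", 2669, 0.601),
#'   tree_strategy("unilateral", 11420, 0.832),
#'   tree_strategy("bilateral", 19420, 0.832)))
#' tree
#' @export
evaluate_tree <- function(strategies, comparator = "no_aid",
                          wtp_threshold = NULL) {
  stopifnot(length(strategies) >= 1L,
            all(vapply(strategies, inherits, logical(1L), "tree_strategy")))
  nm <- vapply(strategies, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate strategy names: ", paste(nm[duplicated(nm)],
         collapse = ", "), call. = FALSE)
  }
  if (!comparator %in% nm) {
    stop("comparator ", sQuote(comparator), " is not among the strategies",
         call. = FALSE)
  }
  tab <- data.frame(
    name = nm,
    cost = vapply(strategies, `[[`, numeric(1L), "total_cost"),
    qalys = vapply(strategies, function(s) {
      qalys_from_utility(s$mean_utility, s$accrual_years)
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  base <- tab[tab$name == comparator, ]
  others <- setdiff(nm, comparator)
  comparisons <- lapply(others, function(s) {
    row <- tab[tab$name == s, ]
    ce_result(row$cost, row$qalys, base$cost, base$qalys, wtp_threshold)
  })
  names(comparisons) <- others
  structure(list(strategies = tab, comparator = comparator,
                 comparisons = comparisons),
            class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("<tree_result> comparator: ", x$comparator, "\n", sep = "")
  print(transform(x$strategies, cost = round(cost, 2),
                  qalys = round(qalys, 3)), row.names = FALSE)
  for (s in names(x$comparisons)) {
    ce <- x$comparisons[[s]]
    cat(sprintf("  %s vs %s: dCost %s, dQALY %s, ICER %s\n",
                s, x$comparator,
                format(round(ce$delta_cost), big.mark = ","),
                format(signif(ce$delta_qaly, 6)), format(ce$icer)))
  }
  invisible(x)
}
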