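#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Computes the ICER (incremental cost / incremental QALYs, INR per QALY
#' gained) when it is meaningful, and a dominance label otherwise. All sign
#' quadrants are mapped:
#' \itemize{
#'   \item \eqn{\Delta Q > 0, \Delta C > 0}: ICER \eqn{= \Delta C / \Delta Q}
#'     (quadrant \code{northeast} -- more effective, more costly).
#'   \item \eqn{\Delta C \le 0, \Delta Q \ge 0} (not both 0): \code{dominant}
#'     -- at least as effective and no more costly.
#'   \item \eqn{\Delta C \ge 0, \Delta Q \le 0} (not both 0): \code{dominated}.
#'   \item \eqn{\Delta C < 0, \Delta Q < 0}: quadrant \code{southwest} --
#'     cheaper and less effective; the ratio (savings per QALY forgone) is
#'     reported and must be judged against the threshold in the opposite
#'     direction.
#'   \item both 0: \code{tie}.
#' }
#' Full precision is kept internally; reports round to the nearest integer
#' INR.
#'
#' @param delta_cost incremental cost, INR.
#' @param delta_qaly incremental QALYs.
#' @return object of class \code{icer}: list with \code{value} (INR/QALY, or
#'   NA under dominance/tie), \code{label} (\code{"icer"}, \code{"dominant"},
#'   \code{"dominated"}, \code{"tie"}), \code{quadrant}, \code{delta_cost},
#'   \code{delta_qaly}.
#' @examples
#' icer(16751, 1.617)   # ~10359 INR/QALY
#' icer(-100, 0.5)      # dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  dc <- as.numeric(delta_cost)
  dq <- as.numeric(delta_qaly)
  stopifnot(length(dc) == 1L, length(dq) == 1L, is.finite(dc), is.finite(dq))
  if (dc == 0 && dq == 0) {
    label <- "tie"; value <- NA_real_; quadrant <- "origin"
  } else if (dc <= 0 && dq >= 0) {
    label <- "dominant"; value <- NA_real_; quadrant <- "northwest"
  } else if (dc >= 0 && dq <= 0) {
    label <- "dominated"; value <- NA_real_; quadrant <- "southeast"
  } else if (dq > 0) {
    label <- "icer"; value <- dc / dq; quadrant <- "northeast"
  } else {
    label <- "icer"; value <- dc / dq; quadrant <- "southwest"
  }
  structure(list(value = value, label = label, quadrant = quadrant,
                 delta_cost = dc, delta_qaly = dq),
            class = "icer")
}

#' @export
format.icer <- function(x, ...) {
  if (x$label == "icer") {
    paste0(format(round(x$value), big.mark = ","), " INR/QALY",
           if (x$quadrant == "southwest") " (southwest: saving per QALY forgone)")
  } else {
    x$label
  }
}

#' @export
print.icer <- function(x, ...) {
  cat("<icer> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness classification against a willingness-to-pay threshold
#'
#' An intervention in the northeast quadrant is \code{cost_effective} iff
#' its ICER is at or below the willingness-to-pay threshold (here benchmarked
#' in practice at 1x India's per-capita GDP per QALY, supplied by the user --
#' no rupee default is hard-coded). Dominant comparisons are always
#' cost-effective, dominated never; in the southwest quadrant the savings per
#' QALY forgone must be at or above the threshold; ties classify as
#' \code{tie}.
#'
#' @param x an [icer()] object (or a bare ICER value, taken as northeast).
#' @param wtp_threshold willingness-to-pay, INR per QALY, > 0.
#' @return one of \code{"cost_effective"}, \code{"not_cost_effective"},
#'   \code{"dominant"}, \code{"dominated"}, \code{"tie"} (the dominance
#'   labels imply the cost-effectiveness verdict).
#' @examples
#' classify_cost_effectiveness(icer(16751, 1.617), wtp_threshold = 100000)
#' @export
classify_cost_effectiveness <- function(x, wtp_threshold) {
  if (!is.numeric(wtp_threshold) || length(wtp_threshold) != 1L ||
      wtp_threshold <= 0) {
    stop("wtp_threshold must be a single positive INR/QALY value",
         call. = FALSE)
  }
  if (!inherits(x, "icer")) {
    x <- structure(list(value = as.numeric(x), label = "icer",
                        quadrant = "northeast"), class = "icer")
  }
  switch(x$label,
    dominant  = "dominant",
    dominated = "dominated",
    tie       = "tie",
    icer = if (x$quadrant == "southwest") {
      if (x$value >= wtp_threshold) "cost_effective" else "not_cost_effective"
    } else {
      if (x$value <= wtp_threshold) "cost_effective" else "not_cost_effective"
    }
  )
}

#' @rdname classify_cost_effectiveness
#' @return `is_cost_effective()`: logical; \code{TRUE} for
#'   \code{cost_effective} or \code{dominant}.
#' @export
is_cost_effective <- function(x, wtp_threshold) {
  classify_cost_effectiveness(x, wtp_threshold) %in%
    c("cost_effective", "dominant")
}

#' Net monetary benefit
#'
#' \code{wtp * delta_qaly - delta_cost}; positive exactly when the
#' intervention is cost-effective at that willingness-to-pay.
#'
#' @param delta_cost incremental cost INR.
#' @param delta_qaly incremental QALYs.
#' @param wtp willingness-to-pay INR/QALY, >= 0.
#' @return INR.
#' @examples
#' net_monetary_benefit(8751, 1.617, 10000)
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Assemble a cost-effectiveness comparison
#'
#' Bundles per-arm totals into increments, ICER and (optionally) the
#' willingness-to-pay classification -- the common result shape for the
#' decision-tree and Markov comparisons.
#'
#' @param cost1,qaly1 intervention arm totals.
#' @param cost0,qaly0 comparator arm totals.
#' @param wtp_threshold optional INR/QALY for classification.
#' @return object of class \code{ce_result}: list with per-arm values,
#'   \code{delta_cost}, \code{delta_qaly}, \code{icer} ([icer()] object) and
#'   \code{classification} (NA without a threshold).
#' @export
ce_result <- function(cost1, qaly1, cost0, qaly0, wtp_threshold = NULL) {
  dc <- cost1 - cost0
  dq <- qaly1 - qaly0
  ic <- icer(dc, dq)
  structure(
    list(cost_intervention = cost1, qaly_intervention = qaly1,
         cost_comparator = cost0, qaly_comparator = qaly0,
         delta_cost = dc, delta_qaly = dq, icer = ic,
         wtp_threshold = wtp_threshold,
         classification = if (is.null(wtp_threshold)) NA_character_
                          else classify_cost_effectiveness(ic, wtp_threshold)),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  intervention: cost %s INR, %s QALYs\n",
              format(round(x$cost_intervention), big.mark = ","),
              format(signif(x$qaly_intervention, 6))))
  cat(sprintf("  comparator:   cost %s INR, %s QALYs\n",
              format(round(x$cost_comparator), big.mark = ","),
              format(signif(x$qaly_comparator, 6))))
  cat(sprintf("  increment:    %s INR, %s QALYs\n",
              format(round(x$delta_cost), big.mark = ","),
              format(signif(x$delta_qaly, 6))))
  cat("  ICER: ", format(x$icer), "\n", sep = "")
  if (!is.na(x$classification)) {
    cat(sprintf("  at WTP %s INR/QALY: %s\n",
                format(x$wtp_threshold, big.mark = ","), x$classification))
  }
  invisible(x)
}
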