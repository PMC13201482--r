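#' Specification for a synthetic survey cohort
#'
#' Describes an arm-by-severity cohort: participant counts and target mean
#' utilities per (arm, severity) cell, a common utility dispersion, utility
#' bounds, and per-arm mean 3-year cost components. [generate_cohort()] draws
#' records with exactly this structure so the downstream pipeline (scoring,
#' costing, tree, Markov) is testable without survey microdata.
#'
#' @param counts named numeric: cell counts, names \code{"arm.severity"}
#'   (e.g. \code{"user.mild"}), all six cells present, non-negative integers.
#' @param mean_utility named numeric: target cell means, same names.
#' @param utility_sd common standard deviation of the utility draw before
#'   truncation and recentring (default 0.15).
#' @param utility_bounds lower/upper utility bounds; draws are truncated to
#'   this interval (default c(-0.6, 1), spanning typical value-set floors).
#' @param cost_means named list per arm: \code{consultation} and
#'   \code{investigations} mean 3-year INR.
#' @param cost_cv coefficient of variation of the (gamma) cost draws
#'   (default 0.3).
#' @param overall_utility optional named numeric \code{c(user=, non_user=)}.
#'   When given, arm-level calibration shifts every record in the arm so the
#'   realised arm mean equals this target (see Details).
#' @details Two calibration modes. Cell mode (default) recentres each cell's
#'   draws so realised cell means equal the targets exactly. Overall mode
#'   (\code{overall_utility} set) additionally applies one constant per arm so
#'   the arm's overall mean matches its target exactly -- useful because
#'   published overall arm means need not equal the count-weighted mean of
#'   published cell means. Recentring shifts values after truncation, so
#'   bounds are respected by the raw draws but may be exceeded by at most the
#'   recentring shift (small when targets sit inside the bounds).
#' @return object of class \code{cohort_spec}.
#' @seealso [survey_cohort_spec()] for the shipped 2023-survey defaults.
#' @export
cohort_spec <- function(counts, mean_utility,
                        utility_sd = 0.15,
                        utility_bounds = c(-0.6, 1),
                        cost_means = list(
                          user = c(consultation = 111, investigations = 4257),
                          non_user = c(consultation = 131,
                                       investigations = 1452)),
                        cost_cv = 0.3,
                        overall_utility = NULL) {
  cells <- cohort_cells()
  counts <- counts[cells]
  mean_utility <- mean_utility[cells]
  if (anyNA(counts) || anyNA(mean_utility)) {
    stop("counts and mean_utility must name all six arm.severity cells: ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(length(utility_bounds) == 2L,
            utility_bounds[1L] < utility_bounds[2L],
            utility_sd > 0, cost_cv > 0)
  occupied <- counts > 0
  if (any(mean_utility[occupied] < utility_bounds[1L] |
          mean_utility[occupied] > utility_bounds[2L])) {
    stop("infeasible target: cell mean utility outside utility_bounds",
         call. = FALSE)
  }
  if (!is.null(overall_utility)) {
    overall_utility <- overall_utility[c("user", "non_user")]
    if (anyNA(overall_utility)) {
      stop("overall_utility must be named c(user=, non_user=)", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, mean_utility = mean_utility,
         utility_sd = utility_sd, utility_bounds = utility_bounds,
         cost_means = cost_means, cost_cv = cost_cv,
         overall_utility = overall_utility),
    class = "cohort_spec"
  )
}

cohort_cells <- function() {
  as.vector(outer(c("user", "non_user"), severity_levels(), paste, sep = "."))
}

#' The 2023 hearing-impairment survey cohort structure
#'
#' Cell counts and mean utilities of the 2023 survey of 636 hearing-impaired
#' adults aged 60+ (276 hearing-aid users, 360 non-users): users mild 36 /
#' moderate 122 / severe 118, non-users mild 153 / moderate 131 / severe 76,
#' with the published cell mean utilities, and mean 3-year cost components of
#' INR 111 + 4,257 (users) and 131 + 1,452 (non-users).
#'
#' @param calibrate \code{"cell"} recentres each cell to its published mean;
#'   \code{"overall"} additionally calibrates arm means to the published
#'   overall values 0.832 (users) and 0.601 (non-users), which are not the
#'   count-weighted means of the published cells.
#' @return a [cohort_spec()].
#' @export
survey_cohort_spec <- function(calibrate = c("cell", "overall")) {
  calibrate <- match.arg(calibrate)
  counts <- c(user.mild = 36, user.moderate = 122, user.severe = 118,
              non_user.mild = 153, non_user.moderate = 131,
              non_user.severe = 76)
  means <- c(user.mild = 0.763, user.moderate = 0.807, user.severe = 0.904,
             non_user.mild = 0.592, non_user.moderate = 0.598,
             non_user.severe = 0.614)
  overall <- if (calibrate == "overall") {
    c(user = 0.832, non_user = 0.601)
  }
  cohort_spec(counts = counts, mean_utility = means,
              overall_utility = overall)
}

# Truncated-normal draw via inverse CDF; exact for any bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Generate a synthetic survey cohort
#'
#' Draws exactly \code{spec$counts} records per (arm, severity) cell.
#' Utilities come from a normal at the cell's target mean (sd
#' \code{spec$utility_sd}) truncated to \code{spec$utility_bounds}, then
#' mean-recentred per cell so each realised cell mean equals its target to
#' machine precision; with \code{spec$overall_utility} set, a per-arm
#' constant shift then pins the overall arm means. Cost components are
#' drawn from gamma distributions at the arm means with coefficient of
#' variation \code{spec$cost_cv}. Fully reproducible: the same (spec, seed)
#' yields an identical table.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; mandatory.
#' @param recentre set \code{FALSE} for raw (stochastic-realism) draws with
#'   no mean calibration.
#' @return a [participant_records()] table with \code{sum(spec$counts)} rows.
#' @examples
#' cohort <- generate_cohort(survey_cohort_spec("overall"), seed = 1)
#' nrow(cohort)
#' mean_utility(cohort, arm = "user")
#' @export
generate_cohort <- function(spec, seed, recentre = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for cohort generation", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- vector("list", length(spec$counts))
  serial <- 0L
  for (i in seq_along(spec$counts)) {
    cell <- names(spec$counts)[i]
    n <- spec$counts[[i]]
    if (n == 0L) next
    parts <- strsplit(cell, ".", fixed = TRUE)[[1L]]
    u <- rtruncnorm(n, spec$mean_utility[[i]], spec$utility_sd,
                    spec$utility_bounds[1L], spec$utility_bounds[2L])
    if (recentre) u <- u + (spec$mean_utility[[i]] - mean(u))
    cm <- spec$cost_means[[parts[1L]]]
    shape <- 1 / spec$cost_cv^2
    cc <- stats::rgamma(n, shape = shape,
                        rate = shape / cm[["consultation"]])
    ci <- stats::rgamma(n, shape = shape,
                        rate = shape / cm[["investigations"]])
    rows[[i]] <- data.frame(
      id = sprintf("P%04d", serial + seq_len(n)),
      arm = parts[1L], severity = parts[2L],
      utility = u, cost_consultation = cc, cost_investigations = ci,
      stringsAsFactors = FALSE
    )
    serial <- serial + n
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(), arm = character(),
                      severity = character(), utility = numeric(),
                      cost_consultation = numeric(),
                      cost_investigations = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (recentre && !is.null(spec$overall_utility) && nrow(out)) {
    for (a in names(spec$overall_utility)) {
      sel <- out$arm == a
      if (any(sel)) {
        out$utility[sel] <- out$utility[sel] +
          (spec$overall_utility[[a]] - mean(out$utility[sel]))
      }
    }
  }
  out$severity <- factor(out$severity, levels = severity_levels())
  rownames(out) <- NULL
  class(out) <- c("participant_records", "data.frame")
  out
}

#' Summarise a cohort by arm and severity
#'
#' Counts and mean utilities per occupied (arm, severity) cell plus an
#' overall row per arm; means agree exactly with [mean_utility()] on the
#' same filters.
#'
#' @param records a [participant_records()] table.
#' @return data.frame with columns arm, severity (\code{"overall"} for the
#'   arm rows), n, mean_utility.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  key <- interaction(records$arm, records$severity, drop = TRUE)
  cell <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    data.frame(arm = parts[1L], severity = parts[2L], n = sum(sel),
               mean_utility = mean(records$utility[sel]),
               stringsAsFactors = FALSE)
  }))
  overall <- do.call(rbind, lapply(unique(records$arm), function(a) {
    sel <- records$arm == a
    data.frame(arm = a, severity = "overall", n = sum(sel),
               mean_utility = mean(records$utility[sel]),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(cell, overall)
  out <- out[order(match(out$arm, c("user", "non_user")),
                   match(out$severity, c(severity_levels(), "overall"))), ]
  rownames(out) <- NULL
  out
}
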