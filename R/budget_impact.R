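#' Budget-impact analysis inputs
#'
#' National scale-up arithmetic for hearing-aid provision among adults aged
#' 60+. Defaults mirror the published scale-up scenario: a projected 60+
#' population of 14.9 crore, hearing-impairment prevalence 10%, 4.7% of the
#' impaired requiring hearing aids, a 35%/65% unilateral/bilateral fitting
#' split, and 3-year per-person fitting costs of INR 12,368 (unilateral) and
#' INR 20,368 (bilateral). 1 crore = 1e7.
#'
#' @param population projected persons aged >= 60 (default 1.49e8).
#' @param prevalence hearing-impairment prevalence fraction (default 0.10).
#' @param need_fraction fraction of the impaired requiring aids
#'   (default 0.047).
#' @param unilateral_fraction share of fittings that are unilateral
#'   (default 0.35; bilateral is the complement).
#' @param cost_unilateral,cost_bilateral per-person 3-year INR
#'   (defaults 12368, 20368).
#' @param horizon_years budget horizon (default 3).
#' @return object of class \code{bia_spec}.
#' @export
bia_spec <- function(population = 1.49e8, prevalence = 0.10,
                     need_fraction = 0.047, unilateral_fraction = 0.35,
                     cost_unilateral = 12368, cost_bilateral = 20368,
                     horizon_years = 3) {
  stopifnot(population >= 0,
            prevalence >= 0, prevalence <= 1,
            need_fraction >= 0, need_fraction <= 1,
            unilateral_fraction >= 0, unilateral_fraction <= 1,
            cost_unilateral >= 0, cost_bilateral >= 0,
            horizon_years >= 1)
  structure(
    list(population = population, prevalence = prevalence,
         need_fraction = need_fraction,
         unilateral_fraction = unilateral_fraction,
         cost_unilateral = cost_unilateral,
         cost_bilateral = cost_bilateral,
         horizon_years = horizon_years),
    class = "bia_spec"
  )
}

#' Eligible population for hearing-aid provision
#'
#' \code{population * prevalence * need_fraction}, carried as a real number;
#' rounding to whole persons happens only at report time.
#'
#' @param population persons.
#' @param prevalence fraction with hearing impairment.
#' @param need_fraction fraction of the impaired requiring aids.
#' @return persons (real-valued).
#' @examples
#' eligible_population(1.49e8, 0.10, 0.047)  # 700,300
#' @export
eligible_population <- function(population, prevalence, need_fraction) {
  stopifnot(population >= 0, prevalence >= 0, prevalence <= 1,
            need_fraction >= 0, need_fraction <= 1)
  population * prevalence * need_fraction
}

#' Split the eligible population across fitting categories
#'
#' @param eligible persons needing aids.
#' @param unilateral_fraction fraction fitted unilaterally, in [0, 1].
#' @return named numeric: \code{unilateral} and \code{bilateral} counts,
#'   summing to \code{eligible} exactly.
#' @export
allocate_fittings <- function(eligible, unilateral_fraction) {
  stopifnot(eligible >= 0,
            unilateral_fraction >= 0, unilateral_fraction <= 1)
  c(unilateral = eligible * unilateral_fraction,
    bilateral = eligible * (1 - unilateral_fraction))
}

#' Budget totals for the scale-up
#'
#' Category cost = fitting count x per-person cost; total = sum of
#' categories; annual = total / horizon. All arithmetic is in raw INR;
#' crore (1e7 INR) renderings are attached for reporting, rounded half-up
#' to whole crore, with persons rounded half-up to integers.
#'
#' @param spec a [bia_spec()].
#' @return object of class \code{bia_result}: list with \code{eligible},
#'   \code{fittings} (named counts), \code{cost_inr} (named: unilateral,
#'   bilateral, total, annual) and \code{report} (rounded persons and whole
#'   crore).
#' @examples
#' budget_totals(bia_spec())
#' @export
budget_totals <- function(spec = bia_spec()) {
  stopifnot(inherits(spec, "bia_spec"))
  eligible <- eligible_population(spec$population, spec$prevalence,
                                  spec$need_fraction)
  fit <- allocate_fittings(eligible, spec$unilateral_fraction)
  cost <- c(unilateral = unname(fit["unilateral"] * spec$cost_unilateral),
            bilateral = unname(fit["bilateral"] * spec$cost_bilateral))
  total <- sum(cost)
  annual <- total / spec$horizon_years
  structure(
    list(eligible = eligible, fittings = fit,
         cost_inr = c(cost, total = total, annual = annual),
         horizon_years = spec$horizon_years,
         report = list(
           eligible = round_half_up(eligible),
           fittings = round_half_up(fit),
           crore = round_half_up(c(cost, total = total, annual = annual) /
                                   1e7))),
    class = "bia_result"
  )
}

# round-half-up at 0 decimals (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' @export
print.bia_result <- function(x, ...) {
  cat("<bia_result> budget impact over ", x$horizon_years, " years\n",
      sep = "")
  cat("  eligible for fitting: ",
      format(x$report$eligible, big.mark = ","), " persons (",
      format(x$report$fittings[["unilateral"]], big.mark = ","),
      " unilateral / ",
      format(x$report$fittings[["bilateral"]], big.mark = ","),
      " bilateral)\n", sep = "")
  cat("  cost: unilateral ", x$report$crore[["unilateral"]],
      " crore, bilateral ", x$report$crore[["bilateral"]],
      " crore\n  total ", x$report$crore[["total"]],
      " crore (annual ", x$report$crore[["annual"]], " crore)\n", sep = "")
  invisible(x)
}
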