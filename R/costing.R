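#' Application schedule for direct medical cost items
#'
#' Over the modelled horizon, hearing-related consultation is applied once
#' (in the first year), and diagnostic investigation/testing twice in the
#' first year and once in each subsequent year; so for a horizon of h >= 1
#' years investigations are applied h + 1 times.
#'
#' @param horizon_years non-negative integer horizon.
#' @return named numeric: applications of \code{consultation} and
#'   \code{investigations} over the horizon.
#' @examples
#' schedule_applications(3)  # consultation 1, investigations 4
#' @export
schedule_applications <- function(horizon_years) {
  h <- as.numeric(horizon_years)
  if (length(h) != 1L || is.na(h) || h < 0 || h != round(h)) {
    stop("horizon_years must be a non-negative integer", call. = FALSE)
  }
  if (h == 0) {
    c(consultation = 0, investigations = 0)
  } else {
    c(consultation = 1, investigations = 2 + (h - 1))
  }
}

#' Total direct medical cost
#'
#' Sum of the consultation and investigation 3-year aggregates (INR per
#' person). Published aggregates are accepted directly; unit-cost scheduling
#' via [schedule_applications()] is available for scenario work.
#'
#' @param consultation,investigations aggregate INR per person, >= 0.
#' @return INR per person.
#' @examples
#' direct_medical_total(111, 4257)  # 4368, hearing-aid users
#' @export
direct_medical_total <- function(consultation, investigations) {
  if (any(consultation < 0) || any(investigations < 0)) {
    stop("cost components must be non-negative", call. = FALSE)
  }
  consultation + investigations
}

#' Total hearing-aid fitting cost
#'
#' Direct medical cost plus the device: \code{ears} times the per-ear device
#' price (default INR 8,000, the government ceiling price for a digital BTE
#' aid with a three-year warranty).
#'
#' @param direct_medical direct medical aggregate INR.
#' @param device_price_per_ear INR per ear (default 8000).
#' @param ears 0 (no device), 1 (unilateral) or 2 (bilateral).
#' @return INR per person over the device lifespan horizon.
#' @examples
#' total_fitting_cost(4368, ears = 1)  # 12368
#' total_fitting_cost(4368, ears = 2)  # 20368
#' @export
total_fitting_cost <- function(direct_medical, device_price_per_ear = 8000,
                               ears = 1) {
  if (!all(ears %in% c(0, 1, 2))) {
    stop("ears must be 0, 1 or 2", call. = FALSE)
  }
  if (any(direct_medical < 0) || any(device_price_per_ear < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  direct_medical + ears * device_price_per_ear
}
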