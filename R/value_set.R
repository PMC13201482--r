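#' EQ-5D-5L health-state profiles
#'
#' An EQ-5D-5L profile records one level (1 = no problems .. 5 = extreme
#' problems) on each of the five dimensions: mobility (mo), self-care (sc),
#' usual activities (ua), pain/discomfort (pd) and anxiety/depression (ad).
#' The profile \code{"11111"} is the full-health state.
#'
#' @param x a five-digit string such as \code{"21321"}, or a numeric vector
#'   of five levels in dimension order mo, sc, ua, pd, ad.
#' @return an object of class \code{eq5d_profile}: a named integer vector of
#'   length five.
#' @examples
#' eq5d_profile("21321")
#' eq5d_profile(c(1, 1, 1, 1, 1))
#' @export
eq5d_profile <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!grepl("^[1-5]{5}$", x)) {
      stop("EQ-5D-5L profile must be five digits, each in 1..5, got ",
           sQuote(x), call. = FALSE)
    }
    lv <- as.integer(strsplit(x, "")[[1L]])
  } else {
    lv <- as.integer(x)
  }
  if (length(lv) != 5L || anyNA(lv) || any(lv < 1L | lv > 5L)) {
    stop("EQ-5D-5L profile needs five levels, each in 1..5", call. = FALSE)
  }
  names(lv) <- eq5d_dimensions()
  structure(lv, class = "eq5d_profile")
}

#' @export
format.eq5d_profile <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
print.eq5d_profile <- function(x, ...) {
  cat("<eq5d_profile> ", format(x), "\n", sep = "")
  invisible(x)
}

#' The five EQ-5D dimension codes
#'
#' @return character vector \code{c("mo","sc","ua","pd","ad")}.
#' @export
eq5d_dimensions <- function() c("mo", "sc", "ua", "pd", "ad")

#' Load and validate an EQ-5D-5L value-set tariff
#'
#' A tariff is an additive scoring table: a utility intercept (the value of
#' full health, usually 1) and a non-negative decrement for every
#' (dimension, level) pair, level 1 carrying decrement 0. The utility of a
#' profile is \code{intercept - sum(decrements)}. Country value sets (e.g. the
#' India EQ-5D-5L value set) can be supplied in this format; the package ships
#' only a synthetic toy tariff for tests and examples.
#'
#' The file is a long CSV with columns \code{dimension}, \code{level},
#' \code{decrement}, plus one row with \code{dimension == "intercept"} whose
#' \code{decrement} column holds the intercept value. On load the tariff must
#' score \code{"11111"} to exactly the intercept; decrements must be
#' non-negative and zero at level 1; a decrement that decreases with worsening
#' level raises a warning (real tariffs are occasionally non-monotone), not an
#' error.
#'
#' @param path path to the tariff CSV.
#' @param name label for the tariff; defaults to the file name.
#' @return an object of class \code{eq5d_tariff} with elements \code{name},
#'   \code{intercept}, \code{decrement} (5 x 5 matrix, dimensions x levels)
#'   and \code{floor} (the utility of \code{"55555"}, the worst scorable
#'   state).
#' @seealso [score_profile()], [toy_tariff()]
#' @export
load_tariff <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("tariff file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tab))) {
    stop("tariff CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  is_int <- tab$dimension == "intercept"
  if (sum(is_int) != 1L) {
    stop("tariff CSV must contain exactly one 'intercept' row", call. = FALSE)
  }
  intercept <- as.numeric(tab$decrement[is_int])
  body <- tab[!is_int, , drop = FALSE]
  new_tariff(name, intercept, body$dimension, as.integer(body$level),
             as.numeric(body$decrement))
}

# Assemble + validate a tariff from its long-format components.
new_tariff <- function(name, intercept, dimension, level, decrement) {
  dims <- eq5d_dimensions()
  bad <- setdiff(unique(dimension), dims)
  if (length(bad)) {
    stop("unknown tariff dimension(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(dims, collapse = ", "), call. = FALSE)
  }
  dec <- matrix(NA_real_, nrow = 5L, ncol = 5L,
                dimnames = list(dims, paste0("L", 1:5)))
  dec[, 1L] <- 0  # level 1 = no problems; rows may omit it
  for (i in seq_along(dimension)) {
    if (level[i] < 1L || level[i] > 5L) {
      stop("tariff level out of range for (", dimension[i], ", level ",
           level[i], ")", call. = FALSE)
    }
    dec[dimension[i], level[i]] <- decrement[i]
  }
  if (anyNA(dec)) {
    miss <- which(is.na(dec), arr.ind = TRUE)
    key <- paste0("(", rownames(dec)[miss[1L, 1L]], ", level ",
                  miss[1L, 2L], ")")
    stop("tariff is missing a decrement for ", key, call. = FALSE)
  }
  if (any(dec[, 1L] != 0)) {
    stop("tariff level-1 decrements must all be 0", call. = FALSE)
  }
  if (any(dec < 0)) stop("tariff decrements must be non-negative",
                         call. = FALSE)
  if (any(apply(dec, 1L, function(r) any(diff(r) < 0)))) {
    warning("tariff decrements are not non-decreasing in level within every ",
            "dimension", call. = FALSE)
  }
  t <- structure(
    list(name = name, intercept = intercept, decrement = dec,
         floor = intercept - sum(dec[, 5L])),
    class = "eq5d_tariff"
  )
  # conformance smoke test: full health must score to the intercept
  stopifnot(score_profile(eq5d_profile("11111"), t) == intercept)
  t
}

#' A synthetic toy tariff for tests and examples
#'
#' Intercept 1.0 with small synthetic decrements (these are not any country's
#' value-set coefficients). Scoring \code{"11111"} gives 1.0; \code{"55555"}
#' gives the floor.
#'
#' @return an \code{eq5d_tariff}.
#' @examples
#' score_profile(eq5d_profile("21111"), toy_tariff())
#' @export
toy_tariff <- function() {
  dims <- eq5d_dimensions()
  base <- c(mo = 0.05, sc = 0.04, ua = 0.04, pd = 0.06, ad = 0.05)
  dimension <- rep(dims, each = 4L)
  level <- rep(2:5, times = 5L)
  decrement <- as.numeric(vapply(dims, function(d) base[[d]] * (1:4),
                                 numeric(4L)))
  new_tariff("toy (synthetic)", 1.0, dimension, level, decrement)
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("<eq5d_tariff> ", x$name, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "   floor: ",
      format(round(x$floor, 4)), "\n", sep = "")
  print(round(x$decrement, 4))
  invisible(x)
}

#' Score an EQ-5D-5L profile against a tariff
#'
#' Returns \code{intercept - sum} of the five (dimension, level) decrements.
#' Deterministic; utilities may be negative down to the tariff floor.
#'
#' @param profile an [eq5d_profile()] (or something coercible to one).
#' @param tariff an \code{eq5d_tariff}.
#' @return utility (dimensionless scalar).
#' @examples
#' score_profile("55555", toy_tariff())
#' @export
score_profile <- function(profile, tariff) {
  if (!inherits(profile, "eq5d_profile")) profile <- eq5d_profile(profile)
  stopifnot(inherits(tariff, "eq5d_tariff"))
  lv <- unclass(profile)[eq5d_dimensions()]
  tariff$intercept - sum(tariff$decrement[cbind(1:5, lv)])
}

#' WHO hearing-loss severity grading from better-ear threshold
#'
#' Grades the better-ear hearing threshold (dB HL) into mild / moderate /
#' severe using WHO cut-offs, with the WHO moderate and moderately-severe
#' grades pooled into one 35-64 dB category. Ranges are half-open:
#' mild \[20, 35), moderate \[35, 65), severe \[65, Inf) -- 35 dB and 65 dB
#' belong to the higher grade, so the integer ranges 20-34 / 35-64 / >=65 are
#' matched exactly and non-integer thresholds are resolved by the half-open
#' rule.
#'
#' @param better_ear_db better-ear threshold(s) in dB, finite and >= 20.
#' @return factor with levels \code{mild}, \code{moderate}, \code{severe}.
#' @examples
#' classify_severity(c(25, 34.9, 35, 64, 65, 90))
#' @export
classify_severity <- function(better_ear_db) {
  x <- as.numeric(better_ear_db)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("better-ear threshold must be finite and non-negative",
         call. = FALSE)
  }
  if (any(x < 20)) {
    stop("threshold below 20 dB is below the impairment range and has no ",
         "severity grade", call. = FALSE)
  }
  cut(x, breaks = c(20, 35, 65, Inf), right = FALSE,
      labels = severity_levels())
}

#' @rdname classify_severity
#' @return `severity_levels()`: the ordered grade labels.
#' @export
severity_levels <- function() c("mild", "moderate", "severe")

#' Build a participant record table
#'
#' One row per survey participant: arm (\code{user} / \code{non_user}),
#' severity grade, utility, and two 3-year aggregate cost components in INR.
#' Utility may be supplied directly (as aggregate published tables do) or
#' scored from a five-digit EQ-5D-5L profile via \code{tariff}.
#'
#' @param id participant identifiers.
#' @param arm \code{"user"} or \code{"non_user"}.
#' @param severity severity grades (see [severity_levels()]), or \code{NULL}
#'   if \code{better_ear_db} is given instead.
#' @param better_ear_db optional better-ear thresholds in dB, graded with
#'   [classify_severity()].
#' @param profile optional character vector of five-digit profiles.
#' @param utility optional numeric utilities; required where profile is NA.
#' @param cost_consultation,cost_investigations 3-year aggregate INR.
#' @param tariff tariff used to score profiles, when any are given.
#' @return data.frame of class \code{participant_records}.
#' @export
participant_records <- function(id, arm, severity = NULL,
                                better_ear_db = NULL,
                                profile = NULL, utility = NULL,
                                cost_consultation = 0,
                                cost_investigations = 0,
                                tariff = NULL) {
  n <- length(id)
  arm <- match.arg(as.character(arm), c("user", "non_user"),
                   several.ok = TRUE)
  arm <- rep_len(arm, n)
  if (is.null(severity)) {
    if (is.null(better_ear_db)) {
      stop("supply either severity grades or better_ear_db thresholds",
           call. = FALSE)
    }
    severity <- classify_severity(better_ear_db)
  }
  severity <- factor(as.character(severity), levels = severity_levels())
  if (anyNA(severity)) stop("unknown severity grade", call. = FALSE)
  if (is.null(utility)) utility <- rep(NA_real_, n)
  utility <- rep_len(as.numeric(utility), n)
  if (!is.null(profile)) {
    profile <- rep_len(as.character(profile), n)
    need <- !is.na(profile)
    if (any(need)) {
      if (is.null(tariff)) {
        stop("a tariff is required to score profiles", call. = FALSE)
      }
      utility[need] <- vapply(profile[need],
                              function(p) score_profile(p, tariff),
                              numeric(1L))
    }
  }
  if (anyNA(utility)) {
    stop("every record needs a utility or a scorable profile", call. = FALSE)
  }
  out <- data.frame(
    id = as.character(id), arm = arm, severity = severity,
    utility = utility,
    cost_consultation = rep_len(as.numeric(cost_consultation), n),
    cost_investigations = rep_len(as.numeric(cost_investigations), n),
    stringsAsFactors = FALSE
  )
  if (any(out$cost_consultation < 0) || any(out$cost_investigations < 0)) {
    stop("cost components must be non-negative", call. = FALSE)
  }
  class(out) <- c("participant_records", "data.frame")
  out
}

#' Mean utility over a (filtered) cohort
#'
#' Arithmetic mean of utilities over the records matching the arm and/or
#' severity filters; filters compose (arm AND severity). An empty selection
#' is an error, never silently 0.
#'
#' @param records a [participant_records()] table.
#' @param arm optional \code{"user"} / \code{"non_user"} filter.
#' @param severity optional severity-grade filter.
#' @return mean utility (scalar).
#' @export
mean_utility <- function(records, arm = NULL, severity = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(arm)) keep <- keep & records$arm %in% arm
  if (!is.null(severity)) {
    keep <- keep & as.character(records$severity) %in% as.character(severity)
  }
  if (!any(keep)) {
    stop("empty selection: no records match arm = ",
         if (is.null(arm)) "<any>" else arm, ", severity = ",
         if (is.null(severity)) "<any>" else severity, call. = FALSE)
  }
  mean(records$utility[keep])
}
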