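# Founder-mutation dating support: average population growth rates from
# historical census records and best-correlation selection of the mutation
# age.
#
# Mutation ages are estimated externally (a Bayesian MCMC
# linkage-disequilibrium method run once per candidate growth rate); this
# module computes the growth-rate inputs and applies the selection rule to
# the external estimates. The growth-rate equation is, as published,
#
#   X = ((P2 - P1) / P1)^(1/n) - 1
#
# with P1 the census population n years ago and P2 the present population
# (1.4e9 by default). Note the numerator is P2 - P1, not P2; this exact
# form reproduces the published per-mille rates, while the conventional
# geometric-growth form (P2/P1)^(1/n) - 1 is available via `form =
# "geometric"` and gives slightly different values.

#' Average annual population growth rate
#'
#' @param P1 population `n` years ago (persons); must be positive and less
#'   than `P2` (the printed form does not support zero or negative growth).
#' @param P2 present population (persons).
#' @param n elapsed years (>= 1).
#' @param form `"as_printed"` (default) uses `((P2 - P1)/P1)^(1/n) - 1`;
#'   `"geometric"` uses the conventional `(P2/P1)^(1/n) - 1`.
#' @return growth rate as a per-year fraction; multiply by 1000 for the
#'   conventional per-mille display ([permille()]).
#' @examples
#' permille(growth_rate(59590e3, 1.4e9, 2018)) # 1.54 per mille
#' @export
growth_rate <- function(P1, P2, n, form = c("as_printed", "geometric")) {
  form <- match.arg(form)
  if (any(is.na(c(P1, P2, n))) || any(P1 <= 0)) {
    stop_rorscan("populations must be positive", "domain_error")
  }
  if (any(n < 1)) stop_rorscan("elapsed years must be >= 1", "domain_error")
  if (any(P2 <= P1)) {
    stop_rorscan("P2 must exceed P1 (zero or negative growth unsupported)", "domain_error")
  }
  ratio <- switch(form,
    as_printed = (P2 - P1) / P1,
    geometric = P2 / P1
  )
  ratio^(1 / n) - 1
}

#' Per-mille display of a growth rate
#'
#' @param x per-year fraction.
#' @param digits decimals (default 2, the conventional display).
#' @return numeric per-mille value rounded to `digits`.
#' @export
permille <- function(x, digits = 2) round(1000 * x, digits)

.unit_multiplier <- c(
  person = 1, persons = 1, unit = 1,
  thousand = 1e3, thousands = 1e3,
  million = 1e6, millions = 1e6,
  billion = 1e9, billions = 1e9
)

#' Growth rates over a table of historical population records
#'
#' @param records data frame with columns `label`, `population`,
#'   `population_unit` (person/thousand/million/billion), `years_till_now`
#'   and optionally `estimated_age` (years, from the external age
#'   estimator).
#' @param present_pop present population in persons (default 1.4e9).
#' @param form passed to [growth_rate()].
#' @return `records` with added columns `persons`, `growth_rate` (per-year
#'   fraction) and `growth_rate_permille` (two decimals).
#' @export
growth_rate_table <- function(records, present_pop = 1.4e9,
                              form = c("as_printed", "geometric")) {
  form <- match.arg(form)
  require_columns(records, c("label", "population", "population_unit", "years_till_now"),
    "population record table")
  mult <- .unit_multiplier[normalize_token(records$population_unit)]
  if (any(is.na(mult))) {
    stop_rorscan(
      sprintf(
        "unknown population unit: %s",
        paste(unique(records$population_unit[is.na(mult)]), collapse = ", ")
      ),
      "config_error"
    )
  }
  records$persons <- records$population * as.numeric(mult)
  records$growth_rate <- growth_rate(records$persons, present_pop,
    records$years_till_now, form = form)
  records$growth_rate_permille <- permille(records$growth_rate)
  records
}

#' Read a historical population record table
#'
#' Delimited table with columns `label, population, population_unit,
#' years_till_now[, estimated_age]`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_population_records <- function(path) {
  rec <- read_delim_auto(path)
  require_columns(rec, c("label", "population", "population_unit", "years_till_now"),
    basename(path))
  rec
}

#' Select the best-correlating growth rate / age pair
#'
#' Each historical record pairs an elapsed time n (years till now) with the
#' mutation age estimated under that record's growth rate. The selection
#' rule picks the record whose estimated age agrees best with its own
#' elapsed time, i.e. minimises |estimated_age - years_till_now|; ties break
#' toward the smaller elapsed time with a logged note.
#'
#' @param records data frame with `years_till_now` and `estimated_age`
#'   columns (rows with `NA` estimated age are ignored).
#' @return object of class `age_selection`: list with `chosen` (the winning
#'   row), `discrepancy` and `age` (the chosen estimated age in years).
#' @export
select_best_rate <- function(records) {
  require_columns(records, c("years_till_now", "estimated_age"), "age record table")
  rec <- records[!is.na(records$estimated_age), , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop_rorscan("no rows with an estimated age to select from", "domain_error")
  }
  disc <- abs(rec$estimated_age - rec$years_till_now)
  best <- min(disc)
  tied <- which(disc == best)
  if (length(tied) > 1L) {
    message(sprintf(
      "tie on discrepancy %s; choosing the smaller elapsed time", format(best)
    ))
  }
  pick <- tied[which.min(rec$years_till_now[tied])]
  structure(
    list(
      chosen = rec[pick, , drop = FALSE],
      discrepancy = best,
      age = rec$estimated_age[pick]
    ),
    class = "age_selection"
  )
}

#' @export
print.age_selection <- function(x, ...) {
  cat(sprintf(
    "Selected record: %s (estimated age %s years, |age - elapsed| = %s)\n",
    if (!is.null(x$chosen$label)) x$chosen$label else rownames(x$chosen),
    format(x$age), format(x$discrepancy)
  ))
  invisible(x)
}

#' Convert an age in years to a calendar label
#'
#' Naive subtraction from the present year, as conventionally quoted for
#' founder ages: an age of 2,090 years from 2020 prints "70 B.C.". Year
#' zero does not exist, so a result of 0 prints "1 B.C.".
#'
#' @param age_years non-negative age in years.
#' @param present_year reference year (default 2020).
#' @return character calendar label, e.g. `"70 B.C."` or `"2020 A.D."`.
#' @export
years_to_calendar <- function(age_years, present_year = 2020) {
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop_rorscan("age must be a non-negative number of years", "domain_error")
  }
  y <- present_year - age_years
  ifelse(y >= 1, sprintf("%d A.D.", as.integer(y)),
    sprintf("%d B.C.", as.integer(pmax(1, -y))))
}
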