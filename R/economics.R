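#' Partial-budget economics configuration
#'
#' The financial comparison is a partial budget: only items that differ
#' between the two living-space scenarios enter. Milk income is valued at a
#' margin over purchased feed per liter; each calving carries a dry/transition
#' -period disease-risk cost by parity class. Defaults are the study
#' conditions: margin U(0.17, 0.23) GBP/L (around the published UK mean of
#' 0.2049), transition cost U(32.43, 129.72) GBP per primiparous calving and
#' U(49.54, 198.16) GBP per multiparous calving (half to double the point
#' estimates of 64.86 and 99.08).
#'
#' @param margin_bounds uniform bounds for the margin over purchased feed
#'   (GBP/liter).
#' @param primiparous_cost_bounds,multiparous_cost_bounds uniform bounds for
#'   the transition cost per calving event (GBP).
#' @param days_per_year divisor converting a calendar span in days to years.
#' @return An object of class \code{econ_config}.
#' @export
econ_config <- function(margin_bounds = c(0.17, 0.23),
                        primiparous_cost_bounds = c(32.43, 129.72),
                        multiparous_cost_bounds = c(49.54, 198.16),
                        days_per_year = 365.25) {
  check_bounds(margin_bounds, "margin_bounds", min_allowed = 0)
  check_bounds(primiparous_cost_bounds, "primiparous_cost_bounds", min_allowed = 0)
  check_bounds(multiparous_cost_bounds, "multiparous_cost_bounds", min_allowed = 0)
  check(is_number(days_per_year) && days_per_year > 0,
        "econ_config: 'days_per_year' must be > 0")
  structure(
    list(margin_bounds = as.numeric(margin_bounds),
         primiparous_cost_bounds = as.numeric(primiparous_cost_bounds),
         multiparous_cost_bounds = as.numeric(multiparous_cost_bounds),
         days_per_year = as.numeric(days_per_year)),
    class = "econ_config")
}

#' Draw the economic parameters of one paired comparison
#'
#' One margin and one transition cost per parity class are drawn per paired
#' comparison and shared by both scenarios, so price variation never
#' contributes to the scenario difference.
#'
#' @param config an [econ_config()] object.
#' @return An object of class \code{econ_draws} with fields \code{margin},
#'   \code{primiparous_cost}, \code{multiparous_cost}.
#' @export
draw_economics <- function(config) {
  stopifnot(inherits(config, "econ_config"))
  structure(
    list(margin = stats::runif(1L, config$margin_bounds[1], config$margin_bounds[2]),
         primiparous_cost = stats::runif(1L, config$primiparous_cost_bounds[1],
                                         config$primiparous_cost_bounds[2]),
         multiparous_cost = stats::runif(1L, config$multiparous_cost_bounds[1],
                                         config$multiparous_cost_bounds[2])),
    class = "econ_draws")
}

#' Total transition cost of a timeline
#'
#' Every calving event, including the first and including replacement-heifer
#' calvings, incurs the parity-class transition cost of the comparison.
#'
#' @param timeline a \code{scenario_timeline}.
#' @param draws an \code{econ_draws} object.
#' @return total cost in GBP.
#' @export
transition_total <- function(timeline, draws) {
  timeline$n_primiparous_calvings * draws$primiparous_cost +
    timeline$n_multiparous_calvings * draws$multiparous_cost
}

#' Financial-return difference of a paired comparison
#'
#' The partial-budget return of each scenario is lifetime milk times the
#' margin per liter minus its total transition cost; the comparison's result
#' is the high-space minus control-space difference, reported in total GBP
#' over the shared span and per cow place per year.
#'
#' @param hs_milk,cs_milk lifetime milk (liters) of the high- and
#'   control-space timeline (including any replacement tail).
#' @param hs_transition,cs_transition total transition costs (GBP).
#' @param margin margin over purchased feed (GBP/liter).
#' @param span_days shared calendar span of the paired timelines (days).
#' @param days_per_year divisor for annualization (default 365.25).
#' @return list with \code{total} (GBP) and \code{per_year} (GBP/cow/year).
#' @export
financial_return_difference <- function(hs_milk, cs_milk,
                                        hs_transition, cs_transition,
                                        margin, span_days,
                                        days_per_year = 365.25) {
  if (any(span_days <= 0))
    stop("financial_return_difference: span must be positive", call. = FALSE)
  total <- (hs_milk * margin - hs_transition) - (cs_milk * margin - cs_transition)
  list(total = total, per_year = total / (span_days / days_per_year))
}

#' Annualized return difference over each scenario's own lifespan
#'
#' The per-cow-per-year financial-return difference used as the headline
#' outcome: each scenario's focal-cow partial-budget return is divided by
#' that scenario's own lifetime (first calving to exit) before differencing,
#' so the comparison is between production rates, not totals over a common
#' horizon. This is the response regressed in [fit_return_model()] and the
#' sample fed to the net-return analysis.
#'
#' @param hs_return,cs_return focal-cow partial-budget returns (GBP):
#'   lifetime milk x margin minus transition costs, per scenario.
#' @param hs_span_days,cs_span_days each scenario's focal lifetime in days
#'   (> 0).
#' @param days_per_year annualization divisor (default 365.25).
#' @return difference in GBP per cow per year.
#' @export
annualized_return_difference <- function(hs_return, cs_return,
                                         hs_span_days, cs_span_days,
                                         days_per_year = 365.25) {
  if (any(hs_span_days <= 0) || any(cs_span_days <= 0))
    stop("annualized_return_difference: spans must be positive", call. = FALSE)
  hs_return / (hs_span_days / days_per_year) -
    cs_return / (cs_span_days / days_per_year)
}
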