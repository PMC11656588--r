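#' Capital costing of a space-provision option
#'
#' Three ways of providing the extra 3.5 m2 of living space per cow are
#' costed: a new build (unit cost 182 GBP/m2, compared between total-space
#' allowances of 14 and 9 m2 per cow), an indoor loafing-area extension
#' (248 GBP/m2 over the 3.5 m2 difference) and an outdoor loafing-area
#' extension (100.75 GBP/m2 over 3.5 m2), each for a 100-cow herd.
#'
#' @param name one of \code{"new_build"}, \code{"indoor_extension"},
#'   \code{"outdoor_extension"}, or a free label.
#' @param unit_cost build cost in GBP per m2 (> 0).
#' @param herd_size number of cow places (>= 1; 0 allowed, costing nothing).
#' @param area_high,area_control per-cow areas (m2) whose cost difference
#'   is financed. For the new build these are the total-space allowances
#'   (14 and 9); for the extensions the extra area (3.5) against 0.
#' @return An object of class \code{build_option}.
#' @export
build_option <- function(name, unit_cost, herd_size = 100,
                         area_high = 3.5, area_control = 0) {
  check(is.character(name) && length(name) == 1L, "build_option: 'name' must be a string")
  check(is_number(unit_cost) && unit_cost > 0, "build_option: 'unit_cost' must be > 0")
  check(is_number(herd_size) && herd_size >= 0, "build_option: 'herd_size' must be >= 0")
  check(is_number(area_high) && is_number(area_control) && area_high > area_control,
        "build_option: 'area_high' must exceed 'area_control'")
  structure(list(name = name, unit_cost = unit_cost, herd_size = herd_size,
                 area_high = area_high, area_control = area_control),
            class = "build_option")
}

#' Default space-provision options
#'
#' @param herd_size number of cow places (default 100).
#' @return named list of the three default [build_option()] objects.
#' @export
space_options <- function(herd_size = 100) {
  list(
    new_build = build_option("new_build", 182, herd_size,
                             area_high = 14, area_control = 9),
    indoor_extension = build_option("indoor_extension", 248, herd_size),
    outdoor_extension = build_option("outdoor_extension", 100.75, herd_size))
}

#' Capital cost of an area allowance
#'
#' @param option a [build_option()].
#' @param area_per_cow floor area in m2 per cow (> 0).
#' @return unit cost x area x herd size, in GBP.
#' @export
capital_cost <- function(option, area_per_cow) {
  stopifnot(inherits(option, "build_option"))
  check(is_number(area_per_cow) && area_per_cow > 0,
        "capital_cost: 'area_per_cow' must be > 0")
  option$unit_cost * area_per_cow * option$herd_size
}

#' Loan terms
#'
#' @param rate annual interest rate as a fraction (e.g. 0.04 for 4\%; >= 0).
#' @param years loan repayment period in whole years (> 0).
#' @param model repayment model. \code{"equal_principal"} (the default)
#'   repays the principal in equal annual installments with interest charged
#'   on the outstanding balance, giving total repayment
#'   \eqn{P (1 + r (n + 1) / 2)}. \code{"annuity"} repays in equal annual
#'   payments \eqn{P r / (1 - (1+r)^{-n})}; it is offered as an alternative
#'   and produces different (higher) totals at the same rate.
#' @return An object of class \code{loan_terms}.
#' @export
loan_terms <- function(rate, years, model = c("equal_principal", "annuity")) {
  model <- match.arg(model)
  if (!is_number(rate) || rate < 0)
    stop("loan_terms: 'rate' must be a non-negative fraction", call. = FALSE)
  check(is_number(years) && years > 0, "loan_terms: 'years' must be > 0")
  structure(list(rate = rate, years = as.integer(years), model = model),
            class = "loan_terms")
}

#' Total loan repayment
#'
#' @param principal amount borrowed (GBP, >= 0).
#' @param terms a [loan_terms()] object.
#' @return total repaid over the term (GBP). At rate 0 this equals the
#'   principal under either model.
#' @export
total_repayment <- function(principal, terms) {
  stopifnot(inherits(terms, "loan_terms"))
  check(is_number(principal) && principal >= 0,
        "total_repayment: 'principal' must be >= 0")
  r <- terms$rate
  n <- terms$years
  switch(terms$model,
         equal_principal = principal * (1 + r * (n + 1) / 2),
         annuity = if (r == 0) principal else
           n * principal * r / (1 - (1 + r)^(-n)))
}

#' Amortized cost of providing the extra living space
#'
#' The financed principal is the capital-cost difference between the high-
#' and control-space areas of the option (for the extensions the control
#' area is 0, so this is simply unit cost x 3.5 m2 x herd). The total
#' repayment is spread over the herd and the loan term. All values are kept
#' at full precision; rounding to pennies is applied at output only (see
#' [sensitivity_table()]).
#'
#' @param option a [build_option()].
#' @param terms a [loan_terms()].
#' @return An object of class \code{amortization} with fields
#'   \code{principal}, \code{total_repayment} (GBP, herd level),
#'   \code{total_per_cow} (GBP/cow) and \code{per_cow_per_year}
#'   (GBP/cow/year).
#' @export
annualized_cost_per_cow <- function(option, terms) {
  stopifnot(inherits(option, "build_option"), inherits(terms, "loan_terms"))
  principal <- option$unit_cost * (option$area_high - option$area_control) *
    option$herd_size
  total <- total_repayment(principal, terms)
  structure(
    list(option = option$name, rate = terms$rate, years = terms$years,
         principal = principal, total_repayment = total,
         total_per_cow = if (option$herd_size > 0) total / option$herd_size else 0,
         per_cow_per_year = if (option$herd_size > 0)
           total / option$herd_size / terms$years else 0),
    class = "amortization")
}

#' Net return on infrastructure investment
#'
#' Subtracts an annualized per-cow space cost from a sample of simulated
#' financial-return differences (GBP/cow/year) and summarizes the resulting
#' net-return distribution. Percentiles use linear interpolation between
#' order statistics (\code{stats::quantile} type 7); the probability of a
#' positive net return counts strictly positive values.
#'
#' @param samples numeric vector of financial-return differences per cow per
#'   year (non-empty).
#' @param cost annualized space cost (GBP/cow/year).
#' @return An object of class \code{net_return_summary} with fields
#'   \code{cost}, \code{p10}, \code{median}, \code{p90}, \code{prob_positive}.
#' @export
net_return_summary <- function(samples, cost) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("net_return_summary: 'samples' must be a non-empty numeric vector",
         call. = FALSE)
  check(is_number(cost), "net_return_summary: 'cost' must be a number")
  net <- samples - cost
  q <- stats::quantile(net, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  structure(list(cost = cost, p10 = q[1], median = q[2], p90 = q[3],
                 prob_positive = mean(net > 0)),
            class = "net_return_summary")
}

#' Interest-rate and loan-term sensitivity grid
#'
#' One row per option x rate x term: the financed cost difference per cow
#' (total over the term and per year) and the net-return summary of the
#' supplied financial-return sample against that annual cost. Monetary
#' columns are rounded half-up to pennies and the probability of a positive
#' net return is expressed in percent, matching how such tables are printed.
#'
#' @param samples financial-return differences per cow per year (GBP).
#' @param options list of [build_option()] objects (default
#'   [space_options()]).
#' @param rates annual interest rates in percent
#'   (default \code{c(0, 3.74, 4, 5.3, 8)}).
#' @param terms_years loan repayment periods in years (default 20).
#' @param model repayment model passed to [loan_terms()].
#' @return data frame of class \code{sensitivity_table} with columns
#'   \code{option}, \code{rate_pct}, \code{term_years},
#'   \code{total_per_cow}, \code{per_cow_per_year}, \code{p10},
#'   \code{median}, \code{p90}, \code{prob_positive_pct}.
#' @export
sensitivity_table <- function(samples, options = space_options(),
                              rates = c(0, 3.74, 4, 5.3, 8),
                              terms_years = 20,
                              model = "equal_principal") {
  check(length(rates) > 0, "sensitivity_table: 'rates' must be non-empty")
  check(length(terms_years) > 0, "sensitivity_table: 'terms_years' must be non-empty")
  rows <- list()
  for (opt in options) {
    for (ty in terms_years) {
      for (rate in rates) {
        am <- annualized_cost_per_cow(opt, loan_terms(rate / 100, ty, model))
        nr <- net_return_summary(samples, am$per_cow_per_year)
        rows[[length(rows) + 1L]] <- data.frame(
          option = opt$name, rate_pct = rate, term_years = ty,
          total_per_cow = round_pennies(am$total_per_cow),
          per_cow_per_year = round_pennies(am$per_cow_per_year),
          p10 = round_pennies(nr$p10),
          median = round_pennies(nr$median),
          p90 = round_pennies(nr$p90),
          prob_positive_pct = round(100 * nr$prob_positive, 2))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' @export
print.net_return_summary <- function(x, ...) {
  cat(sprintf("Net return on infrastructure investment (cost %.2f GBP/cow/year)\n",
              x$cost))
  cat(sprintf("  10th pct %8.2f   median %8.2f   90th pct %8.2f   P(>0) %5.1f%%\n",
              x$p10, x$median, x$p90, 100 * x$prob_positive))
  invisible(x)
}

#' @export
print.amortization <- function(x, ...) {
  cat(sprintf("%s: principal %.2f GBP at %.2f%% over %d y\n",
              x$option, x$principal, 100 * x$rate, x$years))
  cat(sprintf("  total repayment %.2f GBP (%.2f/cow, %.2f/cow/year)\n",
              x$total_repayment, x$total_per_cow, x$per_cow_per_year))
  invisible(x)
}
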