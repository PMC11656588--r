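#' Milk-yield model configuration
#'
#' The daily milk-yield model is a Wilmink lactation curve per parity class,
#' \deqn{y(t) = a + b e^{-k t} + c t,}
#' with \code{t} the days in milk, plus an additive living-space scenario
#' effect (applied to the high-space scenario only) and an additive effect for
#' each of five gestation stages. Per-cow variability enters by drawing each
#' curve coefficient from a normal distribution centred on the configured mean
#' (see [draw_cow_coefficients()]). The shipped coefficient values are
#' illustrative defaults calibrated to plausible Holstein output
#' (roughly 9,000 L over a 305-day multiparous lactation); they are
#' configuration, not estimates.
#'
#' @param primiparous,multiparous named lists with Wilmink coefficients
#'   \code{a} (scale, L/day), \code{b} (ramp, L/day), \code{k} (ramp rate,
#'   1/day) and \code{c} (persistency slope, L/day^2).
#' @param scenario_effect additive daily-yield effect (L/day) of the
#'   high-space scenario relative to control.
#' @param gestation_effects numeric vector of five additive effects (L/day),
#'   one per gestation stage, typically non-positive and non-increasing.
#' @param sd named list of standard deviations for the per-cow draws of
#'   \code{a}, \code{b}, \code{k}, \code{c} (same for both parity classes).
#' @param gestation_breaks lower edges (days pregnant) of the five gestation
#'   stages; stage 5 is open-ended up to \code{max_gestation}.
#' @param max_gestation maximum gestation length (days) the stages must cover.
#'
#' @return An object of class \code{milk_config}.
#' @seealso [draw_cow_coefficients()], [daily_yield()], [lactation_milk()]
#' @export
milk_config <- function(primiparous = list(a = 31, b = -12, k = 0.045, c = -0.022),
                        multiparous = list(a = 41, b = -16, k = 0.055, c = -0.040),
                        scenario_effect = 1.1,
                        gestation_effects = c(-0.8, -3.0, -5.5, -8.0, -11.0),
                        sd = list(a = 2.5, b = 2.0, k = 0.005, c = 0.005),
                        gestation_breaks = c(1, 57, 113, 169, 225),
                        max_gestation = 285) {
  coef_names <- c("a", "b", "k", "c")
  for (cls in list(primiparous, multiparous)) {
    check(is.list(cls) && all(coef_names %in% names(cls)),
          "milk_config: parity-class coefficients must name a, b, k, c")
  }
  check(is_number(scenario_effect), "milk_config: 'scenario_effect' must be a number")
  check(is.numeric(gestation_effects) && length(gestation_effects) == 5L,
        "milk_config: exactly five gestation-stage effects are required")
  check(all(coef_names %in% names(sd)), "milk_config: 'sd' must name a, b, k, c")
  sds <- unlist(sd[coef_names])
  check(all(is.finite(sds)) && all(sds >= 0),
        "milk_config: coefficient standard deviations must be >= 0")
  check(is.numeric(gestation_breaks) && length(gestation_breaks) == 5L,
        "milk_config: exactly five gestation bin edges are required")
  check(gestation_breaks[1] == 1 && !is.unsorted(gestation_breaks, strictly = TRUE),
        "milk_config: gestation bin edges must start at 1 and be strictly increasing")
  check(gestation_breaks[5] <= max_gestation,
        "milk_config: last gestation bin edge must not exceed max_gestation")
  structure(
    list(primiparous = lapply(primiparous[coef_names], as.numeric),
         multiparous = lapply(multiparous[coef_names], as.numeric),
         scenario_effect = as.numeric(scenario_effect),
         gestation_effects = as.numeric(gestation_effects),
         sd = lapply(sd[coef_names], as.numeric),
         gestation_breaks = as.numeric(gestation_breaks),
         max_gestation = as.numeric(max_gestation)),
    class = "milk_config")
}

#' Draw one cow's lactation-curve coefficients
#'
#' Each Wilmink coefficient, for each parity class, is drawn independently
#' from Normal(configured mean, configured sd). The object also records a
#' scalar coefficient-deviation summary: the root mean square of the
#' standardized draws (z-scores) across all coefficients with non-zero sd.
#' That summary is carried through the simulation as a regression covariate
#' measuring how far this cow's curve sits from the population mean curve.
#'
#' With every sd set to 0 the realized coefficients equal the configured
#' means and the deviation summary is 0. Results are reproducible under
#' \code{set.seed()}.
#'
#' @param config a [milk_config()] object.
#' @return An object of class \code{milk_coefficients}: per-parity-class
#'   coefficient lists, the scenario/gestation effects (copied from the
#'   config, they are not stochastic), and \code{deviation}.
#' @export
draw_cow_coefficients <- function(config) {
  stopifnot(inherits(config, "milk_config"))
  coef_names <- c("a", "b", "k", "c")
  z_all <- numeric(0)
  realize <- function(means) {
    out <- list()
    for (nm in coef_names) {
      s <- config$sd[[nm]]
      if (s > 0) {
        z <- stats::rnorm(1L)
        z_all <<- c(z_all, z)
        out[[nm]] <- means[[nm]] + s * z
      } else {
        out[[nm]] <- means[[nm]]
      }
    }
    out
  }
  primi <- realize(config$primiparous)
  multi <- realize(config$multiparous)
  deviation <- if (length(z_all)) sqrt(mean(z_all^2)) else 0
  structure(
    list(primiparous = primi, multiparous = multi,
         scenario_effect = config$scenario_effect,
         gestation_effects = config$gestation_effects,
         gestation_breaks = config$gestation_breaks,
         deviation = deviation),
    class = "milk_coefficients")
}

#' Gestation stage of a pregnancy
#'
#' Maps days pregnant to one of six reproductive states: 0 (non-pregnant,
#' only for 0 days pregnant) or stages 1-5 given by the configured bin edges.
#' Days beyond the last edge clamp to stage 5 (upstream construction keeps
#' pregnancies within gestation length, so this only absorbs edge rounding).
#'
#' @param days_pregnant non-negative days since conception (vectorized).
#' @param config a [milk_config()] object, or anything carrying a
#'   \code{gestation_breaks} field (e.g. a \code{milk_coefficients} object).
#' @return integer vector of stage indices in 0:5.
#' @export
gestation_category <- function(days_pregnant, config) {
  breaks <- config$gestation_breaks
  check(all(days_pregnant >= 0), "days_pregnant must be >= 0")
  cat <- findInterval(days_pregnant, breaks)
  cat[cat > 5L] <- 5L
  as.integer(cat)
}

#' Predicted daily milk yield
#'
#' Evaluates the cow's Wilmink curve for the given parity class at the given
#' days in milk, adds the scenario effect when \code{scenario = "high"} and
#' the gestation-stage effect for \code{gest_cat > 0}, and floors the result
#' at 0 (a curve cannot produce negative milk). Vectorized over \code{dim}
#' and \code{gest_cat}.
#'
#' @param coeffs a \code{milk_coefficients} object from
#'   [draw_cow_coefficients()].
#' @param scenario \code{"control"} or \code{"high"}.
#' @param parity_class \code{"primiparous"} or \code{"multiparous"}.
#' @param dim days in milk (>= 1).
#' @param gest_cat gestation stage in 0:5 (0 = non-pregnant).
#' @return daily yield in liters/day.
#' @export
daily_yield <- function(coeffs, scenario = c("control", "high"),
                        parity_class = c("primiparous", "multiparous"),
                        dim, gest_cat = 0L) {
  scenario <- match.arg(scenario)
  parity_class <- match.arg(parity_class)
  check(all(dim >= 1), "daily_yield: 'dim' must be >= 1")
  check(all(gest_cat %in% 0:5), "daily_yield: 'gest_cat' must be in 0:5")
  p <- coeffs[[parity_class]]
  y <- p$a + p$b * exp(-p$k * dim) + p$c * dim
  if (scenario == "high") y <- y + coeffs$scenario_effect
  ge <- c(0, coeffs$gestation_effects)[gest_cat + 1L]
  pmax(0, y + ge)
}

#' Cumulative milk over a lactation span
#'
#' Sums [daily_yield()] over each whole day in milk of the span. The
#' reproductive state of each day is derived from the conception day: days at
#' or before conception are non-pregnant; afterwards the stage follows the
#' configured gestation bins.
#'
#' @param coeffs a \code{milk_coefficients} object.
#' @inheritParams daily_yield
#' @param end last day in milk of the span (dry-off or exit day).
#' @param conception day in milk of conception, or \code{NA} if the cow did
#'   not conceive before \code{end}.
#' @param start first day in milk (default 1; day 0 is the calving day).
#' @return total liters over the span.
#' @export
lactation_milk <- function(coeffs, scenario, parity_class, end,
                           conception = NA_real_, start = 1) {
  check(is_number(end) && is_number(start), "lactation_milk: scalar span required")
  if (end < start) stop("lactation_milk: invalid span, end < start", call. = FALSE)
  days <- seq.int(start, end)
  dp <- if (is.na(conception)) rep(0, length(days)) else pmax(0, days - conception)
  gc <- gestation_category(dp, coeffs)
  sum(daily_yield(coeffs, scenario, parity_class, days, gc))
}
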