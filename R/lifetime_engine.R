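#' @name lifetime_engine
#' @title Paired cow-lifetime timelines
#' @description
#' A cow enters the simulation at first calving and is run simultaneously
#' through the two living-space scenarios with the same stochastic parameter
#' set. Each scenario timeline is a sequence of lactation spans: for every
#' parity before exit, the cow conceives at the scenario-specific conception
#' draw, calves again conception + gestation days later and dries off a
#' dry-period length before that calving; in the final parity she exits at a
#' pre-specified days in milk. When one scenario's cow exits earlier, she is
#' immediately replaced by a primiparous cow with the same milk-yield and
#' reproductive parameters, so both scenarios span the same calendar horizon
#' (the comparison is per cow place in the herd). Calendar granularity is
#' whole days; the calving day is day 0 of its lactation and the first
#' milking day is day in milk 1.
NULL

# integer-day timing quantities for a scenario, derived once from the draws
timeline_days <- function(draws, scenario) {
  conc_p <- round(draws$conception[[conception_cell(scenario, "primiparous")]])
  conc_m <- round(draws$conception[[conception_cell(scenario, "multiparous")]])
  gest <- round(draws$gestation)
  dry <- round(draws$dry)
  list(conc_p = conc_p, conc_m = conc_m, gest = gest, dry = dry,
       interval_p = conc_p + gest, interval_m = conc_m + gest,
       dryoff_p = conc_p + gest - dry, dryoff_m = conc_m + gest - dry)
}

new_timeline <- function(spans, scenario) {
  structure(
    list(spans = spans, scenario = scenario,
         total_span = max(spans$calving_day + spans$end),
         n_primiparous_calvings = sum(spans$parity == 1L),
         n_multiparous_calvings = sum(spans$parity >= 2L)),
    class = "scenario_timeline")
}

span_row <- function(parity, calving_day, conception, dry_off, end, replacement) {
  data.frame(parity = as.integer(parity), calving_day = calving_day,
             conception = conception, dry_off = dry_off, end = end,
             replacement = replacement)
}

#' Build one scenario's lifetime timeline
#'
#' Lays out the focal cow's lactation spans for one living-space scenario:
#' parities before exit run from calving to dry-off (dry-off = next calving
#' minus the dry-period length); the final parity ends at \code{exit_dim},
#' with its conception recorded only when the conception draw falls before
#' exit (it then affects yield through the gestation stage, but no further
#' calving occurs). The multiparous conception draw is reused for every
#' parity >= 2.
#'
#' @param draws a \code{repro_draws} object ([draw_reproduction()]).
#' @param scenario \code{"control"} or \code{"high"}.
#' @param exit_parity parity at herd exit, 1 to 10.
#' @param exit_dim days in milk at exit in the final parity.
#' @return An object of class \code{scenario_timeline}: a \code{spans} data
#'   frame (parity, calving_day, conception, dry_off, end, replacement),
#'   the total calendar span in days, and calving counts by parity class.
#' @export
build_timeline <- function(draws, scenario = c("control", "high"),
                           exit_parity, exit_dim) {
  scenario <- match.arg(scenario)
  check(is_number(exit_parity) && exit_parity %in% 1:10,
        "build_timeline: 'exit_parity' must be in 1..10")
  check(is_number(exit_dim) && exit_dim >= 1,
        "build_timeline: 'exit_dim' must be >= 1")
  td <- timeline_days(draws, scenario)
  spans <- vector("list", exit_parity)
  cal_day <- 0
  for (p in seq_len(exit_parity)) {
    primi <- p == 1L
    conc <- if (primi) td$conc_p else td$conc_m
    if (p < exit_parity) {
      interval <- conc + td$gest
      dry_off <- interval - td$dry
      if (dry_off <= conc)
        stop("build_timeline: dry-off at or before conception; ",
             "calving interval shorter than dry period + conception", call. = FALSE)
      spans[[p]] <- span_row(p, cal_day, conc, dry_off, dry_off, FALSE)
      cal_day <- cal_day + interval
    } else {
      conc_rec <- if (conc < exit_dim) conc else NA_real_
      spans[[p]] <- span_row(p, cal_day, conc_rec, NA_real_, exit_dim, FALSE)
    }
  }
  new_timeline(do.call(rbind, spans), scenario)
}

# replacement-heifer spans filling [from_day, target_day) in one scenario
replacement_spans <- function(draws, scenario, from_day, target_day) {
  td <- timeline_days(draws, scenario)
  spans <- list()
  D <- from_day
  parity <- 1L
  while (target_day - D >= 1) {
    primi <- parity == 1L
    conc <- if (primi) td$conc_p else td$conc_m
    interval <- conc + td$gest
    dry_off <- interval - td$dry
    remaining <- target_day - D
    end <- min(dry_off, remaining)
    conc_rec <- if (conc < end) conc else NA_real_
    dry_rec <- if (remaining >= dry_off) dry_off else NA_real_
    spans[[length(spans) + 1L]] <- span_row(parity, D, conc_rec, dry_rec, end, TRUE)
    D <- D + interval
    parity <- parity + 1L
  }
  if (length(spans)) do.call(rbind, spans) else NULL
}

#' Pair the two scenario timelines over a common horizon
#'
#' If the two scenarios exit at different calendar days, the earlier-exiting
#' scenario's cow place is filled by a replacement primiparous cow with the
#' same parameter set, whose lactations follow the usual rules (parity
#' restarting at 1) and whose last span is truncated at the later scenario's
#' exit day. After pairing both timelines cover the same total span.
#'
#' @param timeline_hs,timeline_cs \code{scenario_timeline} objects for the
#'   high-space and control-space scenario built from the same draws.
#' @param draws the shared \code{repro_draws} object.
#' @return list with elements \code{high} and \code{control}, the (possibly
#'   extended) timelines.
#' @export
pair_and_replace <- function(timeline_hs, timeline_cs, draws) {
  target <- max(timeline_hs$total_span, timeline_cs$total_span)
  extend <- function(tl) {
    if (tl$total_span >= target) return(tl)
    rep_spans <- replacement_spans(draws, tl$scenario, tl$total_span, target)
    spans <- if (is.null(rep_spans)) tl$spans else rbind(tl$spans, rep_spans)
    out <- new_timeline(spans, tl$scenario)
    out$total_span <- target  # horizon is shared even if the tail is dry
    out
  }
  list(high = extend(timeline_hs), control = extend(timeline_cs))
}

#' Lifetime milk production of a timeline
#'
#' Sums [lactation_milk()] over every span of the timeline, including
#' replacement-heifer spans; each span's parity class follows from its
#' parity number (primiparous iff parity 1).
#'
#' @param timeline a \code{scenario_timeline}.
#' @param coeffs a \code{milk_coefficients} object.
#' @return total liters over the timeline.
#' @export
lifetime_milk <- function(timeline, coeffs) {
  s <- timeline$spans
  total <- 0
  for (i in seq_len(nrow(s))) {
    cls <- if (s$parity[i] == 1L) "primiparous" else "multiparous"
    total <- total + lactation_milk(coeffs, timeline$scenario, cls,
                                    end = s$end[i], conception = s$conception[i])
  }
  total
}

#' Enumerate the paired-comparison design
#'
#' Every simulated cow is used in 50 paired comparisons: one for each exit
#' parity 1-10 crossed with each of her five candidate final-lactation exit
#' times, so exit parity is explored equally across the design.
#'
#' @param n_cows number of simulated cows (>= 1).
#' @return data frame with columns \code{cow}, \code{exit_parity},
#'   \code{exit_slot} and \code{n_cows * 50} rows.
#' @export
enumerate_design <- function(n_cows) {
  check(is_number(n_cows) && n_cows >= 1, "enumerate_design: 'n_cows' must be >= 1")
  n_cows <- as.integer(n_cows)
  data.frame(cow = rep(seq_len(n_cows), each = 50L),
             exit_parity = rep(rep(1:10, each = 5L), times = n_cows),
             exit_slot = rep(1:5, times = 10L * n_cows))
}
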