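#' Full simulation configuration
#'
#' Bundles the three module configurations. Each block can also be loaded
#' from a YAML or JSON file with [read_sim_config()].
#'
#' @param milk_model a [milk_config()].
#' @param reproduction a [repro_config()].
#' @param economics an [econ_config()].
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(milk_model = milk_config(),
                       reproduction = repro_config(),
                       economics = econ_config()) {
  stopifnot(inherits(milk_model, "milk_config"),
            inherits(reproduction, "repro_config"),
            inherits(economics, "econ_config"))
  structure(list(milk_model = milk_model, reproduction = reproduction,
                 economics = economics),
            class = "sim_config")
}

# per-cow, per-scenario lactation components used by the fast assembly:
# cumulative daily-yield curves for a primiparous and a multiparous
# lactation (conception status baked in) plus full-lactation totals.
scenario_components <- function(coeffs, draws, scenario) {
  td <- timeline_days(draws, scenario)
  curve <- function(parity_class, conc, upto) {
    days <- seq_len(upto)
    gc <- gestation_category(pmax(0, days - conc), coeffs)
    cumsum(daily_yield(coeffs, scenario, parity_class, days, gc))
  }
  max_dim <- max(305L, td$dryoff_p, td$dryoff_m)
  cumP <- curve("primiparous", td$conc_p, max_dim)
  cumM <- curve("multiparous", td$conc_m, max_dim)
  list(td = td, cumP = cumP, cumM = cumM,
       L1 = cumP[td$dryoff_p], Lm = cumM[td$dryoff_m])
}

# calving day (days since first calving) of each parity 1..10
calving_days <- function(td) {
  c(0, td$interval_p + (0:8) * td$interval_m)
}

# milk, calving counts of the replacement chain filling a gap of `gap` days
replacement_totals <- function(comp, gap) {
  milk <- 0
  np <- nm <- 0L
  t <- 0
  parity <- 1L
  while (gap - t >= 1) {
    if (parity == 1L) {
      np <- np + 1L
      milk <- milk + comp$cumP[min(comp$td$dryoff_p, gap - t)]
      t <- t + comp$td$interval_p
    } else {
      nm <- nm + 1L
      milk <- milk + comp$cumM[min(comp$td$dryoff_m, gap - t)]
      t <- t + comp$td$interval_m
    }
    parity <- parity + 1L
  }
  list(milk = milk, n_primiparous = np, n_multiparous = nm)
}

#' Run the paired living-space lifetime simulation
#'
#' Simulates \code{n_cows} cows, each run simultaneously through the control
#' (3 m2 living space) and high (6.5 m2) scenario with a shared stochastic
#' parameter set, and each used in 50 paired comparisons (exit parity 1-10
#' crossed with 5 candidate final-lactation exit times). Each comparison
#' yields the partial-budget financial-return difference together with every
#' stochastic input, ready for [fit_return_model()] and [run_finance()].
#'
#' Two related outcomes are recorded per comparison. \code{return_total} is
#' the per-cow-place difference over a shared calendar horizon: whichever
#' scenario's cow exits first is replaced by a heifer with the same
#' parameters and the replacement's milk and calvings count toward that
#' scenario (\code{return_per_year_place} divides this by the shared span).
#' \code{return_per_year}, the headline outcome used for the regression and
#' the net-return analysis, annualizes each scenario's focal-cow return over
#' that scenario's own lifetime before differencing, comparing production
#' rates rather than horizon totals; the two normalizations agree in sign in
#' almost all comparisons but weight the fertility penalty differently.
#'
#' Internally each cow's 50 comparisons are assembled from precomputed
#' lactation components; the assembly is exactly equivalent to building the
#' explicit [build_timeline()] / [pair_and_replace()] / [lifetime_milk()]
#' objects for every comparison (the test suite asserts the equivalence).
#'
#' @param n_cows number of simulated cows; the number of paired comparisons
#'   is \code{50 * n_cows}. The study-scale run uses 40,000 cows
#'   (2,000,000 comparisons); the default 2,000 (100,000 comparisons) is a
#'   desk-scale run with the same design proportions.
#' @param config a [sim_config()].
#' @param seed optional integer seed; with a seed the run is bit-reproducible.
#' @return An object of class \code{space_sim} with fields \code{records}
#'   (one row per paired comparison), \code{config}, \code{n_cows},
#'   \code{seed}.
#' @export
space_sim <- function(n_cows = 2000, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check(is_number(n_cows) && n_cows >= 1, "space_sim: 'n_cows' must be >= 1")
  n_cows <- as.integer(n_cows)
  if (!is.null(seed)) set.seed(seed)

  mcfg <- config$milk_model
  rcfg <- config$reproduction
  ecfg <- config$economics
  check(rcfg$n_exit_draws == 5L,
        "space_sim: the 50-comparison design requires 5 exit draws per cow")

  p_vec <- rep(1:10, each = 5L)
  s_vec <- rep(1:5, times = 10L)
  n_rec <- n_cows * 50L
  cols <- c("cow", "exit_parity", "exit_slot", "exit_dim", "span_days",
            "hs_exit_day", "cs_exit_day", "hs_milk", "cs_milk",
            "hs_focal_milk", "cs_focal_milk",
            "hs_transition", "cs_transition",
            "hs_replacement_calvings", "cs_replacement_calvings",
            "margin", "primiparous_cost", "multiparous_cost",
            "return_total", "return_per_year_place", "return_per_year",
            "conc_control_primiparous", "conc_high_primiparous",
            "conc_control_multiparous", "conc_high_multiparous",
            "gestation", "dry", "coef_deviation")
  rec <- matrix(NA_real_, nrow = n_rec, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (i in seq_len(n_cows)) {
    coeffs <- draw_cow_coefficients(mcfg)
    draws <- draw_reproduction(rcfg)
    margin <- pc <- mc <- numeric(50L)
    for (j in 1:50) {
      e <- draw_economics(ecfg)
      margin[j] <- e$margin
      pc[j] <- e$primiparous_cost
      mc[j] <- e$multiparous_cost
    }

    comp_hs <- scenario_components(coeffs, draws, "high")
    comp_cs <- scenario_components(coeffs, draws, "control")
    cal_hs <- calving_days(comp_hs$td)
    cal_cs <- calving_days(comp_cs$td)

    # replacement chain per exit parity on whichever scenario exits first;
    # the gap is independent of the exit DIM because both scenarios share it
    rep_milk_hs <- rep_milk_cs <- numeric(10L)
    rep_np_hs <- rep_nm_hs <- rep_np_cs <- rep_nm_cs <- numeric(10L)
    for (p in 1:10) {
      gap <- cal_hs[p] - cal_cs[p]
      if (gap < 0) {        # high space exits first, its place is refilled
        rt <- replacement_totals(comp_hs, -gap)
        rep_milk_hs[p] <- rt$milk
        rep_np_hs[p] <- rt$n_primiparous
        rep_nm_hs[p] <- rt$n_multiparous
      } else if (gap > 0) { # control space exits first
        rt <- replacement_totals(comp_cs, gap)
        rep_milk_cs[p] <- rt$milk
        rep_np_cs[p] <- rt$n_primiparous
        rep_nm_cs[p] <- rt$n_multiparous
      }
    }

    ed <- draws$exit_dims[s_vec]
    final_hs <- ifelse(p_vec == 1L, comp_hs$cumP[ed], comp_hs$cumM[ed])
    final_cs <- ifelse(p_vec == 1L, comp_cs$cumP[ed], comp_cs$cumM[ed])
    prior_hs <- ifelse(p_vec == 1L, 0,
                       comp_hs$L1 + (p_vec - 2) * comp_hs$Lm)
    prior_cs <- ifelse(p_vec == 1L, 0,
                       comp_cs$L1 + (p_vec - 2) * comp_cs$Lm)
    hs_milk <- prior_hs + final_hs + rep_milk_hs[p_vec]
    cs_milk <- prior_cs + final_cs + rep_milk_cs[p_vec]

    hs_trans <- pc * (1 + rep_np_hs[p_vec]) + mc * ((p_vec - 1) + rep_nm_hs[p_vec])
    cs_trans <- pc * (1 + rep_np_cs[p_vec]) + mc * ((p_vec - 1) + rep_nm_cs[p_vec])

    hs_exit <- cal_hs[p_vec] + ed
    cs_exit <- cal_cs[p_vec] + ed
    span <- pmax(hs_exit, cs_exit)
    total <- (hs_milk - cs_milk) * margin - (hs_trans - cs_trans)
    per_year_place <- total / (span / ecfg$days_per_year)
    # focal transition costs are identical across scenarios (same calvings)
    focal_trans <- pc + mc * (p_vec - 1)
    focal_hs <- prior_hs + final_hs
    focal_cs <- prior_cs + final_cs
    per_year <- annualized_return_difference(
      focal_hs * margin - focal_trans, focal_cs * margin - focal_trans,
      hs_exit, cs_exit, ecfg$days_per_year)

    idx <- ((i - 1L) * 50L + 1L):(i * 50L)
    rec[idx, ] <- cbind(
      i, p_vec, s_vec, ed, span, hs_exit, cs_exit, hs_milk, cs_milk,
      focal_hs, focal_cs, hs_trans, cs_trans,
      rep_np_hs[p_vec] + rep_nm_hs[p_vec], rep_np_cs[p_vec] + rep_nm_cs[p_vec],
      margin, pc, mc, total, per_year_place, per_year,
      draws$conception[["control_primiparous"]],
      draws$conception[["high_primiparous"]],
      draws$conception[["control_multiparous"]],
      draws$conception[["high_multiparous"]],
      draws$gestation, draws$dry, coeffs$deviation)
  }

  records <- as.data.frame(rec)
  records$cow <- as.integer(records$cow)
  records$exit_parity <- as.integer(records$exit_parity)
  records$exit_slot <- as.integer(records$exit_slot)
  structure(list(records = records, config = config, n_cows = n_cows,
                 seed = seed),
            class = "space_sim")
}

#' One paired comparison through the explicit timeline objects
#'
#' Reference path for a single comparison: builds both scenario timelines,
#' applies the replacement rule, sums lifetime milk and applies the partial
#' budget. Used to verify the fast assembly in [space_sim()] and available
#' for inspecting individual comparisons.
#'
#' @param coeffs a \code{milk_coefficients}.
#' @param draws a \code{repro_draws}.
#' @param econ an \code{econ_draws}.
#' @param exit_parity,exit_dim herd-exit specification.
#' @param days_per_year annualization divisor.
#' @return list with the paired timelines, milk totals, transition totals,
#'   and the financial-return difference (\code{total}, \code{per_year}).
#' @export
simulate_comparison <- function(coeffs, draws, econ, exit_parity, exit_dim,
                                days_per_year = 365.25) {
  t_hs <- build_timeline(draws, "high", exit_parity, exit_dim)
  t_cs <- build_timeline(draws, "control", exit_parity, exit_dim)
  hs_focal_milk <- lifetime_milk(t_hs, coeffs)
  cs_focal_milk <- lifetime_milk(t_cs, coeffs)
  focal_trans <- transition_total(t_hs, econ)  # identical calvings both ways
  per_year <- annualized_return_difference(
    hs_focal_milk * econ$margin - focal_trans,
    cs_focal_milk * econ$margin - focal_trans,
    t_hs$total_span, t_cs$total_span, days_per_year)
  pair <- pair_and_replace(t_hs, t_cs, draws)
  hs_milk <- lifetime_milk(pair$high, coeffs)
  cs_milk <- lifetime_milk(pair$control, coeffs)
  hs_tr <- transition_total(pair$high, econ)
  cs_tr <- transition_total(pair$control, econ)
  span <- pair$high$total_span
  fr <- financial_return_difference(hs_milk, cs_milk, hs_tr, cs_tr,
                                    econ$margin, span, days_per_year)
  list(high = pair$high, control = pair$control,
       hs_milk = hs_milk, cs_milk = cs_milk,
       hs_focal_milk = hs_focal_milk, cs_focal_milk = cs_focal_milk,
       hs_transition = hs_tr, cs_transition = cs_tr,
       span_days = span, total = fr$total,
       per_year_place = fr$per_year, per_year = per_year)
}

#' @export
print.space_sim <- function(x, ...) {
  cat(sprintf("Living-space paired lifetime simulation: %d cows, %d comparisons\n",
              x$n_cows, nrow(x$records)))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  ret <- x$records$return_per_year
  cat(sprintf("  financial-return difference (GBP/cow/year): median %.2f, IQR %.2f-%.2f\n",
              stats::median(ret), stats::quantile(ret, 0.25), stats::quantile(ret, 0.75)))
  cat(sprintf("  share of comparisons favouring high space: %.2f%%\n",
              100 * mean(ret > 0)))
  invisible(x)
}

#' Summarize the financial-return distribution
#'
#' @param object a \code{space_sim}.
#' @param ... unused.
#' @return An object of class \code{summary.space_sim}: overall and
#'   exit-parity-wise medians/IQRs, the exit parity 2-4 pooled summary, and
#'   the share of comparisons with a positive difference.
#' @export
summary.space_sim <- function(object, ...) {
  r <- object$records
  ret <- r$return_per_year
  qs <- function(x) {
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    c(n = length(x), p10 = q[1], q25 = q[2], median = q[3], q75 = q[4],
      p90 = q[5], positive_share = mean(x > 0))
  }
  out <- list(
    n_cows = object$n_cows,
    n_comparisons = nrow(r),
    overall = qs(ret),
    by_exit = summarize_by_exit(r),
    exit_2_4 = qs(ret[r$exit_parity %in% 2:4]))
  class(out) <- "summary.space_sim"
  out
}

#' @export
print.summary.space_sim <- function(x, ...) {
  cat(sprintf("Paired living-space simulation: %d cows, %d comparisons\n",
              x$n_cows, x$n_comparisons))
  cat(sprintf("Overall difference (GBP/cow/year): median %.2f, IQR %.2f-%.2f, %.2f%% positive\n",
              x$overall["median"], x$overall["q25"], x$overall["q75"],
              100 * x$overall["positive_share"]))
  cat(sprintf("Exit within lactations 2-4: median %.2f, IQR %.2f-%.2f, %.2f%% positive\n\n",
              x$exit_2_4["median"], x$exit_2_4["q25"], x$exit_2_4["q75"],
              100 * x$exit_2_4["positive_share"]))
  cat("By exit parity:\n")
  print(format(x$by_exit, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Distribution of the return difference by exit parity
#'
#' Boxplot-ready summary of the per-cow-per-year financial-return difference
#' for each exit parity 1-10 plus the pooled exit-2-4 group.
#'
#' @param records a \code{space_sim} object or its records data frame.
#' @return data frame with one row per group and columns \code{exit},
#'   \code{n}, \code{p10}, \code{q25}, \code{median}, \code{q75},
#'   \code{p90}, \code{positive_share}.
#' @export
summarize_by_exit <- function(records) {
  if (inherits(records, "space_sim")) records <- records$records
  check(is.data.frame(records) && nrow(records) > 0,
        "summarize_by_exit: 'records' must be a non-empty data frame")
  one <- function(x, label) {
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    data.frame(exit = label, n = length(x), p10 = q[1], q25 = q[2],
               median = q[3], q75 = q[4], p90 = q[5],
               positive_share = mean(x > 0))
  }
  groups <- lapply(sort(unique(records$exit_parity)), function(p)
    one(records$return_per_year[records$exit_parity == p], as.character(p)))
  pooled <- records$return_per_year[records$exit_parity %in% 2:4]
  if (length(pooled)) groups <- c(groups, list(one(pooled, "2-4")))
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.space_sim <- function(x, ...) x$records

#' Boxplots of the return difference by exit parity
#'
#' @param x a \code{space_sim}.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.space_sim <- function(x, ...) {
  graphics::boxplot(return_per_year ~ exit_parity, data = x$records,
                    xlab = "Exit parity",
                    ylab = "Financial-return difference (GBP/cow/year)",
                    main = "High vs control living space", ...)
  graphics::abline(h = 0, col = "red", lty = 2)
  invisible(x)
}

#' Run the infrastructure-finance analysis against a simulation
#'
#' Takes either a \code{space_sim} (the financial-return sample is then the
#' per-cow-per-year differences of comparisons exiting within lactations
#' 2-4, the subset relevant to typical herd-exit ages) or an explicit
#' numeric sample, and produces the interest-rate/term sensitivity table.
#'
#' @param sample a \code{space_sim}, a records data frame, or a numeric
#'   vector of financial-return differences (GBP/cow/year).
#' @inheritParams sensitivity_table
#' @return a [sensitivity_table()] data frame.
#' @export
run_finance <- function(sample, options = space_options(),
                        rates = c(0, 3.74, 4, 5.3, 8), terms_years = 20,
                        model = "equal_principal") {
  if (inherits(sample, "space_sim")) sample <- sample$records
  if (is.data.frame(sample))
    sample <- sample$return_per_year[sample$exit_parity %in% 2:4]
  if (is.null(sample) || length(sample) == 0L)
    stop("run_finance: no financial-return sample supplied", call. = FALSE)
  sensitivity_table(sample, options = options, rates = rates,
                    terms_years = terms_years, model = model)
}

#' Persist a simulation run
#'
#' Writes the full records as CSV and the distribution summary (overall, by
#' exit parity, exit-2-4 pooled) as JSON.
#'
#' @param sim a \code{space_sim}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "space_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  records_path <- file.path(dir, "simulation_records.csv")
  summary_path <- file.path(dir, "simulation_summary.json")
  utils::write.csv(sim$records, records_path, row.names = FALSE)
  s <- summary(sim)
  jsonlite::write_json(
    list(n_cows = s$n_cows, n_comparisons = s$n_comparisons,
         overall = as.list(s$overall), exit_2_4 = as.list(s$exit_2_4),
         by_exit = s$by_exit),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(records = records_path, summary = summary_path))
}
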