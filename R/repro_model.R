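#' Reproduction and timing configuration
#'
#' Holds the sampling distributions for all reproductive and timing draws:
#' time to conception (days after calving) for each of the four living-space
#' scenario by parity-class cells, gestation length, dry-period length, and
#' the days in milk at which the final lactation ends. Defaults are the study
#' conditions: conception Normal(82, 10) for control-space primiparous,
#' Normal(155, 25) high-space primiparous, Normal(108, 15) control-space
#' multiparous and Normal(133, 25) high-space multiparous; gestation
#' U(275, 285) days; dry period U(42, 60) days; exit U(1, 305) days in milk
#' with five candidate exit times per cow.
#'
#' @param conception named list of four \code{c(mean, sd)} pairs:
#'   \code{control_primiparous}, \code{high_primiparous},
#'   \code{control_multiparous}, \code{high_multiparous} (days).
#' @param gestation_bounds,dry_bounds,exit_bounds uniform bounds in days.
#' @param conception_floor truncation floor for conception draws (days):
#'   normal draws below it are rejected and redrawn. 21 days is the earliest
#'   biologically plausible post-calving conception.
#' @param n_exit_draws number of candidate final-lactation exit times per cow.
#' @return An object of class \code{repro_config}.
#' @export
repro_config <- function(conception = list(control_primiparous = c(82, 10),
                                           high_primiparous = c(155, 25),
                                           control_multiparous = c(108, 15),
                                           high_multiparous = c(133, 25)),
                         gestation_bounds = c(275, 285),
                         dry_bounds = c(42, 60),
                         exit_bounds = c(1, 305),
                         conception_floor = 21,
                         n_exit_draws = 5L) {
  cells <- c("control_primiparous", "high_primiparous",
             "control_multiparous", "high_multiparous")
  check(is.list(conception) && all(cells %in% names(conception)),
        "repro_config: 'conception' must name the four scenario x parity cells")
  for (cell in cells) {
    p <- conception[[cell]]
    check(is.numeric(p) && length(p) == 2L && all(is.finite(p)),
          "repro_config: conception$%s must be c(mean, sd)", cell)
    check(p[2] >= 0, "repro_config: conception$%s sd must be >= 0", cell)
  }
  check_bounds(gestation_bounds, "gestation_bounds", min_allowed = 1)
  check_bounds(dry_bounds, "dry_bounds", min_allowed = 1)
  check_bounds(exit_bounds, "exit_bounds", min_allowed = 1)
  check(is_number(conception_floor) && conception_floor >= 1,
        "repro_config: 'conception_floor' must be >= 1")
  check(is_number(n_exit_draws) && n_exit_draws >= 1,
        "repro_config: 'n_exit_draws' must be >= 1")
  structure(
    list(conception = lapply(conception[cells], as.numeric),
         gestation_bounds = as.numeric(gestation_bounds),
         dry_bounds = as.numeric(dry_bounds),
         exit_bounds = as.numeric(exit_bounds),
         conception_floor = as.numeric(conception_floor),
         n_exit_draws = as.integer(n_exit_draws)),
    class = "repro_config")
}

#' First value at or above a floor from a redraw stream
#'
#' Returns the initial value if it is already at or above the floor;
#' otherwise keeps calling \code{redraw()} until a value >= floor appears.
#' More than 10,000 consecutive rejections is treated as a configuration
#' error (the distribution puts essentially all its mass below the floor).
#'
#' @param value initial draw (days).
#' @param floor truncation floor (days, >= 1).
#' @param redraw zero-argument function returning the next draw.
#' @return the first accepted value.
#' @export
truncate_positive <- function(value, floor, redraw) {
  check(is_number(floor) && floor >= 1, "truncate_positive: 'floor' must be >= 1")
  tries <- 0L
  while (value < floor) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("truncate_positive: >10,000 rejections; distribution mass below the floor is too large",
           call. = FALSE)
    value <- redraw()
  }
  value
}

# Vectorized truncated-normal sampler used for the conception cells;
# rejection sampling against the floor (negligible rejection mass under the
# default parameters).
rnorm_trunc <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("rnorm_trunc: >10,000 rejection rounds; check mean/sd against the floor",
           call. = FALSE)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Draw one cow's reproductive and timing parameters
#'
#' One truncated-normal time-to-conception draw per scenario x parity-class
#' cell (the multiparous value is reused for every parity >= 2), one
#' gestation-length and one dry-period uniform draw shared across the whole
#' cow lifetime and both scenarios, and \code{n_exit_draws} candidate
#' final-lactation exit times (uniform, rounded to whole days in milk, at
#' least 1).
#'
#' @param config a [repro_config()] object.
#' @return An object of class \code{repro_draws} with fields
#'   \code{conception} (named numeric vector of four cells, days),
#'   \code{gestation}, \code{dry} (days) and \code{exit_dims}
#'   (integer days in milk).
#' @export
draw_reproduction <- function(config) {
  stopifnot(inherits(config, "repro_config"))
  conc <- vapply(config$conception, function(p) {
    if (p[2] == 0) {
      # degenerate draw; still subject to the floor
      check(p[1] >= config$conception_floor,
            "draw_reproduction: degenerate conception mean below the truncation floor")
      p[1]
    } else {
      rnorm_trunc(1L, p[1], p[2], config$conception_floor)
    }
  }, numeric(1))
  gestation <- stats::runif(1L, config$gestation_bounds[1], config$gestation_bounds[2])
  dry <- stats::runif(1L, config$dry_bounds[1], config$dry_bounds[2])
  exit_dims <- pmax(1L, as.integer(round(
    stats::runif(config$n_exit_draws, config$exit_bounds[1], config$exit_bounds[2]))))
  structure(
    list(conception = conc, gestation = gestation, dry = dry,
         exit_dims = exit_dims),
    class = "repro_draws")
}

# conception cell name for a scenario / parity-class pair
conception_cell <- function(scenario, parity_class) {
  paste(scenario, parity_class, sep = "_")
}
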