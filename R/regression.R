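#' Center and standardize a predictor
#'
#' Subtracts the mean and divides by the sample (n - 1) standard deviation,
#' storing both as attributes so estimates can be mapped back to the
#' original scale.
#'
#' @param values numeric vector.
#' @param name predictor name used in error messages.
#' @return z-scored vector with attributes \code{center} and \code{scale}.
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  check(is.numeric(values) && length(values) >= 2L,
        "standardize: '%s' must be a numeric vector of length >= 2", name)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop(sprintf("standardize: predictor '%s' is constant; cannot standardize", name),
         call. = FALSE)
  m <- mean(values)
  structure((values - m) / s, center = m, scale = s)
}

# continuous covariates entering the outcome regression, in presentation order
.return_model_terms <- c(
  coef_deviation = "Milk curve coefficient deviation (RMS z)",
  margin = "Milk margin (GBP/liter)",
  primiparous_cost = "Cost primiparous dry/transition period (GBP)",
  multiparous_cost = "Cost multiparous dry/transition period (GBP)",
  conc_high_primiparous = "Primiparous high space days to conception",
  conc_control_primiparous = "Primiparous control space days to conception",
  conc_high_multiparous = "Multiparous high space days to conception",
  conc_control_multiparous = "Multiparous control space days to conception",
  dry = "Dry period duration (days)",
  gestation = "Gestation duration (days)",
  exit_dim = "Final lactation duration (days)")

#' Regress the financial-return difference on the simulation inputs
#'
#' Ordinary least squares of the per-cow-per-year financial-return difference
#' on the simulation's stochastic inputs: exit parity as a dummy-coded
#' categorical predictor (reference level 3, not standardized) and the
#' continuous inputs (milk-curve coefficient deviation, margin, the two
#' transition costs, the four scenario-by-parity-class conception times, dry
#' and gestation duration, final-lactation duration), each centered and
#' standardized so estimates are comparable per one-standard-deviation
#' change. Lifetime days is deliberately excluded: it is near-collinear with
#' exit parity. Standard-theory two-sided confidence intervals and p-values
#' are reported with no multiplicity correction.
#'
#' @param records a \code{space_sim} object or its records data frame.
#' @param response column to regress (default \code{"return_per_year"}).
#' @param ref_parity reference exit parity (default 3).
#' @return An object of class \code{return_model}: the underlying \code{lm}
#'   fit, a coefficient table with 95\% CIs and p-values, R-squared, n, and
#'   the standardization constants per continuous predictor.
#' @export
fit_return_model <- function(records, response = "return_per_year",
                             ref_parity = 3) {
  if (inherits(records, "space_sim")) records <- records$records
  check(is.data.frame(records), "fit_return_model: 'records' must be a data frame")
  terms <- names(.return_model_terms)
  missing_cols <- setdiff(c(response, "exit_parity", terms), names(records))
  check(length(missing_cols) == 0,
        "fit_return_model: missing columns: %s", paste(missing_cols, collapse = ", "))
  parities <- sort(unique(records$exit_parity))
  check(length(parities) >= 2L, "fit_return_model: need >= 2 exit-parity levels")
  check(ref_parity %in% parities, "fit_return_model: reference parity absent from data")

  d <- data.frame(.y = records[[response]])
  d$exit_parity <- stats::relevel(factor(records$exit_parity, levels = parities),
                                  ref = as.character(ref_parity))
  scaling <- list()
  for (tm in terms) {
    z <- standardize(records[[tm]], name = tm)
    scaling[[tm]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    d[[tm]] <- as.numeric(z)
  }
  check(nrow(d) > length(terms) + length(parities),
        "fit_return_model: n must exceed the number of model terms")

  fml <- stats::as.formula(paste(".y ~ exit_parity +", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("fit_return_model: rank-deficient design; aliased terms: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  tab <- data.frame(term = rownames(sm$coefficients),
                    estimate = sm$coefficients[, "Estimate"],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p_value = sm$coefficients[, "Pr(>|t|)"],
                    row.names = NULL)
  structure(
    list(fit = fit, coefficients = tab, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, n = nrow(d),
         ref_parity = ref_parity, scaling = scaling, response = response),
    class = "return_model")
}

#' Forest-plot data for a fitted return model
#'
#' Plot-ready coefficient records in presentation order: the exit-parity
#' contrasts first (grouped, in parity order, reference level omitted), then
#' the standardized continuous terms; the reference line sits at 0.
#'
#' @param result a [fit_return_model()] object.
#' @return data frame with columns \code{term}, \code{label}, \code{group},
#'   \code{estimate}, \code{ci_low}, \code{ci_high}, \code{p_value}.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "return_model"))
  tab <- result$coefficients
  tab <- tab[tab$term != "(Intercept)", ]
  is_par <- grepl("^exit_parity", tab$term)
  par_tab <- tab[is_par, ]
  par_lev <- as.integer(sub("^exit_parity", "", par_tab$term))
  par_tab <- par_tab[order(par_lev), ]
  par_tab$label <- paste("Exit parity", sort(par_lev),
                         sprintf("(vs %d)", result$ref_parity))
  par_tab$group <- "Exit parity"
  cont <- tab[!is_par, ]
  cont <- cont[match(names(.return_model_terms), cont$term), ]
  cont$label <- unname(.return_model_terms[cont$term])
  cont$group <- "Continuous (per 1 SD)"
  out <- rbind(par_tab, cont)
  rownames(out) <- NULL
  out[, c("term", "label", "group", "estimate", "ci_low", "ci_high", "p_value")]
}

#' @export
print.return_model <- function(x, digits = 4, ...) {
  cat(sprintf("Standardized OLS of %s (n = %d, R2 = %.3f, ref parity = %d)\n\n",
              x$response, x$n, x$r_squared, x$ref_parity))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, digits)
  tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits)
  tab$p_value <- format.pval(tab$p_value, digits = 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.return_model <- function(object, ...) summary(object$fit, ...)

#' @export
coef.return_model <- function(object, ...) stats::coef(object$fit)

#' @export
confint.return_model <- function(object, ...) stats::confint(object$fit, ...)

#' @export
residuals.return_model <- function(object, ...) stats::residuals(object$fit, ...)

#' Forest plot of standardized effects
#'
#' @param x a \code{return_model}.
#' @param ... further arguments passed to plotting functions.
#' @export
plot.return_model <- function(x, ...) {
  fd <- forest_data(x)
  n <- nrow(fd)
  ylim <- c(0.5, n + 0.5)
  xlim <- range(c(0, fd$ci_low, fd$ci_high))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "Estimate (GBP/cow/year)", ylab = "",
                 main = "Standardized effects on financial-return difference", ...)
  ypos <- rev(seq_len(n))
  graphics::abline(v = 0, col = "red")
  graphics::segments(fd$ci_low, ypos, fd$ci_high, ypos)
  graphics::points(fd$estimate, ypos, pch = 15)
  graphics::axis(2, at = ypos, labels = fd$label, las = 1, cex.axis = 0.6)
  invisible(x)
}
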