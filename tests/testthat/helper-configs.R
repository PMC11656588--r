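# fixture configurations built in code

# milk model with no per-cow noise; other fields overridable
noiseless_milk <- function(...) {
  milk_config(sd = list(a = 0, b = 0, k = 0, c = 0), ...)
}

# a single Wilmink curve with no scenario/gestation effects, both parity
# classes identical; handy for closed-form checks
bare_curve <- function(a, b, k, c) {
  noiseless_milk(primiparous = list(a = a, b = b, k = k, c = c),
                 multiparous = list(a = a, b = b, k = k, c = c),
                 scenario_effect = 0,
                 gestation_effects = c(0, 0, 0, 0, 0))
}

# fully degenerate reproduction: all draws are point masses
degenerate_repro <- function(conc_cp = 82, conc_hp = 155,
                             conc_cm = 108, conc_hm = 133,
                             gestation = 280, dry = 50) {
  repro_config(conception = list(control_primiparous = c(conc_cp, 0),
                                 high_primiparous = c(conc_hp, 0),
                                 control_multiparous = c(conc_cm, 0),
                                 high_multiparous = c(conc_hm, 0)),
               gestation_bounds = c(gestation, gestation),
               dry_bounds = c(dry, dry))
}

degenerate_econ <- function(margin = 0.2049, primi = 64.86, multi = 99.08) {
  econ_config(margin_bounds = c(margin, margin),
              primiparous_cost_bounds = c(primi, primi),
              multiparous_cost_bounds = c(multi, multi))
}

# independently coded daily-yield arithmetic for brute-force oracles:
# Wilmink value + high-space effect + gestation-stage effect, floored at 0,
# with 56-day gestation stages
oracle_daily <- function(a, b, k, c, t, high, scen_eff, gest_eff, days_pregnant) {
  y <- a + b * exp(-k * t) + c * t
  if (high) y <- y + scen_eff
  if (days_pregnant >= 1) {
    stage <- min(5, 1 + (ceiling(days_pregnant) - 1) %/% 56)
    y <- y + gest_eff[stage]
  }
  max(0, y)
}

# records-shaped data frame with known predictor structure; callers add the
# response
synth_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    exit_parity = sample(1:10, n, replace = TRUE),
    coef_deviation = abs(rnorm(n, 1, 0.3)),
    margin = runif(n, 0.17, 0.23),
    primiparous_cost = runif(n, 32.43, 129.72),
    multiparous_cost = runif(n, 49.54, 198.16),
    conc_high_primiparous = rnorm(n, 155, 25),
    conc_control_primiparous = rnorm(n, 82, 10),
    conc_high_multiparous = rnorm(n, 133, 25),
    conc_control_multiparous = rnorm(n, 108, 15),
    dry = runif(n, 42, 60),
    gestation = runif(n, 275, 285),
    exit_dim = sample(1:305, n, replace = TRUE))
}
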