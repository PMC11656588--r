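test_that("a seeded run is bit-reproducible", {
  a <- space_sim(10, seed = 5)
  b <- space_sim(10, seed = 5)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 500L)
  expect_equal(as.integer(table(a$records$exit_parity)), rep(50L, 10))
})

test_that("the fast assembly matches the explicit timeline path", {
  cfg <- sim_config()
  seed <- 314
  sim <- space_sim(3, cfg, seed = seed)
  # replay the per-cow draw order and recompute every comparison through
  # build_timeline / pair_and_replace / lifetime_milk
  set.seed(seed)
  for (i in 1:3) {
    coeffs <- draw_cow_coefficients(cfg$milk_model)
    draws <- draw_reproduction(cfg$reproduction)
    econ <- lapply(1:50, function(j) draw_economics(cfg$economics))
    for (j in 1:50) {
      r <- sim$records[(i - 1) * 50 + j, ]
      x <- simulate_comparison(coeffs, draws, econ[[j]],
                               r$exit_parity, r$exit_dim)
      expect_equal(r$hs_milk, x$hs_milk, tolerance = 1e-10)
      expect_equal(r$cs_milk, x$cs_milk, tolerance = 1e-10)
      expect_equal(r$hs_focal_milk, x$hs_focal_milk, tolerance = 1e-10)
      expect_equal(r$hs_transition, x$hs_transition, tolerance = 1e-10)
      expect_equal(r$cs_transition, x$cs_transition, tolerance = 1e-10)
      expect_equal(r$span_days, x$span_days)
      expect_equal(r$return_total, x$total, tolerance = 1e-10)
      expect_equal(r$return_per_year_place, x$per_year_place, tolerance = 1e-10)
      expect_equal(r$return_per_year, x$per_year, tolerance = 1e-10)
    }
  }
})

test_that("records satisfy their accounting identities", {
  sim <- space_sim(30, seed = 8)
  r <- sim$records
  expect_equal(r$return_per_year_place * r$span_days / 365.25, r$return_total,
               tolerance = 1e-9)
  expect_equal(r$span_days, pmax(r$hs_exit_day, r$cs_exit_day))
  expect_true(all(r$hs_milk >= r$hs_focal_milk - 1e-9))
  expect_true(all(r$cs_milk >= r$cs_focal_milk - 1e-9))
  # replacement occurs only in the scenario that exits first
  gap <- r$hs_exit_day - r$cs_exit_day
  expect_true(all(r$cs_replacement_calvings[gap <= 0] == 0))
  expect_true(all(r$hs_replacement_calvings[gap >= 0] == 0))
  # exit DIMs are shared across parities within a cow and slot
  one <- r[r$cow == 1, ]
  expect_equal(as.numeric(tapply(one$exit_dim, one$exit_slot, sd)), rep(0, 5))
})

test_that("scenario effect propagates linearly through lifetime milk", {
  # identical timelines (degenerate equal conception), no noise: the paired
  # milk difference is the scenario effect times the number of milking days
  cfg <- sim_config(
    milk_model = noiseless_milk(),
    reproduction = degenerate_repro(conc_cp = 100, conc_hp = 100,
                                    conc_cm = 120, conc_hm = 120))
  sim <- space_sim(2, cfg, seed = 30)
  r <- sim$records
  milking_days <- ifelse(r$exit_parity == 1, r$exit_dim,
                         330 + (r$exit_parity - 2) * 350 + r$exit_dim)
  expect_equal(r$hs_milk - r$cs_milk,
               cfg$milk_model$scenario_effect * milking_days,
               tolerance = 1e-9)
})

test_that("without a space effect the paired difference vanishes exactly", {
  cfg <- sim_config(
    milk_model = milk_config(scenario_effect = 0),
    reproduction = degenerate_repro(conc_cp = 100, conc_hp = 100,
                                    conc_cm = 100, conc_hm = 100))
  sim <- space_sim(20, cfg, seed = 99)
  expect_true(all(sim$records$return_total == 0))
  expect_true(all(sim$records$return_per_year == 0))
  expect_true(all(sim$records$return_per_year_place == 0))
})

test_that("summaries aggregate by exit parity and pool lactations 2-4", {
  single <- data.frame(exit_parity = 3L, return_per_year = 42)
  s1 <- summarize_by_exit(single)
  expect_equal(s1$median[s1$exit == "3"], 42)
  expect_equal(s1$median[s1$exit == "2-4"], 42)

  five <- data.frame(exit_parity = c(2L, 2L, 3L, 4L, 7L),
                     return_per_year = c(10, 20, 30, 40, -5))
  s5 <- summarize_by_exit(five)
  expect_equal(s5$median[s5$exit == "2"], 15)
  expect_equal(s5$n[s5$exit == "2-4"], 4L)
  expect_equal(s5$median[s5$exit == "2-4"], 25)
  expect_equal(s5$positive_share[s5$exit == "7"], 0)

  sim <- space_sim(10, seed = 2)
  s <- summary(sim)
  expect_equal(s$exit_2_4[["n"]], sum(sim$records$exit_parity %in% 2:4))
  expect_output(print(s), "Overall difference")
  expect_error(summarize_by_exit(data.frame()), "non-empty")
})

test_that("configuration files load, validate and round-trip", {
  path <- system.file("extdata", "default_config.yaml", package = "cowspace")
  expect_true(nzchar(path))
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$milk_model, milk_config())
  expect_identical(cfg$reproduction, repro_config())
  expect_identical(cfg$economics, econ_config())

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("reproduction:", "  dry_bounds: [42, 60]", "  typo_field: 3"), bad)
  expect_error(read_sim_config(bad), "reproduction.typo_field")
  top <- tempfile(fileext = ".yaml")
  writeLines("not_a_block:\n  x: 1", top)
  expect_error(read_sim_config(top), "not_a_block")

  jf <- tempfile(fileext = ".json")
  writeLines('{"economics": {"margin_bounds": [0.2, 0.21]}}', jf)
  cfg2 <- read_sim_config(jf)
  expect_equal(cfg2$economics$margin_bounds, c(0.2, 0.21))
  expect_error(read_sim_config(tempfile(fileext = ".txt")), "not found")
})

test_that("simulation outputs persist as CSV and JSON", {
  sim <- space_sim(4, seed = 77)
  dir <- file.path(tempdir(), "cowspace-out")
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["records"]])
  expect_equal(nrow(back), 200L)
  expect_equal(back$return_per_year, sim$records$return_per_year,
               tolerance = 1e-9)
  js <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  expect_equal(js$n_comparisons, 200L)
  unlink(dir, recursive = TRUE)
})

test_that("the finance runner extracts the exit-2-4 sample", {
  sim <- space_sim(10, seed = 3)
  st <- run_finance(sim, rates = 4)
  expect_equal(nrow(st), 3L)
  med <- median(sim$records$return_per_year[sim$records$exit_parity %in% 2:4])
  expect_lt(abs(st$median[st$option == "new_build"] + 64.61 - med), 0.011)
  expect_error(run_finance(numeric(0)), "no financial-return sample")
})

test_that("print and plot methods run cleanly", {
  sim <- space_sim(40, seed = 1)  # enough cows for a full-rank regression
  expect_output(print(sim), "paired lifetime simulation")
  fit <- fit_return_model(sim)
  expect_output(print(fit), "Standardized OLS")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(sim))
  expect_invisible(plot(fit))
})
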