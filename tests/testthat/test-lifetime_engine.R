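test_that("a single-lactation timeline ends at exit with no dry-off", {
  d <- draw_reproduction(degenerate_repro())
  tl <- build_timeline(d, "control", exit_parity = 1, exit_dim = 200)
  expect_equal(nrow(tl$spans), 1L)
  expect_equal(tl$spans$end, 200)
  expect_true(is.na(tl$spans$dry_off))
  expect_equal(tl$total_span, 200)
  expect_equal(tl$spans$conception, 82)  # conceives before exit at dim 200
  expect_equal(tl$n_primiparous_calvings, 1L)
  expect_equal(tl$n_multiparous_calvings, 0L)
})

test_that("timeline date arithmetic follows the draws", {
  # conception 100, gestation 280, dry 50, exit in parity 2 at dim 150
  d <- draw_reproduction(degenerate_repro(conc_cp = 100, conc_cm = 100))
  tl <- build_timeline(d, "control", exit_parity = 2, exit_dim = 150)
  expect_equal(tl$spans$calving_day, c(0, 380))
  expect_equal(tl$spans$dry_off[1], 330)
  expect_equal(tl$spans$end[1], 330)
  expect_equal(tl$total_span, 530)
})

test_that("the multiparous conception draw is reused beyond parity two", {
  d <- draw_reproduction(degenerate_repro())
  tl <- build_timeline(d, "high", exit_parity = 4, exit_dim = 100)
  expect_equal(tl$spans$conception[1], 155)
  expect_equal(tl$spans$conception[2:3], c(133, 133))
  # final-lactation conception marked only when it precedes exit
  expect_true(is.na(tl$spans$conception[4]))  # 133 >= exit dim 100
  tl2 <- build_timeline(d, "high", exit_parity = 4, exit_dim = 200)
  expect_equal(tl2$spans$conception[4], 133)
})

test_that("replacement fills the gap between scenario exits", {
  d <- draw_reproduction(degenerate_repro(conc_cp = 80, conc_hp = 280,
                                          conc_cm = 108, conc_hm = 108))
  t_hs <- build_timeline(d, "high", 2, 100)
  t_cs <- build_timeline(d, "control", 2, 100)
  expect_equal(t_hs$total_span, 560 + 100)
  expect_equal(t_cs$total_span, 360 + 100)
  pair <- pair_and_replace(t_hs, t_cs, d)
  expect_identical(pair$high, t_hs)   # longer timeline untouched
  expect_equal(pair$control$total_span, 660)
  rep_spans <- pair$control$spans[pair$control$spans$replacement, ]
  expect_equal(nrow(rep_spans), 1L)
  expect_equal(rep_spans$calving_day, 460)
  expect_equal(rep_spans$end, 200)        # truncated at the shared horizon
  expect_equal(rep_spans$conception, 80)  # replacement is primiparous
  expect_equal(pair$control$n_primiparous_calvings, 2L)

  # equal exits: nothing to do
  t1 <- build_timeline(d, "high", 1, 250)
  t2 <- build_timeline(d, "control", 1, 250)
  pair2 <- pair_and_replace(t1, t2, d)
  expect_identical(pair2$high, t1)
  expect_identical(pair2$control, t2)
})

test_that("long gaps chain multiple replacement lactations", {
  d <- draw_reproduction(degenerate_repro(conc_cp = 60, conc_hp = 160,
                                          conc_cm = 80, conc_hm = 160))
  t_hs <- build_timeline(d, "high", 6, 50)
  t_cs <- build_timeline(d, "control", 6, 50)
  gap <- t_hs$total_span - t_cs$total_span
  expect_gt(gap, 60 + 280)  # beyond the first replacement calving interval
  pair <- pair_and_replace(t_hs, t_cs, d)
  rep_spans <- pair$control$spans[pair$control$spans$replacement, ]
  expect_gte(nrow(rep_spans), 2L)
  expect_equal(rep_spans$parity, seq_len(nrow(rep_spans)))
  expect_equal(pair$control$total_span, pair$high$total_span)
  # second replacement calving is multiparous and its cost will be counted
  expect_equal(pair$control$n_multiparous_calvings,
               5L + (nrow(rep_spans) - 1L))
})

test_that("lifetime milk equals a brute-force day loop over the timeline", {
  cfg <- noiseless_milk()
  co <- draw_cow_coefficients(cfg)
  d <- draw_reproduction(degenerate_repro())
  tl <- build_timeline(d, "high", 3, 220)
  oracle <- 0
  for (i in seq_len(nrow(tl$spans))) {
    s <- tl$spans[i, ]
    p <- if (s$parity == 1) cfg$primiparous else cfg$multiparous
    for (t in seq_len(s$end)) {
      dp <- if (is.na(s$conception)) 0 else max(0, t - s$conception)
      oracle <- oracle + oracle_daily(p$a, p$b, p$k, p$c, t, high = TRUE,
                                      scen_eff = cfg$scenario_effect,
                                      gest_eff = cfg$gestation_effects,
                                      days_pregnant = dp)
    }
  }
  expect_equal(lifetime_milk(tl, co), oracle, tolerance = 1e-12)

  zero <- draw_cow_coefficients(bare_curve(0, 0, 0.05, 0))
  expect_equal(lifetime_milk(tl, zero), 0)
  flat <- draw_cow_coefficients(bare_curve(25, 0, 0.05, 0))
  expect_equal(lifetime_milk(tl, flat), 25 * sum(tl$spans$end))
})

test_that("paired timelines always share the same horizon", {
  cfg <- sim_config()
  set.seed(77)
  for (i in 1:25) {
    d <- draw_reproduction(cfg$reproduction)
    p <- sample(1:10, 1)
    ed <- sample(1:305, 1)
    pair <- pair_and_replace(build_timeline(d, "high", p, ed),
                             build_timeline(d, "control", p, ed), d)
    expect_equal(pair$high$total_span, pair$control$total_span)
    # focal calving count equals exit parity in both scenarios
    for (tl in pair) {
      focal <- tl$spans[!tl$spans$replacement, ]
      expect_equal(nrow(focal), p)
      expect_equal(focal$parity, seq_len(p))
    }
  }
})

test_that("the design enumerates every exit parity equally", {
  expect_equal(nrow(enumerate_design(1)), 50L)
  d <- enumerate_design(2)
  expect_equal(nrow(d), 100L)
  expect_equal(sum(d$exit_parity == 7), 10L)
  expect_equal(as.integer(table(d$exit_parity)), rep(10L, 10))
  d4 <- enumerate_design(40000)
  expect_equal(nrow(d4), 2000000L)
  expect_equal(sum(d4$exit_parity == 3), 200000L)
})
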