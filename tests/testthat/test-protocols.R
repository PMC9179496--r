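# Treatment controllers: measurement, response classification, the six
# protocols, vacations and clamping.

started_state <- function(last = 5000, maxb = 5000, dose = c(1, 1),
                          init = 5000, active = NA_integer_,
                          last_use = c(NA_real_, NA_real_), fd_on = FALSE) {
  st <- controller_state()
  st$treatment_started <- TRUE
  st$initiation_burden <- init
  st$last_measured <- last
  st$max_burden <- maxb
  st$last_dose <- dose
  st$active_drug <- active
  st$burden_at_last_use <- last_use
  st$fd_dosing_on <- fd_on
  st
}

test_that("burden measurement is unbiased, integer and non-negative", {
  expect_equal(measure_burden(4321, sd = 0), 4321)
  set.seed(31)
  lows <- replicate(2000, measure_burden(0, sd = 5))
  expect_true(all(lows >= 0))
  draws <- replicate(1e5, measure_burden(5000, sd = 5))
  expect_true(all(draws == round(draws)))
  expect_lt(abs(mean(draws) - 5000), 0.1)
})

test_that("response classification applies the Delta-Tumor thresholds asymmetrically", {
  expect_equal(classify_response(5000, 5600, 0.10), "GREW")    # +12% > 10%
  expect_equal(classify_response(5000, 4500, 0.10), "SHRANK")  # -10% meets 'at least'
  expect_equal(classify_response(5000, 5200, 0.10), "STABLE")
  expect_equal(classify_response(5000, 5500, 0.10), "STABLE")  # +10% is not 'above'
  expect_error(classify_response(0, 10, 0.1), "positive")
})

test_that("standard treatment doses the cocktail MTD forever once started", {
  cfg <- protocol_config("ST")
  expect_equal(decide_st(started_state(), cfg), c(3, 3))
  expect_equal(decide_st(controller_state(), cfg), c(0, 0))
})

test_that("DM Cocktail scales both doses by Delta Dose with min-dose flooring", {
  cfg <- protocol_config("DM_COCKTAIL")
  up <- decide_dm_cocktail(started_state(last = 5000, dose = c(1, 1)), 5600, cfg)
  expect_equal(up$decision, c(1.5, 1.5))
  down <- decide_dm_cocktail(started_state(last = 5000, maxb = 6000, dose = c(1, 1)),
                             4500, cfg)
  expect_equal(down$decision, c(0.5, 0.5))
  floor <- decide_dm_cocktail(started_state(last = 5000, maxb = 6000, dose = c(0.8, 0.8)),
                              4500, cfg)
  expect_equal(floor$decision, c(0.5, 0.5))  # not 0.4: kept at the minimum dose
  stable <- decide_dm_cocktail(started_state(last = 5000, maxb = 6000, dose = c(2, 2)),
                               5200, cfg)
  expect_equal(stable$decision, c(2, 2))
  # exceeding the running maximum counts as growth
  override <- decide_dm_cocktail(started_state(last = 5000, maxb = 5100, dose = c(2, 2)),
                                 5200, cfg)
  expect_equal(override$decision, c(3, 3))
})

test_that("DM Ping-Pong Alternate switches drugs every cycle and adjusts per drug", {
  cfg <- protocol_config("DM_PP_ALT", measurement_noise_sd = 0)
  # initiation starts drug 1 at the single-drug MTD, next cycle drug 2
  st <- controller_state()
  up <- controller_update(st, 5010, cfg)
  expect_equal(up$decision, c(5, 0))
  up2 <- controller_update(up$state, 5010, cfg)
  expect_equal(up2$decision, c(0, 5))
  # a drug resumes at its own last dose scaled by the response since its last use
  st <- started_state(last = 4800, maxb = 6000, dose = c(2, 2), active = 2L,
                      last_use = c(5000, 4800))
  grew <- decide_dm_pingpong_alternate(st, 5600, cfg)
  expect_equal(grew$decision, c(3, 0))
  st <- started_state(last = 5000, maxb = 6000, dose = c(2, 2), active = 1L,
                      last_use = c(4500, 5000))
  shr <- decide_dm_pingpong_alternate(st, 4000, cfg)
  expect_equal(shr$decision, c(0, 1))
  # only ever one non-zero dose
  expect_true(all(rowSums(rbind(grew$decision, shr$decision) > 0) == 1))
})

test_that("DM Ping-Pong on Progression stays while controlled and switches on growth", {
  cfg <- protocol_config("DM_PP_PROG", measurement_noise_sd = 0)
  st <- started_state(last = 5000, maxb = 6000, dose = c(2, 2), active = 1L)
  shr <- decide_dm_pingpong_progression(st, 4500, cfg)
  expect_equal(shr$decision, c(1, 0))
  stb <- decide_dm_pingpong_progression(st, 5100, cfg)
  expect_equal(stb$decision, c(2, 0))
  grew <- decide_dm_pingpong_progression(st, 5600, cfg)
  expect_equal(grew$decision, c(0, 3))  # switch, other drug's last dose * 1.5
  expect_equal(grew$state$active_drug, 2L)
  # first use of the other drug starts at the single-drug MTD
  st2 <- started_state(last = 5000, maxb = 6000, dose = c(2, NA), active = 1L)
  first <- decide_dm_pingpong_progression(st2, 5600, cfg)
  expect_equal(first$decision, c(0, 5))
  # initiation starts drug 1 at MTD
  up <- controller_update(controller_state(), 5010, cfg)
  expect_equal(up$decision, c(5, 0))
})

test_that("FD Dose-Skipping doses 2.25 of each drug only on growth or a new maximum", {
  cfg <- protocol_config("FD_SKIP", measurement_noise_sd = 0)
  st <- started_state(last = 5000, maxb = 6000)
  expect_equal(decide_fd_doseskip(st, 5600, cfg)$decision, c(2.25, 2.25))
  expect_equal(decide_fd_doseskip(st, 4800, cfg)$decision, c(0, 0))
  # above the running maximum: dose even though growth is within Delta Tumor
  st2 <- started_state(last = 5000, maxb = 5100)
  expect_equal(decide_fd_doseskip(st2, 5200, cfg)$decision, c(2.25, 2.25))
})

test_that("FD Intermittent is a pure hysteresis on the initiation burden", {
  cfg <- protocol_config("FD_INT", measurement_noise_sd = 0)
  on <- started_state(init = 5000, fd_on = TRUE)
  off <- decide_fd_intermittent(on, 2400, cfg)
  expect_equal(off$decision, c(0, 0))
  expect_false(off$state$fd_dosing_on)
  mid <- decide_fd_intermittent(off$state, 4000, cfg)   # between thresholds
  expect_equal(mid$decision, c(0, 0))
  back <- decide_fd_intermittent(mid$state, 5100, cfg)  # regrew past initiation
  expect_equal(back$decision, c(2.25, 2.25))
  # replay determinism: the on/off sequence depends only on the trajectory
  traj <- c(5200, 4100, 2300, 3000, 4900, 5050, 2600, 2450, 5200)
  replay <- function() {
    st <- started_state(init = 5000, fd_on = TRUE)
    vapply(traj, function(b) {
      out <- decide_fd_intermittent(st, b, cfg); st <<- out$state
      out$decision[1]
    }, numeric(1))
  }
  expect_identical(replay(), replay())
})

test_that("vacations suppress dosing at or below the threshold; doses are clamped", {
  cfg <- protocol_config("DM_COCKTAIL")
  st <- started_state()
  expect_equal(apply_vacation_and_clamp(c(2, 2), 2500, cfg, st), c(0, 0))
  expect_equal(apply_vacation_and_clamp(c(2, 2), 2501, cfg, st), c(2, 2))
  expect_equal(apply_vacation_and_clamp(c(4, 4), 5000, cfg, st), c(3, 3))
  expect_equal(apply_vacation_and_clamp(c(0.2, 0.2), 5000, cfg, st), c(0.5, 0.5))
  expect_equal(apply_vacation_and_clamp(c(0, 0), 5000, cfg, st), c(0, 0))
})

test_that("treatment initiates at the measured threshold with the protocol's first dose", {
  for (p in protocol_ids()) {
    cfg <- protocol_config(p, measurement_noise_sd = 0)
    not_yet <- controller_update(controller_state(), 4990, cfg)
    expect_equal(not_yet$decision, c(0, 0))
    expect_false(not_yet$state$treatment_started)
    go <- controller_update(controller_state(), 5010, cfg)
    expect_true(go$state$treatment_started)
    expect_equal(go$state$initiation_burden, 5010)
    expected <- switch(p, ST = , DM_COCKTAIL = c(3, 3),
                       DM_PP_ALT = , DM_PP_PROG = c(5, 0),
                       FD_SKIP = , FD_INT = c(2.25, 2.25))
    expect_equal(go$decision, expected)
  }
})

test_that("every protocol only ever emits doses in {0} union [min_dose, MTD]", {
  set.seed(33)
  for (p in protocol_ids()) {
    cfg <- protocol_config(p, measurement_noise_sd = 0)
    cap <- if (p %in% c("DM_PP_ALT", "DM_PP_PROG")) cfg$mtd_single else cfg$mtd_combo
    st <- controller_state()
    burden <- 4500
    for (cycle in 1:120) {
      burden <- max(0, round(burden * exp(runif(1, -0.4, 0.4))))
      out <- controller_update(st, burden, cfg)
      st <- out$state
      d <- out$decision
      expect_true(all(d == 0 | (d >= cfg$min_dose & d <= cap + 1e-12)))
      if (p %in% c("DM_PP_ALT", "DM_PP_PROG")) expect_lte(sum(d > 0), 1)
      if (p %in% c("ST", "DM_COCKTAIL")) expect_equal(d[1], d[2])
    }
  }
})

test_that("a steadily shrinking burden walks the cocktail dose down to the minimum", {
  cfg <- protocol_config("DM_COCKTAIL", measurement_noise_sd = 0)
  st <- controller_update(controller_state(), 6000, cfg)$state  # start at MTD 3
  doses <- numeric(6)
  burden <- 6000
  for (k in 1:6) {
    burden <- round(burden * 0.85)  # always above the vacation threshold
    out <- controller_update(st, burden, cfg)
    st <- out$state
    doses[k] <- out$decision[1]
  }
  expect_true(all(diff(doses) <= 0))
  k_min <- ceiling(log(3 / 0.5) / log(1 / (1 - cfg$delta_dose)))
  expect_equal(doses[k_min], 0.5)
  expect_true(all(doses[1:(k_min - 1)] > 0.5))
})
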