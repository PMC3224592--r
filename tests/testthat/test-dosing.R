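test_that("microgram to micromole conversion uses the elemental molar mass", {
  expect_equal(micrograms_to_micromoles(0), 0)
  expect_equal(round(micrograms_to_micromoles(500), 4), 6.6736)
  expect_equal(round(micrograms_to_micromoles(300), 4), 4.0042)
  expect_error(micrograms_to_micromoles(-1), "non-negative")
})

test_that("gut input pulses have the right height, duration, and integral", {
  sched <- dose_schedule(dose_event(0, 500, "iAs"), background_rate = 0)
  f <- gut_input_function(sched, gut_volume = 1)
  expect_equal(f$rate(0.05)[["iAs"]], micrograms_to_micromoles(500) / 0.1)
  expect_equal(round(f$rate(0)[["iAs"]], 3), 66.736)
  expect_equal(f$rate(0.2)[["iAs"]], 0)
  expect_equal(f$breakpoints, c(0, 0.1))
  # empty schedule, no background: identically zero
  f0 <- gut_input_function(dose_schedule(background_rate = 0), 1)
  expect_equal(unname(f0$rate(3)), c(0, 0, 0))
  # chronic 300 ug/day -> constant rate
  fc <- gut_input_function(dose_schedule(background_rate = 0,
                                         chronic_rate = 300), 1)
  expect_equal(round(fc$rate(10)[["iAs"]], 5), 0.16684)
})

test_that("delivered-mass bookkeeping matches the input-function integral", {
  set.seed(7)
  for (i in 1:5) {
    n_ev <- sample(1:4, 1)
    evs <- lapply(seq_len(n_ev), function(j) {
      dose_event(stats::runif(1, 0, 72), stats::runif(1, 50, 1000),
                 sample(c("iAs", "MMA", "DMA"), 1))
    })
    sched <- dose_schedule(evs, background_rate = stats::runif(1, 0, 20),
                           chronic_rate = stats::runif(1, 0, 400))
    f <- gut_input_function(sched, 1)
    # integrate the piecewise-constant rate exactly over [0, 200]
    bp <- sort(unique(c(0, f$breakpoints, 200)))
    integral <- sum(vapply(seq_len(length(bp) - 1), function(k) {
      sum(f$rate(bp[k])) * (bp[k + 1] - bp[k])
    }, numeric(1)))
    expect_equal(integral, schedule_delivered_micromoles(sched, 200),
                 tolerance = 1e-12)
  }
})

test_that("repeated dosing builds daily events and totals add up", {
  sched <- repeated_dose_schedule(500, 5, "iAs")
  expect_length(sched$events, 5)
  expect_equal(vapply(sched$events, `[[`, numeric(1), "time"),
               c(0, 24, 48, 72, 96))
  total <- sum(vapply(sched$events, `[[`, numeric(1), "amount"))
  expect_equal(micrograms_to_micromoles(total), 2500 / 74.9216)
  # one day degenerates to a single dose event
  one <- repeated_dose_schedule(250, 1, "MMA")
  expect_length(one$events, 1)
  expect_equal(one$events[[1]]$species, "MMA")
  expect_error(repeated_dose_schedule(500, 0), "at least 1")
})

test_that("MMA and DMA doses route to their own blood pools", {
  p <- as_params("table2")
  for (sp in c("MMA", "DMA")) {
    sched <- dose_schedule(dose_event(0, 500, sp), background_rate = 0)
    traj <- simulate_arsenic(p, sched, seq(0, 24, by = 1))
    other <- setdiff(c("BMMAs", "BDMAs"), paste0("B", sp, "s"))
    expect_gt(max(traj[[paste0("B", sp, "s")]]), 0)
    # iAs never appears, and the other methylated pool only via methylation
    expect_equal(max(traj$BiAs), 0)
    if (sp == "DMA") expect_equal(max(traj$BMMAs), 0)
  }
})

test_that("species-specific absorption constants take effect", {
  p <- as_params("table2")
  sched_fast <- dose_schedule(dose_event(0, 500, "MMA"), background_rate = 0)
  traj <- simulate_arsenic(p, sched_fast, seq(0, 10, by = 0.5))
  # k1 for MMA is 2/hr: gut pool nearly empty after 3 hours
  expect_lt(traj$gut_MMA[traj$time == 3],
            0.01 * max(traj$gut_MMA))
  # an explicit absorption_k1 on the event overrides the parameter
  slow <- dose_schedule(dose_event(0, 500, "MMA", absorption_k1 = 0.01),
                        background_rate = 0)
  traj2 <- simulate_arsenic(p, slow, seq(0, 10, by = 0.5))
  expect_gt(traj2$gut_MMA[traj2$time == 3], 0.9 * max(traj2$gut_MMA))
})

test_that("dose constructors validate their arguments", {
  expect_error(dose_event(-1, 100), "non-negative")
  expect_error(dose_event(0, -5), "non-negative")
  expect_error(dose_event(0, 5, absorption_k1 = 0), "positive")
  expect_error(dose_schedule(delivery_window = 0), "positive")
  expect_error(dose_schedule(background_rate = -1), "non-negative")
})
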