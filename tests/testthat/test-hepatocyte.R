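test_that("in-vitro configuration maps volumes and forbids excretion pathways", {
  cfg <- hepatocyte_config()
  # 0.25e6 cells of 2e-9 ml: 0.0005 ml, cells/medium ratio 0.001
  expect_equal(0.25e6 * 2e-9, 0.0005)
  expect_equal(cfg$rcm, 0.001)
  p <- configure_invitro(cfg)
  r <- volume_ratios(p)
  expect_equal(unname(r["rlb"]), 0.001)   # cells/medium replaces liver/blood
  expect_equal(unname(r["rsb"]), 1)       # medium store shares the medium volume
  expect_equal(p$k6 + p$k7 + p$k8 + p$k1 + p$k10 + p$k_10, 0)
  expect_error(hepatocyte_config(k6 = 0.1), "zero")
})

test_that("the closed in-vitro system conserves its initial moles", {
  iv <- simulate_invitro(0.1, times = seq(0, 72, by = 1))
  expect_equal(iv$total_nmol, rep(0.05, nrow(iv)), tolerance = 1e-9 / 0.05)
  # no transport: medium iAs stays put
  frozen <- hepatocyte_config(k2 = 0, k_2 = 0, k3 = 0, k_3 = 0, k4 = 0,
                              k_4 = 0, k5 = 0, k_5 = 0, k9 = 0, k_9 = 0)
  iv0 <- simulate_invitro(0.1, frozen, times = seq(0, 10, by = 1))
  expect_equal(iv0$medium_iAs, rep(0.1, nrow(iv0)))
})

test_that("cell concentrations can exceed medium while holding few moles", {
  iv <- simulate_invitro(0.1, times = seq(0, 72, by = 1))
  late <- iv[nrow(iv), ]
  cell_conc <- late$cell_iAs + late$cell_iAs_store + late$cell_MMA +
    late$cell_DMA
  medium_conc <- late$medium_iAs + late$medium_iAs_store + late$medium_MMA +
    late$medium_DMA
  expect_gt(cell_conc, medium_conc)
  expect_lt(late$cell_total_nmol, 0.5 * late$medium_total_nmol)
})

test_that("total-arsenic time courses keep the observed convex/concave shapes", {
  iv <- simulate_invitro(0.1, times = seq(0, 36, by = 0.5))
  # uptake phase: medium total falls while the cells load, then partially
  # recovers as DMA is exported back -> convex; cell total rises to a
  # peak and declines -> concave
  expect_lt(iv$medium_total_nmol[2], iv$medium_total_nmol[1])
  expect_gt(iv$cell_total_nmol[2], iv$cell_total_nmol[1])
  expect_true(all(diff(diff(iv$medium_total_nmol)) >= -1e-10))
  expect_true(all(diff(diff(iv$cell_total_nmol)) <= 1e-10))
  # the cell burden peaks inside the window (uptake is transient)
  expect_lt(which.max(iv$cell_total_nmol), nrow(iv))
})

test_that("in-vitro trajectory matches a finer independent integration", {
  cfg <- hepatocyte_config()
  times <- c(0, 2, 6, 12, 24)
  iv <- simulate_invitro(0.1, cfg, times, rtol = 1e-10, atol = 1e-13)
  p <- configure_invitro(cfg)
  oracle <- rk4_integrate(p, dose_schedule(background_rate = 0), times,
                          initial = arsenic_state(BiAs = 0.1),
                          substeps = 2000)
  for (i in 2:length(times)) {
    got <- c(iv$medium_iAs[i], iv$cell_iAs[i], iv$cell_MMA[i], iv$cell_DMA[i])
    want <- oracle[i, c("BiAs", "LiAs", "LMMAs", "LDMAs")]
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-10)), 1e-6)
  }
})
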