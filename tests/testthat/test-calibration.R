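test_that("stage loss vanishes only at the generating parameters", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth)
  stage <- fit_stage_spec("DMA_stage", arms$DMA)
  tv <- vapply(stage$free, function(k) truth[[k]], numeric(1))
  expect_lt(stage_loss(tv, stage), 1e-12)
  # perturbing any single free parameter by 10% strictly increases the loss
  for (j in seq_along(tv)) {
    pert <- tv
    pert[j] <- pert[j] * 1.1
    expect_gt(stage_loss(pert, stage), 1e-8)
  }
})

test_that("relative weighting rescales residuals by the observations", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth, noise_model(cv = 0.05, seed = 2))
  abs_stage <- fit_stage_spec("DMA_stage", arms$DMA, weighting = "absolute")
  rel_stage <- fit_stage_spec("DMA_stage", arms$DMA, weighting = "relative")
  tv <- vapply(abs_stage$free, function(k) truth[[k]], numeric(1))
  expect_false(isTRUE(all.equal(stage_loss(tv, abs_stage),
                                stage_loss(tv, rel_stage))))
  expect_gt(stage_loss(tv, rel_stage), 0)
})

test_that("stage and dataset validation guards fire", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth)
  expect_error(fit_stage_spec("unknown", arms$DMA), "unknown stage")
  expect_error(fit_stage_spec("DMA_stage", list(series = NULL)),
               "excretion_series")
  stage <- fit_stage_spec("DMA_stage", arms$DMA)
  guess <- stage$bounds["upper", ] * 2  # outside the bounds
  expect_error(fit_stage(stage, initial_guess = guess), "within bounds")
  expect_error(stage_loss(rep(-1, 6), stage), "positive")
  expect_error(staged_calibration(arms[c("DMA", "MMA")]), "missing dose arm")
})

test_that("short observation horizons warn about store identifiability", {
  truth <- table2_truth()
  sched <- dose_schedule(dose_event(0, 500, "DMA"))
  short <- generate_excretion_dataset(truth, sched, seq(0, 50, by = 5),
                                      noise_model(cv = 0))
  expect_warning(fit_stage_spec("DMA_stage", short), "100 hr")
})

test_that("DMA-arm fit recovers the generating excretion constant", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth)
  stage <- fit_stage_spec("DMA_stage", arms$DMA)
  fit <- fit_stage(stage)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["k8"]] - truth$k8) / truth$k8, 0.01)
  expect_lt(fit$loss, 1e-10)
})

test_that("DMA-stage estimates do not depend on later stages running", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth)
  stage <- fit_stage_spec("DMA_stage", arms$DMA)
  alone <- fit_stage(stage, seed = 123L, n_starts = 2, n_hops = 5)
  staged <- staged_calibration(arms, seed = 123L, n_starts = 2, n_hops = 5,
                               patience = 3)
  expect_equal(staged$stages$DMA_stage$estimates, alone$estimates,
               tolerance = 1e-8)
})
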