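test_that("zero noise reproduces the model rates exactly and seeds are deterministic", {
  truth <- table2_truth()
  sched <- dose_schedule(dose_event(0, 500, "DMA"))
  st <- seq(0, 100, by = 10)
  clean <- generate_excretion_dataset(truth, sched, st, noise_model(cv = 0))
  traj <- simulate_arsenic(truth, sched, st, rtol = 1e-10, atol = 1e-12)
  direct <- interval_excretion_rates(traj, st)
  expect_identical(clean$series$rates$rate_DMA, direct$rates$rate_DMA)
  # determinism: same seed, same dataset, bit for bit
  a <- generate_excretion_dataset(truth, sched, st, noise_model(0.05, 11))
  b <- generate_excretion_dataset(truth, sched, st, noise_model(0.05, 11))
  expect_identical(a$series$rates, b$series$rates)
  c2 <- generate_excretion_dataset(truth, sched, st, noise_model(0.05, 12))
  expect_false(identical(a$series$rates, c2$series$rates))
})

test_that("noise factors have mean one: replicate average converges to the clean rates", {
  truth <- table2_truth()
  sched <- dose_schedule(dose_event(0, 500, "DMA"))
  st <- seq(0, 100, by = 20)
  clean <- generate_excretion_dataset(truth, sched, st, noise_model(cv = 0))
  cv <- 0.1
  n_rep <- 400
  acc <- matrix(0, length(st) - 1, 3)
  for (r in seq_len(n_rep)) {
    d <- generate_excretion_dataset(truth, sched, st, noise_model(cv, r))
    acc <- acc + as.matrix(d$series$rates)
  }
  avg <- acc / n_rep
  se <- cv * as.matrix(clean$series$rates) / sqrt(n_rep)
  diff <- abs(avg - as.matrix(clean$series$rates))
  expect_true(all(diff <= 3 * se + 1e-12))
})

test_that("generated datasets satisfy the excretion-series contract", {
  truth <- table2_truth()
  arms <- synthetic_triple_arm(truth, noise_model(cv = 0.05, seed = 3))
  for (arm in arms) {
    s <- arm$series
    expect_s3_class(s, "excretion_series")
    expect_true(all(as.matrix(s$rates) >= 0))
    expect_true(all(diff(s$sample_times) > 0))
  }
})

test_that("in-vitro generator reproduces the clean trajectory at cv = 0 and conserves moles", {
  d <- generate_invitro_dataset(noise = noise_model(cv = 0),
                                sample_times = seq(0, 24, by = 3))
  expect_equal(d$data$medium_iAs, d$clean$medium_iAs)
  expect_equal(d$clean$total_nmol, rep(0.05, nrow(d$clean)),
               tolerance = 1e-8)
  dn <- generate_invitro_dataset(noise = noise_model(cv = 0.05, seed = 5),
                                 sample_times = seq(0, 24, by = 3))
  expect_false(identical(dn$data$medium_iAs, dn$clean$medium_iAs))
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_excretion_dataset(
    table2_truth(), dose_schedule(dose_event(0, 100, "DMA")),
    seq(0, 50, by = 10), noise_model(0.05, 1)))
  after <- stats::runif(1)
  expect_identical(before, after)
})
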