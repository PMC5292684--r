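test_that("simulation matches the closed-form Langmuir solution when transport is absent", {
  kin <- kinetic_params(1.8e8, 2e-4, 1000, Inf)
  sch <- phase_schedule(0, 200, 0)
  for (conc in c(0, 5e-10, 5e-9, 2e-8)) {
    sg <- simulate_sensorgram(kin, conc, sch)
    expect_equal(sg$response,
                 oracle_langmuir(sg$time, 1.8e8, 2e-4, 1000, conc),
                 tolerance = 1e-10)
  }
})

test_that("transport-limited traces converge uniformly to Langmuir as k_t grows", {
  sch <- phase_schedule(0, 200, 600)
  kin_inf <- kinetic_params(1.8e8, 2e-4, 1000, Inf)
  ref <- simulate_sensorgram(kin_inf, 5e-9, sch)
  kin_big <- kinetic_params(1.8e8, 2e-4, 1000, 1e6 * 1.8e8 * 1000)
  big <- simulate_sensorgram(kin_big, 5e-9, sch)
  expect_lt(max(abs(ref$response - big$response)), 0.1)
})

test_that("700 s dissociation loses 1 - exp(-0.14) ideally, strictly less with rebinding", {
  sch <- phase_schedule(0, 3000, 700)  # long association: near saturation
  loss <- function(k_t) {
    sg <- simulate_sensorgram(kinetic_params(1.8e8, 2e-4, 1000, k_t), 2e-8, sch)
    i0 <- max(which(sg$phase == "association"))
    1 - sg$response[nrow(sg)] / sg$response[i0]
  }
  expect_equal(loss(Inf), 1 - exp(-2e-4 * 700), tolerance = 1e-4)
  expect_lt(loss(6e9), loss(Inf))
  expect_lt(loss(1e9), loss(6e9))  # stronger limitation, more rebinding
})

test_that("equilibrium response follows R_max C/(C + K_D) regardless of transport", {
  # transport slows the approach ~30-fold here, so run the injection long
  sch <- phase_schedule(0, 4e5, 0)
  conc <- 2e-12  # near K_D so equilibrium is discriminating
  req <- 1000 * conc / (conc + 2e-4 / 1.8e8)
  for (k_t in c(Inf, 6e9)) {
    sg <- simulate_sensorgram(kinetic_params(1.8e8, 2e-4, 1000, k_t), conc,
                              sch, dt = 200)
    expect_equal(sg$response[nrow(sg)], req, tolerance = 0.02)
  }
})

test_that("association response is non-decreasing in concentration at every time", {
  sgs <- gen_sensorgram_series(default_kin(), noise = noise_spec(0, 1))
  ia <- sgs[[1]]$phase == "association"
  resp <- sapply(sgs, function(s) s$response[ia])
  expect_true(all(apply(resp, 1, function(r) all(diff(r) >= -1e-9))))
})

test_that("double referencing subtracts references and re-zeroes the baseline", {
  kin <- default_kin()
  sch <- phase_schedule(50, 200, 300)
  raw <- simulate_sensorgram(kin, 5e-9, sch)
  zero <- raw; zero$response <- 0

  out <- double_reference(raw, zero, zero)
  expect_equal(out$response, raw$response - mean(raw$response[raw$phase == "baseline"]))

  half <- raw; half$response <- raw$response / 2
  cancel <- double_reference(raw, half, half)
  expect_equal(cancel$response, rep(0, nrow(raw)), tolerance = 1e-12)

  # a constant bulk jump present in raw and in the buffer reference vanishes
  jump <- ifelse(raw$phase == "association", 10, 0)
  rawj <- raw; rawj$response <- raw$response + jump
  bufj <- zero; bufj$response <- jump
  clean <- double_reference(rawj, zero, bufj)
  ref <- double_reference(raw, zero, zero)
  expect_equal(clean$response, ref$response, tolerance = 1e-12)
})

test_that("capture-drift correction divides out the capture exponential", {
  t <- 0:600
  a <- 3e-4; b <- 2e-4
  sg <- decorakin:::new_sensorgram(t, 500 * exp(-(a + b) * t),
                                   rep("dissociation", length(t)), 5e-9)
  # capture_koff = 0 is the identity
  expect_equal(correct_capture_drift(sg, 0)$response, sg$response)
  out <- correct_capture_drift(sg, a)
  # corrected trace decays with the ligand rate alone (t measured from the
  # first dissociation point of the phase)
  t_rel <- t - t[1] + 1
  expect_equal(out$response, 500 * exp(-(a + b) * t) * exp(a * t_rel))
  expect_warning(correct_capture_drift(sg, 0.01), "amplifies")
})

test_that("dissociation k_off is recovered from corrected composite traces", {
  kin <- default_kin()
  sch <- phase_schedule(0, 300, 600)
  sgs0 <- gen_sensorgram_series(kinetic_params(1.8e8, 2e-4, 1000, Inf),
                                c(5e-9, 1e-8), sch, noise_spec(0, 1))
  f0 <- fit_dissociation_koff(sgs0)
  expect_equal(f0$k_off, 2e-4, tolerance = 1e-6)

  # corrupt with capture decay a, correct, refit: within 5%
  a <- 1e-4
  corrupted <- lapply(sgs0, function(sg) {
    i <- sg$phase == "dissociation"
    t_rel <- sg$time[i] - sg$time[i][1] + 1
    sg$response[i] <- sg$response[i] * exp(-a * t_rel)
    sg
  })
  corrected <- lapply(corrupted, correct_capture_drift, capture_koff = a)
  fc <- fit_dissociation_koff(corrected)
  expect_lt(abs(fc$k_off - 2e-4) / 2e-4, 0.05)

  # noisy recovery within 10% over 8 curves
  sgs <- gen_sensorgram_series(kinetic_params(1.8e8, 2e-4, 1000, Inf),
                               rep(2e-8, 8), sch, noise_spec(0.5, 7))
  fn <- fit_dissociation_koff(sgs)
  expect_lt(abs(fn$k_off - 2e-4) / 2e-4, 0.10)

  # flat trace triggers the lower-bound path
  flat <- decorakin:::new_sensorgram(0:500, rep(100, 501),
                                     rep("dissociation", 501), 1e-9)
  expect_warning(ff <- fit_dissociation_koff(list(flat)), "lower bound")
  expect_equal(ff$k_off, 0)
})

test_that("global fit on ideal data returns the generating constants and K_D = 1.11 pM", {
  sgs <- gen_sensorgram_series(default_kin(), fig5b_concentrations,
                               noise = noise_spec(0, 1))
  fit <- fit_global(sgs, koff_fixed = 2e-4, n_starts = 2, seed = 1)
  expect_equal(fit$k_on, 1.8e8, tolerance = 1e-4)
  expect_identical(fit$K_D, fit$k_off / fit$k_on)  # exact invariant
  expect_equal(round(fit$K_D * 1e12, 2), 1.11)
  expect_true(fit$koff_fixed)
  expect_true(is.na(fit$k_off_se))
})

test_that("a single concentration is rejected as unidentifiable", {
  sgs <- gen_sensorgram_series(default_kin(), c(1e-12, 1e-12),
                               noise = noise_spec(0, 1))
  expect_error(fit_global(sgs), "distinct")
  expect_error(fit_global(sgs[1]), "length")
})

test_that("k_t is reported as unbounded when the data carry no transport signature", {
  kin <- kinetic_params(k_on = 1e5, k_off = 1e-3, r_max = 100, k_t = Inf)
  sgs <- gen_sensorgram_series(kin, c(5e-6, 2e-5), phase_schedule(0, 200, 300),
                               noise_spec(0, 1))
  fit <- fit_global(sgs, koff_fixed = 1e-3, n_starts = 4, seed = 2)
  expect_true(fit$kt_unbounded)
  expect_identical(fit$k_t, Inf)
  expect_equal(fit$k_on, 1e5, tolerance = 0.02)
})

test_that("K_D arithmetic and mass stoichiometry are exact", {
  expect_equal(round(compute_kd(180e6, 2e-4) * 1e12, 2), 1.11)
  expect_equal(round(compute_kd(362e6, 2e-4) * 1e12, 2), 0.55)
  expect_identical(compute_kd(5e7, 0), 0)
  expect_error(compute_kd(-1, 2e-4))

  expect_equal(round(expected_mass_fraction(120, 18.3e3, 26e6), 1), 8.4)
  expect_identical(expected_mass_fraction(0, 18.3e3, 26e6), 0)
  expect_equal(expected_mass_fraction(120, 17.3e3, 26e6), 7.98, tolerance = 1e-3)
})
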