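test_that("spectral density has the rigid limit and matches a literal oracle", {
  tmb <- global_tumbling(8)
  rigid <- motion_params(s2 = 1, tau_e = 500)
  w <- c(0, 2 * pi * 60.8e6, 2 * pi * 600e6)
  expect_equal(spectral_density(rigid, tmb, w),
               0.4 * 8e-9 / (1 + (w * 8e-9)^2))
  expect_equal(spectral_density(rigid, tmb, 0), 0.4 * 8e-9)

  m <- motion_params(s2 = 0.8, tau_e = 50)
  expect_equal(spectral_density(m, tmb, 2 * pi * 60.8e6),
               oracle_j(2 * pi * 60.8e6, 0.8, 8e-9, 50e-12),
               tolerance = 1e-12)
})

test_that("J(omega) is non-negative and non-increasing; S2 = 1 removes tau_e dependence", {
  tmb <- global_tumbling(11)
  w <- seq(0, 2 * pi * 800e6, length.out = 50)
  for (pars in list(c(0.9, 20), c(0.6, 500), c(1, 0))) {
    j <- spectral_density(motion_params(pars[1], pars[2]), tmb, w)
    expect_true(all(j >= 0))
    expect_true(all(diff(j) <= 1e-18))
  }
  j1 <- predict_rates(motion_params(1, 0), tmb, 600)
  j2 <- predict_rates(motion_params(1, 900), tmb, 600)
  expect_identical(j1, j2)
})

test_that("predicted rates match an independent transcription of the expressions", {
  grid <- expand.grid(s2 = c(0.6, 0.85, 1), te = c(0, 40, 200),
                      rex = c(0, 3), tm = c(5, 11), field = c(600, 700))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- predict_rates(motion_params(g$s2, g$te, g$rex),
                         global_tumbling(g$tm), g$field)
    want <- oracle_rates(g$s2, g$tm, g$te, g$rex, g$field)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Rex adds to R2 only and R2/R1 grows with tau_m", {
  tmb <- global_tumbling(9)
  r0 <- predict_rates(motion_params(0.85, 30, 0), tmb, 600)
  r5 <- predict_rates(motion_params(0.85, 30, 5), tmb, 600)
  expect_equal(r5[["R2"]] - r0[["R2"]], 5)
  expect_identical(r5[["R1"]], r0[["R1"]])
  expect_identical(r5[["NOE"]], r0[["NOE"]])

  ratio <- function(tm) {
    r <- predict_rates(motion_params(1), global_tumbling(tm), 600)
    r[["R2"]] / r[["R1"]]
  }
  expect_gt(ratio(8), ratio(4))
  # inverting the rigid relation reproduces the configured average
  tm <- tau_m_for_ratio(17.2, 600)
  expect_equal(ratio(tm), 17.2, tolerance = 1e-8)
})

test_that("per-domain tumbling is recovered and NOE-flexible residues are excluded", {
  p <- two_domain_protein()
  ds <- gen_relaxation_dataset(p$motions, p$tumbling, rel_sd = 0, noe_sd = 0,
                               replicates = 1, seed = 1)
  est <- estimate_tm_from_ratio(ds)
  expect_equal(est$NTD$tau_m, p$tumbling[["NTD"]], tolerance = 0.02)
  expect_equal(est$CTD$tau_m, p$tumbling[["CTD"]], tolerance = 0.02)
  expect_gt(est$CTD$tau_m, est$NTD$tau_m)  # configured ordering preserved

  # poison one domain with flexible residues carrying absurd ratios: the
  # NOE filter must exclude them, leaving the estimate unchanged
  poison <- ds[ds$field == 600 & ds$domain == "NTD", ][1:3, ]
  poison$residue <- poison$residue + 1000
  poison$NOE <- 0.2
  poison$R2 <- poison$R2 * 10
  est2 <- estimate_tm_from_ratio(rbind(ds[ds$field == 600, ], poison))
  expect_equal(est2$NTD$tau_m, est$NTD$tau_m, tolerance = 1e-6)

  few <- ds[ds$residue %in% 1:3, ]
  expect_error(estimate_tm_from_ratio(few), "fewer than")
})

test_that("model selection recovers the generating model in the vanishing-noise limit", {
  tmb <- global_tumbling(10)
  # exact synthetic observables with a tiny stated precision: the weighted
  # fit then behaves as the noise -> 0 asymptote of the selection rule
  cases <- list(
    list(m = motion_params(0.85), want = "M1"),
    list(m = motion_params(0.78, tau_e = 60), want = "M2"),
    list(m = motion_params(0.88, rex = 4), want = c("M3", "M4")))
  for (cs in cases) {
    obs <- do.call(rbind, lapply(c(600, 700), function(f) {
      r <- predict_rates(cs$m, tmb, f)
      data.frame(field = f, R1 = r[["R1"]], R1_err = 1e-3 * r[["R1"]],
                 R2 = r[["R2"]], R2_err = 1e-3 * r[["R2"]],
                 NOE = r[["NOE"]], NOE_err = 1e-3)
    }))
    fit <- fit_residue(obs, tmb)
    expect_true(attr(fit, "model") %in% cs$want)
    expect_equal(fit$s2, cs$m$s2, tolerance = 1e-3)
    if (cs$m$rex > 0) expect_equal(fit$rex, cs$m$rex, tolerance = 1e-2)
  }

  # fully unweighted path: data generated under M1 refit exactly
  r <- predict_rates(motion_params(0.85), tmb, 600)
  obs1 <- data.frame(field = 600, R1 = r[["R1"]], R1_err = 0, R2 = r[["R2"]],
                     R2_err = 0, NOE = r[["NOE"]], NOE_err = 0)
  f1 <- fit_residue(obs1, tmb, models = "M1")
  expect_equal(f1$s2, 0.85, tolerance = 1e-6)
})

test_that("an uninformative record is flagged rather than silently accepted", {
  tmb <- global_tumbling(10)
  r <- predict_rates(motion_params(0.85), tmb, 600)
  obs <- data.frame(field = 600, R1 = r[["R1"]], R1_err = 0.02,
                    R2 = r[["R2"]], R2_err = 0.2, NOE = r[["NOE"]],
                    NOE_err = 1.5)  # error spans the physical NOE range
  fit <- fit_residue(obs, tmb)
  expect_identical(attr(fit, "flag"), "uninformative")
})

test_that("Monte-Carlo intervals collapse at zero error and widen with error", {
  tmb <- global_tumbling(10)
  obs <- do.call(rbind, lapply(c(600, 700), function(f) {
    p <- predict_rates(motion_params(0.85, rex = 3), tmb, f)
    data.frame(field = f, R1 = p[["R1"]], R1_err = 0.02, R2 = p[["R2"]],
               R2_err = 0.2, NOE = p[["NOE"]], NOE_err = 0.02)
  }))
  fit <- fit_residue(obs, tmb, models = "M3")

  zero_obs <- transform(obs, R1_err = 0, R2_err = 0, NOE_err = 0)
  zero_fit <- fit_residue(zero_obs, tmb, models = "M3")
  expect_warning(ci0 <- mc_errors(zero_fit, zero_obs, tmb, n_mc = 100, seed = 1),
                 "collapse")
  expect_true(all(ci0$upper - ci0$lower < 1e-8))

  ci1 <- mc_errors(fit, obs, tmb, n_mc = 150, seed = 2)
  wide_obs <- transform(obs, R1_err = 0.04, R2_err = 0.4, NOE_err = 0.04)
  ci2 <- mc_errors(fit, wide_obs, tmb, n_mc = 150, seed = 2)
  expect_true(all(ci2$upper - ci2$lower > ci1$upper - ci1$lower))
})

test_that("domain averages are order-invariant and exact for single residues", {
  p <- two_domain_protein()
  ds <- gen_relaxation_dataset(p$motions, p$tumbling, seed = 3)
  a <- domain_average_t1t2(ds)
  b <- domain_average_t1t2(ds[sample.int(nrow(ds)), ])
  expect_identical(a[order(names(a))], b[order(names(b))])

  one <- ds[ds$residue == 7 & ds$field == 600, ]
  expect_equal(unname(domain_average_t1t2(one)), one$R2 / one$R1)
  expect_error(domain_average_t1t2(ds, domains = list(A = 1:5, B = 4:9)),
               "disjoint")
})

test_that("exactly the exchange-bearing residues are flagged on noise-free data", {
  p <- two_domain_protein()
  ds <- gen_relaxation_dataset(p$motions, p$tumbling, rel_sd = 0, noe_sd = 0,
                               replicates = 1, seed = 1)
  # exact values with a tiny stated precision (the noise -> 0 limit)
  ds$R1_err <- 1e-3 * ds$R1; ds$R2_err <- 1e-3 * ds$R2; ds$NOE_err <- 1e-3
  tmb <- list(NTD = global_tumbling(p$tumbling[["NTD"]]),
              CTD = global_tumbling(p$tumbling[["CTD"]]))
  fits <- fit_dataset(ds, tmb)
  flagged <- flag_exchange(fits, min_rex = 0.5)
  truth <- p$motions$residue[p$motions$rex > 0]
  expect_setequal(flagged, truth)
  expect_length(flagged, 16)

  # closed threshold: rex exactly at min_rex is included
  fits_edge <- data.frame(residue = 1:2, model = c("M3", "M1"),
                          rex = c(2, 0), rex_lower = NA, rex_upper = NA)
  expect_identical(flag_exchange(fits_edge, min_rex = 2), 1L)
})
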