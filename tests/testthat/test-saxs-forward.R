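test_that("Debye curve matches closed forms and the brute-force double sum", {
  q <- seq(0.01, 0.4, by = 0.01)

  two <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(debye_curve(two, q)$I, 2 + 2 * sin(q * 10) / (q * 10))
  expect_equal(debye_curve(two, c(0, 0.1))$I[1], 4)  # I(0) = (sum w)^2

  wtd <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 7, 0)),
                    weights = c(1, 2, 0.5))
  expect_equal(debye_curve(wtd, q)$I[1:5],
               {
                 w <- wtd$weights
                 vapply(q[1:5], function(qi) {
                   s <- 0
                   for (i in 1:3) for (j in 1:3) {
                     d <- sqrt(sum((wtd$coords[i, ] - wtd$coords[j, ])^2))
                     s <- s + w[i] * w[j] *
                       (if (d == 0) 1 else sin(qi * d) / (qi * d))
                   }
                   s
                 }, numeric(1))
               }, tolerance = 1e-12)

  set.seed(4)
  rand <- bead_model(matrix(rnorm(150 * 3, sd = 12), ncol = 3))
  expect_equal(debye_curve(rand, q)$I, oracle_debye(rand$coords, q),
               tolerance = 1e-10)
  expect_warning(debye_curve(bead_model(matrix(0, 1, 3)), q), "single-bead")
})

test_that("intensity never exceeds the forward limit for positive weights", {
  set.seed(8)
  m <- bead_model(matrix(rnorm(300, sd = 15), ncol = 3))
  cur <- debye_curve(m, seq(0.008, 0.5, length.out = 150))
  expect_true(all(cur$I <= nrow(m$coords)^2 + 1e-9))
})

test_that("P(r) reproduces two-point geometry and coordinate Rg", {
  two <- bead_model(rbind(c(0, 0, 0), c(20, 0, 0)))
  pr <- pr_from_beads(two, bin_width = 1)
  expect_equal(pr$dmax, 20)
  expect_equal(sum(pr$p > 0), 1L)        # single occupied bin
  expect_equal(pr$rg, 10, tolerance = 0.03)  # d/2, up to bin midpoint offset

  m <- gen_two_domain_beads(seed = 2)
  pr1 <- pr_from_beads(m, bin_width = 1)
  expect_equal(pr1$rg, rg_from_coords(m), tolerance = 0.01)
  # binning error shrinks with bin width
  err <- function(bw) abs(pr_from_beads(m, bw)$rg - rg_from_coords(m))
  expect_lt(err(0.25), err(4) + 1e-12)
})

test_that("chi is zero on identity, one for unit residuals, and scale-invariant", {
  q <- seq(0.01, 0.3, length.out = 120)
  m <- gen_two_domain_beads(seed = 3)
  calc <- debye_curve(m, q)
  ex <- scattering_curve(q, calc$I, sigma = 0.02 * calc$I)
  expect_equal(as.numeric(chi_score(ex, calc, fit_scale = FALSE)), 0)

  shifted <- scattering_curve(q, calc$I + 0.02 * calc$I, sigma = 0.02 * calc$I)
  expect_equal(as.numeric(chi_score(shifted, calc, fit_scale = FALSE)), 1)

  # joint rescaling of (Iexp, Icalc, sigma) leaves chi unchanged
  noisy <- scattering_curve(q, calc$I * (1 + stats::rnorm(120, 0, 0.02)),
                            sigma = 0.02 * calc$I)
  c1 <- chi_score(noisy, calc, fit_scale = FALSE)
  noisy2 <- scattering_curve(q, noisy$I * 7, sigma = noisy$sigma * 7)
  calc2 <- scattering_curve(q, calc$I * 7)
  expect_equal(as.numeric(chi_score(noisy2, calc2, fit_scale = FALSE)),
               as.numeric(c1))
  # and fitting the scale absorbs a pure multiplicative offset entirely
  expect_equal(as.numeric(chi_score(scattering_curve(q, 3.7 * calc$I,
                                                     sigma = 0.02 * calc$I),
                                    calc, fit_scale = TRUE)), 0,
               tolerance = 1e-8)

  bad <- scattering_curve(q, calc$I, sigma = c(0, rep(1, 119)))
  expect_error(chi_score(bad, calc), "sigma at q")
})

test_that("chi is near one under matched Gaussian noise", {
  n <- 500
  q <- seq(0.008, 0.5, length.out = n)
  m <- gen_two_domain_beads(seed = 5)
  calc <- debye_curve(m, q)
  sig <- 0.02 * calc$I
  set.seed(17)
  ex <- scattering_curve(q, calc$I + stats::rnorm(n, 0, sig), sigma = sig)
  chi <- chi_score(ex, calc)
  expect_lt(abs(chi - 1), 3 / sqrt(2 * n))
})

test_that("Guinier analysis is exact on a Gaussian curve and fails on short data", {
  q <- seq(0.005, 0.04, length.out = 60)
  gauss <- scattering_curve(q, 100 * exp(-q^2 * 30^2 / 3))
  g <- guinier_rg(gauss)
  expect_equal(g$rg, 30, tolerance = 1e-3)

  short <- scattering_curve(q[1:3], gauss$I[1:3])
  expect_error(guinier_rg(short), "fewer than")
})

test_that("Guinier and P(r) estimates of Rg agree for the synthetic two-lobe model", {
  m <- gen_two_domain_beads(seed = 1)
  cur <- debye_curve(m, seq(0.004, 0.3, length.out = 300))
  # elongated particle: use the conservative q*Rg < 1.0 cut
  g <- guinier_rg(cur, qmax_rg = 1.0)
  pr <- pr_from_beads(m)
  expect_equal(g$rg, pr$rg, tolerance = 0.05)
})
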