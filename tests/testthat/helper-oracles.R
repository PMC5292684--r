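# Independent oracle implementations, written as literal transcriptions of
# the textbook expressions and kept free of any package internals.

# Lipari-Szabo J(omega) for the single-timescale model, SI units throughout.
oracle_j <- function(omega, s2, tau_m_s, tau_e_s) {
  if (tau_e_s > 0) {
    tau <- 1 / (1 / tau_m_s + 1 / tau_e_s)
    second <- (1 - s2) * tau / (1 + (omega * tau)^2)
  } else second <- 0
  (2 / 5) * (s2 * tau_m_s / (1 + (omega * tau_m_s)^2) + second)
}

# 15N R1/R2/NOE from dipolar + CSA relaxation, literal double-checked forms.
oracle_rates <- function(s2, tau_m_ns, tau_e_ps, rex, field_mhz,
                         r_nh = 1.02e-10, csa = -160e-6) {
  gH <- 2.6752218744e8
  gN <- -2.7126e7
  hbar <- 1.054571817e-34
  mu0 <- 4 * pi * 1e-7
  wH <- 2 * pi * field_mhz * 1e6
  wN <- wH * gN / gH
  dd <- mu0 * hbar * gH * gN / (4 * pi * r_nh^3)
  c2 <- (wN * csa)^2 / 3
  tm <- tau_m_ns * 1e-9
  te <- tau_e_ps * 1e-12
  J <- function(w) oracle_j(abs(w), s2, tm, te)
  R1 <- dd^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- dd^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                      6 * J(wH + wN)) +
    c2 / 6 * (4 * J(0) + 3 * J(wN)) + rex * (field_mhz / 600)^2
  NOE <- 1 + dd^2 / 4 * (gH / gN) * (6 * J(wH + wN) - J(wH - wN)) / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}

# O(N^2) literal Debye double sum.
oracle_debye <- function(coords, q) {
  n <- nrow(coords)
  vapply(q, function(qi) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      s <- s + if (d == 0 || qi == 0) 1 else sin(qi * d) / (qi * d)
    }
    s
  }, numeric(1))
}

# Closed-form Langmuir 1:1 association trace.
oracle_langmuir <- function(t, k_on, k_off, r_max, conc) {
  kobs <- k_on * conc + k_off
  req <- r_max * k_on * conc / kobs
  req * (1 - exp(-kobs * t))
}
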