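# Shared small fixtures, built in code at test time.

fig5b_concentrations <- c(0.312, 0.625, 1.25, 2.5, 5, 10, 20) * 1e-9

default_kin <- function() kinetic_params(k_on = 1.8e8, k_off = 2e-4,
                                         r_max = 1000, k_t = 6e9)

# calibrated two-domain relaxation protein shared across NMR tests
two_domain_protein <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mot <- synthetic_protein_motions(n_ntd = 40, n_ctd = 45, n_rex = 16,
                                       seed = 11)
      cache <<- list(
        motions = mot,
        tumbling = c(
          NTD = calibrate_tm_to_ratio(mot[mot$domain == "NTD", ], 12.0, 600),
          CTD = calibrate_tm_to_ratio(mot[mot$domain == "CTD", ], 17.2, 600)))
    }
    cache
  }
})
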