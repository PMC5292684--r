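#!/usr/bin/env Rscript
# Generate the synthetic instrument files every downstream analysis step
# consumes: multi-concentration sensorgrams, a two-field 15N relaxation
# table, a two-lobe bead model with its scattering curve, and a panel of
# DNA-release melting curves. All generators are seeded; rerunning this
# script reproduces the files bit for bit.

suppressPackageStartupMessages(library(decorakin))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

## SPR: the 7-concentration design (0.312-20 nM), transport-limited regime
kin <- kinetic_params(k_on = 1.8e8, k_off = 2e-4, r_max = 1000, k_t = 6e9)
sgs <- gen_sensorgram_series(kin, noise = noise_spec(sd = 0.5, seed = 101))
write_sensorgram_csv(sgs, "results/inputs/sensorgrams.csv")
cat("sensorgrams.csv:", length(sgs), "curves,",
    nrow(sgs[[1]]), "points each\n")

## NMR: 85-residue two-domain protein, domains calibrated to mean T1/T2
## of 12.0 (NTD) and 17.2 (CTD) at 600 MHz, 16 exchange-bearing residues
mot <- synthetic_protein_motions(n_ntd = 40, n_ctd = 45, n_rex = 16,
                                 seed = 102)
tumb <- c(NTD = calibrate_tm_to_ratio(mot[mot$domain == "NTD", ], 12.0, 600),
          CTD = calibrate_tm_to_ratio(mot[mot$domain == "CTD", ], 17.2, 600))
cat(sprintf("tumbling: NTD %.2f ns, CTD %.2f ns\n",
            tumb[["NTD"]], tumb[["CTD"]]))
ds <- gen_relaxation_dataset(mot, tumb, fields = c(600, 700), rel_sd = 0.02,
                             noe_sd = 0.02, replicates = 2, seed = 103)
write_relaxation_tsv(ds, "results/inputs/relaxation.tsv")
utils::write.table(mot, "results/inputs/motions_truth.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("relaxation.tsv:", nrow(ds), "records\n")

## SAXS: 75+75 pseudo-residue two-lobe model and its Debye curve
model <- gen_two_domain_beads(seed = 104)
write_beads_xyz(model, "results/inputs/beads.xyz")
curve <- debye_curve(model, seq(0.008, 0.5, length.out = 500))
curve$sigma <- 0.02 * curve$I
write_saxs_dat(curve, "results/inputs/saxs_ideal.dat")
cat("beads.xyz:", nrow(model$coords), "beads\n")

## Melt: wt vs decoration-less phage, 300 mM NaCl panel, quadruplicates
midpoints <- list(acetate_pH5 = c(wt = 53.8, ddec = 47.5),
                  hepes_pH8.2 = c(wt = 60.3, ddec = 56.1))
i <- 0
for (cond in names(midpoints)) for (ph in c("wt", "ddec")) for (rep in 1:4) {
  i <- i + 1
  mc <- gen_melt_curve(midpoints[[cond]][[ph]],
                       noise = noise_spec(sd = 10, seed = 500 + i),
                       condition = list(phage = ph, condition = cond,
                                        replicate = rep))
  write_melt_csv(mc, sprintf("results/inputs/melt_%s_%s_r%d.csv",
                             cond, ph, rep))
}
cat("melt curves:", i, "files\n")

## Lattice: deterministic hexamer adjacency
write_lattice_edges(build_capsid_graph("icosa-net"),
                    "results/inputs/lattice_edges.tsv")
cat("done\n")
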