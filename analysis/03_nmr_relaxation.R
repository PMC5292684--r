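#!/usr/bin/env Rscript
# Model-free analysis of the synthetic two-domain relaxation data:
# per-domain tumbling from trimmed T1/T2, per-residue model selection
# (M1-M5, AICc), Monte-Carlo errors for exchange terms, exchange census.

suppressPackageStartupMessages(library(decorakin))
dir.create("results", showWarnings = FALSE)

ds <- read_relaxation_tsv("results/inputs/relaxation.tsv")
truth <- utils::read.delim("results/inputs/motions_truth.tsv")

avg <- domain_average_t1t2(ds)
cat(sprintf("mean T1/T2: NTD %.2f, CTD %.2f\n", avg[["NTD"]], avg[["CTD"]]))

tumb <- estimate_tm_from_ratio(ds)
for (d in names(tumb))
  cat(sprintf("estimated tau_m (%s): %.2f ns\n", d, tumb[[d]]$tau_m))

fits <- fit_dataset(ds, tumb, mc_n = 100, seed = 7)
utils::write.table(fits, "results/modelfree_fits.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat("\nmodel selection:\n")
print(table(fits$model))

flagged <- flag_exchange(fits, min_rex = 0.5, require_significance = TRUE)
cat("\nresidues with significant exchange:", length(flagged), "\n")
hit <- intersect(flagged, truth$residue[truth$rex > 0])
cat("of which truly exchange-bearing:", length(hit), "of",
    sum(truth$rex > 0), "\n")

m <- merge(fits, truth, by = "residue", suffixes = c("_fit", "_true"))
cat(sprintf("median |S2 error| = %.3f; median |Rex error| = %.2f /s\n",
            median(abs(m$s2_fit - m$s2_true)),
            median(abs(m$rex_fit[m$rex_true > 0] -
                         m$rex_true[m$rex_true > 0]))))
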