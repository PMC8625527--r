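#!/usr/bin/env Rscript
# Stage 3: build the synthetic GWAS summary-statistic triplet.
#
# Emulates the inputs of a two-step mediation MR: an exposure (dietary
# supplementation proxy), a mediator (gut-microbiome abundance) and an
# outcome (blood lipid level). Step 1 has a true causal effect of 0.4
# (exposure -> mediator), step 2 of 0.5 (mediator -> outcome), so the
# mediated effect is 0.20. Fifty strong instruments per step with GWAS-scale
# standard errors (n = 100,000 per trait); 10% of SNPs are palindromic to
# exercise harmonization. Tables land under results/data/.

library(simpomr)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg1 <- gwas_sim_config(n_snps = 50, instrument_strength = c(0.3, 0.1),
                        theta = 0.4, frac_palindromic = 0.1,
                        seed = 20260903)
cfg2 <- gwas_sim_config(n_snps = 50, instrument_strength = c(0.3, 0.1),
                        theta = 0.5, frac_palindromic = 0.1,
                        seed = 20260904)
tri <- simulate_gwas_triplet(cfg1, cfg2)

write_tsv(tri$exposure, file.path(out, "exposure_gwas.tsv"))
write_tsv(tri$mediator, file.path(out, "mediator_gwas.tsv"))
write_tsv(tri$outcome, file.path(out, "outcome_gwas.tsv"))

cat("Simulated GWAS triplet:", nrow(tri$exposure), "exposure,",
    nrow(tri$mediator), "mediator,", nrow(tri$outcome), "outcome records\n")
cat("True effects: theta1 =", tri$truth$theta1, ", theta2 =",
    tri$truth$theta2, "; mediated =", tri$truth$mediated_effect, "\n")
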