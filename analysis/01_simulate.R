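#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Writes, under results/synthetic/, the three CSV inputs the downstream
# steps consume: transwell transport time courses (three replicates per
# compound, 5 % lognormal measurement noise, 5 % cell sequestration),
# differentiation plate counts (three 24-well experiments per compound)
# and 5-day viability curves. Ground truth mirrors the six-triazole case
# study's parameter ranges (Papp 3-39 x 1e-6 cm/s, BMC50 1.8-11.4 uM)
# plus the freely transported reference compound.

library(devtoxrank)

seed <- 42
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

truth <- default_cohort_truth()
write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)

cfg <- transwell_config()
coh <- simulate_cohort(truth, cfg, n_replicates = 3, cv = 0.05, seed = seed)

write_transport_csv(coh$timecourses, file.path(out_dir, "transport.csv"))
write_plate_csv(unlist(coh$runs, recursive = FALSE),
                file.path(out_dir, "plates.csv"))

# 5-day viability: benign curves except one compound mirroring the most
# cytotoxic case-study profile (viability ~10 % at 60 uM)
viab <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  cid <- truth$compound[i]
  if (!is.finite(truth$bmc50[i])) return(NULL)
  ec50 <- if (cid == "cmpF") 25 else 300 # cmpF: strong 5-day cytotoxicity
  conc <- c(0.2, 1, 3, 10, 30, 60)
  mu <- 5 + 95 / (1 + (conc / ec50)^1.8)
  data.frame(compound = cid, exposure_days = 5, concentration_uM = conc,
             viability_percent = round(pmax(mu, 0), 1))
}))
write.csv(viab, file.path(out_dir, "viability.csv"), row.names = FALSE)

# in vivo ordering implied by the true corrected BMC (most toxic first)
tr <- truth[is.finite(truth$bmc50), ]
tr$corrected <- tr$bmc50 /
  (tr$papp / truth$papp[truth$compound == "reference"])
writeLines(c("# true corrected-potency ordering, most toxic first",
             tr$compound[order(tr$corrected)]),
           file.path(out_dir, "invivo_ranking.txt"))

cat("Synthetic cohort written to", out_dir, "\n")
cat(sprintf("  %d transport time courses, %d differentiation runs, %d viability curves\n",
            length(coh$timecourses), length(unlist(coh$runs, FALSE)),
            length(unique(viab$compound))))
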