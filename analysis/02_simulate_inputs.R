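#!/usr/bin/env Rscript
# Stage 2: generate the default synthetic input bundle (200 miRNAs, 2000
# mRNAs, 50 lncRNAs, 3 samples per phase, 10 planted triplets over 2
# sponge lncRNAs) together with its ground-truth manifest, so the whole
# cascade can be exercised and audited without any external download.

library(cernet)

bundle <- simulate_cerna_bundle(seed = 42L)
paths <- write_cerna_bundle(bundle, "results/synthetic_inputs")

cat("wrote synthetic inputs:\n")
for (nm in names(paths)) cat(sprintf("  %-12s %s\n", nm, paths[[nm]]))
cat(sprintf("planted: %d up-miRNAs, %d down-mRNAs, %d down-lncRNAs, %d triplets\n",
            length(bundle$truth$up_mirnas), length(bundle$truth$down_mrnas),
            length(bundle$truth$down_lncrnas), nrow(bundle$truth$triplets)))
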