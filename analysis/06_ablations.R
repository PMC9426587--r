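#!/usr/bin/env Rscript
# Ablation experiments on the unified trichome's O2-management machinery:
#  - no AET: all electrons run the linear O2-evolving pathway, so
#    photosynthetic O2 production jumps, respiratory protection has to work
#    harder, and growth collapses;
#  - no RP: without respiratory protection the intracellular O2 never drops
#    below ambient and N2 fixation is nearly abolished.

library(trichodiel)
dir.create("results", showWarnings = FALSE)

aet <- ablate_aet_run()
cat("Turning off AET:\n")
cat(sprintf("  O2 production %+.0f%%, RP carbon %+.0f%%, growth %+.0f%%\n",
            100 * aet$rel_change[["o2_production"]],
            100 * aet$rel_change[["rp_C"]],
            100 * aet$rel_change[["G"]]))

rp <- ablate_rp_run()
cat("Turning off respiratory protection:\n")
cat(sprintf("  N2 fixation %+.0f%%, growth %+.0f%%, minimal O2 %.3f mol m-3\n",
            100 * rp$rel_change[["gross_N"]], 100 * rp$rel_change[["G"]],
            rp$ablated$integrals$O2_min))

jsonlite::write_json(
  list(ablate_AET = as.list(aet$rel_change),
       ablate_RP = as.list(rp$rel_change),
       ablate_RP_O2_min = rp$ablated$integrals$O2_min),
  "results/ablations.json", auto_unbox = TRUE, digits = NA
)
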