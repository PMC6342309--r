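#!/usr/bin/env Rscript
# Step 1 — phantom validation of the quantification engine.
#
# Generates a matrix of synthetic three-slice lung phantoms with planted
# topology (k low-attenuation components, m enclosed normal islands per
# slice), runs the full quantification, and tabulates planted vs
# recovered (b0, b1) and LAA%. Writes results/phantom_topology.csv.

suppressPackageStartupMessages(library(heqct))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (k in 0:10) for (m in 0:min(k, 5)) {
  ph <- generate_phantom(phantom_spec(n_components = k, n_enclosed = m,
                                      seed = 9000 + 17 * k + m))
  q <- quantify_patient(ph$volume, ph$masks)
  rows[[length(rows) + 1]] <- data.frame(
    k = k, m = m,
    b0_planted = ph$truth$b0_total, b0_recovered = unname(q$b0["-880"]),
    b1_planted = ph$truth$b1_total, b1_recovered = unname(q$b1["-880"]),
    laa_planted_pct = 100 * ph$truth$laa_fraction,
    laa_recovered_pct = unname(q$laa_pct["-880"]),
    n_regenerated = ph$n_regenerated)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/phantom_topology.csv", row.names = FALSE)

exact <- with(tab, b0_planted == b0_recovered & b1_planted == b1_recovered &
                abs(laa_planted_pct - laa_recovered_pct) < 1e-9)
cat(sprintf("phantoms: %d specs, exact topology + LAA recovery in %d (%.0f%%)\n",
            nrow(tab), sum(exact), 100 * mean(exact)))
cat(sprintf("slices regenerated by the exact-recovery guard: %d\n",
            sum(tab$n_regenerated)))
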