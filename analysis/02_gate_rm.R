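#!/usr/bin/env Rscript
# Gate each simulated course from its 0 h samples and assemble the pooled
# relative-movement series. Writes per-course gate parameters, the RM
# series as TSV, and a bivariate cytogram of the 0 h root-like sample.
suppressPackageStartupMessages(library(rmphase))

for (course in c("root_like", "arrest_like")) {
  mpath <- file.path("results/sim", course, "manifest.yaml")
  tc <- load_manifest(mpath)
  series <- assemble_series(tc)
  write_rm_series(series, file.path("results", paste0("rm_", course, ".tsv")))
  gates <- attr(series, "gates")
  write_gates(gates[["1"]], file.path("results", paste0("gates_", course, ".json")))
  message(sprintf("%s: %d RM points; replicate-1 gates: G1 [%.0f, %.0f], G2/M [%.0f, %.0f]",
                  course, nrow(series),
                  gates[["1"]]$g1_box[1], gates[["1"]]$g1_box[2],
                  gates[["1"]]$g2m_box[1], gates[["1"]]$g2m_box[2]))
  if (course == "root_like") {
    pdf("results/cytogram_t0.pdf", width = 5, height = 4)
    print(plot_cytogram(tc$entries[[1]], gates[["1"]]))
    dev.off()
  }
}
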