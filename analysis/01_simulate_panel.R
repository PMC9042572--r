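#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel.
#
# Emulates the study conditions: 3 healthy controls sampled for 24 h with
# regular ultradian pulsatility and circadian-modulated amplitude, and 9
# post-surgical subjects (3 per disruption regime) sampled for 12 h, with
# cytokine responses added to the surgical subjects. Writes the panel as
# canonical long-format CSV plus a JSON manifest of specs and seeds.

suppressPackageStartupMessages(library(hpadyn))

seed <- 20260922L
panel <- gen_panel(n_per_regime = 3, seed = seed, cytokines = TRUE)

dir.create("results", showWarnings = FALSE)
write_panel_csv(panel, "results/panel.csv")
manifest <- list(seed = seed, n_per_regime = 3,
                 regimes = c("control", "two_pulse", "multiple_pulse", "single_pulse"),
                 noise_sd_frac = 0.05,
                 subjects = vapply(panel, `[[`, character(1), "subject_id"))
jsonlite::write_json(manifest, "results/panel_manifest.json", auto_unbox = TRUE)

message(sprintf("wrote %d subjects to results/panel.csv", length(panel)))
for (p in panel) {
  message(sprintf("  %s: ACTH AUC %.0f ng h/l, cortisol AUC %.0f nmol h/l",
                  p$subject_id,
                  area_under_curve(p$acth, 0, 720),
                  area_under_curve(p$cortisol, 0, 720)))
}
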