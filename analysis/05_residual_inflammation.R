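#!/usr/bin/env Rscript
# Stage 5: inflammation versus model-residual correlation analysis.
#
# PCA over the pooled post-surgery cytokine trajectories identifies the
# dominant mediators; each surgical subject's cortisol is then re-fit under
# the fixed-sensitivity/fixed-Hill scenario and the z-scored residual error
# is correlated with each mediator and with additive combinations. Rows of
# the resulting matrix are subjects, mirroring a correlation heat map.

suppressPackageStartupMessages(library(hpadyn))

panel <- read_panel_csv("results/panel.csv")
surg <- Filter(function(p) length(p$cytokines) > 0, panel)

pca <- cytokine_pca(surg)
message(sprintf("PC1 explains %.0f%% of cytokine variance; dominant mediators: %s",
                100 * pca$variance_explained[1],
                paste(head(pca$dominant, 2), collapse = ", ")))
jsonlite::write_json(list(variance_explained = pca$variance_explained,
                          dominant = pca$dominant,
                          loadings = as.data.frame(pca$loadings)),
                     "results/cytokine_pca.json", auto_unbox = TRUE, digits = NA)

res <- panel_residuals(surg, n_draws = 10000, keep = 10, seed = 47,
                       scenario = "fixed_both")
rep <- residual_cytokine_correlations(res, surg)
m <- rep$correlations
write.csv(data.frame(subject_id = rownames(m), m, check.names = FALSE),
          "results/residual_correlations.csv", row.names = FALSE)

message("residual-mediator correlation matrix (subjects x combos):")
print(round(m, 2))
strongest <- apply(abs(m), 1, max, na.rm = TRUE)
by_reg <- tapply(strongest, sub("_s[0-9]+$", "", rownames(m)), mean)
message("mean strongest |r| per subject by regime: ",
        paste(names(by_reg), round(by_reg, 2), sep = "=", collapse = ", "))
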