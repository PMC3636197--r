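#!/usr/bin/env Rscript
# Chemical-space comparison of a synthetic natural-product library and a
# synthetic approved-drug library: separate unscaled PCA per library, then
# cross-projection and percentile-box overlap.

suppressMessages(library(npnet))
dir.create("results/chemspace", recursive = TRUE, showWarnings = FALSE)
seed <- 1234

np_cfg <- generator_config(seed = seed, n_compounds = 5000)
drug_cfg <- generator_config(seed = seed + 1, n_compounds = 1380,
                             descriptor_params = drug_descriptor_params)
np <- as.matrix(gen_descriptor_table(np_cfg)$descriptors[DESCRIPTOR_COLS])
dr <- as.matrix(gen_descriptor_table(drug_cfg)$descriptors[DESCRIPTOR_COLS])

np_pca <- fit_pca(np, k = 3)
dr_pca <- fit_pca(dr, k = 3)
message("NP library PC1-3 variance fractions: ",
        paste(sprintf("%.3f", np_pca$explained_variance_fraction), collapse = ", "))
message("drug library PC1-3 variance fractions: ",
        paste(sprintf("%.3f", dr_pca$explained_variance_fraction), collapse = ", "))
message("unscaled descriptors put nearly all variance on PC1, which is ",
        "dominated by molecular weight; this is the expected behavior of ",
        "covariance PCA on raw descriptor units")

# common frame: project both libraries into the NP space
s_np <- pca_project(np_pca, np)
s_dr <- pca_project(np_pca, dr)
ov <- chemspace_overlap(s_np, s_dr)
message(sprintf(
  "overlap: %.1f%% of NPs inside the drug box, %.1f%% of drugs inside the NP box",
  100 * ov$fraction_a_in_b, 100 * ov$fraction_b_in_a))

write.csv(data.frame(library = "np", s_np), "results/chemspace/np_scores.csv",
          row.names = FALSE)
write.csv(data.frame(library = "drug", s_dr), "results/chemspace/drug_scores.csv",
          row.names = FALSE)
jsonlite::write_json(
  list(np_variance = np_pca$explained_variance_fraction,
       drug_variance = dr_pca$explained_variance_fraction,
       overlap = ov),
  "results/chemspace/overlap.json", auto_unbox = TRUE, digits = NA)
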