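#!/usr/bin/env Rscript
# Docking-based drug-target network: synthetic docking campaign with
# planted strong binders, screening hit rates at the permissive (7) and
# stringent (9) cutoffs, and topology of the stringent network.

suppressMessages(library(npnet))
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
seed <- 1234

cfg <- generator_config(seed = seed)  # 2884 x 243, 10% planted binders
dk <- gen_docking_scores(cfg)
message(sprintf("scored %d compound-target pairs (%d planted strong binders)",
                nrow(dk$scores), nrow(dk$truth)))

hr7 <- hit_rate(dk$scores, 7, dk$reference)
hr9 <- hit_rate(dk$scores, 9, dk$reference)
message(sprintf("hit rate: %.1f%% above score 7, %.1f%% above score 9 (both also above the reference ligand)",
                100 * hr7, 100 * hr9))

g <- build_network(dk$scores, threshold = 9, reference_scores = dk$reference)
st <- network_stats(g)
message(sprintf(
  "stringent DTN: %d compounds, %d targets, %d edges in %d components; giant %.1f%%",
  st$n_compounds, st$n_targets, st$n_edges, st$n_components,
  100 * st$giant_fraction))
message("the stringent synthetic network is nearly all planted singleton ",
        "links, so it fragments far more than a real campaign would")

recovered <- mean(dk$truth$compound_id %in% igraph::V(g)$name)
message(sprintf("planted binder recovery at the stringent cutoff: %.1f%%",
                100 * recovered))

write_network_graphml(g, "results/network/dtn_docking.graphml")
jsonlite::write_json(
  c(st, list(hit_rate_screening = hr7, hit_rate_network = hr9,
             planted_recovery = recovered)),
  "results/network/dtn_docking_stats.json", auto_unbox = TRUE, digits = NA)
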