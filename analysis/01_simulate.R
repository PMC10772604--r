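#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A 2-degree, 12-level synthetic ocean climatology (zonal-mean temperature
# and pO2 with a low-latitude oxygen-minimum zone) stands in for the
# gridded hydrography, and 20 synthetic species with known (A_eco,
# E_eco_ref, dEdT) stand in for the occurrence database. Everything
# downstream is checked against this ground truth.

suppressPackageStartupMessages(library(aerotraits))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 7

env <- make_ocean(resolution_deg = 2, seed = seed)
print(env)
write_env_grid(env, file.path(out, "grid"))

asm <- simulate_assemblage(env, n_species = 20, n_presence = 500,
                           noise_rate = 0.05, seed = seed)
cat(sprintf("simulated %d species, %d occurrence records (5%% label noise)\n",
            nrow(asm$truth), nrow(asm$occurrences)))
write_occurrences(asm$occurrences, file.path(out, "occurrences.csv"))
write.csv(asm$truth, file.path(out, "truth.csv"), row.names = FALSE,
          quote = FALSE)

# a random topology with Grafen branch lengths (rho = 0.4) for the
# phylogenetic stage; tips are the synthetic species
tree <- aerotraits:::.with_seed(seed,
                                ape::rtree(20,
                                           tip.label = asm$truth$species_id))
tree <- grafen_branch_lengths(tree, rho = 0.4)
write_newick(tree, file.path(out, "tree.nwk"))

write_manifest(file.path(out, "manifest.json"),
               config = list(stage = "simulate", seed = seed,
                             resolution_deg = 2, n_species = 20,
                             n_presence = 500, noise_rate = 0.05),
               counts = list(records = nrow(asm$occurrences)))
cat("stage 1 outputs written to", out, "\n")
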