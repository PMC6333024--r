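#!/usr/bin/env Rscript
# Stage 1: simulate the breeding population.
# 13 families (4 resistant backcross, 5 susceptible backcross, 4 F2) of 15
# plants from 3 + 3 founders; a SNP panel over 11 chromosomes plus "chr0"
# and a UNIGENE group, with injected missing calls and invariant "false
# SNP" markers; 18 traits (11 continuous, 7 score-scale) over 3 years.
source("analysis/00_common.R")

ped <- simulate_pedigree(seed = MASTER_SEED)
msg("pedigree: %d individuals in %d families (%s)",
    nrow(ped$individuals), nrow(ped$families),
    paste(names(table(ped$families$type)), table(ped$families$type),
          sep = "=", collapse = ", "))

panel <- simulate_genotypes(ped, n_markers = N_MARKERS,
                            missing_rate = 0.02, invariant_fraction = 0.02,
                            seed = MASTER_SEED + 1L)
msg("panel: %d x %d markers, %d forced invariant, %.2f%% missing calls",
    nrow(panel$genotypes), ncol(panel$genotypes),
    length(panel$invariant_markers), 100 * mean(is.na(panel$genotypes)))

specs <- lapply(default_trait_specs(), function(s) {
  s$n_qtl <- min(s$n_qtl, N_MARKERS); s
})
sim <- simulate_phenotypes(panel, ped, specs, seed = MASTER_SEED + 2L)
msg("phenotypes: %d records over %d traits", nrow(sim$phenotypes),
    length(unique(sim$phenotypes$trait)))

write_panel(panel, file.path(DATA_DIR, "genotypes.tsv"),
            file.path(DATA_DIR, "marker_map.tsv"))
write.csv(sim$phenotypes, file.path(DATA_DIR, "phenotypes.csv"),
          row.names = FALSE)
tbv <- do.call(rbind, lapply(names(sim$truth), function(tr)
  data.frame(trait = tr, individual = names(sim$truth[[tr]]$true_breeding_values),
             tbv = unname(sim$truth[[tr]]$true_breeding_values))))
write.csv(tbv, file.path(DATA_DIR, "true_breeding_values.csv"),
          row.names = FALSE)
write.csv(ped$individuals, file.path(DATA_DIR, "individuals.csv"),
          row.names = FALSE)
msg("wrote %s/{genotypes.tsv,marker_map.tsv,phenotypes.csv,...}", DATA_DIR)
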