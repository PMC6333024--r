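#!/usr/bin/env Rscript
# Stage 5: derived breeding-design statistics and the density experiment.
# Per trait: selective accuracy r_gg = r_gy/sqrt(ha2), effective QTL
# number, required population sizes for target accuracies 0.5..0.9, and
# selective efficiency of GS at 12- and 24-year horizons against a 24-year
# phenotypic cycle. The marker-density response is run for two
# representative traits.
source("analysis/00_common.R")

comps <- read.csv(file.path(OUT_DIR, "variance_components.csv"))
cvres <- read.csv(file.path(OUT_DIR, "cv_results.csv"))
stats_list <- lapply(seq_len(nrow(cvres)), function(i) {
  j <- match(cvres$trait[i], comps$trait)
  list(trait = cvres$trait[i], h2_phen = comps$h2_phen[j],
       r_yy = comps$r_yy[j], ha2 = cvres$ha2[i], r_gy = cvres$r_gy[i],
       sd_r = cvres$sd_r[i], b = cvres$b[i], sd_b = cvres$sd_b[i])
})

tab <- build_tables(stats_list, n = 195, targets = c(0.5, 0.6, 0.7, 0.8, 0.9),
                    L_f = 24, L_GS = c(12, 24))
write.csv(tab, file.path(OUT_DIR, "derived_stats.csv"), row.names = FALSE)
fmt <- format_derived_stats(tab)
write.csv(fmt, file.path(OUT_DIR, "derived_stats_formatted.csv"),
          row.names = FALSE)
print(fmt[, c("trait", "h2_phen", "r_yy", "ha2", "r_gy", "b", "r_gg",
              "n_qtl", "Ni_0.7", "Ef_12", "Ef_24")], row.names = FALSE)
n_beat <- sum(tab$Ef_12 > 1, na.rm = TRUE)
msg("GS beats phenotypic selection per unit time (12-year horizon) for %d of %d traits",
    n_beat, nrow(tab))

# density response for a high- and a mid-accuracy trait
panel <- read_panel(file.path(DATA_DIR, "genotypes_qc.tsv"),
                    file.path(DATA_DIR, "marker_map_qc.tsv"))
corr <- read.csv(file.path(DATA_DIR, "corrected_phenotypes.csv"),
                 check.names = FALSE)
sizes <- unique(pmin(c(500, 1000, 2000, 3000, ncol(panel$genotypes)),
                     ncol(panel$genotypes)))
for (tr in intersect(c("PH", "Y"), names(corr))) {
  y <- setNames(corr[[tr]], corr$individual)
  h2 <- cvres$ha2[match(tr, cvres$trait)]
  de <- density_experiment(panel, y, sizes = sizes, h2 = h2,
                           seed = MASTER_SEED + 4L)
  write.csv(de, file.path(OUT_DIR, paste0("density_", tr, ".csv")),
            row.names = FALSE)
  msg("density response for %s: r_gy %s", tr,
      paste(sprintf("%.2f@%d", de$r_gy, de$size), collapse = ", "))
}
msg("done; tables under %s/", OUT_DIR)
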