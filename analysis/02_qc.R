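#!/usr/bin/env Rscript
# Stage 2: SNP quality control.
# Call rate >= 90%, MAF >= 5% (both inclusive), and removal of markers with
# no genetic variance among individuals ("false SNPs"); per-chromosome
# retention is reported. The advisory critical MAF 1/(2N) is printed for
# comparison with the conventional 5% threshold.
source("analysis/00_common.R")

panel <- read_panel(file.path(DATA_DIR, "genotypes.tsv"),
                    file.path(DATA_DIR, "marker_map.tsv"))
msg("critical MAF at N = %d individuals: %.4f (filter uses 0.05)",
    nrow(panel$genotypes), maf_critical_level(nrow(panel$genotypes)))

qc <- run_qc(panel, cr_threshold = 0.90, maf_threshold = 0.05)
print(qc$report)

write_qc_report(qc$report, file.path(OUT_DIR, "qc_report.json"))
write_panel(qc$panel, file.path(DATA_DIR, "genotypes_qc.tsv"),
            file.path(DATA_DIR, "marker_map_qc.tsv"))
msg("retained %d of %d markers (%.2f%% reduction)",
    qc$report$n_retained, qc$report$n_input, qc$report$reduction_percent)
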