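#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study all later stages analyse.
#
# The scenario emulates a two-arm FFPE cohort (30 tumor / 30 control)
# measured by triplicate qPCR across 4 runs with a pooled inter-run
# calibrator, plus a small-RNA-seq experiment (8 + 8 pools) and three mock
# differential-expression tables. Planted truth: candidate controls
# miR-ref-01/-02 are stable (0.45-cycle noise floor), the other candidates
# carry 0.9-1.5 cycles of per-gene noise, miR-ref-05 is pushed above the
# detection limit in one sample, and targets miR-tgt-01/-02/-03 change
# 4-fold, 4-fold and 8-fold down.

library(mirnorm)

seed <- 7L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(seed = seed)

write_ct_dataset(study$ct, file.path(out, "qpcr"))
write_matrix_tsv(study$counts$counts, file.path(out, "counts.tsv"))
write_table_tsv(data.frame(sample_id = names(study$counts$groups),
                           group = study$counts$groups),
                file.path(out, "count_groups.tsv"))
write_table_tsv(study$counts$truth, file.path(out, "count_truth.tsv"))
for (m in names(study$de_tables)) {
  write_table_tsv(study$de_tables[[m]],
                  file.path(out, sprintf("de_%s.tsv", m)))
}
write_table_tsv(
  data.frame(gene = c(study$ec_genes, study$target_genes),
             role = rep(c("ec_candidate", "target"),
                        c(length(study$ec_genes),
                          length(study$target_genes))),
             planted_stable = c(study$ec_genes %in% study$stable_pair,
                                rep(NA, length(study$target_genes))),
             planted_fc = c(rep(NA, length(study$ec_genes)),
                            study$planted_fc)),
  file.path(out, "gene_roles.tsv")
)

cat(sprintf(
  "Simulated study (seed %d): %d genes x %d samples x %d replicates (qPCR),\n%d miRNAs x %d samples (counts), %d DE tables.\nPlanted stable pair: %s. Planted target FCs: %s.\n",
  seed, dim(study$ct$ct)[1], dim(study$ct$ct)[2], dim(study$ct$ct)[3],
  nrow(study$counts$counts), ncol(study$counts$counts),
  length(study$de_tables),
  paste(study$stable_pair, collapse = " + "),
  paste(sprintf("%s=%.3g", names(study$planted_fc), study$planted_fc),
        collapse = ", ")
))
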