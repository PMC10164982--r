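#!/usr/bin/env Rscript
# Stage 2: select the endogenous control from the qPCR data.
#
# Replicates are collapsed (mean of detected, QC flag at SD > 0.5 cycles),
# genes undetected in any cohort sample are discarded, run offsets are
# removed with the pooled inter-run calibrator, and single candidates plus
# all pairwise geometric-mean combinations are ranked by the four
# stability statistics aggregated RefFinder-style; candidates with
# CV > 200% over control samples are excluded.

library(mirnorm)

data_dir <- "results/data"
out <- "results"
dataset <- read_ct_dataset(file.path(data_dir, "qpcr"))
roles <- read.delim(file.path(data_dir, "gene_roles.tsv"))
ec_genes <- roles$gene[roles$role == "ec_candidate"]

collapsed <- collapse_replicates(dataset, max_sd = 0.5)
cohort <- collapsed$meta$sample_id[!collapsed$meta$is_calibrator]
det <- detection_filter(collapsed, limit = 40, samples = cohort)
cat(sprintf("Detection filter: %d/%d genes retained.\n",
            length(det$retained), nrow(collapsed$ct)))
if (nrow(det$discarded) > 0) {
  cat("  discarded:",
      paste(unique(det$discarded$gene), collapse = ", "), "\n")
}

cal <- interrun_calibrate(det$ct, collapsed$meta)
write_matrix_tsv(cal$ct, file.path(out, "ct_calibrated.tsv"))

ec_retained <- intersect(ec_genes, det$retained)
groups <- cal$meta$group
ec_ext <- make_combinations(cal$ct[ec_retained, ], k = 2)
report <- stability_report(ec_ext, groups = groups)
write_table_tsv(as.data.frame(report), file.path(out, "stability_report.tsv"))
write_table_tsv(attr(report, "genorm_v"), file.path(out, "genorm_v.tsv"))

ranking <- aggregate_ranks(report)
cvs <- cv_of_candidates(make_combinations(det$ct[ec_retained, ], k = 2),
                        collapsed$meta)
sel <- select_endogenous_control(ranking, cvs, cv_max = 200,
                                 stability_max = 5)
write_table_tsv(sel$verdicts, file.path(out, "ec_verdicts.tsv"))

n_excl <- sum(sel$verdicts$verdict == "excluded")
cat(sprintf(
  "Ranked %d candidates (%d singles + %d combinations); %d excluded by CV > 200%%.\nShortlist (stability value < 5): %s.\nSelected endogenous control: %s (stability value %.3f, CV %.1f%%).\n",
  nrow(sel$verdicts), length(ec_retained),
  nrow(sel$verdicts) - length(ec_retained), n_excl,
  paste(sel$shortlist, collapse = ", "),
  sel$selected,
  sel$verdicts$stability_value[sel$verdicts$gene == sel$selected],
  sel$verdicts$cv_percent[sel$verdicts$gene == sel$selected]
))
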