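#!/usr/bin/env Rscript
# Stage 4: relative quantification of the target miRNAs.
#
# Target Ct values are normalized to the selected endogenous control
# (delta-Ct; multi-gene controls enter as the per-sample geometric mean),
# referenced to the control-group mean (delta-delta-Ct), and converted to
# fold changes with the signed convention (ratios < 1 reported as negative
# reciprocals). Group differences are tested with Student's t-test or
# Mann-Whitney U depending on Shapiro-Wilk normality; significance needs
# p < 0.05 and |FC| >= 2.

library(mirnorm)

out <- "results"
cal_ct <- read_matrix_tsv(file.path(out, "ct_calibrated.tsv"))
verdicts <- read.delim(file.path(out, "ec_verdicts.tsv"))
roles <- read.delim("results/data/gene_roles.tsv")
meta <- read.delim("results/data/qpcr_meta.tsv")
groups <- meta$group[match(colnames(cal_ct), meta$sample_id)]

selected <- verdicts$gene[verdicts$verdict == "selected"]
normalizer <- strsplit(selected, "+", fixed = TRUE)[[1]]
targets <- intersect(roles$gene[roles$role == "target"], rownames(cal_ct))

dct <- delta_ct(cal_ct, normalizer)
res <- ddct_fold_change(dct$delta_ct[targets, , drop = FALSE], groups)
res <- classify_significance(res, p_max = 0.05, fc_min = 2)
write_table_tsv(as.data.frame(res), file.path(out, "expression.tsv"))
# per-sample log2 relative expression (-ddCt), the panel's feature space
write_matrix_tsv(-attr(res, "ddct"), file.path(out, "log2_rel_expr.tsv"))

cat(sprintf("Normalizer: %s. Targets quantified: %d.\n",
            selected, nrow(res)))
for (i in seq_len(nrow(res))) {
  cat(sprintf("  %s: FC %+.3f (p = %.3g, %s) -> %s\n",
              res$gene[i], res$fc_reported[i], res$p_value[i],
              res$test_used[i],
              ifelse(res$significant[i], res$direction[i],
                     "not significant")))
}
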