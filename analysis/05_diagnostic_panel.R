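#!/usr/bin/env Rscript
# Stage 5: fit the diagnostic panel on the significant miRNAs.
#
# A multiple logistic regression of group on the per-sample log2 relative
# expression of the significantly deregulated miRNAs; evaluated in-sample
# (as cohort studies of this design are) with a ROC curve, its AUC, and
# the confusion matrix at probability cutoff 0.5.

library(mirnorm)

out <- "results"
expr <- read.delim(file.path(out, "expression.tsv"))
feat_all <- read_matrix_tsv(file.path(out, "log2_rel_expr.tsv"))
meta <- read.delim("results/data/qpcr_meta.tsv")
groups <- meta$group[match(colnames(feat_all), meta$sample_id)]

panel_genes <- expr$gene[expr$significant]
features <- t(feat_all[panel_genes, , drop = FALSE])

fit <- fit_panel(features, groups)
roc <- roc_curve(fit$scores, groups)
conf <- confusion_at_cutoff(fit$scores, groups, cutoff = 0.5)

write_table_tsv(roc$points, file.path(out, "roc_points.tsv"))
jsonlite::write_json(
  list(features = panel_genes,
       coefficients = as.list(fit$coefficients),
       separation = fit$separation,
       auc = roc$auc,
       confusion = as.list(conf$confusion),
       sensitivity = conf$sensitivity,
       specificity = conf$specificity),
  file.path(out, "panel_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)

cat(sprintf(
  "Panel: %s.\nAUC = %.3f; at cutoff 0.5: TP=%d FP=%d TN=%d FN=%d;\nsensitivity %.2f%%, specificity %.2f%%.%s\n",
  paste(panel_genes, collapse = " + "), roc$auc,
  conf$confusion["TP"], conf$confusion["FP"], conf$confusion["TN"],
  conf$confusion["FN"], conf$sensitivity, conf$specificity,
  ifelse(fit$separation,
         "\n(Perfect separation detected; ridge-stabilized fit.)", "")
))
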