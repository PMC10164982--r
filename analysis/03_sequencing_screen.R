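#!/usr/bin/env Rscript
# Stage 3: sequencing-based screens.
#
# Zero-expression isoforms are discarded, counts are RPM-normalized, the
# normalizer screen keeps miRNAs with base mean >= 100 RPM and
# |log2FC| <= 2 and ranks them by |log2FC| (most group-invariant first),
# and the three mock differential-expression tables are intersected with a
# base-mean >= 100 consensus filter.

library(mirnorm)

data_dir <- "results/data"
out <- "results"
counts <- read_matrix_tsv(file.path(data_dir, "counts.tsv"))
storage.mode(counts) <- "integer"
groups <- read.delim(file.path(data_dir, "count_groups.tsv"))
groups <- setNames(groups$group, groups$sample_id)[colnames(counts)]

expr_f <- expression_filter(counts)
cat(sprintf("Expression filter: %d sequenced, %d silent, %d retained.\n",
            expr_f$n_input, expr_f$n_discarded, expr_f$n_retained))

rpm <- rpm_normalize(expr_f$counts)
write_matrix_tsv(rpm, file.path(out, "rpm.tsv"))

screen <- ec_candidate_screen(rpm, groups, base_min = 100, lfc_max = 2,
                              top_n = 5)
write_table_tsv(screen$table, file.path(out, "ec_screen.tsv"))
cat(sprintf(
  "Normalizer screen: %d/%d pass the base-mean and fold-change gates;\ntop 5 by |log2FC|: %s.\n",
  sum(!screen$table$discarded), nrow(screen$table),
  paste(screen$candidates, collapse = ", ")
))

de_files <- list.files(data_dir, pattern = "^de_.*\\.tsv$",
                       full.names = TRUE)
tables <- lapply(de_files, read.delim)
names(tables) <- sub("^de_(.*)\\.tsv$", "\\1", basename(de_files))
cons <- de_consensus(tables, base_min = 100, alpha = 0.05)
write_table_tsv(
  data.frame(id = cons$intersection,
             low_expression = cons$intersection %in%
               cons$dropped_low_expression),
  file.path(out, "de_consensus.tsv")
)
cat(sprintf(
  "DE consensus: per-method significant counts [%s]; intersection %d;\n%d dropped for base mean < 100; consensus set: %s.\n",
  paste(sprintf("%s=%d", names(cons$per_method), cons$per_method),
        collapse = ", "),
  length(cons$intersection), length(cons$dropped_low_expression),
  paste(cons$consensus, collapse = ", ")
))
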