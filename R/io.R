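# Plain-text (TSV/YAML/JSON) readers and writers for every pipeline artifact.
# Ct datasets are written wide: genes in rows, one column per
# sample-replicate ("<sample>_rep<i>"); undetected cells as "ND".

ND <- "ND"

#' Write / read a replicate-level Ct dataset as TSV
#'
#' Two files are produced: `<stem>_ct.tsv` (genes x sample-replicate
#' columns, undetected as `"ND"`) and `<stem>_meta.tsv` (`sample_id`,
#' `group`, `run`, `is_calibrator`).
#'
#' @param dataset a `ct_dataset`.
#' @param stem path stem (no extension).
#' @return `write_ct_dataset()` the two paths, invisibly;
#'   `read_ct_dataset()` a `ct_dataset`.
#' @export
write_ct_dataset <- function(dataset, stem) {
  arr <- dataset$ct
  wide <- do.call(cbind, lapply(seq_len(dim(arr)[3]), function(r) {
    m <- arr[, , r, drop = TRUE]
    colnames(m) <- sprintf("%s_rep%d", dimnames(arr)[[2]], r)
    m
  }))
  # interleave replicates per sample for readability
  ord <- as.vector(t(matrix(seq_len(ncol(wide)), ncol = dim(arr)[3])))
  wide <- wide[, ord, drop = FALSE]
  df <- data.frame(gene = rownames(wide), wide, check.names = FALSE)
  df[is.na(df)] <- ND
  ct_path <- paste0(stem, "_ct.tsv")
  meta_path <- paste0(stem, "_meta.tsv")
  write.table(df, ct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(ct = ct_path, meta = meta_path))
}

#' @rdname write_ct_dataset
#' @param detection_limit carried into the reconstructed dataset.
#' @export
read_ct_dataset <- function(stem, detection_limit = 40) {
  df <- read.delim(paste0(stem, "_ct.tsv"), check.names = FALSE,
                   colClasses = "character")
  meta <- read.delim(paste0(stem, "_meta.tsv"), check.names = FALSE)
  genes <- df$gene
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ND] <- NA
  storage.mode(vals) <- "double"
  parts <- regmatches(colnames(vals),
                      regexec("^(.*)_rep(\\d+)$", colnames(vals)))
  samples <- unique(vapply(parts, `[`, "", 2))
  n_rep <- max(as.integer(vapply(parts, `[`, "", 3)))
  arr <- array(NA_real_, dim = c(length(genes), length(samples), n_rep),
               dimnames = list(genes, samples, NULL))
  for (j in seq_along(parts)) {
    arr[, parts[[j]][2], as.integer(parts[[j]][3])] <- vals[, j]
  }
  meta$is_calibrator <- as.logical(meta$is_calibrator)
  meta$group <- ifelse(meta$group %in% c("", "NA"), NA_character_,
                       as.character(meta$group))
  structure(list(ct = arr, meta = meta, detection_limit = detection_limit,
                 truth = NULL),
            class = "ct_dataset")
}

#' Write / read a numeric feature-by-sample matrix as TSV
#'
#' First column `id`, one column per sample; `NA` written as `"ND"`.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  df[is.na(df)] <- ND
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ND] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
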