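#' Geometric mean
#'
#' Geometric mean of a positive numeric vector. Used for per-sample
#' normalization factors (BestKeeper index, multi-gene normalizers and
#' pseudo-gene combinations) and for RefFinder-style rank aggregation.
#'
#' @param x positive numeric vector.
#' @param na.rm drop `NA` values before averaging.
#' @return single numeric value.
#' @export
#' @examples
#' geom_mean(c(24, 26)) # sqrt(24 * 26)
geom_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0, na.rm = TRUE)) stop("geom_mean() requires positive values")
  exp(mean(log(x)))
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
# Keeps the generators deterministic without clobbering global reproducibility.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# shared argument checks
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (strict) x > lower else x >= lower)
  if (!ok) {
    stop(sprintf(
      "'%s' must be numeric and %s %s", name,
      if (strict) "greater than" else "at least", format(lower)
    ), call. = FALSE)
  }
  invisible(x)
}

stopifnot_matrix <- function(ct, min_genes = 1, min_samples = 1, what = "ct") {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", what),
         call. = FALSE)
  }
  if (nrow(ct) < min_genes) {
    stop(sprintf("'%s' needs at least %d genes, got %d", what, min_genes,
                 nrow(ct)), call. = FALSE)
  }
  if (ncol(ct) < min_samples) {
    stop(sprintf("'%s' needs at least %d samples, got %d", what, min_samples,
                 ncol(ct)), call. = FALSE)
  }
  invisible(ct)
}
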