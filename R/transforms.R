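# Shared matrix transforms: quantile normalization, unit-vector rows,
# Benjamini-Hochberg adjustment, the log2 zero-floor transform, the FROT QC
# metric, and correlation-by-stage-separation.

.grid_or_matrix <- function(x) if (inherits(x, "signal_grid")) x$values else as.matrix(x)

.rewrap <- function(x, values, units = NULL) {
  if (inherits(x, "signal_grid")) {
    out <- x
    out$values <- values
    if (!is.null(units)) out$units <- units
    out
  } else values
}

#' Quantile normalization across sample columns
#'
#' Every column's sorted values are replaced by the across-column mean of
#' sorted values (the reference distribution). Ties within a column receive
#' the mean of the reference quantiles they span.
#'
#' @param x numeric matrix or signal grid with >= 2 columns.
#' @return object of the same kind, quantile normalized. A single-column input
#'   is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  v <- .grid_or_matrix(x)
  if (ncol(v) < 2) {
    warning("quantile_normalize: single column, returned unchanged")
    return(x)
  }
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # ties share the mean of the reference quantiles assigned to their group
    ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  .rewrap(x, out)
}

#' Scale each row to a unit Euclidean vector
#'
#' Rows become \code{x / sqrt(sum(x^2))}, so overall signal level cannot
#' dominate downstream clustering. All-zero rows have no direction and are
#' dropped (with a warning).
#'
#' @param x numeric matrix or signal grid.
#' @return same kind of object with unit-norm rows (zero rows removed).
#' @export
unit_vector_rows <- function(x) {
  v <- .grid_or_matrix(x)
  norms <- sqrt(rowSums(v^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("unit_vector_rows: dropped %d all-zero rows", sum(zero)))
    v <- v[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  out <- v / norms
  if (inherits(x, "signal_grid")) {
    keep <- which(!zero)
    regions <- if (!is.null(x$regions)) x$regions[keep, , drop = FALSE]
    return(signal_grid(out, x$samples$tissue, x$samples$stage,
                       x$samples$replicate, regions = regions,
                       ids = x$ids[keep], units = x$units,
                       stage_levels = x$stage_levels))
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
}

#' log2 transform with zero floor
#'
#' Zeros are replaced by the smallest strictly positive value in the matrix
#' before taking log2, so the dynamic range is preserved without -Inf.
#'
#' @param x non-negative numeric matrix or signal grid.
#' @return same kind of object, log2 transformed.
#' @export
log2_with_zero_floor <- function(x) {
  v <- .grid_or_matrix(x)
  if (any(v < 0)) stop("negative values cannot be log2 transformed")
  pos <- v[v > 0]
  if (length(pos) == 0) stop("all-zero matrix has no detectable value")
  v[v == 0] <- min(pos)
  units <- if (inherits(x, "signal_grid")) {
    switch(x$units, RPKM = "log2RPKM", FPKM = "log2FPKM", x$units)
  } else NULL
  .rewrap(x, log2(v), units = units)
}

#' Fraction of reads overlapping TSSs (FROT)
#'
#' The ATAC library QC metric: reads within \code{flank} bp of any TSS,
#' divided by all reads. Windows are half-open \code{[tss - flank, tss + flank)}.
#'
#' @param reads data.frame(chrom, pos) of read positions.
#' @param tss data.frame(chrom, pos) of TSS positions.
#' @param flank window half-width in bp (default 1000).
#' @return fraction in [0, 1].
#' @export
frot <- function(reads, tss, flank = 1000) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1, flank > 0)
  read_iv <- intervals(reads$chrom, reads$pos, reads$pos + 1)
  mean(window_overlap(read_iv, tss, flank))
}

#' Sample-pair correlations grouped by developmental-stage separation
#'
#' Within each tissue, correlates every pair of sample columns and reports the
#' correlation together with the number of stages separating the pair
#' (0 for replicate pairs from the same stage). Pairs involving a constant
#' column are skipped with a warning.
#'
#' @param grid signal grid.
#' @param method "spearman" or "pearson".
#' @return data.frame(tissue, key_a, key_b, separation, correlation).
#' @export
correlation_by_separation <- function(grid, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "signal_grid"))
  sidx <- .stage_index(grid)
  out <- list()
  skipped <- 0L
  for (tis in unique(grid$samples$tissue)) {
    cols <- which(grid$samples$tissue == tis)
    if (length(cols) < 2) next
    for (ij in combn(cols, 2, simplify = FALSE)) {
      a <- grid$values[, ij[1]]; b <- grid$values[, ij[2]]
      if (sd(a) == 0 || sd(b) == 0) { skipped <- skipped + 1L; next }
      out[[length(out) + 1]] <- data.frame(
        tissue = tis,
        key_a = colnames(grid$values)[ij[1]],
        key_b = colnames(grid$values)[ij[2]],
        separation = abs(sidx[ij[1]] - sidx[ij[2]]),
        correlation = cor(a, b, method = method),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(sprintf("correlation_by_separation: skipped %d constant pairs", skipped))
  if (length(out) == 0) stop("need >= 2 usable samples in at least one tissue")
  do.call(rbind, out)
}
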