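# SignalGrid: a region-x-sample (or gene-x-sample) numeric matrix with the
# tissue/stage/replicate identity of every column. The container used for
# H3K27ac enrichment, ATAC counts and FPKM expression throughout the package.

#' Construct a signal grid
#'
#' @param values numeric matrix, rows = regions or genes, cols = samples.
#' @param tissue,stage,replicate vectors describing each column.
#' @param regions optional interval table (one row per matrix row).
#' @param ids optional character row identifiers (e.g. gene ids). Defaults to
#'   \code{rownames(values)} or region coordinates.
#' @param units one of "RPKM", "log2RPKM", "FPKM", "log2FPKM", "raw_count".
#' @param stage_levels the total order of stages within a tissue; defaults to
#'   \code{sort(unique(stage))}.
#' @return object of class \code{signal_grid}.
#' @export
signal_grid <- function(values, tissue, stage, replicate = 1L,
                        regions = NULL, ids = NULL,
                        units = c("RPKM", "log2RPKM", "FPKM", "log2FPKM",
                                  "raw_count"),
                        stage_levels = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  n <- ncol(values)
  samples <- data.frame(tissue = as.character(rep_len(tissue, n)),
                        stage = as.character(rep_len(stage, n)),
                        replicate = as.integer(rep_len(replicate, n)),
                        stringsAsFactors = FALSE)
  if (is.null(stage_levels)) stage_levels <- sort(unique(samples$stage))
  if (!all(samples$stage %in% stage_levels))
    stop("stage values outside stage_levels")
  if (anyNA(values)) stop("signal grid contains missing values")
  if (!is.null(regions)) {
    validate_intervals(regions)
    if (nrow(regions) != nrow(values))
      stop("regions and values row counts differ")
  }
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(values))) rownames(values)
           else if (!is.null(regions))
             paste0(regions$chrom, ":", regions$start, "-", regions$end)
           else as.character(seq_len(nrow(values)))
  }
  colnames(values) <- sample_key(samples$tissue, samples$stage, samples$replicate)
  rownames(values) <- ids
  structure(list(values = values, samples = samples, regions = regions,
                 ids = ids, units = units, stage_levels = stage_levels),
            class = "signal_grid")
}

#' Compose sample keys "<tissue>:<stage>:<rep>"
#' @param tissue,stage,replicate per-sample identity vectors.
#' @return character keys.
#' @export
sample_key <- function(tissue, stage, replicate) {
  paste(tissue, stage, replicate, sep = ":")
}

#' Parse sample keys back into tissue/stage/replicate
#' @param keys character vector "<tissue>:<stage>:<rep>".
#' @return data.frame(tissue, stage, replicate).
#' @export
parse_sample_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed sample key: ", keys[bad][1])
  data.frame(tissue = vapply(parts, `[[`, "", 1),
             stage = vapply(parts, `[[`, "", 2),
             replicate = as.integer(vapply(parts, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' @export
print.signal_grid <- function(x, ...) {
  cat(sprintf("signal_grid: %d regions x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  cat(sprintf("  tissues: %s\n", paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("  stages:  %s\n", paste(x$stage_levels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.signal_grid <- function(x) dim(x$values)

# Integer index of each column's stage in the stage order.
.stage_index <- function(grid) match(grid$samples$stage, grid$stage_levels)

#' Subset signal grid columns
#' @param grid signal grid.
#' @param cols logical or integer column selector.
#' @return signal grid restricted to the selected columns.
#' @export
grid_subset_samples <- function(grid, cols) {
  signal_grid(grid$values[, cols, drop = FALSE],
              tissue = grid$samples$tissue[cols],
              stage = grid$samples$stage[cols],
              replicate = grid$samples$replicate[cols],
              regions = grid$regions, ids = grid$ids, units = grid$units,
              stage_levels = grid$stage_levels)
}

#' Write a signal grid as TSV
#'
#' Region grids use the header "chrom start end <keys...>"; id grids (gene
#' expression) use "gene_id <keys...>".
#'
#' @param grid signal grid.
#' @param path output file.
#' @export
write_signal_grid <- function(grid, path) {
  if (!is.null(grid$regions)) {
    df <- cbind(grid$regions[, c("chrom", "start", "end")],
                as.data.frame(grid$values, check.names = FALSE))
  } else {
    df <- cbind(data.frame(gene_id = grid$ids),
                as.data.frame(grid$values, check.names = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signal grid from TSV
#'
#' @param path TSV written by \code{\link{write_signal_grid}}.
#' @param units unit tag to attach.
#' @param stage_levels optional explicit stage order.
#' @return signal grid.
#' @export
read_signal_grid <- function(path, units = "RPKM", stage_levels = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (identical(names(df)[1], "gene_id")) {
    ids <- df$gene_id
    vals <- as.matrix(df[, -1, drop = FALSE])
    regions <- NULL
  } else {
    regions <- intervals(df$chrom, df$start, df$end)
    vals <- as.matrix(df[, -(1:3), drop = FALSE])
    ids <- NULL
  }
  s <- parse_sample_key(colnames(vals))
  signal_grid(vals, s$tissue, s$stage, s$replicate, regions = regions,
              ids = ids, units = units, stage_levels = stage_levels)
}
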