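# Readers/writers for the plain-text formats the pipeline exchanges:
# BED3/4/6, narrowPeak, and dense segmentation BED4 (column 4 = state label).

#' Read a BED file
#'
#' Accepts BED3 (chrom/start/end), BED4 (+name) or BED6 (+name/score/strand).
#' Coordinates are validated as 0-based half-open.
#'
#' @param path file path.
#' @return interval table; extra columns name/score/strand when present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  validate_intervals(df)
  class(df) <- c("intervals", "data.frame")
  df
}

#' Write intervals as BED
#' @param x interval table.
#' @param path output path.
#' @param columns which columns to emit (defaults to all present BED columns).
#' @export
write_bed <- function(x, path, columns = NULL) {
  validate_intervals(x)
  if (is.null(columns))
    columns <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                         names(x))
  write.table(format(x[, columns, drop = FALSE], scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' Ten-column BED6+4: signalValue, pValue, qValue, peak (summit offset).
#'
#' @param path file path.
#' @return interval table with the narrowPeak columns.
#' @export
read_narrowpeak <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) != 10) stop("narrowPeak requires 10 columns, got ", ncol(df))
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak")
  validate_intervals(df)
  class(df) <- c("intervals", "data.frame")
  df
}

#' Read a dense segmentation (BED4, column 4 = state label)
#'
#' @param path file path.
#' @param genome named numeric vector of chromosome lengths; inferred from the
#'   data (max end per chromosome) when omitted.
#' @param tissue,stage,replicate sample identity to attach.
#' @return a \code{segmentation} object.
#' @export
read_segmentation <- function(path, genome = NULL, tissue = NA, stage = NA,
                              replicate = NA) {
  df <- read_bed(path)
  if (is.null(df$name)) stop("segmentation BED needs a 4th (state) column")
  names(df)[names(df) == "name"] <- "state"
  segmentation(df, genome = genome, tissue = tissue, stage = stage,
               replicate = replicate)
}

#' Write a segmentation as dense BED4
#' @param seg segmentation object.
#' @param path output path.
#' @export
write_segmentation <- function(seg, path) {
  df <- seg$intervals
  write.table(format(df[, c("chrom", "start", "end", "state")],
                     scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns gene_id, chrom, strand, tss (comma-separated bp positions)
#' and biotype.
#'
#' @param path file path.
#' @return annotation data.frame; \code{tss} is a list column of positions.
#' @export
read_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$tss <- lapply(strsplit(as.character(df$tss), ","), as.numeric)
  df
}

#' Write a gene annotation table
#' @param ann annotation data.frame (list column \code{tss}).
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  out <- ann
  out$tss <- vapply(ann$tss, function(p) paste(format(p, scientific = FALSE,
                                                      trim = TRUE),
                                               collapse = ","), character(1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flatten a gene annotation into one row per TSS.
.tss_table <- function(ann) {
  n <- lengths(ann$tss)
  data.frame(gene_id = rep(ann$gene_id, n),
             chrom = rep(ann$chrom, n),
             pos = unlist(ann$tss),
             biotype = rep(ann$biotype, n),
             stringsAsFactors = FALSE)
}
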