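# Interval algebra over BED-convention (0-based, half-open) coordinates.
# Backed by IRanges/GenomicRanges; all public interfaces use plain data frames
# with columns chrom/start/end (+ optional name, score) so that files written
# by this package are ordinary BED.

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-ish vectors; 0-based half-open, \code{end > start}.
#' @param name optional label per interval.
#' @param score optional numeric score per interval.
#' @return data.frame with class \code{c("intervals", "data.frame")}.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(),
                      name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  class(df) <- c("intervals", "data.frame")
  df
}

#' Validate an interval table
#'
#' Checks the half-open invariants: \code{start >= 0}, \code{end > start}.
#'
#' @param x data.frame with chrom/start/end columns.
#' @return \code{x}, invisibly; errors on violation.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$chrom)))
    stop("intervals contain NA coordinates")
  if (any(x$start < 0)) stop("interval start < 0")
  if (any(x$end <= x$start)) stop("malformed interval: end <= start")
  invisible(x)
}

# data.frame (0-based half-open) <-> GRanges (1-based closed)
.to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

.from_gr <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  class(df) <- c("intervals", "data.frame")
  df
}

.sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge (union) overlapping intervals
#'
#' Produces a sorted, non-overlapping interval set covering exactly the union
#' of the input bases. If the input carries a \code{name} column, the names of
#' merged constituents are concatenated (comma-separated, input order) onto
#' each output interval.
#'
#' @param x interval table.
#' @return merged, sorted interval table (with \code{name} if input had one).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    out <- x[, intersect(names(x), c("chrom", "start", "end", "name")), drop = FALSE]
    class(out) <- c("intervals", "data.frame")
    return(out)
  }
  gr <- .to_gr(x)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  out <- .from_gr(red)
  if (!is.null(x$name)) {
    revmap <- S4Vectors::mcols(red)$revmap
    out$name <- vapply(revmap, function(i) paste(x$name[sort(i)], collapse = ","),
                       character(1))
  }
  rownames(out) <- NULL
  .sort_intervals(out)
}

#' Subtract one interval set from another
#'
#' Returns the bases of \code{a} not covered by \code{b}, splitting intervals
#' where necessary. Chromosomes absent from \code{b} pass through untouched.
#'
#' @param a,b interval tables.
#' @return interval table of residual bases (merged within \code{a}'s union).
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0) return(merge_intervals(a))
  if (nrow(b) == 0) return(merge_intervals(a))
  res <- GenomicRanges::setdiff(.to_gr(a), .to_gr(b))
  out <- .from_gr(res)
  rownames(out) <- NULL
  .sort_intervals(out)
}

#' Flag regions near anchor positions
#'
#' A region is flagged for an anchor iff it intersects the half-open window
#' \code{[anchor - flank, anchor + flank)} on the same chromosome. Strand is
#' ignored (windows are symmetric). Anchors on chromosomes absent from
#' \code{regions} simply never match; a warning notes them.
#'
#' @param regions interval table.
#' @param anchors data.frame with columns \code{chrom}, \code{pos}.
#' @param flank positive window half-width in bp.
#' @return logical vector, one flag per region.
#' @export
window_overlap <- function(regions, anchors, flank) {
  validate_intervals(regions)
  stopifnot(is.data.frame(anchors), all(c("chrom", "pos") %in% names(anchors)),
            flank > 0)
  if (nrow(regions) == 0) return(logical(0))
  if (nrow(anchors) == 0) return(rep(FALSE, nrow(regions)))
  unknown <- !(anchors$chrom %in% unique(regions$chrom))
  if (any(unknown))
    .ca_log("window_overlap: %d anchors on chromosomes absent from regions",
            sum(unknown))
  win <- data.frame(chrom = anchors$chrom,
                    start = pmax(0, anchors$pos - flank),
                    end = anchors$pos + flank)
  validate_intervals(win)
  hits <- GenomicRanges::countOverlaps(.to_gr(regions), .to_gr(win))
  hits > 0
}

#' Total bases covered by an interval set
#'
#' @param x interval table (need not be merged).
#' @return numeric, bases in the union of \code{x}.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}

#' Intersection of two interval sets
#'
#' @param a,b interval tables.
#' @return merged interval table of bases covered by both inputs.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(intervals())
  }
  res <- GenomicRanges::intersect(.to_gr(a), .to_gr(b))
  out <- .from_gr(res)
  rownames(out) <- NULL
  .sort_intervals(out)
}

# Index pairs (query, subject) of overlapping intervals between two tables.
.overlap_pairs <- function(query, subject) {
  h <- GenomicRanges::findOverlaps(.to_gr(query), .to_gr(subject))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

# Overlap width in bases for each (query, subject) hit pair.
.overlap_widths <- function(query, subject, pairs) {
  s <- pmax(query$start[pairs$query], subject$start[pairs$subject])
  e <- pmin(query$end[pairs$query], subject$end[pairs$subject])
  pmax(0, e - s)
}
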