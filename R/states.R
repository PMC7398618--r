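# Replicate-consensus segmentation and chromatin-state summaries: coverage,
# between-sample variability, temporal transition graphs, and state-based
# sample clustering.

#' Sentinel label for bases without a reproducible state call
#' @export
NRS <- "NRS"

#' Construct a segmentation
#'
#' A per-sample partition of the genome into labelled chromatin-state
#' intervals (dense BED4 semantics). Intervals must tile each chromosome
#' \code{[0, length)} without gaps or overlaps.
#'
#' @param intervals data.frame(chrom, start, end, state).
#' @param genome named numeric vector of chromosome lengths; inferred as the
#'   per-chromosome max end when omitted.
#' @param tissue,stage,replicate sample identity.
#' @return object of class \code{segmentation}.
#' @export
segmentation <- function(intervals, genome = NULL, tissue = NA, stage = NA,
                         replicate = NA) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(intervals)))
  validate_intervals(intervals)
  intervals$state <- as.character(intervals$state)
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (is.null(genome))
    genome <- tapply(intervals$end, intervals$chrom, max)
  genome <- setNames(as.numeric(genome), names(genome))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    if (iv$start[1] != 0 || iv$end[nrow(iv)] != genome[[ch]] ||
        (nrow(iv) > 1 && any(iv$start[-1] != iv$end[-nrow(iv)])))
      stop("segmentation does not partition chromosome ", ch)
  }
  structure(list(intervals = intervals, genome = genome,
                 tissue = tissue, stage = stage, replicate = replicate),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation %s:%s rep%s  (%d intervals, %d chrom, %d states)\n",
              x$tissue, x$stage, x$replicate, nrow(x$intervals),
              length(x$genome), length(unique(x$intervals$state))))
  invisible(x)
}

# Decompose several same-genome segmentations into shared atomic segments.
# Returns data.frame(chrom, start, end, width, s1, s2, ...) with one state
# column per input segmentation.
.seg_atoms <- function(segs) {
  g <- segs[[1]]$genome
  for (s in segs[-1]) {
    if (!identical(sort(names(s$genome)), sort(names(g))) ||
        any(s$genome[names(g)] != g))
      stop("segmentations cover different genomes")
  }
  out <- vector("list", length(g))
  for (k in seq_along(g)) {
    ch <- names(g)[k]
    bp <- sort(unique(c(0, g[[k]],
                        unlist(lapply(segs, function(s)
                          s$intervals$start[s$intervals$chrom == ch])))))
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    atom <- data.frame(chrom = ch, start = starts, end = ends,
                       width = ends - starts, stringsAsFactors = FALSE)
    for (j in seq_along(segs)) {
      iv <- segs[[j]]$intervals[segs[[j]]$intervals$chrom == ch, ]
      atom[[paste0("s", j)]] <- iv$state[findInterval(starts, iv$start)]
    }
    out[[k]] <- atom
  }
  do.call(rbind, out)
}

# Collapse equal-state runs of adjacent atoms back into maximal intervals.
.collapse_runs <- function(chrom, start, end, state) {
  n <- length(state)
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character()))
  new_run <- c(TRUE, state[-1] != state[-n] | chrom[-1] != chrom[-n] |
                     start[-1] != end[-n])
  run <- cumsum(new_run)
  data.frame(chrom = chrom[new_run],
             start = start[new_run],
             end = tapply(end, run, max)[as.character(unique(run))],
             state = state[new_run],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate-consensus segmentation
#'
#' Per base: the shared state where both replicates agree, otherwise the
#' sentinel \code{NRS} ("no reproducible signal", distinct from the no-signal
#' state itself). Output intervals are maximal runs.
#'
#' @param rep1,rep2 segmentations of the same tissue-stage and genome.
#' @return \code{segmentation} object (replicate = NA) whose states include
#'   the sentinel.
#' @export
consensus_segmentation <- function(rep1, rep2) {
  atoms <- .seg_atoms(list(rep1, rep2))
  state <- ifelse(atoms$s1 == atoms$s2, atoms$s1, NRS)
  iv <- .collapse_runs(atoms$chrom, atoms$start, atoms$end, state)
  segmentation(iv, genome = rep1$genome, tissue = rep1$tissue,
               stage = rep1$stage, replicate = NA)
}

#' Per-state coverage of a segmentation
#'
#' @param seg segmentation (typically a consensus).
#' @param denominator bp denominator for fractions; defaults to the genome
#'   length. For real mm10 runs the annotated-sequence total 2,725,535,600 bp
#'   is the documented choice.
#' @return data.frame(state, bp, fraction); bp sums to genome length.
#' @export
state_coverage <- function(seg, denominator = NULL) {
  if (is.null(denominator)) denominator <- sum(seg$genome)
  bp <- tapply(seg$intervals$end - seg$intervals$start, seg$intervals$state, sum)
  data.frame(state = names(bp), bp = as.numeric(bp),
             fraction = as.numeric(bp) / denominator,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome fraction carrying a reproducible functional signature in any sample
#'
#' Bases whose consensus state maps to a functional class (promoter, enhancer,
#' transcription, heterochromatin) in at least one sample, excluding the
#' stated states (defaults: "11" permissive, "15" no signal) and the
#' no-reproducible-signal sentinel.
#'
#' @param segs list of consensus segmentations.
#' @param classes named character vector mapping every state label to a class
#'   ("none" allowed); unmapped states are an error.
#' @param exclusions state labels excluded from the union.
#' @param denominator bp denominator (default: genome length).
#' @return fraction of the denominator covered.
#' @export
functional_class_coverage <- function(segs, classes,
                                      exclusions = c("11", "15"),
                                      denominator = NULL) {
  if (is.null(denominator)) denominator <- sum(segs[[1]]$genome)
  pieces <- lapply(segs, function(s) {
    st <- s$intervals$state
    real <- setdiff(unique(st), NRS)
    if (!all(real %in% names(classes)))
      stop("unmapped state label: ",
           paste(setdiff(real, names(classes)), collapse = ", "))
    keep <- st != NRS & !(st %in% exclusions) & classes[st] != "none"
    s$intervals[keep, c("chrom", "start", "end")]
  })
  un <- merge_intervals(do.call(rbind, pieces))
  covered_bases(un) / denominator
}

#' Fraction of bases whose state differs between two samples
#'
#' Sentinel-vs-state counts as differing; sentinel-vs-sentinel as equal.
#'
#' @param a,b consensus segmentations over the same genome.
#' @param denominator bp denominator (default: genome length).
#' @return fraction in [0, 1].
#' @export
variability_fraction <- function(a, b, denominator = NULL) {
  if (is.null(denominator)) denominator <- sum(a$genome)
  atoms <- .seg_atoms(list(a, b))
  sum(atoms$width[atoms$s1 != atoms$s2]) / denominator
}

#' State-transition graph between two stages
#'
#' Bases labelled \code{focus_state} at either stage are tracked; edge weight
#' is the bp moving from state i to state j, normalized so the largest
#' transition has weight 1 (or by \code{norm_max} when the caller normalizes
#' across a whole series).
#'
#' @param cons_n,cons_n1 consensus segmentations at stages n and n + 1.
#' @param focus_state state whose territory is tracked (default "5").
#' @param norm_max optional externally supplied maximum bp for normalization.
#' @return data.frame(state_from, state_to, bp, weight); zero rows when the
#'   focus state is never observed.
#' @export
transition_graph <- function(cons_n, cons_n1, focus_state = "5",
                             norm_max = NULL) {
  atoms <- .seg_atoms(list(cons_n, cons_n1))
  atoms <- atoms[atoms$s1 == focus_state | atoms$s2 == focus_state, ,
                 drop = FALSE]
  if (nrow(atoms) == 0)
    return(data.frame(state_from = character(), state_to = character(),
                      bp = numeric(), weight = numeric()))
  bp <- tapply(atoms$width, list(atoms$s1, atoms$s2), sum)
  df <- as.data.frame(as.table(bp), stringsAsFactors = FALSE)
  names(df) <- c("state_from", "state_to", "bp")
  df <- df[!is.na(df$bp), , drop = FALSE]
  if (is.null(norm_max)) norm_max <- max(df$bp)
  df$weight <- df$bp / norm_max
  df[order(-df$bp), , drop = FALSE]
}

#' Hierarchical clustering of samples on one state's territory
#'
#' Per-base binarization (in \code{state} vs not), pairwise binary distance
#' (1 - Jaccard over state-positive bases, the R \code{dist} "binary"
#' convention), Ward linkage.
#'
#' @param segs named list (>= 3) of consensus segmentations; names label the
#'   dendrogram leaves.
#' @param state state label to binarize on (default "5", strong enhancer).
#' @param linkage hclust method (default "ward.D2").
#' @return list(hclust, dist) with the tree and the distance matrix.
#' @export
cluster_samples_by_state <- function(segs, state = "5", linkage = "ward.D2") {
  stopifnot(length(segs) >= 3)
  if (is.null(names(segs))) names(segs) <- paste0("sample", seq_along(segs))
  sets <- lapply(segs, function(s)
    merge_intervals(s$intervals[s$intervals$state == state,
                                c("chrom", "start", "end")]))
  sizes <- vapply(sets, covered_bases, numeric(1))
  if (any(sizes == 0))
    .ca_log("cluster_samples_by_state: %d samples with zero state-%s bases",
            sum(sizes == 0), state)
  n <- length(segs)
  d <- matrix(0, n, n, dimnames = list(names(segs), names(segs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- covered_bases(intersect_intervals(sets[[i]], sets[[j]]))
    uni <- sizes[i] + sizes[j] - inter
    d[i, j] <- d[j, i] <- if (uni == 0) 1 else 1 - inter / uni
  }
  hc <- hclust(stats::as.dist(d), method = linkage)
  list(hclust = hc, dist = d)
}

#' Write a sample dendrogram as Newick
#' @param hc hclust object.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
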