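# The d-TAC catalogue: merged accessible regions across all tissue-stages,
# their chromatin-state enrichment, temporal dynamics (library-size-normalized
# exact rate-ratio test), gain/loss state-transition enrichment, lead-lag
# offset profiles, and TAD-constrained correlation structure.

#' Build the d-TAC catalogue from replicated peak sets
#'
#' Peaks from all tissue-stages are concatenated, merged and sorted; each
#' merged region records which tissue-stages contributed a constituent peak,
#' and is classed proximal iff it intersects a TSS +/- \code{tss_flank}
#' window.
#'
#' @param peak_sets named list of interval tables; names are tissue-stage
#'   keys ("tissue:stage").
#' @param tss data.frame(chrom, pos) of TSS positions.
#' @param tss_flank proximity window half-width (default 1000).
#' @return object of class \code{dtac_catalogue}: list(regions, membership
#'   logical matrix, proximity character vector).
#' @export
build_catalogue <- function(peak_sets, tss, tss_flank = 1000) {
  if (length(peak_sets) == 0 || sum(vapply(peak_sets, nrow, 0L)) == 0)
    stop("empty peak input")
  if (is.null(names(peak_sets))) stop("peak_sets must be named by tissue-stage")
  tagged <- do.call(rbind, lapply(names(peak_sets), function(k) {
    p <- peak_sets[[k]][, c("chrom", "start", "end")]
    p$name <- k
    p
  }))
  regions <- merge_intervals(tagged)
  membership <- matrix(FALSE, nrow(regions), length(peak_sets),
                       dimnames = list(NULL, names(peak_sets)))
  for (k in names(peak_sets)) {
    hits <- .overlap_pairs(regions, peak_sets[[k]])
    membership[unique(hits$query), k] <- TRUE
  }
  stopifnot(all(rowSums(membership) >= 1))
  prox <- ifelse(window_overlap(regions, tss, tss_flank), "proximal", "distal")
  structure(list(regions = regions[, c("chrom", "start", "end")],
                 membership = membership, proximity = prox),
            class = "dtac_catalogue")
}

#' @export
print.dtac_catalogue <- function(x, ...) {
  cat(sprintf("d-TAC catalogue: %d regions (%d proximal / %d distal), %d samples\n",
              nrow(x$regions), sum(x$proximity == "proximal"),
              sum(x$proximity == "distal"), ncol(x$membership)))
  invisible(x)
}

#' Chromatin-state enrichment of the d-TAC catalogue
#'
#' enrichment(s) = observed d-TAC bp in state s / (total d-TAC bp x genome
#' fraction of state s). States with zero genome coverage report NA.
#'
#' @param catalogue dtac_catalogue.
#' @param consensus consensus segmentation of one tissue-stage.
#' @param denominator genome-fraction denominator (default genome length).
#' @return data.frame(state, observed_bp, genome_fraction, enrichment).
#' @export
state_enrichment <- function(catalogue, consensus, denominator = NULL) {
  cov <- state_coverage(consensus, denominator = denominator)
  total_bp <- covered_bases(catalogue$regions)
  pairs <- .overlap_pairs(catalogue$regions, consensus$intervals)
  w <- .overlap_widths(catalogue$regions, consensus$intervals, pairs)
  obs <- tapply(w, consensus$intervals$state[pairs$subject], sum)
  out <- data.frame(state = cov$state,
                    observed_bp = as.numeric(obs[cov$state]),
                    genome_fraction = cov$fraction,
                    stringsAsFactors = FALSE)
  out$observed_bp[is.na(out$observed_bp)] <- 0
  out$enrichment <- ifelse(out$genome_fraction == 0, NA,
                           out$observed_bp / (total_bp * out$genome_fraction))
  out
}

#' Sensitivity and specificity of an accessible-region set
#'
#' Sensitivity: fraction of reference positive regions overlapped by the
#' accessible set. Specificity: fraction of reference negative anchors NOT
#' overlapped.
#'
#' @param accessible interval table of accessible regions (one tissue-stage).
#' @param positives interval table of reference positives (e.g. active
#'   promoters, validated enhancers).
#' @param negatives interval table of reference negatives (e.g. inaccessible
#'   TSS windows).
#' @return list(sensitivity, specificity).
#' @export
sensitivity_specificity <- function(accessible, positives, negatives) {
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("empty reference set")
  hit_pos <- unique(.overlap_pairs(positives, accessible)$query)
  hit_neg <- unique(.overlap_pairs(negatives, accessible)$query)
  list(sensitivity = length(hit_pos) / nrow(positives),
       specificity = 1 - length(hit_neg) / nrow(negatives))
}

# Exact two-sided binomial p-value (minimum-likelihood method, the
# binom.test convention), vectorized over observations.
.binom_two_sided <- function(k, n, p0) {
  mapply(function(ki, ni) {
    if (ni == 0) return(1)
    d <- stats::dbinom(0:ni, ni, p0)
    min(1, sum(d[d <= d[ki + 1] * (1 + 1e-7)]))
  }, k, n)
}

#' Call temporally dynamic d-TACs
#'
#' For each region and each pair of sequential stages within a tissue,
#' replicate-summed counts are compared by an exact two-sided rate-ratio
#' (binomial) test conditioned on library sizes; fold change is the ratio of
#' library-size-normalized means. Calls with |fold change| >= \code{fc} and
#' p <= \code{alpha} are retained; a region with >= 1 retained call is
#' dynamic.
#'
#' @param counts signal grid of raw ATAC counts (2 replicates per stage).
#' @param tissue tissue to analyse.
#' @param fc fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05, unadjusted as printed;
#'   set \code{adjust = TRUE} for an optional BH mode).
#' @param adjust apply BH across regions within each transition.
#' @return data.frame of retained calls: region id/coords, transition,
#'   log2 fold change, p, adjusted p, direction.
#' @export
call_dynamic <- function(counts, tissue, fc = 2, alpha = 0.05,
                         adjust = FALSE) {
  stopifnot(inherits(counts, "signal_grid"), counts$units == "raw_count")
  lib <- colSums(counts$values)
  sel <- counts$samples$tissue == tissue
  stages <- counts$stage_levels[counts$stage_levels %in%
                                counts$samples$stage[sel]]
  out <- list()
  for (i in seq_len(length(stages) - 1)) {
    c1 <- which(sel & counts$samples$stage == stages[i])
    c2 <- which(sel & counts$samples$stage == stages[i + 1])
    N1 <- sum(lib[c1]); N2 <- sum(lib[c2])
    if (N1 == 0 || N2 == 0) {
      .ca_log("call_dynamic: zero library at %s->%s, skipped",
              stages[i], stages[i + 1])
      next
    }
    x1 <- rowSums(counts$values[, c1, drop = FALSE])
    x2 <- rowSums(counts$values[, c2, drop = FALSE])
    m1 <- x1 / N1; m2 <- x2 / N2
    log2fc <- log2(m2 / m1)  # Inf/-Inf when one side is zero
    p <- .binom_two_sided(x2, x1 + x2, N2 / (N1 + N2))
    padj <- bh_adjust(p)
    crit <- if (adjust) padj else p
    keep <- which(abs(log2fc) >= log2(fc) & crit <= alpha & (x1 + x2) > 0)
    if (length(keep)) {
      out[[length(out) + 1]] <- data.frame(
        region_id = counts$ids[keep],
        chrom = counts$regions$chrom[keep],
        start = counts$regions$start[keep],
        end = counts$regions$end[keep],
        tissue = tissue,
        stage_from = stages[i], stage_to = stages[i + 1],
        transition = i,
        log2fc = log2fc[keep], p = p[keep], padj = padj[keep],
        direction = ifelse(log2fc[keep] > 0, "gain", "loss"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), tissue = character(),
                      stage_from = character(), stage_to = character(),
                      transition = integer(), log2fc = numeric(),
                      p = numeric(), padj = numeric(),
                      direction = character()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# bp of a region set falling in each (state at n, state at n+1) combination.
.state_combo_bp <- function(regions, cons_n, cons_n1) {
  atoms <- .seg_atoms(list(cons_n, cons_n1))
  atoms_iv <- atoms[, c("chrom", "start", "end")]
  pairs <- .overlap_pairs(regions, atoms_iv)
  w <- .overlap_widths(regions, atoms_iv, pairs)
  tapply(w, list(atoms$s1[pairs$subject], atoms$s2[pairs$subject]), sum)
}

#' State-transition enrichment of accessibility gainers and losers
#'
#' For one stage transition, the observed fraction of dynamic d-TAC bases in
#' each (state at n, state at n + 1) combination is divided by the expected
#' fraction computed from all catalogue d-TACs (dynamic plus non-dynamic).
#' Gainers and losers are evaluated separately.
#'
#' @param calls output of \code{\link{call_dynamic}}, filtered to one
#'   transition.
#' @param catalogue dtac_catalogue (expectation basis).
#' @param cons_n,cons_n1 consensus segmentations at the two stages.
#' @return list(gain, loss): enrichment matrices (NA where a direction class
#'   is empty or a combination is unobserved in the expectation).
#' @export
gain_loss_state_transition_enrichment <- function(calls, catalogue,
                                                  cons_n, cons_n1) {
  all_bp <- .state_combo_bp(catalogue$regions, cons_n, cons_n1)
  exp_frac <- all_bp / sum(all_bp, na.rm = TRUE)
  one <- function(direction) {
    sub <- calls[calls$direction == direction, , drop = FALSE]
    if (nrow(sub) == 0) return(exp_frac * NA)
    dyn_bp <- .state_combo_bp(intervals(sub$chrom, sub$start, sub$end),
                              cons_n, cons_n1)
    obs <- exp_frac * 0
    obs[rownames(dyn_bp), colnames(dyn_bp)] <-
      ifelse(is.na(dyn_bp), 0, dyn_bp)
    (obs / sum(obs, na.rm = TRUE)) / exp_frac
  }
  list(gain = one("gain"), loss = one("loss"))
}

#' Mean log fold change by stage-transition offset
#'
#' Elements that are dynamic at transition t are matched to the response
#' grid's regions by maximal base overlap (elements without any overlapping
#' region are skipped and counted). The response log2 fold change
#' (library-size-normalized replicate-summed means for counts, plain means
#' otherwise) is evaluated at every transition u and indexed by offset u - t.
#' Loss-direction elements are sign-aligned so gains and losses reinforce.
#'
#' @param dynamic data.frame with chrom/start/end/tissue/transition/direction
#'   (e.g. filtered \code{\link{call_dynamic}} output or dynamic enhancer
#'   bins).
#' @param response signal grid whose fold changes are profiled.
#' @return list(profile = data.frame(offset, mean_log2fc, n),
#'   n_unmatched).
#' @export
offset_profile <- function(dynamic, response) {
  stopifnot(nrow(dynamic) > 0)
  resp_iv <- response$regions
  pairs <- .overlap_pairs(intervals(dynamic$chrom, dynamic$start, dynamic$end),
                          resp_iv)
  w <- .overlap_widths(dynamic, resp_iv, pairs)
  match_of <- rep(NA_integer_, nrow(dynamic))
  if (nrow(pairs)) {
    best <- tapply(seq_len(nrow(pairs)), pairs$query,
                   function(ii) pairs$subject[ii[which.max(w[ii])]])
    match_of[as.integer(names(best))] <- as.integer(best)
  }
  n_unmatched <- sum(is.na(match_of))
  # per-tissue normalized stage means of the response
  is_count <- response$units == "raw_count"
  lib <- if (is_count) colSums(response$values) else
    rep(1, ncol(response$values))
  acc <- list()
  for (tis in unique(dynamic$tissue)) {
    sel <- response$samples$tissue == tis
    stages <- response$stage_levels
    means <- vapply(stages, function(st) {
      cols <- which(sel & response$samples$stage == st)
      if (length(cols) == 0) return(rep(NA_real_, nrow(response$values)))
      rowSums(response$values[, cols, drop = FALSE]) / sum(lib[cols])
    }, numeric(nrow(response$values)))
    eps <- if (is_count) 0.5 / mean(lib[sel]) else 0
    lfc <- log2(means[, -1, drop = FALSE] + eps) -
           log2(means[, -ncol(means), drop = FALSE] + eps)
    dd <- dynamic[dynamic$tissue == tis & !is.na(match_of), , drop = FALSE]
    mo <- match_of[dynamic$tissue == tis & !is.na(match_of)]
    for (k in seq_len(nrow(dd))) {
      sgn <- if (!is.null(dd$direction) && dd$direction[k] == "loss") -1 else 1
      for (u in seq_len(ncol(lfc))) {
        acc[[length(acc) + 1]] <- c(offset = u - dd$transition[k],
                                    lfc = sgn * lfc[mo[k], u])
      }
    }
  }
  acc <- do.call(rbind, acc)
  prof <- data.frame(
    offset = sort(unique(acc[, "offset"])),
    mean_log2fc = as.numeric(tapply(acc[, "lfc"], acc[, "offset"], mean)),
    n = as.integer(table(acc[, "offset"])))
  list(profile = prof, n_unmatched = n_unmatched)
}

# TAD id of each region by midpoint containment (NA when outside all TADs).
.tad_of_midpoint <- function(regions, tads) {
  mid <- floor((regions$start + regions$end) / 2)
  mid_iv <- intervals(regions$chrom, mid, mid + 1)
  pairs <- .overlap_pairs(mid_iv, tads)
  tad <- rep(NA_character_, nrow(regions))
  tad[pairs$query] <- if (!is.null(tads$name)) tads$name[pairs$subject] else
    as.character(pairs$subject)
  tad
}

#' Correlated d-TAC pairs within TADs
#'
#' All pairs of regions assigned (by midpoint) to the same TAD whose Pearson
#' correlation across the sample series reaches \code{threshold}. Values are
#' expected to be log2(RPKM + pseudocount); use
#' \code{\link{rpkm_log2}} to prepare a count grid.
#'
#' @param signal signal grid (log2 scale).
#' @param tads TAD interval table (with \code{name}).
#' @param threshold PCC threshold (default 0.7).
#' @return data.frame(region_a, region_b, pcc, tad).
#' @export
correlation_map <- function(signal, tads, threshold = 0.7) {
  tad <- .tad_of_midpoint(signal$regions, tads)
  keep <- !is.na(tad) & apply(signal$values, 1, sd) > 0
  n_const <- sum(apply(signal$values, 1, sd) == 0)
  if (n_const > 0) .ca_log("correlation_map: skipped %d constant regions",
                           n_const)
  out <- list()
  for (td in unique(tad[keep])) {
    idx <- which(keep & tad == td)
    if (length(idx) < 2) next
    cm <- cor(t(signal$values[idx, , drop = FALSE]))
    pr <- which(upper.tri(cm) & cm >= threshold, arr.ind = TRUE)
    if (nrow(pr)) {
      out[[length(out) + 1]] <- data.frame(
        region_a = signal$ids[idx[pr[, 1]]],
        region_b = signal$ids[idx[pr[, 2]]],
        pcc = cm[pr], tad = td, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(region_a = character(), region_b = character(),
                      pcc = numeric(), tad = character()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Convert a raw-count grid to log2 RPKM
#'
#' @param counts signal grid of raw counts with regions.
#' @param pseudocount RPKM pseudocount before log2 (default 0.5).
#' @return signal grid in log2RPKM units.
#' @export
rpkm_log2 <- function(counts, pseudocount = 0.5) {
  stopifnot(counts$units == "raw_count", !is.null(counts$regions))
  kb <- (counts$regions$end - counts$regions$start) / 1e3
  lib_m <- colSums(counts$values) / 1e6
  rpkm <- sweep(counts$values / kb, 2, lib_m, "/")
  g <- counts
  g$values <- log2(rpkm + pseudocount)
  g$units <- "log2RPKM"
  g
}

#' Correlation versus genomic distance, intra- versus inter-TAD
#'
#' Regions are assigned to \code{bin}-bp bins by midpoint; for every pair of
#' regions within \code{max_dist}, the PCC across samples is grouped by bin
#' separation and by whether the two regions share a TAD. Per distance, a
#' two-sided Wilcoxon signed-rank test pairs each anchor region's mean
#' intra-TAD and mean inter-TAD correlation.
#'
#' @param signal signal grid (log2 scale).
#' @param tads TAD interval table.
#' @param bin distance bin width (default 1e4).
#' @param max_dist maximum separation (default 2e6).
#' @return data.frame(distance, mean_intra, mean_inter, n_intra, n_inter, p).
#' @export
distance_profile <- function(signal, tads, bin = 1e4, max_dist = 2e6) {
  tad <- .tad_of_midpoint(signal$regions, tads)
  mid <- floor((signal$regions$start + signal$regions$end) / 2)
  dist_bin <- list(); same_tad <- list(); pcc <- list(); anchor <- list()
  for (ch in unique(signal$regions$chrom)) {
    idx <- which(signal$regions$chrom == ch & apply(signal$values, 1, sd) > 0)
    if (length(idx) < 2) next
    cm <- cor(t(signal$values[idx, , drop = FALSE]))
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    d <- abs(mid[idx[pr[, 1]]] - mid[idx[pr[, 2]]])
    db <- floor(mid[idx] / bin)
    sep <- abs(db[pr[, 1]] - db[pr[, 2]]) * bin
    okd <- sep > 0 & sep <= max_dist
    dist_bin[[ch]] <- sep[okd]
    same_tad[[ch]] <- !is.na(tad[idx[pr[okd, 1]]]) &
      !is.na(tad[idx[pr[okd, 2]]]) &
      tad[idx[pr[okd, 1]]] == tad[idx[pr[okd, 2]]]
    pcc[[ch]] <- cm[pr][okd]
    anchor[[ch]] <- paste0(ch, ":", pmin(idx[pr[okd, 1]], idx[pr[okd, 2]]))
  }
  dist_bin <- unlist(dist_bin); same_tad <- unlist(same_tad)
  pcc <- unlist(pcc); anchor <- unlist(anchor)
  ds <- sort(unique(dist_bin))
  out <- lapply(ds, function(d) {
    sel <- dist_bin == d
    intra <- pcc[sel & same_tad]; inter <- pcc[sel & !same_tad]
    p <- NA_real_
    # pair anchors having both kinds of partner at this distance
    a_in <- tapply(pcc[sel & same_tad], anchor[sel & same_tad], mean)
    a_out <- tapply(pcc[sel & !same_tad], anchor[sel & !same_tad], mean)
    common <- intersect(names(a_in), names(a_out))
    if (length(common) >= 3)
      p <- suppressWarnings(wilcox.test(a_in[common], a_out[common],
                                        paired = TRUE)$p.value)
    data.frame(distance = d,
               mean_intra = if (length(intra)) mean(intra) else NA,
               mean_inter = if (length(inter)) mean(inter) else NA,
               n_intra = length(intra), n_inter = length(inter), p = p)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
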