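# Dynamic strong-enhancer bins: a moderated two-sample test with
# empirical-Bayes variance shrinkage per adjacent-stage comparison,
# unit-vector k-means clustering with an elbow rule, matched-background motif
# enrichment, and super-enhancer calling by the rank-signal tangent cutoff.

# Newton inversion of the trigamma function (for the prior-df estimate).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Empirical-Bayes moderated two-sample t-test on log2 signal.
# Method-of-moments fit of a scaled F prior to the per-bin pooled variances
# (the squeeze used by the standard moderated linear-model engines).
.moderated_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  df <- n1 + n2 - 2
  stopifnot(df >= 1)
  d <- rowMeans(x2) - rowMeans(x1)
  s2 <- ((n1 - 1) * apply(x1, 1, var) + (n2 - 1) * apply(x2, 1, var)) / df
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df)
             else rep(s02, length(s2))
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- d / se
  df_total <- if (is.finite(d0)) d0 + df else Inf
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!ok] <- NA  # zero-variance bins are excluded from calling
  list(log2fc = d, t = tstat, p = p, prior_df = d0, prior_var = s02,
       excluded = !ok)
}

#' Call temporally dynamic enhancer bins
#'
#' Per adjacent-stage comparison within a tissue, a moderated two-sample test
#' (empirical-Bayes variance shrinkage across bins) on log2 signal with BH
#' adjustment across bins; a bin is overall dynamic if any comparison's
#' adjusted p falls below \code{alpha}. Bins with zero variance everywhere
#' are excluded and reported.
#'
#' @param signal signal grid of log2 enhancer-bin signal (2 replicates per
#'   stage).
#' @param tissue tissue to analyse.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list(dynamic = logical per bin, comparisons = per-transition
#'   data.frame(bin, log2fc, p, padj), n_excluded).
#' @export
call_dynamic_bins <- function(signal, tissue, alpha = 0.05) {
  sel <- signal$samples$tissue == tissue
  stages <- signal$stage_levels[signal$stage_levels %in%
                                signal$samples$stage[sel]]
  stopifnot(length(stages) >= 2)
  n <- nrow(signal$values)
  any_sig <- matrix(FALSE, n, length(stages) - 1)
  comps <- list()
  excluded <- rep(FALSE, n)
  for (i in seq_len(length(stages) - 1)) {
    c1 <- which(sel & signal$samples$stage == stages[i])
    c2 <- which(sel & signal$samples$stage == stages[i + 1])
    mt <- .moderated_t(signal$values[, c1, drop = FALSE],
                       signal$values[, c2, drop = FALSE])
    padj <- rep(NA_real_, n)
    padj[!is.na(mt$p)] <- bh_adjust(mt$p[!is.na(mt$p)])
    any_sig[, i] <- !is.na(padj) & padj < alpha
    excluded <- excluded | mt$excluded
    comps[[i]] <- data.frame(bin = signal$ids,
                             stage_from = stages[i], stage_to = stages[i + 1],
                             transition = i, log2fc = mt$log2fc,
                             p = mt$p, padj = padj,
                             stringsAsFactors = FALSE)
  }
  list(dynamic = rowSums(any_sig) > 0,
       comparisons = do.call(rbind, c(comps, list(make.row.names = FALSE))),
       n_excluded = sum(excluded))
}

#' 1-kb bins overlapping a state's territory in any stage
#'
#' @param segs list of consensus segmentations (the stages of one tissue).
#' @param state state label (default "5", strong enhancer).
#' @param bin_bp bin width (default 1000).
#' @return interval table of bins.
#' @export
enhancer_bins <- function(segs, state = "5", bin_bp = 1000) {
  territory <- merge_intervals(do.call(rbind, lapply(segs, function(s)
    s$intervals[s$intervals$state == state, c("chrom", "start", "end")])))
  genome <- segs[[1]]$genome
  bins <- do.call(rbind, lapply(names(genome), function(ch) {
    nb <- ceiling(genome[[ch]] / bin_bp)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * bin_bp,
               end = pmin(seq_len(nb) * bin_bp, genome[[ch]]),
               stringsAsFactors = FALSE)
  }))
  hits <- unique(.overlap_pairs(bins, territory)$query)
  out <- bins[hits, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intervals", "data.frame")
  out
}

#' Cluster dynamic-bin trajectories with an elbow-selected k
#'
#' Rows (per-stage signal of dynamic bins) are normalized to unit vectors,
#' k-means is run over \code{k_range}, and k* is the interior k maximizing
#' the second difference of total within-cluster sum of squares (the point
#' where the curve turns from dropping quickly to dropping steadily).
#' Identical rows (zero within-SS at k = 1) yield k* = 1.
#'
#' @param traj numeric matrix, dynamic bins x stages.
#' @param k_range candidate k values (default 1:10; truncated to the number
#'   of distinct rows).
#' @param nstart k-means restarts per k.
#' @param seed RNG seed.
#' @return list(k, cluster, centers, wss, order): \code{order} sorts rows
#'   within cluster by mean signal (descending).
#' @export
cluster_dynamic_bins <- function(traj, k_range = 1:10, nstart = 10,
                                 seed = 1) {
  stopifnot(nrow(traj) >= 2)
  set.seed(seed)
  u <- unit_vector_rows(traj)
  k_range <- k_range[k_range <= nrow(unique(u))]
  wss <- vapply(k_range, function(k) {
    if (k == 1) sum(scale(u, scale = FALSE)^2)
    else suppressWarnings(kmeans(u, k, nstart = nstart,
                                 iter.max = 100)$tot.withinss)
  }, numeric(1))
  if (wss[1] < 1e-10 || length(k_range) < 3) {
    k_star <- k_range[1]
  } else {
    # elbow: the k whose within-SS drop most out-sizes the next drop --
    # where the curve turns from dropping quickly to dropping steadily.
    # The denominator floor (2% of the largest drop) keeps a chance
    # near-zero late drop from winning.
    d <- -diff(wss)
    ratio <- d[-length(d)] / pmax(d[-1], 0.02 * max(d))
    k_star <- k_range[which.max(ratio) + 1]
  }
  km <- if (k_star == 1)
    list(cluster = rep(1L, nrow(u)),
         centers = matrix(colMeans(u), 1, ncol(u)))
  else suppressWarnings(kmeans(u, k_star, nstart = nstart, iter.max = 100))
  ord <- order(km$cluster, -rowMeans(traj))
  list(k = k_star, cluster = km$cluster, centers = km$centers,
       wss = data.frame(k = k_range, wss = wss), order = ord)
}

#' Motif enrichment of dynamic clusters against a signal-matched background
#'
#' The non-dynamic pool is sampled with replacement, stratified over
#' \code{n_strata} equal-width bins of the pooled average-signal range so the
#' background matches the cluster's signal distribution. Per motif, a
#' two-sided Fisher's exact test compares occurrence counts; BH adjustment is
#' applied across motifs within each cluster.
#'
#' @param occurrences logical/0-1 matrix, bins x motifs (rownames = bin ids).
#' @param clusters named integer vector: cluster id per dynamic bin id.
#' @param pool character vector of non-dynamic bin ids (the background pool).
#' @param signal named numeric: average signal per bin (dynamic and pool).
#' @param n_strata signal strata for matching (default 20).
#' @param seed RNG seed for the background draw.
#' @return data.frame(cluster, motif, odds_ratio, p, padj, n_cluster, n_bg).
#' @export
motif_enrichment <- function(occurrences, clusters, pool, signal,
                             n_strata = 20, seed = 1) {
  stopifnot(length(pool) >= 1)
  set.seed(seed)
  occurrences <- occurrences > 0
  rng <- range(signal[c(names(clusters), pool)])
  strat <- function(ids) {
    if (diff(rng) == 0) return(rep(1L, length(ids)))
    pmin(n_strata, 1L + floor((signal[ids] - rng[1]) / diff(rng) * n_strata))
  }
  pool_strata <- strat(pool)
  out <- list()
  for (cl in sort(unique(clusters))) {
    ids <- names(clusters)[clusters == cl]
    if (length(pool) < length(ids))
      stop("background pool smaller than cluster ", cl)
    cl_strata <- strat(ids)
    bg <- unlist(lapply(seq_len(n_strata), function(s) {
      need <- sum(cl_strata == s)
      if (need == 0) return(character(0))
      cand <- pool[pool_strata == s]
      if (length(cand) == 0) {
        # borrow the nearest non-empty stratum
        dists <- abs(sort(unique(pool_strata)) - s)
        cand <- pool[pool_strata == sort(unique(pool_strata))[which.min(dists)]]
      }
      sample(cand, need, replace = TRUE)
    }))
    for (m in colnames(occurrences)) {
      a <- sum(occurrences[ids, m]); b <- length(ids) - a
      c_ <- sum(occurrences[bg, m]); d <- length(bg) - c_
      if (a + c_ == 0) next  # motif absent everywhere
      or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
      p <- fisher.test(matrix(c(a, b, c_, d), 2, 2))$p.value
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, motif = m, odds_ratio = or, p = p,
        n_cluster = length(ids), n_bg = length(bg),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$padj <- NA_real_
  for (cl in unique(res$cluster)) {
    sel <- res$cluster == cl
    res$padj[sel] <- bh_adjust(res$p[sel])
  }
  res
}

#' Call super-enhancers by the rank-signal tangent cutoff
#'
#' Peaks within \code{stitch} bp are stitched; stitched regions are ranked by
#' total signal; rank and signal are scaled to [0, 1]; the cutoff is the
#' point where the tangent to the signal-versus-rank curve has slope
#' \code{slope} (the point of maximal vertical gap below the slope-line);
#' regions with signal above the cutoff are super-enhancers.
#'
#' @param peaks interval table with a \code{score} column (H3K27ac signal).
#' @param stitch stitching distance in bp (default 12500).
#' @param slope tangent slope of the cutoff (default 1).
#' @param tss optional data.frame(chrom, pos); peaks within
#'   \code{tss_flank} of a TSS are excluded before stitching (off by
#'   default, as in the reference tool's defaults).
#' @param tss_flank exclusion half-width (default 2500).
#' @return data.frame of stitched regions: chrom, start, end, n_constituents,
#'   total_signal, rank (1 = strongest), is_super.
#' @export
call_super_enhancers <- function(peaks, stitch = 12500, slope = 1,
                                 tss = NULL, tss_flank = 2500) {
  stopifnot(!is.null(peaks$score))
  if (!is.null(tss)) {
    keep <- !window_overlap(peaks, tss, tss_flank)
    peaks <- peaks[keep, , drop = FALSE]
  }
  peaks <- .sort_intervals(peaks)
  # stitch: group peaks whose gap to the previous peak is <= stitch
  n <- nrow(peaks)
  grp <- integer(n); g <- 0L; last_end <- -Inf; last_chrom <- ""
  for (i in seq_len(n)) {
    if (peaks$chrom[i] != last_chrom || peaks$start[i] - last_end > stitch) {
      g <- g + 1L
      last_end <- peaks$end[i]
    } else last_end <- max(last_end, peaks$end[i])
    last_chrom <- peaks$chrom[i]
    grp[i] <- g
  }
  st <- data.frame(
    chrom = tapply(peaks$chrom, grp, `[`, 1),
    start = tapply(peaks$start, grp, min),
    end = tapply(peaks$end, grp, max),
    n_constituents = as.integer(table(grp)),
    total_signal = as.numeric(tapply(peaks$score, grp, sum)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(st) < 3) stop("need >= 3 stitched regions to place a cutoff")
  o <- order(st$total_signal)  # ascending for the hockey-stick curve
  y <- st$total_signal[o] / max(st$total_signal)
  x <- (seq_len(nrow(st)) - 1) / (nrow(st) - 1)
  gap <- slope * x - y
  cutoff_y <- y[which.max(gap)]
  st$rank <- rank(-st$total_signal, ties.method = "first")
  st$is_super <- st$total_signal / max(st$total_signal) > cutoff_y
  st[order(st$rank), , drop = FALSE]
}
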