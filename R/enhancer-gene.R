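# TAD-constrained enhancer-gene map: derive candidate enhancer regions from
# strong-enhancer consensus calls, link genes to enhancers by Spearman
# correlation with a chromosome-wide empirical null, intersect replicate
# maps, and evaluate against interaction and eQTL-style fixtures.

#' Derive candidate enhancer regions
#'
#' Strong-enhancer (state 5) consensus calls from all samples are merged;
#' TSS +/- \code{tss_flank} windows are subtracted; remnants shorter than
#' \code{pad_to} are enlarged symmetrically about their midpoint (which may
#' graze the subtracted windows -- signal robustness wins over strict
#' exclusion, as in the original procedure); each region is assigned to the
#' TAD containing its midpoint, and regions outside all TADs are dropped.
#'
#' @param state5_calls interval table of strong-enhancer calls pooled across
#'   samples (or a list of tables).
#' @param tss data.frame(chrom, pos).
#' @param tads TAD interval table with \code{name}.
#' @param pad_to minimum region width after padding (default 2000).
#' @param tss_flank TSS exclusion half-width (default 2500).
#' @return interval table with \code{tad}; attribute \code{n_dropped} counts
#'   regions whose midpoint fell outside all TADs.
#' @export
derive_enhancer_regions <- function(state5_calls, tss, tads, pad_to = 2000,
                                    tss_flank = 2500) {
  if (is.list(state5_calls) && !is.data.frame(state5_calls))
    state5_calls <- do.call(rbind, lapply(state5_calls, function(x)
      x[, c("chrom", "start", "end")]))
  merged <- merge_intervals(state5_calls[, c("chrom", "start", "end")])
  tss_win <- intervals(tss$chrom, pmax(0, tss$pos - tss_flank),
                       tss$pos + tss_flank)
  resid <- subtract_intervals(merged, tss_win)
  if (nrow(resid) == 0) return(resid)
  w <- resid$end - resid$start
  short <- w < pad_to
  midf <- (resid$start + resid$end) / 2
  resid$start[short] <- pmax(0, round(midf[short] - pad_to / 2))
  resid$end[short] <- resid$start[short] + pad_to
  tad <- .tad_of_midpoint(resid, tads)
  dropped <- sum(is.na(tad))
  out <- resid[!is.na(tad), , drop = FALSE]
  out$tad <- tad[!is.na(tad)]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

# Spearman correlations of one vector against the rows of a matrix,
# computed via Pearson on ranks (average ranks for ties).
.spearman_vs_rows <- function(v, M) {
  rv <- rank(v)
  rM <- t(apply(M, 1, rank))
  rv <- rv - mean(rv)
  rM <- rM - rowMeans(rM)
  num <- as.numeric(rM %*% rv)
  den <- sqrt(sum(rv^2) * rowSums(rM^2))
  ifelse(den == 0, NA, num / den)
}

#' Link genes to enhancers by TAD-constrained Spearman correlation
#'
#' Within each TAD, every protein-coding gene is correlated (Spearman, across
#' the sample series) with every enhancer in the TAD and assigned to the
#' enhancer with the highest SCC. Significance uses a chromosome-wide
#' empirical null: the SCC of that enhancer with all genes on the chromosome
#' (focal gene included by default). \code{z_p} is the upper-tail normal
#' p-value of the z-scored SCC; \code{empirical_p} is the fraction of null
#' SCCs >= the observed one. Retained links satisfy SCC >= \code{min_scc}
#' and both p-values <= \code{alpha}.
#'
#' @param enh_signal signal grid of enhancer H3K27ac (log2; one replicate
#'   series), regions carrying a \code{tad} assignment via
#'   \code{enh_signal$regions$tad} or a \code{tads} table.
#' @param expr signal grid of gene expression (log2 FPKM; same samples, same
#'   column order).
#' @param annotation gene annotation (gene_id, chrom, biotype, tss, tad).
#' @param tads TAD table (used when enhancer regions lack \code{tad}).
#' @param min_scc SCC threshold (default 0.25).
#' @param alpha p-value threshold (default 0.05).
#' @param include_focal keep the focal gene in the null (default TRUE).
#' @return data.frame: enhancer coords/id, gene_id, scc, z_p, empirical_p.
#' @export
link_by_correlation <- function(enh_signal, expr, annotation, tads = NULL,
                                min_scc = 0.25, alpha = 0.05,
                                include_focal = TRUE) {
  stopifnot(ncol(enh_signal$values) == ncol(expr$values))
  enh_reg <- enh_signal$regions
  tad <- enh_reg$tad
  if (is.null(tad)) {
    if (is.null(tads)) stop("need TAD assignments for enhancers")
    tad <- .tad_of_midpoint(enh_reg, tads)
  }
  ann <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  # rank-transform once per chromosome for fast null computation
  out <- list()
  for (ch in unique(ann$chrom)) {
    genes_ch <- ann[ann$chrom == ch, , drop = FALSE]
    gi <- match(genes_ch$gene_id, expr$ids)
    if (anyNA(gi)) stop("expression grid missing genes: ",
                        genes_ch$gene_id[is.na(gi)][1])
    gmat <- expr$values[gi, , drop = FALSE]
    const_gene <- apply(gmat, 1, sd) == 0
    if (any(const_gene))
      .ca_log("link_by_correlation: %d constant genes skipped on %s",
              sum(const_gene), ch)
    for (td in unique(genes_ch$tad)) {
      g_idx <- which(genes_ch$tad == td & !const_gene)
      e_idx <- which(tad == td & enh_reg$chrom == ch)
      if (length(g_idx) == 0 || length(e_idx) == 0) next
      for (g in g_idx) {
        scc <- .spearman_vs_rows(gmat[g, ],
                                 enh_signal$values[e_idx, , drop = FALSE])
        if (all(is.na(scc))) next
        best <- which.max(scc)
        e_best <- e_idx[best]
        null_scc <- .spearman_vs_rows(enh_signal$values[e_best, ],
                                      gmat[!const_gene, , drop = FALSE])
        if (!include_focal) {
          null_scc <- null_scc[which(!const_gene) != g]
        }
        null_scc <- null_scc[!is.na(null_scc)]
        mu <- mean(null_scc); sig <- sd(null_scc)
        z_p <- if (sig == 0) 1 else pnorm((scc[best] - mu) / sig,
                                          lower.tail = FALSE)
        emp_p <- mean(null_scc >= scc[best])
        out[[length(out) + 1]] <- data.frame(
          chrom = enh_reg$chrom[e_best], start = enh_reg$start[e_best],
          end = enh_reg$end[e_best],
          enh_id = if (!is.null(enh_signal$ids)) enh_signal$ids[e_best] else
            NA_character_,
          gene_id = genes_ch$gene_id[g], tad = td,
          scc = scc[best], z_p = z_p, empirical_p = emp_p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      enh_id = character(), gene_id = character(),
                      tad = character(), scc = numeric(), z_p = numeric(),
                      empirical_p = numeric()))
  map <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  keep <- map$scc >= min_scc & map$z_p <= alpha & map$empirical_p <= alpha
  map <- map[keep, , drop = FALSE]
  rownames(map) <- NULL
  stopifnot(all(map$scc >= min_scc), all(map$z_p <= alpha),
            all(map$empirical_p <= alpha))
  map
}

#' Intersect the two replicate maps
#'
#' Links present (same enhancer region, same gene) in both replicate-series
#' maps, marked \code{replicate_support = "both"}.
#'
#' @param map1,map2 outputs of \code{\link{link_by_correlation}}.
#' @return the intersection, with map1's statistics.
#' @export
intersect_replicate_maps <- function(map1, map2) {
  k1 <- paste(map1$chrom, map1$start, map1$end, map1$gene_id)
  k2 <- paste(map2$chrom, map2$start, map2$end, map2$gene_id)
  out <- map1[k1 %in% k2, , drop = FALSE]
  if (nrow(out)) out$replicate_support <- "both"
  rownames(out) <- NULL
  out
}

#' Fraction of interactions supported by the map versus nearest gene
#'
#' Among interactions whose anchor overlaps a map enhancer, the fraction
#' whose gene matches the map-assigned gene, and the same for nearest-TSS
#' assignment.
#'
#' @param map enhancer-gene map.
#' @param interactions data.frame(chrom, start, end, gene_id): experimental
#'   anchor-gene pairs.
#' @param annotation gene annotation (for nearest-TSS assignment).
#' @return list(map_fraction, nearest_fraction, n_evaluated); NA fractions
#'   when no enhancer overlaps an anchor.
#' @export
interaction_support <- function(map, interactions, annotation) {
  if (nrow(interactions) == 0 || nrow(map) == 0)
    return(list(map_fraction = NA, nearest_fraction = NA, n_evaluated = 0L))
  tssall <- .tss_table(annotation)
  pairs <- .overlap_pairs(map, interactions)
  if (nrow(pairs) == 0)
    return(list(map_fraction = NA, nearest_fraction = NA, n_evaluated = 0L))
  enh_mid <- (map$start + map$end) / 2
  nearest_gene <- vapply(seq_len(nrow(map)), function(i) {
    cand <- tssall[tssall$chrom == map$chrom[i], ]
    cand$gene_id[which.min(abs(cand$pos - enh_mid[i]))]
  }, character(1))
  map_hit <- map$gene_id[pairs$query] == interactions$gene_id[pairs$subject]
  near_hit <- nearest_gene[pairs$query] == interactions$gene_id[pairs$subject]
  list(map_fraction = mean(map_hit), nearest_fraction = mean(near_hit),
       n_evaluated = nrow(pairs))
}

#' Mirrored control region for each link
#'
#' A region of the enhancer's width, centred at the same distance from the
#' gene's (nearest) TSS but on the opposite side. Links whose mirror falls
#' off the chromosome start are dropped and counted.
#'
#' @param map enhancer-gene map.
#' @param annotation gene annotation.
#' @return list(controls = data.frame(chrom, start, end, gene_id, link_row),
#'   n_dropped).
#' @export
mirrored_control_set <- function(map, annotation) {
  tssall <- .tss_table(annotation)
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(map))) {
    cand <- tssall[tssall$gene_id == map$gene_id[i], ]
    mid <- (map$start[i] + map$end[i]) / 2
    tss <- cand$pos[which.min(abs(cand$pos - mid))]
    ctr <- 2 * tss - mid
    half <- (map$end[i] - map$start[i]) / 2
    s <- round(ctr - half); e <- round(ctr + half)
    if (s < 0) { dropped <- dropped + 1L; next }
    out[[length(out) + 1]] <- data.frame(
      chrom = map$chrom[i], start = s, end = e, gene_id = map$gene_id[i],
      link_row = i, stringsAsFactors = FALSE)
  }
  controls <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
    else data.frame(chrom = character(), start = numeric(), end = numeric(),
                    gene_id = character(), link_row = integer())
  list(controls = controls, n_dropped = dropped)
}

# is link i supported by >= 1 eQTL (variant inside region, same gene)?
.eqtl_supported <- function(regions, genes, eqtl) {
  v_iv <- intervals(eqtl$chrom, eqtl$pos, eqtl$pos + 1)
  pairs <- .overlap_pairs(regions, v_iv)
  ok <- pairs[genes[pairs$query] == eqtl$gene_id[pairs$subject], , drop = FALSE]
  seq_len(nrow(regions)) %in% ok$query
}

#' eQTL support by enhancer-TSS distance decile
#'
#' Links are split into (up to) ten equal-size bins by enhancer-TSS distance;
#' per bin, the counts of eQTL-supported versus unsupported links are
#' compared between the map and its mirrored controls by a two-sided
#' Fisher's exact test.
#'
#' @param map enhancer-gene map.
#' @param controls output of \code{\link{mirrored_control_set}} (its
#'   \code{controls} element).
#' @param eqtl data.frame(chrom, pos, gene_id) of variant-gene associations.
#' @param annotation gene annotation (for TSS distances).
#' @param n_bins number of distance bins (default 10; reduced when there are
#'   fewer links than bins).
#' @return data.frame(decile, n, map_supported, control_supported, p).
#' @export
distance_decile_test <- function(map, controls, eqtl, annotation,
                                 n_bins = 10) {
  eval_rows <- controls$link_row
  m <- map[eval_rows, , drop = FALSE]
  tssall <- .tss_table(annotation)
  mid <- (m$start + m$end) / 2
  dist <- vapply(seq_len(nrow(m)), function(i) {
    cand <- tssall[tssall$gene_id == m$gene_id[i], ]
    min(abs(cand$pos - mid[i]))
  }, numeric(1))
  n_bins <- min(n_bins, nrow(m))
  if (n_bins < 10) .ca_log("distance_decile_test: only %d bins", n_bins)
  decile <- ceiling(rank(dist, ties.method = "first") / (nrow(m) / n_bins))
  sup_map <- .eqtl_supported(m, m$gene_id, eqtl)
  sup_ctl <- .eqtl_supported(controls, controls$gene_id, eqtl)
  out <- lapply(seq_len(n_bins), function(d) {
    sel <- decile == d
    tab <- matrix(c(sum(sup_map[sel]), sum(!sup_map[sel]),
                    sum(sup_ctl[sel]), sum(!sup_ctl[sel])), 2, 2,
                  byrow = TRUE)
    data.frame(decile = d, n = sum(sel),
               map_supported = tab[1, 1], control_supported = tab[2, 1],
               p = fisher.test(tab)$p.value)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
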