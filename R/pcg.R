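# Polycomb (PcG) target classification: per-TSS activity calls against the
# consensus chromatin states, gene-level aggregation, cumulative fraction
# curves and the 2x2 enrichment statistic.

# State sets of the classification rule. "Active" requires the active
# promoter state without any repressive state in the window; "repressed"
# requires the PcG heterochromatin state without any active state. The
# permissive and no-signal states appear in neither exclusion list.
PCG_ACTIVE_STATE <- "1"
PCG_REPRESSIVE_STATES <- c("3", "13", "14")
PCG_REPRESSED_STATE <- "13"
PCG_ACTIVE_STATES <- c("1", "2", "4", "5", "6", "7", "10", "12")

#' Classify TSSs as active / repressed / unclassified in one tissue-stage
#'
#' A symmetric window (default 2 kb total, i.e. TSS +/- 1 kb) is intersected
#' with the consensus states. Active: overlaps the active promoter state and
#' no repressive state (3, 13, 14). Repressed: overlaps the PcG state (13)
#' and no active state (1, 2, 4, 5, 6, 7, 10, 12). Anything else, including
#' TSSs off the covered genome, is unclassified.
#'
#' @param tss data.frame(gene_id, chrom, pos) of TSS positions.
#' @param consensus consensus segmentation for the tissue-stage.
#' @param window total window width in bp (split symmetrically).
#' @return data.frame(gene_id, chrom, pos, label).
#' @export
classify_tss <- function(tss, consensus, window = 2000) {
  stopifnot(window > 0)
  flank <- window / 2
  iv <- consensus$intervals
  lab <- rep("unclassified", nrow(tss))
  off <- !(tss$chrom %in% names(consensus$genome))
  if (any(off)) .ca_log("classify_tss: %d TSSs off the covered genome", sum(off))
  win <- intervals(tss$chrom[!off],
                   pmax(0, tss$pos[!off] - flank),
                   tss$pos[!off] + flank)
  pairs <- .overlap_pairs(win, iv)
  st <- iv$state[pairs$subject]
  has <- function(states) {
    idx <- unique(pairs$query[st %in% states])
    seq_len(nrow(win)) %in% idx
  }
  act <- has(PCG_ACTIVE_STATE) & !has(PCG_REPRESSIVE_STATES)
  rep_ <- has(PCG_REPRESSED_STATE) & !has(PCG_ACTIVE_STATES)
  sub_lab <- rep("unclassified", nrow(win))
  sub_lab[act] <- "active"
  sub_lab[rep_] <- "repressed"
  lab[!off] <- sub_lab
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom, pos = tss$pos,
             label = lab, stringsAsFactors = FALSE)
}

#' Aggregate TSS classifications into gene-level PcG labels
#'
#' A gene is a putative PcG target iff it has at least one repressed TSS in at
#' least one tissue-stage; \code{n_tissue_stages_repressed} counts the
#' tissue-stages with >= 1 repressed TSS.
#'
#' @param classifications data.frame with columns gene_id, tissue, stage,
#'   label (rbind of \code{\link{classify_tss}} outputs, one per tissue-stage,
#'   with tissue/stage columns added).
#' @param gene_ids optional universe of genes; defaults to those observed.
#' @return data.frame(gene_id, is_PcG_target, n_tissue_stages_repressed).
#' @export
classify_genes <- function(classifications, gene_ids = NULL) {
  stopifnot(all(c("gene_id", "tissue", "stage", "label") %in%
                names(classifications)))
  if (is.null(gene_ids)) gene_ids <- unique(classifications$gene_id)
  repr <- classifications[classifications$label == "repressed", , drop = FALSE]
  key <- unique(paste(repr$gene_id, repr$tissue, repr$stage, sep = "\r"))
  gene_of <- vapply(strsplit(key, "\r", fixed = TRUE), `[[`, "", 1)
  counts <- table(factor(gene_of, levels = gene_ids))
  data.frame(gene_id = gene_ids,
             is_PcG_target = as.integer(counts) >= 1,
             n_tissue_stages_repressed = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cumulative PcG-repression fraction curves per gene subset
#'
#' For each subset, the fraction of genes repressed in at least x
#' tissue-stages, for x = 1..max. The value at x = 1 is the subset's
#' PcG-target fraction; curves are non-increasing in x by construction.
#'
#' @param labels output of \code{\link{classify_genes}}.
#' @param gene_subsets named list of gene-id vectors.
#' @param max_x largest minimum-count on the x axis (default: the number of
#'   tissue-stages observed, i.e. max of the counts, at least 1).
#' @return data.frame(subset, min_tissue_stages, fraction).
#' @export
cumulative_fraction_curve <- function(labels, gene_subsets, max_x = NULL) {
  if (is.null(max_x)) max_x <- max(1, labels$n_tissue_stages_repressed)
  out <- list()
  for (nm in names(gene_subsets)) {
    ids <- gene_subsets[[nm]]
    if (length(ids) == 0) stop("empty gene subset: ", nm)
    n <- labels$n_tissue_stages_repressed[match(ids, labels$gene_id)]
    if (anyNA(n)) stop("subset ", nm, " contains unknown gene ids")
    frac <- vapply(seq_len(max_x), function(x) mean(n >= x), numeric(1))
    out[[nm]] <- data.frame(subset = nm, min_tissue_stages = seq_len(max_x),
                            fraction = frac, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' 2x2 fold enrichment with Pearson chi-square
#'
#' Compares positive fractions between two groups: fold =
#' (a_pos/a_tot)/(b_pos/b_tot); chi-square is the Pearson statistic on the
#' 2x2 table without continuity correction, 1 df.
#'
#' @param a_pos,a_tot positives and total in group A.
#' @param b_pos,b_tot positives and total in group B.
#' @return list(fold, chi2, p, infinite_fold).
#' @export
two_by_two_enrichment <- function(a_pos, a_tot, b_pos, b_tot) {
  stopifnot(a_pos >= 0, b_pos >= 0, a_tot >= a_pos, b_tot >= b_pos)
  fold <- if (b_pos == 0) Inf else (a_pos / a_tot) / (b_pos / b_tot)
  tab <- matrix(c(a_pos, a_tot - a_pos, b_pos, b_tot - b_pos), 2, 2,
                byrow = TRUE)
  n <- sum(tab)
  # Pearson chi-square, textbook closed form N(ad - bc)^2 / row/col products
  ad_bc <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  denom <- prod(rowSums(tab)) * prod(colSums(tab))
  chi2 <- if (denom == 0) 0 else n * ad_bc^2 / denom
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(fold = fold, chi2 = chi2, p = p, infinite_fold = !is.finite(fold))
}
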