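# Synthetic-data generators. Every input the pipeline consumes can be
# simulated at desk scale with planted, recorded ground truth: gene
# annotation and TADs, replicated chromatin-state segmentations, the
# H3K27ac / ATAC / expression signal grids with planted enhancer-gene links
# and temporal dynamics, validation tables, motif occurrence matrices and
# chromatin-state emission-model families.
#
# The default sample grid is 6 tissues x 11 stages x 2 replicates, giving a
# 66-tissue-stage series per replicate (the scale of the real atlas).

CA_DEFAULT_TISSUES <- paste0("T", 1:6)
CA_DEFAULT_STAGES <- sprintf("S%02d", 1:11)

#' Generate a gene annotation and TAD set
#'
#' Non-overlapping TADs tile most of each chromosome (separated by small
#' boundary gaps); each gene carries 1-3 TSSs inside a single TAD, and at
#' least 80\% of genes are protein coding.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (default 1e7).
#' @param n_genes total genes (default 300).
#' @param n_tads TADs per chromosome (default 20).
#' @param seed RNG seed.
#' @return list(annotation, tads, genome); \code{tads$name} holds TAD ids.
#' @export
gen_annotation_and_tads <- function(n_chrom = 2, chrom_len = 1e7,
                                    n_genes = 300, n_tads = 20, seed = 1) {
  stopifnot(n_tads >= 1, n_genes >= 1)
  set.seed(seed)
  gap <- 2e4
  if (n_tads * 5e4 > chrom_len)
    stop("parameters imply overlapping TADs: chromosome too short")
  tads <- list()
  for (ci in seq_len(n_chrom)) {
    ch <- paste0("chr", ci)
    # random interior boundaries, minimum TAD span enforced by spacing
    cuts <- sort(sample(seq(5e4, chrom_len - 5e4, by = 1e4), n_tads - 1))
    starts <- c(1e4, cuts + gap / 2)
    ends <- c(cuts - gap / 2, chrom_len - 1e4)
    ok <- ends - starts >= 3e4
    tads[[ci]] <- data.frame(chrom = ch, start = starts[ok], end = ends[ok],
                             stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, tads)
  tads$name <- paste0("tad", seq_len(nrow(tads)))
  validate_intervals(tads)
  class(tads) <- c("intervals", "data.frame")

  tad_idx <- sample(seq_len(nrow(tads)), n_genes, replace = TRUE,
                    prob = (tads$end - tads$start))
  ann <- vector("list", n_genes)
  used_anchors <- list()
  for (i in seq_len(n_genes)) {
    td <- tads[tad_idx[i], ]
    n_tss <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    # keep TSSs away from the TAD edge so +/-2.5 kb windows stay inside,
    # and >= 6 kb from other genes so planted promoter windows never collide
    anchor <- NA
    for (try in 1:200) {
      prev <- used_anchors[[td$chrom]]
      cand <- sample(seq(td$start + 5e3, td$end - 5e3, by = 1), 1)
      if (is.null(prev) || all(abs(prev - cand) >= 6e3)) { anchor <- cand; break }
      if (try %% 50 == 0)  # crowded TAD: move the gene elsewhere
        td <- tads[sample(seq_len(nrow(tads)), 1,
                          prob = tads$end - tads$start), ]
    }
    if (is.na(anchor)) stop("could not place gene ", i, ": genome too crowded")
    used_anchors[[td$chrom]] <- c(used_anchors[[td$chrom]], anchor)
    tss <- sort(unique(pmin(td$end - 3e3,
                            pmax(td$start + 3e3,
                                 anchor + c(0, sample(500:3000, n_tss - 1))))))
    ann[[i]] <- data.frame(
      gene_id = sprintf("gene%04d", i), chrom = td$chrom,
      strand = sample(c("+", "-"), 1),
      biotype = if (runif(1) < 0.85) "protein_coding" else "lincRNA",
      tad = td$name, stringsAsFactors = FALSE)
    ann[[i]]$tss <- list(tss)
  }
  ann <- do.call(rbind, ann)
  genome <- setNames(rep(chrom_len, n_chrom), paste0("chr", seq_len(n_chrom)))
  list(annotation = ann, tads = tads, genome = genome)
}

# Markov run-length state sequence for one chromosome of n_bins bins.
.random_state_bins <- function(n_bins, states, p_stay = 0.9) {
  # expected run length 1/(1-p_stay); draw generously then trim
  n_runs <- ceiling(n_bins * (1 - p_stay) * 1.5) + 50
  lens <- stats::rgeom(n_runs, prob = 1 - p_stay) + 1
  while (sum(lens) < n_bins)
    lens <- c(lens, stats::rgeom(50, prob = 1 - p_stay) + 1)
  st <- sample(states, length(lens), replace = TRUE)
  rep(st, lens)[seq_len(n_bins)]
}

#' Generate replicated chromatin-state segmentations
#'
#' Per tissue-stage, two replicate segmentations over a fixed bin lattice.
#' Replicate 2 copies replicate 1's state per bin with probability
#' \code{concordance}, otherwise resamples uniformly from the alphabet.
#' Planted PcG genes receive the Polycomb state ("13") across their TSS
#' +/- 1 kb windows in both replicates for the tissue-stages listed in
#' \code{pcg_plan}; all other genes are planted active (state "1") over the
#' same window so that gene-level recovery is exact at concordance 1.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param annotation gene annotation (from \code{gen_annotation_and_tads}).
#' @param pcg_plan data.frame(gene_id, tissue, stage) of planted repression;
#'   NULL plants none.
#' @param n_states number of states (default 15).
#' @param bin_bp bin width (default 200).
#' @param concordance replicate agreement probability in [0, 1].
#' @param tissues,stages sample grid.
#' @param seed RNG seed.
#' @return list(samples = nested list [[tissue]][[stage]] of
#'   list(rep1, rep2), pcg_plan).
#' @export
gen_segmentation_replicates <- function(genome, annotation = NULL,
                                        pcg_plan = NULL, n_states = 15,
                                        bin_bp = 200, concordance = 0.95,
                                        tissues = CA_DEFAULT_TISSUES,
                                        stages = CA_DEFAULT_STAGES,
                                        seed = 1) {
  stopifnot(concordance >= 0, concordance <= 1)
  set.seed(seed)
  states <- as.character(seq_len(n_states))
  n_bins <- floor(genome / bin_bp)
  if (any(genome %% bin_bp != 0))
    .ca_log("gen_segmentation_replicates: last partial bin truncated")
  plant_window <- function(bins_chrom, ch, tss_pos, state) {
    lo <- pmax(1, floor((tss_pos - 1000) / bin_bp) + 1)
    hi <- pmin(length(bins_chrom), ceiling((tss_pos + 1000) / bin_bp))
    for (k in seq_along(lo)) bins_chrom[lo[k]:hi[k]] <- state
    bins_chrom
  }
  tss_by_chrom <- NULL
  if (!is.null(annotation)) {
    tt <- .tss_table(annotation)
    tss_by_chrom <- split(tt, tt$chrom)
  }
  samples <- list()
  for (tis in tissues) {
    samples[[tis]] <- list()
    for (stg in stages) {
      reps <- list()
      bins1 <- bins2 <- list()
      for (ch in names(genome)) {
        b1 <- .random_state_bins(n_bins[[ch]], states)
        flip <- runif(n_bins[[ch]]) > concordance
        b2 <- b1
        b2[flip] <- sample(states, sum(flip), replace = TRUE)
        if (!is.null(tss_by_chrom) && !is.null(tss_by_chrom[[ch]])) {
          tt <- tss_by_chrom[[ch]]
          planted_pcg <- if (is.null(pcg_plan)) character(0) else
            pcg_plan$gene_id[pcg_plan$tissue == tis & pcg_plan$stage == stg]
          act <- tt[!(tt$gene_id %in% planted_pcg), ]
          rep_ <- tt[tt$gene_id %in% planted_pcg, ]
          if (nrow(act)) {
            b1 <- plant_window(b1, ch, act$pos, "1")
            b2 <- plant_window(b2, ch, act$pos, "1")
          }
          if (nrow(rep_)) {
            b1 <- plant_window(b1, ch, rep_$pos, "13")
            b2 <- plant_window(b2, ch, rep_$pos, "13")
          }
        }
        bins1[[ch]] <- b1; bins2[[ch]] <- b2
      }
      mk_seg <- function(binlist, rep_no) {
        iv <- do.call(rbind, lapply(names(genome), function(ch) {
          nb <- n_bins[[ch]]
          start <- (seq_len(nb) - 1) * bin_bp
          end <- pmin(start + bin_bp, genome[[ch]])
          # force full partition: extend last bin over any truncated tail
          end[nb] <- genome[[ch]]
          .collapse_runs(rep(ch, nb), start, end, binlist[[ch]])
        }))
        segmentation(iv, genome = genome, tissue = tis, stage = stg,
                     replicate = rep_no)
      }
      samples[[tis]][[stg]] <- list(rep1 = mk_seg(bins1, 1L),
                                    rep2 = mk_seg(bins2, 2L))
    }
  }
  list(samples = samples, pcg_plan = pcg_plan)
}

#' Default planted-repression plan
#'
#' Picks \code{n_pcg} protein-coding genes and plants repression in a random
#' non-empty subset of tissue-stages for each.
#'
#' @param annotation gene annotation.
#' @param tissues,stages sample grid.
#' @param n_pcg number of PcG target genes to plant.
#' @param seed RNG seed.
#' @return data.frame(gene_id, tissue, stage).
#' @export
gen_pcg_plan <- function(annotation, tissues = CA_DEFAULT_TISSUES,
                         stages = CA_DEFAULT_STAGES, n_pcg = 30, seed = 1) {
  set.seed(seed)
  pc <- annotation$gene_id[annotation$biotype == "protein_coding"]
  genes <- sample(pc, min(n_pcg, length(pc)))
  grid <- expand.grid(tissue = tissues, stage = stages,
                      stringsAsFactors = FALSE)
  out <- lapply(genes, function(g) {
    k <- sample(seq_len(nrow(grid)), sample(1:nrow(grid), 1))
    cbind(gene_id = g, grid[k, , drop = FALSE])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# One latent log2 temporal profile across the tissue x stage grid:
# per tissue a logistic ramp with random amplitude (half the tissues silent),
# direction and midpoint, on a random baseline. Returns a vector indexed by
# the tissue-stage columns (tissue-major, stage-minor ordering).
.latent_profile <- function(n_tissues, n_stages, steepness = 0.75) {
  repeat {
    prof <- unlist(lapply(seq_len(n_tissues), function(t) {
      a <- if (runif(1) < 0.5) runif(1, 0, 0.15) else rgamma(1, 2, rate = 1)
      up <- runif(1) < 0.5
      m <- runif(1, 1.5, n_stages - 0.5)
      r <- 1 / (1 + exp(-(seq_len(n_stages) - m) / steepness))
      a * (if (up) r else 1 - r)
    }))
    # continuous condition-to-condition variation shared by everything the
    # profile drives (keeps ranks informative even in silent tissues)
    prof <- prof + runif(1, 0.5, 2) + rnorm(length(prof), 0, 0.55)
    if (sd(prof) > 0.1) return(prof)
  }
}

#' Generate the H3K27ac / ATAC / expression signal grids with planted truth
#'
#' For each planted enhancer-gene link, the enhancer H3K27ac profile and the
#' gene expression profile share a latent temporal profile (per-tissue
#' logistic ramps with random midpoints) plus Gaussian noise on the log2
#' scale, calibrated so the expected correlation across the series is
#' approximately \code{link_strength}. Unlinked entities carry independent
#' latent profiles. ATAC counts are negative binomial around a mean
#' proportional to the (optionally time-shifted) enhancer signal; planted
#' dynamic regions get an accessibility step at a chosen stage transition,
#' \code{lead} stages before the matching H3K27ac step.
#'
#' @param world output of \code{\link{gen_annotation_and_tads}}.
#' @param n_enhancers number of enhancer regions (default 400).
#' @param n_links number of planted enhancer-gene links (default 300).
#' @param link_strength target correlation of planted links, in (0, 1].
#' @param dynamics list(n_dynamic, log2fc, lead): planted accessibility
#'   steps; \code{lead} is how many stages accessibility changes before
#'   H3K27ac (default 1).
#' @param noise_sd log2-scale Gaussian noise sd for unlinked profiles; 0
#'   makes the whole grid noiseless (planted links then correlate exactly).
#' @param dispersion negative-binomial dispersion of ATAC counts (default 0.1).
#' @param tad_coregulation weight in [0, 1) of a shared per-TAD latent blended
#'   into member enhancers (0 = none; used by the correlative-map analyses).
#' @param tissues,stages,replicates sample grid.
#' @param seed RNG seed.
#' @return list(h3k27ac, atac, expression, truth). Grids carry both
#'   replicates as columns; \code{truth} is a \code{synthetic_truth} list.
#' @export
gen_signal_grid <- function(world, n_enhancers = 400, n_links = 300,
                            link_strength = 0.9,
                            dynamics = list(n_dynamic = 60, log2fc = 1.5,
                                            lead = 1),
                            noise_sd = 0.25, dispersion = 0.1,
                            tad_coregulation = 0,
                            tissues = CA_DEFAULT_TISSUES,
                            stages = CA_DEFAULT_STAGES, replicates = 2,
                            seed = 1) {
  stopifnot(link_strength > 0, link_strength <= 1)
  set.seed(seed)
  ann <- world$annotation; tads <- world$tads
  n_t <- length(tissues); n_s <- length(stages)
  n_cols <- n_t * n_s
  col_tissue <- rep(tissues, each = n_s)
  col_stage <- rep(stages, times = n_t)

  # place enhancers inside TADs, clear of TSS +/- 3 kb
  tss_all <- .tss_table(ann)
  enh <- list()
  tries <- 0
  while (length(enh) < n_enhancers && tries < n_enhancers * 50) {
    tries <- tries + 1
    td <- tads[sample(nrow(tads), 1, prob = tads$end - tads$start), ]
    if (td$end - td$start < 1e4) next
    s <- sample(seq(td$start + 1e3, td$end - 3e3, by = 1), 1)
    cand <- data.frame(chrom = td$chrom, start = s, end = s + 2000,
                       tad = td$name, stringsAsFactors = FALSE)
    near_tss <- any(tss_all$chrom == cand$chrom &
                    abs(tss_all$pos - (s + 1000)) < 4000)
    if (near_tss) next
    clash <- any(vapply(enh, function(e)
      e$chrom == cand$chrom && e$start < cand$end && cand$start < e$end,
      logical(1)))
    if (!clash) enh[[length(enh) + 1]] <- cand
  }
  enh <- do.call(rbind, enh)
  enh$enh_id <- sprintf("enh%04d", seq_len(nrow(enh)))

  # pick links: one enhancer per gene, same TAD
  pc <- ann[ann$biotype == "protein_coding", ]
  # per-TAD bipartite matching: each gene gets a distinct enhancer
  candidates <- do.call(rbind, lapply(unique(pc$tad), function(td) {
    g <- sample(pc$gene_id[pc$tad == td])
    e <- sample(enh$enh_id[enh$tad == td])
    n <- min(length(g), length(e))
    if (n == 0) return(NULL)
    data.frame(gene_id = g[seq_len(n)], enh_id = e[seq_len(n)], tad = td,
               stringsAsFactors = FALSE)
  }))
  if (is.null(candidates) || nrow(candidates) < n_links)
    stop("more links requested than enhancer-gene pairs available in TADs")
  links <- candidates[sample(nrow(candidates), n_links), ]

  # latent profiles
  enh_lat <- t(vapply(seq_len(nrow(enh)), function(i)
    .latent_profile(n_t, n_s), numeric(n_cols)))
  if (tad_coregulation > 0) {
    # blend a per-TAD latent into its member enhancers so that same-TAD
    # accessibility correlates (the structure the correlative map detects)
    for (td in unique(enh$tad)) {
      mem <- which(enh$tad == td)
      tp <- .latent_profile(n_t, n_s)
      enh_lat[mem, ] <- (1 - tad_coregulation) * enh_lat[mem, , drop = FALSE] +
        tad_coregulation * matrix(tp, length(mem), n_cols, byrow = TRUE)
    }
  }
  gene_lat <- t(vapply(seq_len(nrow(ann)), function(i)
    .latent_profile(n_t, n_s), numeric(n_cols)))
  rownames(enh_lat) <- enh$enh_id
  rownames(gene_lat) <- ann$gene_id
  # linked genes share their enhancer's latent profile (affine, rank-safe)
  gene_lat[links$gene_id, ] <- 0.8 * enh_lat[links$enh_id, ] +
    matrix(runif(n_links, 0, 0.5), n_links, n_cols)

  # planted dynamics: a >= 2-fold accessibility step, `lead` stages before
  # the matching H3K27ac step
  dyn <- NULL
  atac_lat <- enh_lat
  if (!is.null(dynamics) && dynamics$n_dynamic > 0) {
    di <- sample(seq_len(nrow(enh)), min(dynamics$n_dynamic, nrow(enh)))
    dyn <- data.frame(enh_id = enh$enh_id[di],
                      tissue = sample(tissues, length(di), replace = TRUE),
                      transition = sample(seq_len(n_s - 1 - dynamics$lead),
                                          length(di), replace = TRUE) +
                                   dynamics$lead,
                      direction = sample(c("gain", "loss"), length(di),
                                         replace = TRUE),
                      stringsAsFactors = FALSE)
    for (k in seq_len(nrow(dyn))) {
      tsel <- which(col_tissue == dyn$tissue[k])
      sidx <- match(col_stage[tsel], stages)
      sgn <- if (dyn$direction[k] == "gain") 1 else -1
      # H3K27ac step at the named transition
      step_h <- as.numeric(sidx > dyn$transition[k]) * sgn * dynamics$log2fc
      # accessibility leads by `lead` stages
      step_a <- as.numeric(sidx > dyn$transition[k] - dynamics$lead) * sgn *
        dynamics$log2fc
      enh_lat[dyn$enh_id[k], tsel] <- enh_lat[dyn$enh_id[k], tsel] + step_h
      atac_lat[dyn$enh_id[k], tsel] <- atac_lat[dyn$enh_id[k], tsel] + step_a
    }
    # dynamics modified enh_lat after link latents were copied: refresh
    gene_lat[links$gene_id, ] <- 0.8 * enh_lat[links$enh_id, ] +
      matrix(runif(n_links, 0, 0.5), n_links, n_cols)
  }

  # per-link noise sd calibrated against the Spearman target: the latent is
  # not Gaussian (ramps + wiggle), so the closed Pearson formula would
  # overshoot the noise; a short Monte Carlo bisection per link finds the sd
  # at which E[SCC(L + e1, 0.8 L + e2)] matches link_strength
  calibrate_sd <- function(L, target, n_mc = 30) {
    if (target >= 0.999) return(0)
    g <- function(s) {
      mean(vapply(seq_len(n_mc), function(i)
        cor(L + rnorm(length(L), 0, s),
            0.8 * L + rnorm(length(L), 0, 0.8 * s),
            method = "spearman"), numeric(1)))
    }
    lo <- 0; hi <- 4 * sd(L)
    for (it in 1:10) {
      mid <- (lo + hi) / 2
      if (g(mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  sd_enh <- rep(noise_sd, nrow(enh))
  sd_gene <- rep(noise_sd, nrow(ann))
  if (noise_sd > 0) {
    link_s <- vapply(seq_len(n_links), function(k)
      calibrate_sd(enh_lat[links$enh_id[k], ], link_strength), numeric(1))
    sd_enh[match(links$enh_id, enh$enh_id)] <- link_s
    sd_gene[match(links$gene_id, ann$gene_id)] <- 0.8 * link_s
  } else {
    sd_enh[] <- 0; sd_gene[] <- 0
    gene_lat[links$gene_id, ] <- 0.8 * enh_lat[links$enh_id, ] + 0.1
  }

  reps <- seq_len(replicates)
  mk <- function(lat, sds) {
    vals <- do.call(cbind, lapply(reps, function(r)
      lat + matrix(rnorm(length(lat), 0, rep(sds, ncol(lat))),
                   nrow(lat), ncol(lat))))
    vals
  }
  h3_log2 <- mk(enh_lat, sd_enh)
  expr_log2 <- mk(gene_lat, sd_gene)
  tissue_cols <- rep(col_tissue, replicates)
  stage_cols <- rep(col_stage, replicates)
  rep_cols <- rep(reps, each = n_cols)

  enh_iv <- intervals(enh$chrom, enh$start, enh$end, name = enh$enh_id)
  enh_iv$tad <- enh$tad
  h3 <- signal_grid(2^h3_log2, tissue_cols, stage_cols, rep_cols,
                    regions = enh_iv, ids = enh$enh_id, units = "RPKM",
                    stage_levels = stages)
  expr <- signal_grid(2^expr_log2, tissue_cols, stage_cols, rep_cols,
                      ids = ann$gene_id, units = "FPKM",
                      stage_levels = stages)

  # ATAC counts: NB around a mean proportional to the (lead-shifted) signal
  atac_log2 <- mk(atac_lat, pmin(sd_enh, 0.15))
  mu <- 30 * 2^atac_log2
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow(mu), ncol(mu))
  atac <- signal_grid(counts, tissue_cols, stage_cols, rep_cols,
                      regions = enh_iv, ids = enh$enh_id, units = "raw_count",
                      stage_levels = stages)

  truth <- synthetic_truth(
    true_links = data.frame(links,
                            enh$chrom[match(links$enh_id, enh$enh_id)],
                            enh$start[match(links$enh_id, enh$enh_id)],
                            enh$end[match(links$enh_id, enh$enh_id)],
                            planted_strength = link_strength,
                            stringsAsFactors = FALSE),
    dynamic_regions = dyn, seed = seed)
  names(truth$true_links)[4:6] <- c("chrom", "start", "end")
  list(h3k27ac = h3, atac = atac, expression = expr, truth = truth,
       enhancers = enh)
}

#' Container for planted ground truth
#'
#' @param true_links data.frame of planted enhancer-gene links.
#' @param dynamic_regions data.frame of planted dynamic elements.
#' @param pcg_genes character vector of planted PcG target genes.
#' @param state_signatures emission matrix used to simulate model families.
#' @param validation_curve parameters of the rank -> positive-probability map.
#' @param seed integer seed the data were generated under.
#' @return list of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(true_links = NULL, dynamic_regions = NULL,
                            pcg_genes = NULL, state_signatures = NULL,
                            validation_curve = NULL, seed = NA) {
  structure(list(true_links = true_links, dynamic_regions = dynamic_regions,
                 pcg_genes = pcg_genes, state_signatures = state_signatures,
                 validation_curve = validation_curve, seed = seed),
            class = "synthetic_truth")
}

#' Serialize / restore a truth object as JSON
#' @param truth synthetic_truth object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_truth, x[c("true_links", "dynamic_regions", "pcg_genes",
                               "state_signatures", "validation_curve", "seed")])
}

#' Generate validation records and a motif-occurrence matrix
#'
#' Element i is positive with probability \code{curve(rank_i)}; the curve must
#' be monotone non-increasing in rank. Per-dataset ranks are noisy
#' re-rankings of the underlying order. Motif occurrences are planted at
#' cluster-specific frequencies against a background frequency.
#'
#' @param n_elements number of elements.
#' @param curve function rank -> probability, or a numeric vector of length
#'   \code{n_elements}.
#' @param rank_noise sd of the Gaussian jitter applied to ranks per dataset.
#' @param n_datasets replicate ranked datasets (default 2).
#' @param n_motifs motifs in the occurrence matrix.
#' @param enrichment_spec data.frame(motif, cluster, p_in, p_bg) of planted
#'   occurrence frequencies; NULL plants none (uniform background 0.1).
#' @param clusters integer cluster id per element (for motif planting).
#' @param seed RNG seed.
#' @return list(validation, motifs, curve_values).
#' @export
gen_validation_and_motif_fixtures <- function(n_elements = 300,
                                              curve = function(r)
                                                pmax(0.05, 0.7 - 0.6 * r / 300),
                                              rank_noise = 10, n_datasets = 2,
                                              n_motifs = 20,
                                              enrichment_spec = NULL,
                                              clusters = NULL, seed = 1) {
  set.seed(seed)
  ranks <- seq_len(n_elements)
  pr <- if (is.function(curve)) curve(ranks) else rep_len(curve, n_elements)
  if (any(diff(pr) > 1e-12)) stop("validation curve must be non-increasing")
  if (any(pr < 0 | pr > 1)) stop("curve probabilities must lie in [0, 1]")
  positive <- rbinom(n_elements, 1, pr) == 1
  rank_mat <- vapply(seq_len(n_datasets), function(d)
    rank(ranks + rnorm(n_elements, 0, rank_noise), ties.method = "first"),
    numeric(n_elements))
  colnames(rank_mat) <- paste0("rank_rep", seq_len(n_datasets))
  starts <- sample(seq(0, 9.9e6, by = 1e3), n_elements)
  validation <- data.frame(element = sprintf("el%04d", ranks),
                           chrom = sample(c("chr1", "chr2"), n_elements,
                                          replace = TRUE),
                           start = starts, end = starts + 1500,
                           rank_mat, tissue = "T1", positive = positive,
                           stringsAsFactors = FALSE)
  if (is.null(clusters)) clusters <- rep(0L, n_elements)
  occ <- matrix(rbinom(n_elements * n_motifs, 1, 0.1), n_elements, n_motifs,
                dimnames = list(validation$element,
                                sprintf("motif%02d", seq_len(n_motifs))))
  if (!is.null(enrichment_spec)) {
    for (k in seq_len(nrow(enrichment_spec))) {
      m <- enrichment_spec$motif[k]
      in_cl <- clusters == enrichment_spec$cluster[k]
      occ[in_cl, m] <- rbinom(sum(in_cl), 1, enrichment_spec$p_in[k])
      occ[!in_cl, m] <- rbinom(sum(!in_cl), 1, enrichment_spec$p_bg[k])
    }
  }
  list(validation = validation, motifs = occ, curve_values = pr)
}

#' Simulate a complete desk-scale atlas and write it to disk
#'
#' Generates annotation + TADs, replicated segmentations with planted PcG
#' genes, the three signal grids with planted links and dynamics, and
#' validation/motif fixtures; writes everything in the package's plain-text
#' formats plus a JSON truth record.
#'
#' @param outdir output directory (created if needed).
#' @param seed master RNG seed; sub-generators use offsets of it.
#' @param n_genes,n_enhancers,n_links,n_pcg,concordance world parameters
#'   (kept small by default so a simulation stays desk-sized).
#' @param tissues,stages sample grid.
#' @return invisibly, the in-memory world:
#'   list(world, segs, grids, plan, fixtures, truth).
#' @export
simulate_atlas <- function(outdir, seed = 1, n_genes = 120, n_enhancers = 150,
                           n_links = 60, n_pcg = 15, concordance = 0.95,
                           tissues = c("T1", "T2"),
                           stages = c("S01", "S02", "S03")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- gen_annotation_and_tads(n_chrom = 2, chrom_len = 2e6,
                               n_genes = n_genes, n_tads = 8, seed = seed)
  plan <- gen_pcg_plan(w$annotation, tissues, stages, n_pcg = n_pcg,
                       seed = seed + 1)
  segs <- gen_segmentation_replicates(w$genome, w$annotation, plan,
                                      concordance = concordance,
                                      tissues = tissues, stages = stages,
                                      seed = seed + 2)
  grids <- gen_signal_grid(w, n_enhancers = n_enhancers, n_links = n_links,
                           tissues = tissues, stages = stages,
                           seed = seed + 3)
  fx <- gen_validation_and_motif_fixtures(seed = seed + 4)
  write_annotation(w$annotation, file.path(outdir, "annotation.tsv"))
  write_bed(w$tads, file.path(outdir, "tads.bed"))
  segdir <- file.path(outdir, "segmentations")
  dir.create(segdir, showWarnings = FALSE)
  for (tis in tissues) for (stg in stages) for (r in 1:2) {
    s <- segs$samples[[tis]][[stg]][[paste0("rep", r)]]
    write_segmentation(s, file.path(segdir,
                                    sprintf("%s_%s_rep%d.bed", tis, stg, r)))
  }
  write_signal_grid(grids$h3k27ac, file.path(outdir, "h3k27ac_rpkm.tsv"))
  write_signal_grid(grids$atac, file.path(outdir, "atac_counts.tsv"))
  write_signal_grid(grids$expression, file.path(outdir, "expression_fpkm.tsv"))
  write.table(fx$validation, file.path(outdir, "validation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(element = rownames(fx$motifs), fx$motifs),
              file.path(outdir, "motif_occurrences.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- grids$truth
  truth$pcg_genes <- unique(plan$gene_id)
  truth$validation_curve <- list(type = "linear_decay", p0 = 0.7,
                                 slope = -0.6, floor = 0.05)
  write_truth_json(truth, file.path(outdir, "truth.json"))
  invisible(list(world = w, segs = segs, grids = grids, plan = plan,
                 fixtures = fx, truth = truth))
}

# --- emission-model families -------------------------------------------------

# 16 codewords of the extended Hamming [8,4,4] code: any two distinct
# signatures differ in >= 4 marks, giving well-separated state signatures.
.hamming_codebook <- function() {
  G <- rbind(c(1, 1, 1, 1, 1, 1, 1, 1),
             c(0, 0, 0, 0, 1, 1, 1, 1),
             c(0, 0, 1, 1, 0, 0, 1, 1),
             c(0, 1, 0, 1, 0, 1, 0, 1))
  msgs <- as.matrix(expand.grid(rep(list(0:1), 4)))
  (msgs %*% G) %% 2
}

#' Generate a synthetic family of emission models
#'
#' Plants \code{n_signatures} well-separated state signatures (combinatorial
#' mark-presence patterns, pairwise Hamming distance >= 4 for the default
#' 8-mark, <= 16-signature case) and builds, for each k in \code{ks} and each
#' replicate series, an emission model whose states are noisy copies of a
#' rotating subset of the signatures (k < n_signatures) or of all signatures
#' plus duplicates (k >= n_signatures).
#'
#' @param n_signatures planted signature count (default 15).
#' @param n_marks histone marks (default 8).
#' @param ks model sizes (default 2:24).
#' @param n_series replicate series (default 2).
#' @param noise_sd Gaussian sd added to emission entries (default 0.02).
#' @param seed RNG seed.
#' @return list(families = list of named model lists, signatures).
#' @export
gen_model_family <- function(n_signatures = 15, n_marks = 8, ks = 2:24,
                             n_series = 2, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  if (n_marks == 8 && n_signatures <= 16) {
    cb <- .hamming_codebook()
    sig <- cb[sample(16, n_signatures), , drop = FALSE]
  } else {
    # greedy farthest-point selection over random binary patterns
    pool <- matrix(rbinom(256 * n_marks, 1, 0.5), 256, n_marks)
    pool <- unique(pool)
    sig <- pool[1, , drop = FALSE]
    while (nrow(sig) < n_signatures) {
      d <- apply(pool, 1, function(p)
        min(colSums(abs(t(sig) - p))))
      sig <- rbind(sig, pool[which.max(d), ])
    }
  }
  sig <- sig * 0.9 + 0.05
  colnames(sig) <- paste0("mark", seq_len(n_marks))
  mk_model <- function(k, offset) {
    idx <- if (k <= n_signatures) ((offset + seq_len(k) - 1) %% n_signatures) + 1
           else c(seq_len(n_signatures),
                  sample(n_signatures, k - n_signatures, replace = TRUE))
    em <- sig[idx, , drop = FALSE] +
      matrix(rnorm(k * n_marks, 0, noise_sd), k, n_marks)
    emission_model(pmin(pmax(em, 0), 1))
  }
  families <- lapply(seq_len(n_series), function(s) {
    fam <- lapply(seq_along(ks), function(i) mk_model(ks[i], offset = i))
    names(fam) <- as.character(ks)
    fam
  })
  list(families = families, signatures = sig)
}
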