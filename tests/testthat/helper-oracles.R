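# Independent brute-force oracles used against the interval algebra and the
# segmentation machinery: everything here works base-by-base on small genomes
# and never calls the code paths it checks.

# boolean coverage vector of a genome (list of per-chromosome logical vectors)
oracle_coverage <- function(iv, genome) {
  cov <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    cov[[ch]][(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  cov
}

oracle_union_bases <- function(iv, genome) {
  sum(vapply(oracle_coverage(iv, genome), sum, numeric(1)))
}

oracle_subtract_cov <- function(a, b, genome) {
  ca <- oracle_coverage(a, genome)
  cb <- oracle_coverage(b, genome)
  mapply(function(x, y) x & !y, ca, cb, SIMPLIFY = FALSE)
}

# per-base state vector of a segmentation (character, one per bp)
oracle_state_vector <- function(seg, ch) {
  iv <- seg$intervals[seg$intervals$chrom == ch, ]
  rep(iv$state, iv$end - iv$start)
}

# random interval set on a small genome
random_intervals <- function(n, genome, max_len = 500) {
  ch <- sample(names(genome), n, replace = TRUE)
  len <- sample(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample(genome[[ch[i]]] - len[i], 1), numeric(1))
  intervals(ch, start, start + len)
}

# random segmentation over bin_bp bins
random_segmentation <- function(genome, bin_bp, states, tissue = "T1",
                                stage = "S1", replicate = 1) {
  iv <- do.call(rbind, lapply(names(genome), function(ch) {
    nb <- genome[[ch]] / bin_bp
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * bin_bp,
               end = seq_len(nb) * bin_bp,
               state = sample(states, nb, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  segmentation(iv, genome = genome, tissue = tissue, stage = stage,
               replicate = replicate)
}

# exact enumeration of the two-sided Wilcoxon signed-rank p-value
# (no ties, n <= 12): distribution of V = sum of positive ranks over all
# 2^n sign assignments
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-9)
  p
}

# exhaustive best k-partition WSS ratio for small point sets
oracle_best_partition_ratio <- function(x, k) {
  n <- nrow(x)
  tot <- sum(scale(x, scale = FALSE)^2)
  best <- Inf
  # enumerate assignments in restricted growth form (set partitions into <= k)
  assign_next <- function(lab, mx) {
    if (length(lab) == n) {
      if (length(unique(lab)) == k) {
        wss <- sum(vapply(unique(lab), function(g) {
          pts <- x[lab == g, , drop = FALSE]
          sum(scale(pts, scale = FALSE)^2)
        }, numeric(1)))
        best <<- min(best, wss)
      }
      return(invisible(NULL))
    }
    for (g in seq_len(min(mx + 1, k))) {
      assign_next(c(lab, g), max(mx, g))
    }
  }
  assign_next(1L, 1L)
  1 - best / tot
}

# shared small world for pipeline tests (built once per test file)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_annotation_and_tads(n_chrom = 1, chrom_len = 2e6,
                                        n_genes = 60, n_tads = 6, seed = 42)
    cache
  }
})
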