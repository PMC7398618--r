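# Interval algebra and shared matrix transforms, checked against per-base
# boolean oracles and closed forms.

test_that("merge_intervals: trivial cases and label concatenation", {
  empty <- merge_intervals(intervals())
  expect_equal(nrow(empty), 0)
  m <- merge_intervals(intervals(c("chr1", "chr1"), c(0, 5), c(10, 20)))
  expect_equal(m$start, 0)
  expect_equal(m$end, 20)
  lab <- merge_intervals(intervals(c("chr1", "chr1", "chr1"), c(0, 5, 100),
                                   c(10, 20, 120), name = c("a", "b", "c")))
  expect_equal(lab$name, c("a,b", "c"))
  expect_error(merge_intervals(data.frame(chrom = "chr1", start = 10, end = 5)),
               "malformed")
})

test_that("merge/subtract agree with per-base oracles on random sets", {
  set.seed(7)
  genome <- c(chr1 = 5e4, chr2 = 5e4)
  for (rep in 1:5) {
    a <- random_intervals(200, genome)
    b <- random_intervals(200, genome)
    m <- merge_intervals(a)
    expect_equal(sum(m$end - m$start), oracle_union_bases(a, genome))
    # merged set must be non-overlapping and sorted
    for (ch in names(genome)) {
      mm <- m[m$chrom == ch, ]
      if (nrow(mm) > 1) expect_true(all(mm$start[-1] > mm$end[-nrow(mm)] - 1))
    }
    s <- subtract_intervals(a, b)
    oc <- oracle_subtract_cov(a, b, genome)
    expect_equal(sum(s$end - s$start), sum(vapply(oc, sum, numeric(1))))
    # every returned base really is in a-but-not-b
    sc <- oracle_coverage(s, genome)
    expect_true(all(mapply(function(x, y) all(!x | y), sc, oc)))
  }
})

test_that("subtract_intervals trivial identities", {
  a <- intervals("chr1", 0, 100)
  expect_equal(subtract_intervals(a, intervals())$end, 100)
  sp <- subtract_intervals(a, intervals("chr1", 40, 60))
  expect_equal(sp$start, c(0, 60))
  expect_equal(sp$end, c(40, 100))
})

test_that("window_overlap matches an all-pairs check", {
  expect_true(window_overlap(intervals("chr1", 1500, 1600),
                             data.frame(chrom = "chr1", pos = 1000), 1000))
  expect_false(window_overlap(intervals("chr1", 2500, 2600),
                              data.frame(chrom = "chr1", pos = 1000), 1000))
  set.seed(8)
  genome <- c(chr1 = 1e4, chr2 = 1e4)
  regions <- random_intervals(100, genome, max_len = 100)
  anchors <- data.frame(chrom = sample(names(genome), 40, replace = TRUE),
                        pos = sample(1e4, 40))
  got <- window_overlap(regions, anchors, 250)
  want <- vapply(seq_len(nrow(regions)), function(i)
    any(anchors$chrom == regions$chrom[i] &
        regions$start[i] < anchors$pos + 250 &
        regions$end[i] > anchors$pos - 250), logical(1))
  expect_equal(got, want)
})

test_that("quantile_normalize: forced example, idempotence, sorted-column identity", {
  x <- cbind(c(1, 2, 3), c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))
  same <- cbind(c(2, 1, 5), c(2, 1, 5))
  expect_equal(quantile_normalize(same), same)
  set.seed(1)
  r <- matrix(rnorm(400), 80, 5)
  qr <- quantile_normalize(r)
  ref <- sort(qr[, 1])
  for (j in 2:5) expect_equal(sort(qr[, j]), ref)
  expect_equal(quantile_normalize(qr), qr)  # idempotent
  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "single column")
})

test_that("quantile_normalize: ties get the mean of their reference quantiles", {
  set.seed(2)
  x <- matrix(sample(1:8, 60, replace = TRUE), 12, 5)  # plenty of ties
  qn <- quantile_normalize(x)
  ref <- rowMeans(apply(x, 2, sort))
  for (j in 1:5) {
    for (v in unique(x[, j])) {
      slots <- which(sort(x[, j]) == v)
      expect_equal(unique(qn[x[, j] == v, j]), mean(ref[slots]))
    }
  }
  # on tie-free data the result matches the standard implementation
  y <- matrix(rnorm(60), 12, 5)
  expect_equal(unname(quantile_normalize(y)),
               unname(limma::normalizeQuantiles(y)))
})

test_that("unit_vector_rows: norms, cosine preservation, zero rows dropped", {
  expect_equal(unit_vector_rows(matrix(c(3, 4), 1, 2))[1, ], c(0.6, 0.8))
  expect_equal(unit_vector_rows(matrix(2, 1, 4))[1, ], rep(0.5, 4))
  set.seed(3)
  m <- matrix(rnorm(60), 10, 6)
  u <- unit_vector_rows(m)
  expect_true(all(abs(sqrt(rowSums(u^2)) - 1) < 1e-12))
  cos_before <- m %*% t(m) / outer(sqrt(rowSums(m^2)), sqrt(rowSums(m^2)))
  expect_equal(u %*% t(u), cos_before, tolerance = 1e-12)
  expect_warning(z <- unit_vector_rows(rbind(m, 0)), "all-zero")
  expect_equal(nrow(z), 10)
})

test_that("bh_adjust: hand example, formula oracle, monotonicity", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  sp <- sort(p)
  expect_true(all(diff(bh_adjust(sp)) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("log2_with_zero_floor", {
  x <- matrix(c(0, 2, 4, 8), 2, 2, byrow = TRUE)
  expect_equal(log2_with_zero_floor(x), matrix(c(1, 1, 2, 3), 2, 2,
                                               byrow = TRUE))
  y <- matrix(c(1, 2, 4, 8), 2, 2)
  expect_equal(log2_with_zero_floor(y), log2(y))
  set.seed(5)
  z <- matrix(rexp(40), 8, 5); z[sample(40, 6)] <- 0
  expect_equal(min(log2_with_zero_floor(z)), log2(min(z[z > 0])))
  expect_error(log2_with_zero_floor(matrix(0, 2, 2)), "all-zero")
})

test_that("frot counts reads near TSSs", {
  tss <- data.frame(chrom = "chr1", pos = 5000)
  reads <- data.frame(chrom = "chr1", pos = c(rep(5100, 3), rep(90000, 7)))
  expect_equal(frot(reads, tss), 0.3)
  expect_equal(frot(data.frame(chrom = "chr1", pos = rep(5000, 5)), tss), 1)
  set.seed(6)
  rr <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                   pos = sample(2e4, 200))
  tt <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                   pos = sample(2e4, 10))
  want <- mean(vapply(seq_len(200), function(i)
    any(tt$chrom == rr$chrom[i] & rr$pos[i] >= tt$pos - 1000 &
        rr$pos[i] < tt$pos + 1000), logical(1)))
  expect_equal(frot(rr, tt), want)
  expect_error(frot(data.frame(chrom = character(), pos = numeric()), tss))
})

test_that("correlation_by_separation groups pairs by stage distance", {
  set.seed(7)
  base <- rnorm(50)
  # identical replicates at each stage, drifting across stages
  stages <- paste0("S", 1:4)
  vals <- do.call(cbind, lapply(1:4, function(s) {
    v <- base + s * 0.8 + rnorm(50, 0, 0.2 * s)
    cbind(v, v)
  }))
  g <- signal_grid(vals, tissue = "T1", stage = rep(stages, each = 2),
                   replicate = rep(1:2, 4))
  tab <- correlation_by_separation(g, "spearman")
  expect_equal(unique(tab$correlation[tab$separation == 0]), 1)
  # drifting signal: median correlation non-increasing in separation
  set.seed(8)
  drift <- matrix(0, 50, 6)
  drift[, 1] <- rnorm(50)
  for (s in 2:6)  # AR(1): expected correlation 0.9^separation
    drift[, s] <- 0.9 * drift[, s - 1] + sqrt(1 - 0.81) * rnorm(50)
  g2 <- signal_grid(drift, tissue = "T1", stage = paste0("S", 1:6),
                    replicate = 1)
  tab2 <- correlation_by_separation(g2, "pearson")
  med <- tapply(tab2$correlation, tab2$separation, median)
  expect_true(all(diff(med) <= 0.15))  # non-increasing up to noise
  expect_true(med[1] > med[length(med)])
})
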