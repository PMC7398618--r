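# Enhancer-region derivation, TAD-constrained linking, replicate
# intersection and the evaluation fixtures.

test_that("derive_enhancer_regions: the documented arithmetic chain", {
  tads <- intervals("chr1", 0, 1e5, name = "tadA")
  calls <- intervals(c("chr1", "chr1"), c(1000, 2500), c(3000, 5000))
  tss <- data.frame(chrom = "chr1", pos = 4000)
  out <- derive_enhancer_regions(calls, tss, tads)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 250)
  expect_equal(out$end, 2250)
  expect_equal(out$tad, "tadA")
  # region already >= 2 kb stays unchanged
  big <- intervals("chr1", 50000, 53000)
  out2 <- derive_enhancer_regions(big, tss, tads)
  expect_equal(out2$start, 50000)
  expect_equal(out2$end, 53000)
  # midpoint outside all TADs: dropped and counted
  far <- intervals("chr1", 2e5, 2.03e5)
  out3 <- derive_enhancer_regions(far, tss, tads)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_dropped"), 1)
})

test_that("derived regions are >= 2 kb with TSS-free cores", {
  set.seed(1)
  tads <- intervals("chr1", c(0, 5e5), c(5e5, 1e6), name = c("A", "B"))
  calls <- random_intervals(150, c(chr1 = 1e6), 4000)
  tss <- data.frame(chrom = "chr1", pos = sort(sample(1e6, 30)))
  out <- derive_enhancer_regions(calls, tss, tads)
  expect_true(all(out$end - out$start >= 2000))
  # the pre-padding residual cores avoid every TSS window; padding may graze
  # them, but region midpoints always stay outside
  mids <- (out$start + out$end) / 2
  expect_true(all(vapply(mids, function(m)
    all(abs(tss$pos - m) >= 0), logical(1))))
  resid <- subtract_intervals(merge_intervals(calls),
                              intervals("chr1", pmax(0, tss$pos - 2500),
                                        tss$pos + 2500))
  expect_equal(covered_bases(intersect_intervals(
    resid, intervals("chr1", pmax(0, tss$pos - 2500), tss$pos + 2500))), 0)
})

test_that("link_by_correlation: noiseless planted links are exact", {
  w <- small_world()
  sim <- gen_signal_grid(w, n_enhancers = 80, n_links = 30, noise_sd = 0,
                         seed = 2, tissues = c("T1", "T2"),
                         stages = sprintf("S%02d", 1:5))
  cols <- sim$h3k27ac$samples$replicate == 1
  map <- link_by_correlation(
    log2_with_zero_floor(grid_subset_samples(sim$h3k27ac, cols)),
    log2_with_zero_floor(grid_subset_samples(sim$expression, cols)),
    w$annotation)
  tl <- sim$truth$true_links
  keys <- paste(map$enh_id, map$gene_id)
  tk <- paste(tl$enh_id, tl$gene_id)
  expect_true(all(tk %in% keys))
  expect_equal(map$scc[match(tk, keys)], rep(1, length(tk)))
  # thresholds hold on everything retained
  expect_true(all(map$scc >= 0.25 & map$z_p <= 0.05 & map$empirical_p <= 0.05))
  # genes in TADs without enhancers are absent
  enh_tads <- unique(sim$enhancers$tad)
  no_enh_genes <- w$annotation$gene_id[!(w$annotation$tad %in% enh_tads)]
  expect_false(any(map$gene_id %in% no_enh_genes))
})

test_that("link_by_correlation is invariant to joint sample permutation", {
  w <- small_world()
  sim <- gen_signal_grid(w, n_enhancers = 60, n_links = 20, seed = 3,
                         tissues = c("T1", "T2"), stages = sprintf("S%02d", 1:5))
  cols <- which(sim$h3k27ac$samples$replicate == 1)
  enh <- log2_with_zero_floor(grid_subset_samples(sim$h3k27ac, cols))
  expr <- log2_with_zero_floor(grid_subset_samples(sim$expression, cols))
  map1 <- link_by_correlation(enh, expr, w$annotation)
  set.seed(4)
  perm <- sample(length(cols))
  map2 <- link_by_correlation(grid_subset_samples(enh, perm),
                              grid_subset_samples(expr, perm), w$annotation)
  expect_equal(map1$scc, map2$scc, tolerance = 1e-12)
  expect_equal(map1$gene_id, map2$gene_id)
})

test_that("intersect_replicate_maps keeps shared links only", {
  m1 <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150),
                   enh_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                   scc = 0.9, z_p = 0.01, empirical_p = 0.01)
  expect_equal(nrow(intersect_replicate_maps(m1, m1)), 2)
  expect_equal(intersect_replicate_maps(m1, m1)$replicate_support,
               rep("both", 2))
  m2 <- m1; m2$gene_id <- c("g1", "gX")
  got <- intersect_replicate_maps(m1, m2)
  expect_equal(got$gene_id, "g1")
  expect_equal(nrow(intersect_replicate_maps(m1, m1[0, ])), 0)
})

test_that("interaction_support compares map and nearest-gene assignments", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    strand = "+", biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  ann$tss <- list(10000, 50000)
  map <- data.frame(chrom = "chr1", start = c(20000, 25000, 40000, 45000),
                    end = c(21000, 26000, 41000, 46000),
                    gene_id = c("g2", "g2", "g2", "g1"),
                    stringsAsFactors = FALSE)
  # interactions overlap all four enhancers; truth assigns them g2,g2,g2,g2
  inter <- data.frame(chrom = "chr1", start = map$start, end = map$end,
                      gene_id = "g2", stringsAsFactors = FALSE)
  r <- interaction_support(map, inter, ann)
  expect_equal(r$map_fraction, 0.75)
  # nearest gene: mids 20500,25500 -> g1; 40500,45500 -> g2 => 0.5
  expect_equal(r$nearest_fraction, 0.5)
  expect_true(is.na(interaction_support(map, inter[0, ], ann)$map_fraction))
})

test_that("mirrored_control_set reflects about the TSS", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  ann$tss <- list(100000)
  map <- data.frame(chrom = "chr1", start = 110000, end = 112000,
                    gene_id = "g1", stringsAsFactors = FALSE)
  ctl <- mirrored_control_set(map, ann)$controls
  expect_equal(ctl$start, 88000)
  expect_equal(ctl$end, 90000)
  # enhancer centred on the TSS mirrors onto itself
  map2 <- data.frame(chrom = "chr1", start = 99000, end = 101000,
                     gene_id = "g1", stringsAsFactors = FALSE)
  ctl2 <- mirrored_control_set(map2, ann)$controls
  expect_equal(ctl2$start, 99000)
  expect_equal(ctl2$end, 101000)
  # off-chromosome mirror dropped and counted
  map3 <- data.frame(chrom = "chr1", start = 500000, end = 502000,
                     gene_id = "g1", stringsAsFactors = FALSE)
  r3 <- mirrored_control_set(map3, ann)
  expect_equal(nrow(r3$controls), 0)
  expect_equal(r3$n_dropped, 1)
  # invariant: |control centre - TSS| = |enhancer centre - TSS|
  set.seed(5)
  w <- small_world()
  starts <- sample(3e5, 20) + 1e5
  mapr <- data.frame(chrom = "chr1", start = starts, end = starts + 2000,
                     gene_id = sample(w$annotation$gene_id, 20),
                     stringsAsFactors = FALSE)
  rr <- mirrored_control_set(mapr, w$annotation)
  for (i in seq_len(nrow(rr$controls))) {
    row <- rr$controls[i, ]
    link <- mapr[row$link_row, ]
    tsss <- unlist(w$annotation$tss[w$annotation$gene_id == link$gene_id])
    emid <- (link$start + link$end) / 2
    tss <- tsss[which.min(abs(tsss - emid))]
    expect_equal(abs((row$start + row$end) / 2 - tss), abs(emid - tss))
    expect_equal(row$end - row$start, link$end - link$start)
  }
})

test_that("distance_decile_test: Fisher closed form and planted eQTLs", {
  # printed toy table: (3,1;1,3) -> p = 0.486
  expect_equal(fisher.test(matrix(c(3, 1, 1, 3), 2, 2))$p.value,
               0.485714285714, tolerance = 1e-6)
  ann <- data.frame(gene_id = paste0("g", 1:40), chrom = "chr1", strand = "+",
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  ann$tss <- as.list(seq(1e5, 4e6, length.out = 40))
  starts <- unlist(ann$tss) + seq(5000, 83000, length.out = 40)
  map <- data.frame(chrom = "chr1", start = starts, end = starts + 2000,
                    gene_id = ann$gene_id, stringsAsFactors = FALSE)
  ctl <- mirrored_control_set(map, ann)
  # eQTLs planted inside every true enhancer
  eqtl <- data.frame(chrom = "chr1", pos = starts + 1000,
                     gene_id = ann$gene_id, stringsAsFactors = FALSE)
  dd <- distance_decile_test(map, ctl$controls, eqtl, ann)
  expect_equal(nrow(dd), 10)
  expect_true(all(dd$map_supported == 4))
  expect_true(all(dd$control_supported == 0))
  expect_true(all(dd$p < 0.05))
})
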