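test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 5, n_genes = 30)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$truth, g2$truth)
  c1 <- generate_counts(cfg)
  c2 <- generate_counts(cfg)
  expect_identical(c1$counts$counts, c2$counts$counts)
  j1 <- generate_junctions(cfg, g1$annotation)
  j2 <- generate_junctions(cfg, g1$annotation)
  expect_identical(j1$junction_tab, j2$junction_tab)
  expect_identical(generate_cross(cfg)$cross, generate_cross(cfg)$cross)
})

test_that("planted motif instances are present verbatim at recorded spans", {
  cfg <- synthetic_config(seed = 17, n_genes = 60)
  gen <- generate_genome(cfg)
  tr <- gen$truth
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    slice <- substring(gen$sequences[[tr$seqid[i]]], tr$start[i] + 1L,
                       tr$end[i])
    expect_identical(slice, tr$instance[i])
  }
})

test_that("a motif-free background yields zero hits on both strands", {
  cfg <- synthetic_config(seed = 23, n_genes = 20, gt_factor = 0,
                          plant_rates = matrix(0, 3, 4,
                            dimnames = list(1:3,
                              c("intron", "exon", "five_prime_utr",
                                "three_prime_utr"))))
  gen <- generate_genome(cfg)
  ht <- annotate_gene_hits(gen$annotation, gen$sequences)
  expect_equal(nrow(ht$hits), 0)
  expect_false(any(ht$has_site))
})

test_that("planted DE structure has the configured size and direction skew", {
  cfg <- synthetic_config(seed = 29, n_genes = 100, de_fraction = 0.1)
  gc <- generate_counts(cfg)
  tr <- gc$truth
  expect_equal(sum(tr$de_ko), 10)
  expect_equal(sum(tr$direction_ko == "up", na.rm = TRUE), 8)  # 3:1 up
  expect_equal(sum(tr$de_oe), 10)
  expect_equal(sum(tr$direction_oe == "down", na.rm = TRUE), 8)
  # rescue statuses partition the knockout-DE set
  expect_true(all(!is.na(tr$rescue_status[tr$de_ko])))
  expect_true(all(is.na(tr$rescue_status[!tr$de_ko])))
  # null genes are centred: group-mean log2 difference averages ~0
  cm <- gc$counts$counts
  d <- gc$design
  nulls <- which(!tr$de_ko)
  diffs <- log2(rowMeans(cm[nulls, d$sample_id[d$genotype == "G2"]]) + 1) -
    log2(rowMeans(cm[nulls, d$sample_id[d$genotype == "A1"]]) + 1)
  expect_lt(abs(mean(diffs)), 0.1)
  # a too-small DE fraction warns and plants nothing
  cfg2 <- synthetic_config(seed = 29, n_genes = 100, de_fraction = 0.001)
  expect_warning(gc2 <- generate_counts(cfg2), "zero DE genes")
  expect_equal(sum(gc2$truth$de_ko), 0)
})

test_that("junction tables encode the planted isoform switches", {
  cfg <- synthetic_config(seed = 31, n_genes = 40)
  gen <- generate_genome(cfg)
  ju <- generate_junctions(cfg, gen$annotation)
  tr <- ju$truth
  expect_true(any(tr$switch_ko))
  # per-sample totals over a gene's junction rows are conserved
  jt <- ju$junction_tab
  d <- ju$design
  for (gid in unique(jt$gene_id)[1:5]) {
    rows <- jt[jt$gene_id == gid, d$sample_id]
    er <- ju$exon_tab[ju$exon_tab$gene_id == gid, d$sample_id]
    expect_true(all(colSums(er) >= colSums(rows)))
  }
  # switch genes reverse the dominant first junction between G2 and A1
  sw <- tr$gene_id[tr$switch_ko][1]
  j <- jt[jt$gene_id == sw, ]
  a1 <- rowSums(j[, d$sample_id[d$genotype == "A1"]])
  g2 <- rowSums(j[, d$sample_id[d$genotype == "G2"]])
  d12 <- which(j$donor == 1 & j$acceptor == 2)
  d13 <- which(j$donor == 1 & j$acceptor == 3)
  expect_gt(a1[d12], a1[d13])
  expect_lt(g2[d12], g2[d13])
  expect_error(generate_junctions(
    synthetic_config(seed = 31, junction_depth = 0), gen$annotation),
    ">= 1")
})

test_that("cross simulation respects class sizes and survival truth", {
  cfg <- synthetic_config(seed = 37)
  cr <- generate_cross(cfg)
  expect_s3_class(cr$cross, "cross_counts")
  expect_equal(cr$truth$ratio, 10)
  # zero survival gives zero survivors
  cfg0 <- synthetic_config(seed = 37, s_rescue = 0, s_mutant = 0)
  cr0 <- generate_cross(cfg0)
  expect_equal(cr0$cross$rescue[["survivors"]], 0)
  expect_equal(cr0$cross$mutant[["survivors"]], 0)
  # balancer adults track T * f_bal * s_bal within 3 binomial sd
  bal <- sapply(1:30, function(i) {
    generate_cross(synthetic_config(seed = 1000 + i))$cross$rescue[["balancer"]]
  })
  expected <- 4000 * 0.5
  expect_true(all(abs(bal - expected) < 3 * sqrt(4000 * 0.5 * 0.5) + 1))
  expect_error(synthetic_config(seed = 1, s_rescue = 1.4),
               "survival probabilities")
})
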