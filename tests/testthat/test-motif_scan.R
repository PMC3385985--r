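test_that("canonical motif examples scan as expected", {
  h <- scan_sequence("GTGTGTTTT", search_mode = "forward_only")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(0, 9))
  expect_equal(h$motif_id, 1L)
  expect_equal(h$strand, "+")

  # reverse complement of GTGTGTTTT: invisible forward, found on minus
  expect_equal(nrow(scan_sequence("AAAACACAC",
                                  search_mode = "forward_only")), 0)
  h2 <- scan_sequence("AAAACACAC", search_mode = "double_stranded")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$motif_id, 1L)
  expect_equal(h2$match, "GTGTGTTTT")

  h3 <- scan_sequence("GTGTGTATGTGTG", search_mode = "forward_only")
  expect_equal(h3$motif_id, 2L)
  expect_equal(c(h3$start, h3$end), c(0, 13))

  # a UG run trailing into a U tract belongs to motif 1, not motif 3
  h4 <- scan_sequence("GTGTGTGTTTT", search_mode = "forward_only")
  expect_equal(h4$motif_id, 1L)
  expect_equal(c(h4$start, h4$end), c(0, 11))
})

test_that("scanner equals the run-length oracle on random sequences", {
  set.seed(401)
  for (r in 1:150) {
    s <- random_seq(200, gt_rich = (r %% 2 == 0))
    got <- scan_sequence(s)[, c("start", "end", "strand", "motif_id")]
    want <- oracle_scan(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("run-length oracle equals exhaustive enumeration on tiny inputs", {
  set.seed(402)
  for (r in 1:60) {
    s <- random_seq(24, gt_rich = TRUE)
    for (m in 1:3) {
      a <- oracle_scan_forward(s, m)[, c("start", "end")]
      b <- oracle_enumerate(s, m)
      rownames(a) <- rownames(b) <- NULL
      expect_equal(as.data.frame(a), b, ignore_attr = TRUE)
    }
  }
})

test_that("double-stranded scans are mirror-symmetric under reverse complement", {
  set.seed(403)
  for (r in 1:40) {
    s <- random_seq(150, gt_rich = TRUE)
    n <- nchar(s)
    fwd <- scan_sequence(s)
    rev <- scan_sequence(oracle_revcomp(s))
    mirrored <- data.frame(start = n - rev$end, end = n - rev$start,
                           strand = unname(c("+" = "-",
                                             "-" = "+")[rev$strand]),
                           motif_id = rev$motif_id,
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$motif_id,
                               mirrored$strand), ]
    fwd <- fwd[, c("start", "end", "strand", "motif_id")]
    rownames(fwd) <- rownames(mirrored) <- NULL
    expect_equal(fwd, mirrored, ignore_attr = TRUE)
  }
})

test_that("sequences without the GT dinucleotide never match forward", {
  set.seed(404)
  for (r in 1:20) {
    s <- random_seq(300)
    s <- gsub("GT", "GA", s)
    expect_equal(nrow(scan_sequence(s, search_mode = "forward_only")), 0)
  }
})

test_that("hits are attributed to feature classes by base majority", {
  # gene: exon [0,50) + intron [50,150) + exon [150,200)
  g <- data.frame(gene_id = "g1", seqid = "chr1", start = 0L, end = 200L,
                  strand = "+")
  tx <- data.frame(tx_id = "g1.t1", gene_id = "g1")
  f <- data.frame(tx_id = "g1.t1", type = "exon",
                  start = c(0L, 150L), end = c(50L, 200L))
  ann <- genome_annotation(g, tx, f)
  base <- strrep("A", 200)

  # fully intronic hit
  s1 <- base
  substr(s1, 61, 69) <- "GTGTGTTTT"
  ht <- annotate_gene_hits(ann, c(chr1 = s1))
  expect_true(ht$has_site[["g1"]])
  expect_equal(ht$hits$feature_class, "intron")
  expect_equal(c(ht$hits$start, ht$hits$end), c(60, 69))

  # no GT at all
  expect_false(annotate_gene_hits(ann, c(chr1 = base))$has_site[["g1"]])

  # boundary-spanning: 9-base motif-1 hit with 5 exon bases, 4 intron
  s2 <- base
  substr(s2, 46, 54) <- "GTGTGTTTT"       # genomic [45,54): exon 45..49
  ht2 <- annotate_gene_hits(ann, c(chr1 = s2))
  expect_equal(ht2$hits$feature_class, "exon")

  # shifted one base: 4 exon, 5 intron -> intron majority
  s3 <- base
  substr(s3, 47, 55) <- "GTGTGTTTT"
  ht3 <- annotate_gene_hits(ann, c(chr1 = s3))
  expect_equal(ht3$hits$feature_class, "intron")

  # per-base class oracle agrees on the majority call
  cls <- c(rep("exon", 50), rep("intron", 100), rep("exon", 50))
  span_major <- function(s, e) {
    tab <- table(cls[(s + 1):e])
    names(tab)[which.max(tab)]
  }
  expect_equal(span_major(45, 54), "exon")
  expect_equal(span_major(46, 55), "intron")
})

test_that("distribution summary counts each gene once per (motif, class)", {
  g <- data.frame(gene_id = "g1", seqid = "chr1", start = 0L, end = 400L,
                  strand = "+")
  tx <- data.frame(tx_id = "g1.t1", gene_id = "g1")
  f <- data.frame(tx_id = "g1.t1", type = c("exon", "exon",
                                            "three_prime_utr"),
                  start = c(0L, 300L, 360L), end = c(50L, 400L, 400L))
  ann <- genome_annotation(g, tx, f)
  s <- strrep("A", 400)
  substr(s, 101, 109) <- "GTGTGTTTT"    # intron
  substr(s, 151, 159) <- "GTGTGTTTT"    # intron again, same motif
  substr(s, 201, 209) <- "GTGTGTTTT"    # intron, third copy
  substr(s, 366, 374) <- "GTGTGTTTT"    # 3'UTR
  ht <- annotate_gene_hits(ann, c(chr1 = s))
  ds <- distribution_summary(ht)
  expect_equal(ds$n_genes[ds$motif_id == 1 & ds$feature_class == "intron"],
               1)
  expect_equal(
    ds$n_genes[ds$motif_id == 1 & ds$feature_class == "three_prime_utr"],
    1)
  expect_equal(sum(ds$n_genes), 2)

  # empty hit table -> all-zero summary
  ht0 <- annotate_gene_hits(ann, c(chr1 = strrep("A", 400)))
  expect_true(all(distribution_summary(ht0)$n_genes == 0))
})

test_that("BED output is six-column, 0-based half-open", {
  cfg <- synthetic_config(seed = 8, n_genes = 10)
  gen <- generate_genome(cfg)
  ht <- annotate_gene_hits(gen$annotation, gen$sequences)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed_hits(ht$hits, p)
  bed <- utils::read.delim(p, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(nrow(bed), nrow(ht$hits))
  expect_true(all(bed$V2 < bed$V3))
  expect_true(all(bed$V6 %in% c("+", "-")))
})
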