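make_expr <- function(counts, totals = NULL, len = 1000L) {
  cm <- count_matrix(counts, totals = totals)
  compute_rpkm(cm, flat_annotation(rownames(counts), len = len))
}

test_that("RPKM follows the formula and is scale invariant", {
  m <- matrix(c(10L, 20L), nrow = 1,
              dimnames = list("g1", c("s1", "s2")))
  expr <- make_expr(m, totals = c(s1 = 1e6, s2 = 2e6))
  expect_equal(expr$rpkm["g1", "s1"], 10)          # 10 / (1kb * 1M/1e6)
  expect_equal(expr$log2_rpkm["g1", "s1"], log2(10), tolerance = 1e-12)
  # doubling counts and totals in a sample leaves RPKM unchanged
  expect_equal(expr$rpkm["g1", "s2"], 10)

  # zero counts floor at log2(min positive / 2)
  m2 <- matrix(c(0L, 4L, 16L, 16L), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expr2 <- make_expr(m2, totals = c(s1 = 1e6, s2 = 1e6))
  expect_equal(expr2$log2_rpkm["g1", "s1"],
               log2(min(expr2$rpkm[expr2$rpkm > 0]) / 2))

  expect_error(make_expr(m, totals = c(s1 = 1e6, s2 = 2e6), len = 0L))
})

test_that("read-depth filter excludes genes under 10 mean reads everywhere", {
  set.seed(11)
  counts <- matrix(c(rep(5L, 6),            # under threshold in both
                     rep(c(5L, 50L), each = 3),  # over in one genotype
                     rep(100L, 6)), nrow = 3, byrow = TRUE,
                   dimnames = list(c("low", "half", "high"),
                                   paste0("s", 1:6)))
  expr <- make_expr(counts)
  de <- differential_expression(expr, paste0("s", 1:3), paste0("s", 4:6))
  expect_false(de$tested[de$gene_id == "low"])
  expect_true(de$tested[de$gene_id == "half"])
  expect_true(de$tested[de$gene_id == "high"])
  expect_true(is.na(de$p[de$gene_id == "low"]))
})

test_that("t statistics match an independently computed Student t", {
  set.seed(21)
  counts <- matrix(rnbinom(60, mu = 300, size = 20), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   paste0("s", 1:6)))
  expr <- make_expr(counts)
  ga <- paste0("s", 1:3)
  gb <- paste0("s", 4:6)
  de <- differential_expression(expr, ga, gb)
  for (i in 1:10) {
    a <- expr$log2_rpkm[i, ga]
    b <- expr$log2_rpkm[i, gb]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) +
                                               1 / length(b)))
    p_hand <- 2 * pt(-abs(t_hand), df = length(a) + length(b) - 2)
    expect_equal(de$t[i], t_hand, tolerance = 1e-10)
    expect_equal(de$p[i], p_hand, tolerance = 1e-10)
  }
})

test_that("a strong planted shift is called up with the 2-fold flag", {
  base <- matrix(rep(c(400L, 401L, 399L, 100L, 101L, 99L), 2), nrow = 2,
                 byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  base["g2", ] <- c(200L, 201L, 199L, 200L, 199L, 201L)
  expr <- make_expr(base, totals = setNames(rep(1e6, 6), paste0("s", 1:6)))
  de <- differential_expression(expr, paste0("s", 1:3), paste0("s", 4:6))
  g1 <- de[de$gene_id == "g1", ]
  expect_true(g1$significant)
  expect_equal(g1$direction, "up")
  expect_true(g1$twofold)
  expect_equal(g1$log2fc, 2, tolerance = 0.05)
})

test_that("identical replicate vectors give the zero-variance p = 1", {
  counts <- matrix(rep(c(50L, 60L, 70L), 2), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:6)))
  expr <- make_expr(counts)
  de <- differential_expression(expr, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$p, 1)
  expect_false(de$significant)
})

test_that("BH adjustment is monotone and never below raw p", {
  set.seed(31)
  counts <- matrix(rnbinom(600, mu = 200, size = 5), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   paste0("s", 1:6)))
  expr <- make_expr(counts)
  de <- differential_expression(expr, paste0("s", 1:3), paste0("s", 4:6))
  t <- de[de$tested, ]
  expect_true(all(t$p_adj >= t$p - 1e-12))
  o <- order(t$p)
  expect_true(all(diff(t$p_adj[o]) >= -1e-12))
  expect_equal(t$p_adj, p.adjust(t$p, "BH"))
})

test_that("statistics are invariant to replicate order within groups", {
  set.seed(41)
  counts <- matrix(rnbinom(120, mu = 150, size = 10), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   paste0("s", 1:6)))
  expr <- make_expr(counts)
  de1 <- differential_expression(expr, c("s1", "s2", "s3"),
                                 c("s4", "s5", "s6"))
  de2 <- differential_expression(expr, c("s3", "s1", "s2"),
                                 c("s6", "s4", "s5"))
  expect_equal(de1, de2)
})

test_that("rescue classification implements the three-way rule", {
  de_mut <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    log2fc = c(2, 2, 2, 1), stringsAsFactors = FALSE)
  de_resc <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    significant = c(FALSE, TRUE, TRUE, FALSE),
    log2fc = c(0.1, 0.8, 2.0, 0), stringsAsFactors = FALSE)
  rc <- classify_rescue(de_mut, de_resc, rho = 0.5)
  expect_equal(nrow(rc), 3)          # only mutant-DE genes are classified
  expect_equal(rc$status[rc$gene_id == "a"], "rescued")
  expect_equal(rc$status[rc$gene_id == "b"], "partial")
  expect_equal(rc$status[rc$gene_id == "c"], "not_rescued")
  # opposite-sign residual change is never "partial"
  de_resc$log2fc[2] <- -0.8
  rc2 <- classify_rescue(de_mut, de_resc, rho = 0.5)
  expect_equal(rc2$status[rc2$gene_id == "b"], "not_rescued")
  expect_error(classify_rescue(de_mut,
                               data.frame(gene_id = "zz",
                                          significant = TRUE,
                                          log2fc = 1)),
               "share no genes")
})

test_that("overlap summary tallies direction concordance", {
  de_a <- data.frame(gene_id = c("a", "b", "c"),
                     significant = c(TRUE, TRUE, TRUE),
                     direction = c("up", "up", "down"))
  de_b <- data.frame(gene_id = c("b", "c", "d"),
                     significant = c(TRUE, TRUE, TRUE),
                     direction = c("down", "down", "up"))
  ov <- overlap_summary(de_a, de_b)
  expect_equal(ov$n_intersect, 2)
  expect_equal(ov$n_same_direction, 1)      # c: down/down
  expect_equal(ov$n_opposite_direction, 1)  # b: up/down
  expect_equal(ov$n_same_direction + ov$n_opposite_direction,
               ov$n_intersect)
  # a table against itself is all same-direction
  self <- overlap_summary(de_a, de_a)
  expect_equal(self$n_intersect, self$n_a)
  expect_equal(self$n_opposite_direction, 0)
  # disjoint significant sets
  de_c <- data.frame(gene_id = "zz", significant = TRUE, direction = "up")
  expect_equal(overlap_summary(de_a, de_c)$n_intersect, 0)
})
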