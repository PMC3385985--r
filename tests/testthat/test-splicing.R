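test_that("splice index is the correlation of exon-usage proportions", {
  # identical usage -> 1
  r1 <- splice_index(c(20, 30, 50) * 10, c(20, 30, 50) * 4)
  expect_equal(r1$index, 1)

  # hand-computed product-moment correlation of (.5,.5,0) vs (0,.5,.5)
  r2 <- splice_index(c(100, 100, 0), c(0, 100, 100))
  expect_equal(r2$index, -0.5, tolerance = 1e-12)

  # read floor: 150 reads in one genotype is insufficient
  r3 <- splice_index(c(75, 75), c(300, 300), min_reads = 200)
  expect_false(r3$sufficient)
  r4 <- splice_index(c(150, 150), c(300, 300), min_reads = 200)
  expect_true(r4$sufficient)

  # degenerate shapes
  expect_false(splice_index(c(100), c(100))$assessable)
  expect_equal(splice_index(c(50, 50), c(80, 80))$index, 1)  # both flat
  expect_false(splice_index(c(50, 50), c(10, 90))$assessable) # one flat

  # symmetric in genotype order, invariant to uniform count scaling
  a <- c(10, 40, 80, 20)
  b <- c(30, 30, 20, 70)
  expect_equal(splice_index(a, b)$index, splice_index(b, a)$index)
  expect_equal(splice_index(a, b)$index, splice_index(a * 7, b)$index)
})

test_that("candidate flag needs depth, low index, and a binding site", {
  et <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 3),
    exon_index = rep(1:3, 2),
    a1 = c(100, 100, 0, 100, 100, 0),
    a2 = c(100, 100, 0, 100, 100, 0),
    b1 = c(0, 100, 100, 0, 100, 100),
    b2 = c(0, 100, 100, 0, 100, 100))
  design <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       genotype = c("A", "A", "B", "B"),
                       replicate = c(1L, 2L, 1L, 2L))
  ht <- list(has_site = c(g1 = TRUE, g2 = FALSE))
  class(ht) <- "gene_hit_table"
  sc <- splice_screen(et, design, "A", "B", hit_table = ht)
  expect_equal(sc$index, c(-0.5, -0.5), tolerance = 1e-12)
  expect_true(sc$candidate[sc$gene_id == "g1"])
  expect_false(sc$candidate[sc$gene_id == "g2"])   # no binding site

  # below the read floor nothing is a candidate however low the index
  et_small <- et
  et_small[, c("a1", "a2")] <- et_small[, c("a1", "a2")] / 4
  sc2 <- splice_screen(et_small, design, "A", "B", hit_table = ht)
  expect_false(any(sc2$candidate))
})

test_that("junction posterior is the conjugate beta update of Jeffreys", {
  p0 <- junction_posterior(0, 0)
  expect_equal(c(p0$a, p0$b, p0$mean), c(0.5, 0.5, 0.5))
  p1 <- junction_posterior(3, 1)
  expect_equal(c(p1$a, p1$b), c(3.5, 1.5))
  expect_equal(p1$mean, 0.7)
  expect_error(junction_posterior(-1, 0), "non-negative")
  expect_error(junction_posterior(2.5, 0), "non-negative")
})

test_that("failure definitions split the junction table as published", {
  ju <- data.frame(donor = c(1L, 1L, 2L), acceptor = c(2L, 3L, 4L),
                   A = c(10L, 5L, 20L), B = c(10L, 5L, 20L))
  r_alt <- junction_compare(ju, c(1L, 2L), "A", "B", "alternate_second")
  expect_equal(r_alt$successes_a, 10)
  expect_equal(r_alt$failures_a, 5)      # e1-e3 only
  r_all <- junction_compare(ju, c(1L, 2L), "A", "B", "all_other")
  expect_equal(r_all$failures_a, 25)     # e1-e3 + e2-e4
  expect_error(junction_compare(ju, c(3L, 4L), "A", "B"), "not present")
  expect_error(junction_compare(ju, c(2L, 1L), "A", "B"), "donor index")
})

test_that("posterior comparison is symmetric and matches Monte Carlo", {
  # identical counts -> exactly 1/2 by symmetry
  ju <- data.frame(donor = 1L, acceptor = 2L, A = 30L, B = 30L)
  ju <- rbind(ju, data.frame(donor = 1L, acceptor = 3L, A = 15L, B = 15L))
  r <- junction_compare(ju, c(1L, 2L), "A", "B", "alternate_second")
  expect_equal(r$p_a_greater, 0.5, tolerance = 1e-9)
  expect_equal(r$p_two_sided, 1, tolerance = 1e-8)

  # total separation
  pa <- junction_posterior(50, 0)
  pb <- junction_posterior(0, 50)
  expect_gt(prob_greater(pa, pb), 0.999)

  # genotype swap maps P -> 1 - P exactly
  set.seed(71)
  for (r in 1:20) {
    s1 <- rpois(1, 20); f1 <- rpois(1, 10)
    s2 <- rpois(1, 15); f2 <- rpois(1, 15)
    p12 <- prob_greater(junction_posterior(s1, f1),
                        junction_posterior(s2, f2))
    p21 <- prob_greater(junction_posterior(s2, f2),
                        junction_posterior(s1, f1))
    expect_equal(p12, 1 - p21, tolerance = 1e-7)
  }

  # integration agrees with 1e5-draw Monte Carlo on random configurations
  set.seed(72)
  for (r in 1:10) {
    s1 <- rpois(1, 30); f1 <- rpois(1, 20)
    s2 <- rpois(1, 25); f2 <- rpois(1, 25)
    p_int <- prob_greater(junction_posterior(s1, f1),
                          junction_posterior(s2, f2))
    p_mc <- mc_prob_greater(s1 + 0.5, f1 + 0.5, s2 + 0.5, f2 + 0.5,
                            draws = 1e5)
    expect_equal(p_int, p_mc, tolerance = 0.02)
  }

  # one-sample tail
  expect_equal(beta_tail(junction_posterior(3, 1), 0.5),
               pbeta(0.5, 3.5, 1.5, lower.tail = FALSE))
})
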