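test_that("vectorized rank-sum matches wilcox.test on random data", {
  set.seed(15)
  groups <- factor(rep(c("a", "b"), each = 12), levels = c("a", "b"))
  x <- matrix(rnbinom(50 * 24, mu = 10, size = 2), nrow = 50)
  res <- lrcdorm:::ranksum_rows(x, groups == "a")
  ref <- apply(x, 1, function(row) {
    suppressWarnings(wilcox.test(row[groups == "a"], row[groups == "b"],
                                 exact = FALSE, correct = TRUE)$p.value)
  })
  expect_equal(res$p, unname(ref), tolerance = 1e-10)
})

test_that("identical groups give zero fold-changes; zero genes carried", {
  set.seed(25)
  half <- matrix(rpois(100 * 10, 5), nrow = 100)
  counts <- cbind(half, half)
  counts[1, ] <- 0 # all-zero gene
  rownames(counts) <- sprintf("g%03d", 1:100)
  groups <- factor(rep(c("dormant", "active"), each = 10),
                   levels = c("dormant", "active"))
  de <- differential_expression(counts, groups)
  expect_equal(de$log2fc, rep(0, 100))
  expect_equal(de$fdr[1], 1)
  expect_equal(nrow(de), 100L)
})

test_that("planted large-effect genes dominate the DE ranking", {
  planted <- data.frame(gene = 1:50, log2fc = 5)
  sim <- simulate_expression(1000, 50, planted, dispersion = 0.4, seed = 35)
  de <- differential_expression(sim$counts, sim$groups)
  sig <- derive_signature(de)
  recall <- mean(sim$truth$gene[sim$truth$planted] %in% sig$gene)
  expect_gte(recall, 0.9)
  expect_true(all(sig$direction[sig$gene %in%
                                  sim$truth$gene[1:50]] == "up"))
})

test_that("signature thresholds are applied as stated and monotone", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(1.5, 0.9, -2, 0),
                   stat = c(3, 2, -4, 0),
                   p = c(0.001, 0.002, 1e-5, 0.9),
                   fdr = c(0.04, 0.04, 0.001, 0.95))
  sig <- derive_signature(de)
  expect_setequal(sig$gene, c("a", "c"))
  expect_equal(sig$direction[sig$gene == "a"], "up")
  expect_equal(sig$direction[sig$gene == "c"], "down")
  # degenerate thresholds keep every gene with any fold-change
  all_sig <- derive_signature(de, fdr_max = 1, min_abs_log2fc = 0)
  expect_setequal(all_sig$gene, c("a", "b", "c"))
  # tightening either threshold never adds genes
  for (fdr_max in c(0.05, 0.01, 0.001)) {
    for (lfc in c(0.5, 1, 2)) {
      inner <- derive_signature(de, fdr_max, lfc)
      outer <- derive_signature(de, fdr_max * 2, lfc / 2)
      expect_true(all(inner$gene %in% outer$gene))
    }
  }
})

test_that("integrated two-table derivation requires both modalities to
           agree", {
  a <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, 2, 2),
                  stat = 3, p = c(0.001, 0.001, 0.001),
                  fdr = c(0.01, 0.01, 0.01))
  b <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, -2, 2),
                  stat = 3, p = c(0.002, 0.001, 0.5),
                  fdr = c(0.02, 0.01, 0.6))
  sig <- derive_signature(list(a, b))
  # g2 flips direction, g3 fails thresholds in b
  expect_equal(sig$gene, "g1")
  expect_equal(sig$fdr, 0.02) # worse of the two
})

test_that("BH correction equals the textbook step-up on random p-vectors", {
  set.seed(45)
  for (i in 1:20) {
    p <- runif(sample(5:500, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("overlap test equals exact enumeration on small universes", {
  set.seed(55)
  for (i in 1:25) {
    u <- sample(5:20, 1)
    universe <- sprintf("g%02d", seq_len(u))
    a <- sample(universe, sample(1:u, 1))
    b <- sample(universe, sample(1:u, 1))
    got <- overlap_test(a, b, u)
    expect_equal(got$overlap, length(intersect(a, b)))
    expect_equal(got$p_value,
                 hyper_tail_enum(got$overlap, length(a), length(b), u),
                 tolerance = 1e-12)
  }
  # worked example: two 5-gene signatures coinciding in a 10-gene universe
  p5 <- overlap_test(letters[1:5], letters[1:5], 10)$p_value
  expect_equal(p5, 1 / choose(10, 5), tolerance = 1e-12)
})

test_that("overlap test handles identity, disjoint and directional cases", {
  u <- sprintf("g%03d", 1:100)
  expect_equal(overlap_test(u, u, 100)$p_value, 1)
  expect_gt(overlap_test(u[1:10], u[51:60], 1e4)$p_value, 0.99)
  expect_error(overlap_test(c("x", u[1:3]), u[1:3], u), "outside")
  expect_error(overlap_test(u[1:60], u[40:100], 80), "universe smaller")
  sig_a <- structure(data.frame(gene = u[1:10],
                                direction = rep(c("up", "down"), each = 5),
                                log2fc = rep(c(2, -2), each = 5),
                                fdr = 0.01, rank = 1:10),
                     class = c("signature", "data.frame"))
  sig_b <- sig_a
  sig_b$direction <- rev(sig_b$direction) # flip: no matching-direction hits
  dir_same <- overlap_test(sig_a, sig_a, 100, directional = TRUE)
  dir_flip <- overlap_test(sig_a, sig_b, 100, directional = TRUE)
  expect_equal(dir_same$overlap, 10L)
  expect_equal(dir_flip$overlap, 0L)
  expect_lt(dir_same$p_value, dir_flip$p_value)
})

test_that("fold-change concordance spans agreement, flip and null", {
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200), stat = 0, p = 0.5, fdr = 0.5)
  genes <- de$gene
  expect_equal(concordance(de, de, genes)$agreement, 1)
  flipped <- transform(de, log2fc = -log2fc)
  expect_equal(concordance(de, flipped, genes)$agreement, 0)
  set.seed(65)
  agree <- replicate(50, {
    a <- transform(de, log2fc = rnorm(200))
    b <- transform(de, log2fc = rnorm(200))
    concordance(a, b, genes)$agreement
  })
  expect_lt(abs(mean(agree) - 0.5), 3 * sqrt(0.25 / (200 * 50)))
  expect_error(concordance(de, de, "absent"), "empty intersection")
})

test_that("rank enrichment scores extremes and respects symmetry", {
  set.seed(75)
  stats_vec <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  names(stats_vec) <- sprintf("g%03d", 1:100)
  top <- names(stats_vec)[1:10]
  res <- rank_enrichment(top, stats_vec, n_perm = 100, seed = 1)
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # unweighted: set and complement scores are equal and opposite
  some <- sample(names(stats_vec), 30)
  comp <- setdiff(names(stats_vec), some)
  es_a <- rank_enrichment(some, stats_vec, n_perm = 1, weighted = FALSE,
                          seed = 2)$es
  es_b <- rank_enrichment(comp, stats_vec, n_perm = 1, weighted = FALSE,
                          seed = 2)$es
  expect_equal(es_a + es_b, 0, tolerance = 1e-12)
  expect_error(rank_enrichment(names(stats_vec), stats_vec), "smaller")
  expect_error(rank_enrichment("absent", stats_vec), "missing")
})

test_that("permutation p-values are uniform under a random signature", {
  set.seed(85)
  stats_vec <- sort(rnorm(150), decreasing = TRUE)
  names(stats_vec) <- sprintf("g%03d", 1:150)
  pvals <- replicate(200, {
    sig <- sample(names(stats_vec), 15)
    rank_enrichment(sig, stats_vec, n_perm = 200)$p_value
  })
  # one-sided permutation p under the null is approximately uniform
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
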