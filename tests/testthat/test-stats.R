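test_that("r_squared: exact cases, oracle agreement, guards", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x + 1), 1.0)
  # orthogonal contrast: zero correlation by construction
  y <- c(1, -1, 1, -1, 1, -1)
  expect_equal(r_squared(c(1, 1, 2, 2, 3, 3), y), 0.0, tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(50); b <- 0.3 * a + rnorm(50)
  expect_equal(r_squared(a, b), cor(a, b)^2, tolerance = 1e-12)
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_error(r_squared(1:2, 2:3), "at least 3")
  expect_error(r_squared(rep(1, 5), 1:5), "zero variance")
})

test_that("paired_t: identity, degenerate shift, textbook oracle", {
  x <- rnorm(8)
  r <- paired_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  xr <- c(0.5, 1.5, 2.5, 3.5)   # exactly representable, so x+2-x == 2
  rd <- paired_t(xr + 2, xr)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p))
  expect_equal(rd$mean_diff, 2)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  r2 <- paired_t(a, b)
  o <- t.test(a, b, paired = TRUE)
  expect_equal(r2$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r2$p, o$p.value, tolerance = 1e-10)
  expect_equal(r2$mean_diff, unname(o$estimate), tolerance = 1e-12)
})

test_that("heritability: boundary cases and balanced-design identity", {
  g <- rep(1:5, each = 3)
  # replicates identical, genotypes differ: all variance genetic
  h1 <- heritability(replicated_phenotypes(g, rep(c(1, 3, 5, 7, 9), each = 3)))
  expect_equal(h1$H2, 1)
  # all observations identical: no variance at all
  h0 <- heritability(replicated_phenotypes(g, rep(2, 15)))
  expect_equal(h0$H2, 0)
  expect_error(heritability(replicated_phenotypes(rep(1, 4), rnorm(4))),
               "2 genotypes")
  expect_error(heritability(replicated_phenotypes(1:6, rnorm(6))),
               "replication")
  # balanced design: matches aov-based variance components
  set.seed(3)
  G <- 40; r <- 4
  gg <- rep(seq_len(G), each = r)
  y <- rep(rnorm(G, sd = 2), each = r) + rnorm(G * r)
  h <- heritability(replicated_phenotypes(gg, y))
  ms <- anova(aov(y ~ factor(gg)))[["Mean Sq"]]
  Vg <- max(0, (ms[1] - ms[2]) / r)
  expect_equal(h$Vg, Vg, tolerance = 1e-10)
  expect_equal(h$Ve, ms[2], tolerance = 1e-10)
  expect_equal(h$H2, Vg / (Vg + ms[2] / r), tolerance = 1e-10)
  expect_true(h$balanced)
  expect_equal(h$r, r)
})

test_that("heritability is within [0,1] and increases with replication", {
  set.seed(4)
  G <- 60
  h_prev <- 0
  for (r in c(2, 5, 10)) {
    gg <- rep(seq_len(G), each = r)
    y <- rep(rnorm(G, sd = 1), each = r) + rnorm(G * r, sd = 2)
    h <- heritability(replicated_phenotypes(gg, y))$H2
    expect_gte(h, 0); expect_lte(h, 1)
    expect_gte(h, h_prev - 0.15)  # stochastic, but the trend must hold
    h_prev <- h
  }
})

test_that("tip_validation computes both correlations and keeps the table", {
  truth <- seq(30, 210, length.out = 12)
  v <- tip_validation(truth, truth, truth + 17)
  expect_equal(v$r2_cleaned, 1.0)
  # constant debris offset preserves correlation: this is why the
  # validation design must vary debris counts across images
  expect_equal(v$r2_uncleaned, 1.0, tolerance = 1e-12)
  expect_equal(v$n, 12)
  expect_error(tip_validation(1:5, 1:5, 1:5), "at least 10")
  set.seed(5)
  raw <- truth + runif(12, 10, 60)
  v2 <- tip_validation(truth, truth + rnorm(12, 0, 2), raw)
  expect_gt(v2$r2_cleaned, v2$r2_uncleaned)
})

test_that("linkage block counting: windows, correlation, guards", {
  set.seed(6)
  n_lines <- 40
  # mutually uncorrelated SNPs -> every SNP its own block
  dos <- matrix(sample(0:2, 8 * n_lines, replace = TRUE), nrow = 8)
  pos <- seq(0, 7) * 10000
  B <- count_linkage_blocks(pos, dos, r2_min = 0.9)
  expect_equal(B, 8)
  # perfectly correlated SNPs within 200 kb -> one block
  one <- matrix(rep(sample(0:2, n_lines, replace = TRUE), 6),
                nrow = 6, byrow = TRUE)
  expect_equal(count_linkage_blocks(seq(0, 5) * 30000, one), 1)
  # identical genotypes but beyond the window -> the window dominates
  expect_equal(count_linkage_blocks(c(0, 250000), one[1:2, ]), 2)
  # duplicating a block member at the same position leaves B unchanged
  pos3 <- c(0, 10000, 20000)
  d3 <- one[1:3, ]
  B3 <- count_linkage_blocks(pos3, d3)
  expect_equal(count_linkage_blocks(c(pos3, 20000), one[1:4, ]), B3)
  expect_error(count_linkage_blocks(c(5, 1), dos[1:2, ]), "sorted")
  # per-chromosome scan: blocks never merge across chromosomes
  expect_equal(count_linkage_blocks(c(0, 1000), one[1:2, ],
                                    chromosome = c(1, 2)), 2)
})

test_that("block-wise Bonferroni threshold", {
  expect_equal(round(bonferroni_block_threshold(0.05, 212612), 1), 6.6)
  expect_equal(bonferroni_block_threshold(0.05, 1), 1.301, tolerance = 1e-3)
  expect_equal(bonferroni_block_threshold(0.05, 5000), 5.0, tolerance = 1e-10)
  # strictly increasing in B, decreasing in alpha
  expect_gt(bonferroni_block_threshold(0.05, 1001),
            bonferroni_block_threshold(0.05, 1000))
  expect_lt(bonferroni_block_threshold(0.1, 1000),
            bonferroni_block_threshold(0.05, 1000))
  expect_error(bonferroni_block_threshold(0, 10), "alpha")
  expect_error(bonferroni_block_threshold(0.05, 0), "positive integer")
})

test_that("phenotype and genotype CSV readers round-trip", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(genotype = rep(c("g1", "g2", "g3"), each = 2),
                   replicate = rep(1:2, 3),
                   TRL = c(10, 11, 20, 21, 30, 31))
  write.csv(df, tmp, row.names = FALSE)
  ph <- read_phenotypes_csv(tmp, "TRL")
  expect_equal(ph$value, df$TRL)
  expect_error(read_phenotypes_csv(tmp, "nope"), "not found")
  tmp2 <- tempfile(fileext = ".csv")
  gd <- data.frame(chrom = c(1, 1, 2), pos = c(100, 200, 100),
                   l1 = c(0, 1, 2), l2 = c(2, 1, 0))
  write.csv(gd, tmp2, row.names = FALSE)
  gm <- read_genotypes_csv(tmp2)
  expect_equal(dim(gm$dosages), c(3, 2))
  gd$l1[1] <- 5
  write.csv(gd, tmp2, row.names = FALSE)
  expect_error(read_genotypes_csv(tmp2), "dosages")
})
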