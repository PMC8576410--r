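test_that("Shapiro-Wilk wrapper behaves across sample shapes", {
  x <- qnorm(ppoints(50))                 # perfect normal quantiles
  nt <- normality_test(x)
  expect_gt(nt$statistic, 0.99)
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(c(1, 2)), "3 <= n")
  # uniform samples are detected as non-normal in nearly every draw
  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    normality_test(runif(500))$p.value < 0.05
  }, logical(1))
  expect_gte(sum(rejections), 19)
})

test_that("Mann-Whitney exact p equals full enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p.value, 0.1)            # 2 * 1/20 over C(6,3) arrangements
  orc <- mw_enumeration_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p.value, orc$p)

  set.seed(31)
  for (rep in 1:8) {
    a <- round(rnorm(sample(3:8, 1)), 3)
    b <- round(rnorm(sample(3:8, 1)) + runif(1, -1, 1), 3)
    got <- mann_whitney(a, b)
    orc <- mw_enumeration_oracle(a, b)
    expect_equal(got$u, orc$u)
    expect_equal(got$p.value, orc$p, tolerance = 1e-12)
  }
})

test_that("identical groups give p near one; exact and approximate p agree", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(mann_whitney(a, a)$p.value, 1)   # fully tied -> approximate, z = 0
  set.seed(32)
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney(a, b, exact = TRUE)$p.value
    pa <- mann_whitney(a, b, exact = FALSE)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Kruskal-Wallis and Dunn-Bonferroni have the documented structure", {
  x <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_equal(kw$p.value, 1, tolerance = 1e-12)
  dn <- dunn_bonferroni(x, g)
  expect_true(all(dn$p.adjusted == 1))

  x2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g2 <- rep(c("lo", "mid", "hi"), each = 3)
  kw2 <- kruskal_wallis(x2, g2)
  expect_gt(kw2$statistic, 7)             # near the n = 9 maximum (7.2)
  dn2 <- dunn_bonferroni(x2, g2)
  expect_equal(nrow(dn2), 3L)
  expect_equal(dn2$p.adjusted, pmin(1, dn2$p.value * 3))
  # rank ordering lo < mid < hi is preserved in the z signs
  zlohi <- dn2$z[dn2$group1 == "hi" & dn2$group2 == "lo" |
                 dn2$group1 == "lo" & dn2$group2 == "hi"]
  s <- if (dn2$group1[which(dn2$group1 %in% c("hi", "lo") &
                            dn2$group2 %in% c("hi", "lo"))[1]] == "hi") 1 else -1
  expect_gt(s * zlohi, 0)
  expect_error(dunn_bonferroni(x2[1:6], g2[1:6]), "3 groups")
})

test_that("paired t and Pearson follow their closed forms", {
  a <- c(1, 2, 3, 4, 5)
  sym <- a + c(0.3, -0.3, 0.3, -0.3, 0)   # differences symmetric about zero
  pt <- paired_t(a, sym)
  expect_equal(pt$t, 0, tolerance = 1e-12)
  expect_equal(pt$p.value, 1, tolerance = 1e-12)
  expect_equal(pt$mean_diff, 0, tolerance = 1e-12)
  expect_lt(pt$conf.low, 0); expect_gt(pt$conf.high, 0)
  expect_error(paired_t(a, a), "variance")
  expect_error(paired_t(a, a[1:3]), "equal length")

  x <- c(-2, -1, 0, 1, 2.5)
  pc <- pearson_cor(x, -2 * x)
  expect_equal(pc$r, -1, tolerance = 1e-12)
  expect_equal(pc$r.squared, 1, tolerance = 1e-12)
})

test_that("paired-t confidence intervals attain nominal coverage", {
  set.seed(33)
  nrep <- 10000; n <- 12; true_diff <- 0.7
  a <- matrix(rnorm(nrep * n), nrep)
  b <- matrix(rnorm(nrep * n, -true_diff), nrep)
  d <- a - b
  m <- rowMeans(d)
  se <- sqrt((rowSums(d^2) - n * m^2) / (n - 1)) / sqrt(n)
  tq <- qt(0.975, n - 1)
  covered <- (m - tq * se <= true_diff) & (true_diff <= m + tq * se)
  expect_lt(abs(mean(covered) - 0.95), 0.007)
  # spot-check the vectorised CI against the package function
  pt <- paired_t(a[1, ], b[1, ])
  expect_equal(pt$conf.low, m[1] - tq * se[1], tolerance = 1e-12)
  expect_equal(pt$conf.high, m[1] + tq * se[1], tolerance = 1e-12)
})

test_that("compare_groups dispatches by group count and reports medians/IQR", {
  d <- data.frame(v = c(1:6, 11:16), g = rep(c("a", "b"), each = 6))
  two <- compare_groups(d, v, g)
  expect_equal(nrow(two$summary), 2L)
  expect_equal(two$summary$median, c(3.5, 13.5))
  expect_match(two$test$method, "Mann-Whitney")
  expect_null(two$pairwise)
  d3 <- data.frame(v = c(1:5, 6:10, 11:15), g = rep(c("a", "b", "c"), each = 5))
  three <- compare_groups(d3, v, g)
  expect_match(three$test$method, "Kruskal")
  expect_equal(nrow(three$pairwise), 3L)
  expect_true(all(three$pairwise$p.adjusted >= three$pairwise$p.value - 1e-12))
  expect_true(all(three$pairwise$p.adjusted <= 1))
})
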