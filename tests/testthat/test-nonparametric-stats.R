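test_that("pooling keeps every technical replicate and rejects duplicates", {
  rec <- expand.grid(bio_rep = 1:3, tech_rep = 1:3,
                     conc_h295r = c(1e-8, 1e-7), stringsAsFactors = FALSE)
  rec$plate_id <- "P"
  rec$chemical_id <- "x"
  rec$endpoint <- "estrogen_activity"
  rec$pct_of_basal <- rnorm(nrow(rec), 100, 5)
  pooled <- pool_replicates(rec)
  expect_equal(nrow(pooled), 2)
  expect_equal(pooled$n, c(9L, 9L))

  # a bio replicate missing one concentration gives n = 6
  rec2 <- rec[!(rec$bio_rep == 2 & rec$conc_h295r == 1e-8), ]
  pooled2 <- pool_replicates(rec2)
  expect_equal(pooled2$n[pooled2$conc_h295r == 1e-8], 6L)

  expect_error(pool_replicates(rbind(rec, rec[1, ])), "duplicate record")
})

test_that("Kruskal-Wallis matches the hand-computed H and degenerates to p=1", {
  # three cleanly separated triplets: H by the rank formula is
  # 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 7.2 with N = 9
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 7.2)
  expect_lt(kw$p_value, 0.05)

  same <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2, 3))), "at least 2")
})

test_that("Mann-Whitney exact path matches enumeration and known values", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2 * 1/20 over all C(6,3) arrangements
  expect_equal(mw$method, "exact")

  tied <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tied$p_value, 1)

  # swapping the samples reflects U and preserves the two-sided p
  set.seed(11)
  for (i in 1:25) {
    x <- sample(1:100, 4)
    y <- sample(setdiff(1:100, x), 5)
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$U, length(x) * length(y) - b$U)
    expect_equal(a$p_value, b$p_value)
    # rank statistics are invariant under strictly monotone transforms
    tr <- mann_whitney(log(x), log(y))
    expect_equal(tr$p_value, a$p_value)
    expect_equal(tr$U, a$U)
  }
})

test_that("exact p-values agree with wilcox.test as an independent oracle", {
  set.seed(23)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- sample(1:1000, n1); y <- sample(setdiff(1:1000, x), n2)
    ours <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # large samples fall back to the corrected normal approximation
  set.seed(31)
  x <- rnorm(9, 110, 10); y <- rnorm(9, 100, 10)
  ours <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal_approximation")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("significance bins honour their boundaries and glyph families", {
  expect_equal(star_bin(0.03), "*")
  expect_equal(star_bin(5e-5), "****")
  expect_equal(star_bin(0.05), "*")       # boundary inclusive
  expect_equal(star_bin(0.051), "ns")
  expect_equal(star_bin(c(0.009, 0.0009, 1e-4)), c("**", "***", "****"))
  expect_equal(star_bin(0.03, "direct"), "#")
  expect_equal(star_bin(0.0001, "direct"), "####")
})

test_that("the normality screen is diagnostic only", {
  set.seed(19)
  normal_rate <- mean(vapply(1:300, function(i) {
    normality_screen(list(g = rnorm(9)))$shapiro_p > 0.05
  }, logical(1)))
  expect_gte(normal_rate, 0.9)

  skew_rate <- mean(vapply(1:300, function(i) {
    normality_screen(list(g = rexp(9)))$shapiro_p < 0.05
  }, logical(1)))
  expect_gt(skew_rate, 0.2)        # heavily skewed data often flagged
  expect_gt(skew_rate, 1 - normal_rate)

  const <- normality_screen(list(g = rep(3, 9)))
  expect_true(is.na(const$shapiro_p))
  expect_true(const$flag)
})

test_that("stat_calls assembles gated, directed per-concentration calls", {
  set.seed(3)
  rec <- expand.grid(bio_rep = 1:3, tech_rep = 1:3,
                     conc_h295r = c(1e-8, 3e-8, 1e-7),
                     stringsAsFactors = FALSE)
  rec$plate_id <- "P"
  rec$chemical_id <- "x"
  rec$endpoint <- "estrogen_activity"
  shift <- c(`1e-08` = 0, `3e-08` = -30, `1e-07` = -60)
  rec$pct_of_basal <- 100 + shift[as.character(rec$conc_h295r)] + rnorm(27, 0, 4)
  control <- rnorm(9, 100, 4)
  calls <- stat_calls(pool_replicates(rec), control)
  calls <- calls[order(calls$conc_h295r), ]
  expect_equal(calls$direction[2:3], c("down", "down"))
  expect_true(all(calls$significant[2:3]))
  expect_false(calls$significant[1])
  expect_true(all(calls$star_bin[2:3] != "ns"))
  expect_equal(calls$n_treated, rep(9L, 3))
})
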