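test_that("null population recentres both groups at the grand mean", {
  st <- make_study(G = 5, n = 4, shift = 1.2, seed = 2)
  np <- build_null_population(st)
  m1 <- rowMeans(np$matrix[, 1:4]); m2 <- rowMeans(np$matrix[, 5:8])
  grand <- rowMeans(st$matrix[, 1:4]) / 2 + rowMeans(st$matrix[, 5:8]) / 2
  expect_equal(m1, grand)   # equal n: grand mean is the simple average
  expect_equal(m2, grand)

  # per-group covariance (and hence dependence structure) is unchanged
  expect_equal(cov(t(np$matrix[, 1:4])), cov(t(st$matrix[, 1:4])))
  expect_equal(cov(t(np$matrix[, 5:8])), cov(t(st$matrix[, 5:8])))

  # already-null data is a fixed point
  st0 <- st
  st0$matrix <- np$matrix
  expect_equal(build_null_population(st0)$matrix, np$matrix)

  # unbalanced groups: weighted grand mean
  stu <- expression_study(st$matrix[, 1:7],
                          group = c(1, 1, 1, 2, 2, 2, 2))
  npu <- build_null_population(stu)
  grand_u <- (3 * rowMeans(st$matrix[, 1:3]) +
                4 * rowMeans(st$matrix[, 4:7])) / 7
  expect_equal(rowMeans(npu$matrix[, 1:3]), grand_u)
  expect_equal(rowMeans(npu$matrix[, 4:7]), grand_u)
})

test_that("bootstrap_pvalue follows the add-one convention", {
  expect_equal(bootstrap_pvalue(10, rep(1, 4999)), 1 / 5000)
  expect_equal(bootstrap_pvalue(0, rep(1, 100)), 1)
  null_med <- c(seq_len(499), rep(500, 1), 501:999)  # 500 is the median
  expect_equal(bootstrap_pvalue(500, null_med), (1 + 500) / 1000)
  expect_error(bootstrap_pvalue(1, numeric(0)), "non-empty")
  expect_error(bootstrap_pvalue(NaN, 1:5), "finite")

  # non-increasing in the observed statistic for a fixed null sample
  set.seed(8)
  ns <- rchisq(200, 3)
  obs <- sort(runif(50, 0, 10))
  p <- vapply(obs, bootstrap_pvalue, numeric(1), null_stats = ns)
  expect_true(all(diff(p) <= 0))
})

test_that("bootstrap null distributions are reproducible and shared", {
  st <- make_study(G = 6, n = 5, seed = 4)
  h <- make_hierarchy(list(c(2, 2), 2))
  nd1 <- bootstrap_null_statistics(st, h, B = 50, seed = 99)
  nd2 <- bootstrap_null_statistics(st, h, B = 50, seed = 99)
  expect_identical(nd1$stats, nd2$stats)
  expect_equal(dim(nd1$stats), c(3L, 50L))
  expect_true(all(is.finite(nd1$stats)) && all(nd1$stats >= 0))

  # B = 1 works
  nd_b1 <- bootstrap_null_statistics(st, h, B = 1, seed = 5)
  expect_equal(ncol(nd_b1$stats), 1L)

  # two subsets with identical gene lists share the same resamples,
  # hence identical bootstrap statistic sequences
  h_dup <- gene_set_hierarchy(list(
    A = list(x = c("g1", "g2", "g3"), y = c("g1", "g2", "g3"))))
  nd_dup <- bootstrap_null_statistics(st, h_dup, B = 40, seed = 7)
  expect_identical(nd_dup$stats[1, ], nd_dup$stats[2, ])
})

test_that("bootstrap statistics agree with the moments/diag_t2 route", {
  # The C++ engine accumulates sums in one sweep; recompute each
  # replicate through the public moments + diag_t2 path instead.
  st <- make_study(G = 7, n = 6, shift = 0.5, seed = 10)
  h <- make_hierarchy(list(c(3, 2), 2))
  B <- 8; seed <- 31
  nd <- bootstrap_null_statistics(st, h, B = B, seed = seed)

  np <- build_null_population(st)
  set.seed(seed)
  idx1 <- matrix(sample.int(6, 6 * B, replace = TRUE), 6, B)
  idx2 <- matrix(sample.int(6, 6 * B, replace = TRUE), 6, B)
  flat <- list(1:3, 4:5, 6:7)
  for (b in seq_len(B)) {
    mb <- cbind(np$matrix[, 1:6][, idx1[, b]],
                np$matrix[, 7:12][, idx2[, b]])
    colnames(mb) <- paste0("r", 1:12)
    momb <- compute_group_moments(
      expression_study(mb, group = rep(1:2, each = 6)))
    for (s in 1:3)
      expect_equal(unname(nd$stats[s, b]), diag_t2(momb, flat[[s]]),
                   tolerance = 1e-10)
  }
})

test_that("single-gene bootstrap null matches an independent Welch-t2 simulation", {
  set.seed(55)
  n <- 40
  m <- matrix(rnorm(2 * n), 1, 2 * n,
              dimnames = list("g1", paste0("s", 1:(2 * n))))
  st <- expression_study(m, group = rep(1:2, each = n))
  h <- gene_set_hierarchy(list(s = list(a = "g1")))
  nd <- bootstrap_null_statistics(st, h, B = 2000, seed = 17)

  # independent Monte-Carlo reference: Welch t^2 for two N(0,1) samples
  ref <- replicate(4000, {
    a <- rnorm(n); b <- rnorm(n)
    (mean(a) - mean(b))^2 / (var(a) / n + var(b) / n)
  })
  ks <- suppressWarnings(ks.test(nd$stats[1, ], ref))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("paired bootstrap centres differences and reproduces", {
  m <- matrix(rnorm(4 * 10, mean = 0.3), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  st <- expression_study(m, pair = rep(paste0("p", 1:5), each = 2),
                         condition = rep(c("a", "b"), 5))
  h <- make_hierarchy(list(c(2, 2)))
  nd <- bootstrap_null_statistics(st, h, B = 30, seed = 3,
                                  statistic = "paired")
  expect_equal(dim(nd$stats), c(2L, 30L))
  expect_identical(
    nd$stats,
    bootstrap_null_statistics(st, h, B = 30, seed = 3,
                              statistic = "paired")$stats)
  expect_error(bootstrap_null_statistics(st, h, B = 10, seed = 1,
                                         statistic = "diag"),
               "two-group")
})

test_that("paired gsa_test flags a shifted subset and only that subset", {
  set.seed(71)
  n_pairs <- 12
  base <- matrix(rnorm(6 * n_pairs), 6, n_pairs)
  fup <- base + matrix(rnorm(6 * n_pairs, sd = 0.5), 6, n_pairs)
  fup[1:3, ] <- fup[1:3, ] + 2          # consistent within-pair shift
  m <- matrix(0, 6, 2 * n_pairs,
              dimnames = list(paste0("g", 1:6),
                              paste0("s", 1:(2 * n_pairs))))
  m[, seq(1, 2 * n_pairs, 2)] <- base
  m[, seq(2, 2 * n_pairs, 2)] <- fup
  st <- expression_study(
    m, pair = rep(paste0("p", 1:n_pairs), each = 2),
    condition = rep(c("base", "fup"), n_pairs))
  h <- make_hierarchy(list(c(3, 3)))
  res <- gsa_test(st, h, B = 800, seed = 5, statistic = "paired")
  expect_true(res$subsets$subset_significant[1])
  expect_false(res$subsets$subset_significant[2])
  # observed statistic agrees with the direct paired computation
  d <- paired_differences(st)
  expect_equal(res$subsets$statistic[1], paired_diag_t2(d, 1:3))
})

test_that("null p-values are approximately uniform", {
  # 600 null studies; the p-value ECDF at 0.05 must sit within +/- 0.02
  set.seed(123)
  R <- 600; B <- 400; n <- 15; G <- 5
  h <- make_hierarchy(list(G))
  p <- numeric(R)
  for (r in seq_len(R)) {
    x <- make_intraclass(G, 2 * n, sigma = sample(c(0.5, 1, 1.5), G, TRUE),
                         rho = sample(c(0, 0.5, 0.9), 1))
    colnames(x) <- paste0("s", seq_len(2 * n))
    st <- expression_study(x, group = rep(1:2, each = n))
    obs <- diag_t2(compute_group_moments(st), seq_len(G))
    nd <- bootstrap_null_statistics(st, h, B = B, seed = r)
    p[r] <- bootstrap_pvalue(obs, nd$stats[1, ])
  }
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
  # and no gross distortion at the median
  expect_lt(abs(mean(p <= 0.5) - 0.5), 0.07)
})
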