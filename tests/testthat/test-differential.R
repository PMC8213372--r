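# Normalization, dispersion, NB Wald testing, BH, module clustering

make_nb_counts <- function(n_regions, n_per_group, mu, alpha,
                           lfc = 0, de = rep(FALSE, n_regions)) {
  cond <- rep(c("g1", "g2"), each = n_per_group)
  l2 <- ifelse(de, lfc, 0)
  m <- outer(mu, rep(1, 2 * n_per_group)) *
    2^outer(l2, as.numeric(cond == "g2"))
  counts <- matrix(rnbinom(length(m), mu = m, size = 1 / alpha),
                   nrow = n_regions,
                   dimnames = list(paste0("r", seq_len(n_regions)),
                                   paste0("s", seq_len(2 * n_per_group))))
  list(counts = counts,
       samples = sample_table(colnames(counts), cond))
}

test_that("size factors follow the median-of-ratios definition", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                   dimnames = list(paste0("r", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(counts)), c(1, 1))

  counts[, "b"] <- 2 * counts[, "a"]
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(sf))), 1)

  # independent literal re-implementation on a random NB matrix
  set.seed(31)
  counts <- matrix(rnbinom(400 * 6, mu = 40, size = 4), ncol = 6,
                   dimnames = list(paste0("r", 1:400), paste0("s", 1:6)))
  sf <- estimate_size_factors(counts)
  ok <- apply(counts > 0, 1, all)
  logref <- rowMeans(log(counts[ok, ]))
  oracle <- apply(counts[ok, ], 2, function(cnt)
    exp(median(log(cnt) - logref)))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-10)

  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("size factors agree with the reference median-of-ratios tool", {
  skip_if_not_installed("DESeq2")
  set.seed(32)
  counts <- matrix(rnbinom(300 * 8, mu = 50, size = 5), ncol = 8,
                   dimnames = list(paste0("r", 1:300), paste0("s", 1:8)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(estimate_size_factors(counts)), unname(ref),
               tolerance = 1e-10)
})

test_that("method-of-moments dispersion recovers alpha and floors under-dispersion", {
  set.seed(33)
  # Poisson data: estimates concentrate near zero
  sim <- make_nb_counts(300, 10, mu = rep(50, 300), alpha = 1e-9)
  sim$counts[] <- rpois(length(sim$counts), 50)
  sf <- estimate_size_factors(sim$counts)
  a <- estimate_dispersion(sim$counts, sf, sim$samples)
  expect_gte(mean(a < 0.05), 0.9)

  # NB alpha = 0.5 with 50 replicates per group
  sim <- make_nb_counts(300, 50, mu = rep(50, 300), alpha = 0.5)
  sf <- estimate_size_factors(sim$counts)
  a <- estimate_dispersion(sim$counts, sf, sim$samples)
  expect_gt(median(a), 0.35)
  expect_lt(median(a), 0.65)

  # constant counts: zero variance -> floor
  counts <- matrix(7L, nrow = 3, ncol = 4,
                   dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
  a <- estimate_dispersion(counts, stats::setNames(rep(1, 4), colnames(counts)),
                           sample_table(colnames(counts), rep(c("x", "y"), 2)),
                           floor = 1e-8)
  expect_equal(unname(a), rep(1e-8, 3), ignore_attr = TRUE)
})

test_that("identical groups give log2FC 0 and p 1", {
  counts <- matrix(rep(c(5L, 9L, 14L), 4), nrow = 3, byrow = FALSE,
                   dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
  st <- sample_table(colnames(counts), rep(c("a", "b"), each = 2))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, st)
  res <- test_pairwise(counts, sf, disp, st, c("a", "b"))
  expect_equal(res$log2_fold_change, rep(0, 3), tolerance = 1e-8)
  expect_equal(res$p_value, rep(1, 3), tolerance = 1e-8)
})

test_that("tests are equivariant under joint count/size-factor rescaling", {
  set.seed(34)
  sim <- make_nb_counts(100, 4, mu = runif(100, 20, 80), alpha = 0.2,
                        lfc = 1.5, de = runif(100) < 0.2)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf, sim$samples)
  res1 <- test_pairwise(sim$counts, sf, disp, sim$samples, c("g1", "g2"))

  scaled <- sim$counts
  scaled[, 1] <- scaled[, 1] * 4L
  sf2 <- sf; sf2[1] <- sf2[1] * 4
  disp2 <- estimate_dispersion(scaled, sf2, sim$samples)
  expect_equal(unname(disp2), unname(disp), tolerance = 1e-10,
               ignore_attr = TRUE)
  res2 <- test_pairwise(scaled, sf2, disp2, sim$samples, c("g1", "g2"))
  # equivariance is exact for the normalized mean structure; the NB
  # variance function makes the Wald statistics agree only approximately
  expect_lt(max(abs(res2$log2_fold_change - res1$log2_fold_change)), 0.1)
  expect_gt(cor(res2$wald_statistic, res1$wald_statistic), 0.99)
  expect_equal(mean(res2$p_value < 0.05), mean(res1$p_value < 0.05),
               tolerance = 0.02)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(35)
  p <- runif(1000)
  expect_equal(bh_adjust(p), bh_oracle(p))

  # NA p-values are excluded before m is set
  p_na <- c(0.01, NA, 0.04)
  q <- bh_adjust(p_na)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.04)))

  # BH never returns more discoveries than the raw threshold
  expect_lte(sum(bh_adjust(p) < 0.05), sum(p < 0.05))
})

test_that("the differential union pools regions significant in any comparison", {
  mk <- function(q) data.frame(region_id = paste0("r", seq_along(q)),
                               comparison = "x", log2_fold_change = 1,
                               standard_error = 1, wald_statistic = 1,
                               p_value = q, q_value = q)
  res <- list(a = mk(c(0.01, 0.2, 0.9)), b = mk(c(0.5, 0.04, NA)))
  ids <- suppressMessages(select_differential_union(res, 0.05))
  expect_setequal(as.character(ids), c("r1", "r2"))
  expect_equal(attr(ids, "n_universe"), 3)
  empty <- suppressMessages(
    select_differential_union(list(a = mk(c(0.9, 0.8))), 0.05))
  expect_length(empty, 0)
})

test_that("condition means average log2 normalized counts per condition", {
  counts <- matrix(c(3L, 7L, 3L, 7L, 10L, 2L), nrow = 2,
                   dimnames = list(c("r1", "r2"), c("s1", "s2", "s3")))
  st <- sample_table(c("s1", "s2", "s3"), c("a", "a", "b"))
  sf <- stats::setNames(c(1, 1, 2), colnames(counts))
  cm <- condition_mean_rows(counts, sf, st)
  # direct arithmetic oracle
  nrm <- log2(sweep(counts, 2, sf, "/") + 1)
  expect_equal(cm[, "a"], rowMeans(nrm[, 1:2]))
  expect_equal(cm[, "b"], nrm[, 3])
  # duplicated sample within a condition leaves the mean unchanged
  counts2 <- counts[, c(1, 1, 2, 3)]
  colnames(counts2) <- c("s1", "s1b", "s2", "s3")
  st2 <- sample_table(colnames(counts2), c("a", "a", "a", "b"))
  sf2 <- stats::setNames(c(1, 1, 1, 2), colnames(counts2))
  cm2 <- condition_mean_rows(counts2, sf2, st2)
  expect_equal(cm2[, "a"], rowMeans(nrm[, c(1, 1, 2)]))
})

test_that("row normalization is a population z-score with flagged flat rows", {
  m <- matrix(c(1, 2, 3), nrow = 1)
  z <- row_normalize(m)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  m2 <- rbind(c(1, 2, 3), c(5, 5, 5))
  z2 <- row_normalize(m2)
  expect_equal(unname(z2[2, ]), c(0, 0, 0))
  expect_equal(attr(z2, "flagged_constant"), 2L, ignore_attr = TRUE)
  # non-degenerate rows have mean 0, population sd 1
  set.seed(36)
  m3 <- matrix(rnorm(40), nrow = 10)
  z3 <- row_normalize(m3)
  expect_equal(rowMeans(z3), rep(0, 10), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z3^2)), rep(1, 10), tolerance = 1e-12)
})

test_that("k-means modules recover separated patterns deterministically", {
  set.seed(37)
  centers <- rbind(c(2, -2, 0, 0), c(-2, 2, 0, 0))
  truth <- rep(1:2, each = 60)
  m <- centers[truth, ] + matrix(rnorm(480, sd = 0.2), ncol = 4)
  rownames(m) <- paste0("r", 1:120)
  mods <- kmeans_modules(row_normalize(m), k = 2, seed = 1)
  # perfect partition: labels are a pure relabeling of truth
  expect_equal(length(unique(paste(truth, mods$labels))), 2)
  # same seed twice: identical labels
  mods2 <- kmeans_modules(row_normalize(m), k = 2, seed = 1)
  expect_identical(mods$labels, mods2$labels)
  # labels ordered by descending cluster size
  sizes <- table(mods$labels)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_error(kmeans_modules(m, k = 1), "k must be >= 2")
  expect_error(kmeans_modules(m[1:3, ], k = 4), "fewer rows")
})

test_that("null Wald p-values are approximately uniform", {
  set.seed(38)
  sim <- make_nb_counts(800, 5, mu = exp(rnorm(800, log(50), 0.5)), alpha = 0.2)
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sf, sim$samples)
  res <- test_pairwise(sim$counts, sf, disp, sim$samples, c("g1", "g2"))
  p <- res$p_value[!is.na(res$p_value)]
  ks <- suppressWarnings(ks.test(p, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("the union over comparisons recovers sign-balanced planted effects", {
  set.seed(39)
  n_regions <- 2000; n <- 5; conds <- c("w", "x", "y", "z")
  base <- exp(rnorm(n_regions, log(50), 0.5))
  de <- runif(n_regions) < 0.1
  # each planted region shifts one random condition by +/- 2 log2 units,
  # sign-balanced so normalization stays unbiased
  shift_cond <- sample(conds, n_regions, TRUE)
  shift_sign <- sample(c(2, -2), n_regions, TRUE)
  cond <- rep(conds, each = n)
  l2 <- outer(ifelse(de, shift_sign, 0), rep(1, length(cond))) *
    (matrix(shift_cond, n_regions, length(cond)) ==
       matrix(cond, n_regions, length(cond), byrow = TRUE))
  mu <- outer(base, rep(1, length(cond))) * 2^l2
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.2),
                   nrow = n_regions,
                   dimnames = list(paste0("r", seq_len(n_regions)),
                                   paste0("s", seq_along(cond))))
  samples <- sample_table(colnames(counts), cond)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, samples)
  res <- all_pairwise(counts, sf, disp, samples)
  ids <- suppressMessages(select_differential_union(res, 0.05))
  recall <- mean(rownames(counts)[de] %in% ids)
  union_fdr <- mean(!de[match(ids, rownames(counts))])
  expect_gte(recall, 0.8)
  expect_lte(union_fdr, 0.10)
})
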