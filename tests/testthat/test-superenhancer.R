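# Regulatory domains, region-gene assignment, elbow detection, SE calling

test_that("basal domains are strand-aware and extensions stop at neighbor basals", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(10000L, 40000L), strand = c("+", "+"))
  d <- build_domains(g)
  expect_equal(d$basal_start[1], 5000)
  expect_equal(d$basal_end[1], 11000)
  # upstream gene's extension stops at the neighbor's basal start
  expect_equal(d$ext_end[1], 35000)
  # downstream gene's extension stops at the neighbor's basal end
  expect_equal(d$ext_start[2], 11000)

  dm <- build_domains(data.frame(gene_id = "g", chrom = "chr1",
                                 tss = 10000L, strand = "-"))
  expect_equal(dm$basal_start, 9000)
  expect_equal(dm$basal_end, 15000)
  # chromosome start clips at zero
  d0 <- build_domains(data.frame(gene_id = "g", chrom = "chr1",
                                 tss = 3000L, strand = "+"))
  expect_equal(d0$basal_start, 0)
  expect_equal(d0$ext_start, 0)
})

test_that("extended domains never cross a neighbor's basal boundary", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    g <- data.frame(gene_id = paste0("g", 1:n), chrom = "chr1",
                    tss = sort(sample.int(2e6, n)) + 10000L,
                    strand = sample(c("+", "-"), n, TRUE))
    d <- build_domains(g)
    d <- d[order(d$tss), ]
    for (j in seq_len(n)) {
      before <- d$basal_end[d$tss < d$tss[j]]
      after <- d$basal_start[d$tss > d$tss[j]]
      prev_end <- if (length(before)) max(before) else 0
      next_start <- if (length(after)) min(after) else Inf
      expect_gte(d$ext_start[j], min(d$basal_start[j], prev_end))
      expect_lte(d$ext_end[j], max(d$basal_end[j], next_start))
    }
    # extension never shrinks the basal domain
    expect_true(all(d$ext_start <= d$basal_start))
    expect_true(all(d$ext_end >= d$basal_end))
  }
})

test_that("regions are assigned to every domain containing their midpoint", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  tss = c(10000L, 40000L), strand = c("+", "+"))
  d <- build_domains(g)
  # midpoint in exactly one extension
  r1 <- genomic_intervals("chr1", 20000, 20500)
  expect_equal(assign_regions(r1, d)$n_regions, c(1L, 1L))  # gap is shared
  # midpoint inside g1's basal only
  r2 <- genomic_intervals("chr1", 9000, 9500)
  expect_equal(assign_regions(r2, d)$n_regions, c(1L, 0L))
  # zero-count genes are retained
  r3 <- genomic_intervals("chr1", 9000, 9500)
  expect_equal(nrow(assign_regions(r3, d)), 2)
})

test_that("assignment counts equal brute-force all-pairs containment", {
  set.seed(52)
  n <- 25
  g <- data.frame(gene_id = paste0("g", 1:n), chrom = "chr1",
                  tss = sort(sample.int(2e6, n)) + 10000L,
                  strand = sample(c("+", "-"), n, TRUE))
  d <- build_domains(g)
  regions <- genomic_intervals(rep("chr1", 1000),
                               sample.int(2e6, 1000),
                               sample.int(2e6, 1000) + 2e6 + 500L,
                               sort = FALSE)
  regions$end <- regions$start + 500L
  counts <- assign_regions(regions, d)
  mid <- (regions$start + regions$end) %/% 2L
  brute <- vapply(seq_len(n), function(j)
    sum(mid >= d$ext_start[j] & mid < d$ext_end[j]), 0L)
  expect_equal(counts$n_regions[match(d$gene_id, counts$gene_id)], brute)
})

test_that("ranking and unit scaling follow the definition", {
  cnt <- data.frame(gene_id = c("a", "b", "c", "z"),
                    n_regions = c(10L, 5L, 1L, 0L))
  curve <- rank_and_scale(cnt)
  expect_equal(nrow(curve), 3)  # zero-count gene dropped
  expect_equal(curve$x, c(0, 0.5, 1))
  expect_equal(curve$y, c(1.0, 0.5, 0.1))
  expect_false(attr(curve, "degenerate"))

  flat <- rank_and_scale(data.frame(gene_id = letters[1:4],
                                    n_regions = rep(3L, 4)))
  expect_true(attr(flat, "degenerate"))
  expect_equal(flat$y, rep(1, 4))
  expect_error(rank_and_scale(data.frame(gene_id = c("a", "b"),
                                         n_regions = c(2L, 1L))),
               "too short")
  # ties break lexicographically; x strictly increasing, y non-increasing
  set.seed(53)
  cnt <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    n_regions = sample.int(10, 50, TRUE))
  curve <- rank_and_scale(cnt)
  expect_true(all(diff(curve$x) > 0))
  expect_true(all(diff(curve$y) <= 0))
})

test_that("the chord elbow matches brute-force perpendicular distance", {
  curve <- data.frame(gene_id = letters[1:5],
                      n_regions = c(10L, 9L, 8L, 2L, 1L),
                      x = c(0, 0.25, 0.5, 0.75, 1),
                      y = c(1, 0.9, 0.8, 0.2, 0))
  el <- find_elbow(curve)
  expect_equal(el$index, 3L)  # the (0.5, 0.8) point
  expect_false(el$collinear)

  # straight line: collinear flag, index 1
  line <- data.frame(gene_id = letters[1:4], n_regions = 4:1,
                     x = c(0, 1/3, 2/3, 1), y = c(1, 2/3, 1/3, 0))
  expect_true(find_elbow(line)$collinear)
  expect_equal(find_elbow(line)$index, 1L)

  # 200-point convex curve equals the exhaustive argmax
  x <- seq(0, 1, length.out = 200)
  y <- (1 - x)^3
  cv <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   n_regions = rev(seq_len(200)), x = x, y = y)
  expect_equal(find_elbow(cv)$index, elbow_brute_oracle(x, y)$index)

  bad <- data.frame(x = c(0, 0.5, 1), y = c(1, 1.2, 0), gene_id = 1:3,
                    n_regions = 3:1)
  expect_error(find_elbow(bad), "non-increasing")
})

test_that("SE genes are those strictly above the elbow count", {
  curve <- rank_and_scale(data.frame(gene_id = letters[1:5],
                                     n_regions = c(10L, 9L, 8L, 2L, 1L)))
  er <- call_se_genes(curve)
  expect_equal(er$elbow_count, 8L)
  expect_setequal(er$se_genes, c("a", "b"))
  # elbow at rank 1: strict inequality empties the set
  er1 <- call_se_genes(curve, elbow = list(index = 1L, collinear = FALSE))
  expect_length(er1$se_genes, 0)
  # collinear curve: SE set empty by convention
  erc <- call_se_genes(curve, elbow = list(index = 1L, collinear = TRUE))
  expect_length(erc$se_genes, 0)
})

test_that("per-gene counts are monotone under region subsetting", {
  set.seed(54)
  g <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                  tss = sort(sample.int(5e5, 10)) + 10000L,
                  strand = "+")
  d <- build_domains(g)
  regions <- genomic_intervals(rep("chr1", 200), sample.int(5e5, 200),
                               sample.int(5e5, 200) + 5e5 + 400L, sort = FALSE)
  regions$end <- regions$start + 400L
  full <- assign_regions(regions, d)
  sub <- assign_regions(regions[sample.int(200, 80), ], d)
  expect_true(all(sub$n_regions <= full$n_regions))
})

test_that("locus tracks conserve cut sites and scale linearly", {
  fr <- fragments("chr1", 1000, 1001)
  tk <- locus_track(fr, "chr1", 990, 1010, bin = 1)
  expect_equal(sum(tk$count), 2)  # both cut sites of the 1 bp fragment
  expect_equal(tk$count[tk$start == 1000], 2)

  set.seed(55)
  st <- sample.int(8000, 500) + 500L
  fr <- fragments(rep("chr1", 500), st, st + sample.int(300, 500, TRUE))
  tk1 <- locus_track(fr, "chr1", 1000, 9000, bin = 50)
  cs <- fragment_to_cutsites(fr)
  expect_equal(sum(tk1$count), sum(cs$pos >= 1000 & cs$pos < 9000))
  expect_equal(attr(tk1, "n_in_view"), sum(tk1$count))
  # doubling the fragments doubles every bin
  fr2 <- fragments(rep(fr$chrom, 2), rep(fr$start, 2), rep(fr$end, 2))
  tk2 <- locus_track(fr2, "chr1", 1000, 9000, bin = 50)
  expect_equal(tk2$count, 2 * tk1$count)
  expect_error(locus_track(fr, "chr1", 500, 500), "empty")
})
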