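# Independent brute-force oracles used to validate the fast implementations.

# merge via a per-base boolean occupancy mask (one toy chromosome at a time)
mask_merge_oracle <- function(intervals, chrom_len = 10000L) {
  out <- lapply(sort(unique(intervals$chrom)), function(ch) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    mask <- logical(chrom_len)
    for (i in seq_len(nrow(sub)))
      mask[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep] - 1L, end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-region cut-site counts by an all-pairs double loop
brute_count_oracle <- function(cutsites, regions) {
  n <- nrow(regions)
  counts <- integer(n)
  for (r in seq_len(n)) {
    for (j in seq_len(nrow(cutsites))) {
      if (cutsites$chrom[j] == regions$chrom[r] &&
          cutsites$pos[j] >= regions$start[r] &&
          cutsites$pos[j] < regions$end[r])
        counts[r] <- counts[r] + 1L
    }
  }
  counts
}

# Benjamini-Hochberg from the min-over-tail step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o[rank_i:m]] * m / (rank_i:m)))
  }
  q
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of draws
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K items are the category
  mean(hits >= k)
}

# elbow by brute-force perpendicular distance to the endpoint chord
elbow_brute_oracle <- function(x, y) {
  n <- length(x)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- vapply(seq_len(n), function(i)
    abs((y2 - y1) * x[i] - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) / len, 0)
  list(index = which.max(d), distance = max(d))
}

# random interval table on a toy chromosome
random_intervals <- function(n, chrom = "chrT", chrom_len = 10000L,
                             max_width = 200L) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals(rep(chrom, n), start, start + width, sort = FALSE)
}
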