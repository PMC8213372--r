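# Negative-binomial differential accessibility: median-of-ratios size
# factors, method-of-moments dispersions with empirical-Bayes moderation,
# and per-region Wald tests on the condition coefficient fitted by IRLS.

#' Median-of-ratios size factors
#'
#' Per sample: the median, over regions with nonzero counts in every
#' sample, of the ratio of the sample's count to the region's geometric
#' mean across samples; rescaled so the factors have geometric mean 1.
#'
#' @param counts Integer count matrix (regions x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    stop("no region has nonzero counts in every sample; ",
         "filter low-count regions before normalization")
  sub <- counts[ok, , drop = FALSE]
  logref <- rowMeans(log(sub))
  f <- apply(sub, 2, function(col) exp(median(log(col) - logref)))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Per-region method-of-moments dispersion
#'
#' On size-factor-normalized counts, pools the within-condition variance
#' across conditions with >= 2 replicates and solves the NB
#' mean-variance relation `var = mu + alpha * mu^2` for alpha:
#' `alpha_r = max(floor, (s2 - m) / m^2)` with `m` the grand mean of the
#' region's normalized counts.
#'
#' @param counts Count matrix (regions x samples).
#' @param size_factors From [estimate_size_factors()].
#' @param samples A [sample_table()] matching the columns.
#' @param floor Lower bound absorbing under-dispersion (default `1e-8`).
#' @return Numeric vector of raw dispersion estimates, one per region,
#'   with attribute `resid_df` (pooled within-condition residual df).
#' @export
estimate_dispersion <- function(counts, size_factors, samples, floor = 1e-8) {
  stopifnot(ncol(counts) == nrow(samples))
  cond <- samples$condition[match(colnames(counts), samples$sample_id)]
  reps <- table(cond)
  if (!any(reps >= 2))
    stop("dispersion estimation needs >= 2 replicates in >= 1 condition")
  nrm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  use <- cond %in% names(reps)[reps >= 2]
  resid_df <- sum(reps[reps >= 2] - 1)
  groups <- split(seq_len(ncol(nrm))[use], cond[use])
  m <- rowMeans(nrm)
  ss <- rowSums(do.call(cbind, lapply(groups, function(ix) {
    sub <- nrm[, ix, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  })))
  s2 <- ss / resid_df
  alpha <- ifelse(m > 0, pmax(floor, (s2 - m) / m^2), floor)
  attr(alpha, "resid_df") <- resid_df
  alpha
}

#' Moderate raw dispersions toward the cross-region center
#'
#' Empirical-Bayes moment moderation: each region's raw estimate is a
#' weighted average of itself (weight: its residual df) and the
#' 10 percent trimmed mean over regions (weight: `prior_df`). Stabilizes
#' the Wald test at small replicate numbers.
#'
#' @param alpha Raw dispersions from [estimate_dispersion()].
#' @param resid_df Residual df behind each estimate (taken from the
#'   `resid_df` attribute when `NULL`).
#' @param prior_df Prior weight (default 10).
#' @return Moderated dispersion vector with attribute `total_df =
#'   resid_df + prior_df`, the df of the t reference used downstream.
#' @export
moderate_dispersion <- function(alpha, resid_df = NULL, prior_df = 10) {
  if (is.null(resid_df)) resid_df <- attr(alpha, "resid_df")
  stopifnot(!is.null(resid_df), resid_df >= 1, prior_df >= 0)
  a0 <- mean(alpha, trim = 0.1)
  out <- (resid_df * alpha + prior_df * a0) / (resid_df + prior_df)
  attr(out, "total_df") <- resid_df + prior_df
  out
}

# NB log-linear IRLS fit for one region; X is the design, off = log size
# factors, alpha the fixed dispersion. Returns coef, Wald SE of the last
# coefficient, and convergence flag.
.nb_irls <- function(y, X, off, alpha, max_iter = 100L, tol = 1e-8) {
  b <- c(log(mean(y / exp(off)) + 0.1), rep(0, ncol(X) - 1L))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- off + drop(X %*% b)
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    bn <- tryCatch(solve(XtW %*% X, XtW %*% z),
                   error = function(e) NULL)
    if (is.null(bn) || any(!is.finite(bn))) return(NULL)
    if (max(abs(bn - b)) < tol) { b <- bn; converged <- TRUE; break }
    b <- bn
  }
  eta <- off + drop(X %*% b)
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  V <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  list(coef = drop(b), se_last = sqrt(V[ncol(X), ncol(X)]),
       converged = converged)
}

#' Pairwise differential accessibility test
#'
#' For each region, fits a negative-binomial log-linear model with the
#' condition indicator as covariate and log size factors as offsets
#' (IRLS with fixed moderated dispersion), and performs a Wald test on
#' the condition coefficient against a t reference with
#' `resid_df + prior_df` degrees of freedom. Fold changes are reported as
#' the second condition relative to the first. Benjamini-Hochberg q-values
#' are computed across all converged regions within the comparison.
#'
#' @param counts Count matrix (regions x samples).
#' @param size_factors From [estimate_size_factors()].
#' @param dispersions Raw per-region dispersions
#'   ([estimate_dispersion()]); moderated internally.
#' @param samples A [sample_table()].
#' @param pair Character vector `c(condA, condB)`; log2 fold change is B
#'   relative to A.
#' @param prior_df Moderation prior weight (see [moderate_dispersion()]).
#' @return `data.frame`: `region_id`, `comparison`, `log2_fold_change`,
#'   `standard_error`, `wald_statistic`, `p_value`, `q_value`.
#'   Non-converged regions carry `NA` statistics and are excluded from the
#'   BH family.
#' @export
test_pairwise <- function(counts, size_factors, dispersions, samples, pair,
                          prior_df = 10) {
  stopifnot(length(pair) == 2)
  cond <- samples$condition[match(colnames(counts), samples$sample_id)]
  sel <- cond %in% pair
  if (sum(cond == pair[1]) < 2 || sum(cond == pair[2]) < 2)
    stop("both conditions need >= 2 samples: ", paste(pair, collapse = " vs "))
  sub <- counts[, sel, drop = FALSE]
  sfs <- size_factors[colnames(sub)]
  x <- as.numeric(cond[sel] == pair[2])
  X <- cbind(1, x)
  off <- log(sfs)
  alpha <- moderate_dispersion(dispersions, prior_df = prior_df)
  tdf <- attr(alpha, "total_df")
  n <- nrow(sub)
  lfc <- se <- stat <- p <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    y <- sub[r, ]
    if (all(y == 0)) next
    fit <- .nb_irls(y, X, off, alpha[r])
    if (is.null(fit) || !fit$converged) next
    lfc[r] <- fit$coef[2] / log(2)
    se[r] <- fit$se_last / log(2)
    stat[r] <- fit$coef[2] / fit$se_last
    p[r] <- 2 * pt(-abs(stat[r]), df = tdf)
  }
  data.frame(region_id = rownames(counts),
             comparison = paste(pair[2], "vs", pair[1], sep = "_"),
             log2_fold_change = lfc, standard_error = se,
             wald_statistic = stat, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input. `NA` p-values
#' are excluded before the family size is set and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' All pairwise differential comparisons
#'
#' @inheritParams test_pairwise
#' @param conditions Conditions to compare (default: order of first
#'   appearance in `samples`).
#' @return Named list of [test_pairwise()] results, one per unordered
#'   condition pair.
#' @export
all_pairwise <- function(counts, size_factors, dispersions, samples,
                         conditions = NULL, prior_df = 10) {
  if (is.null(conditions)) conditions <- unique(samples$condition)
  pairs <- combn(conditions, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr)
    test_pairwise(counts, size_factors, dispersions, samples, pr,
                  prior_df = prior_df))
  names(res) <- vapply(pairs, function(pr) paste(pr[2], "vs", pr[1], sep = "_"), "")
  res
}

#' Differential region union across comparisons
#'
#' Regions with `q_value < fdr_threshold` in at least one pairwise
#' comparison — the differential ChAR set.
#'
#' @param results List of per-comparison result tables.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Character vector of region ids; attributes `n_universe` and
#'   `n_differential` report sizes.
#' @export
select_differential_union <- function(results, fdr_threshold = 0.05) {
  stopifnot(length(results) >= 1, fdr_threshold > 0, fdr_threshold < 1)
  ids <- unique(unlist(lapply(results, function(df)
    df$region_id[!is.na(df$q_value) & df$q_value < fdr_threshold])))
  ids <- ids[order(match(ids, results[[1]]$region_id))]
  attr(ids, "n_universe") <- nrow(results[[1]])
  attr(ids, "n_differential") <- length(ids)
  message(length(ids), " differential region(s) out of a universe of ",
          nrow(results[[1]]))
  ids
}

#' Condition-mean matrix of transformed normalized counts
#'
#' Normalized counts (`count / size_factor`) are `log2(x + 1)`
#' transformed and averaged within condition.
#'
#' @param counts Count matrix.
#' @param size_factors From [estimate_size_factors()].
#' @param samples A [sample_table()].
#' @param regions Region ids to keep (default: all rows).
#' @return Matrix regions x conditions (column order: first appearance in
#'   `samples`).
#' @export
condition_mean_rows <- function(counts, size_factors, samples,
                                regions = rownames(counts)) {
  stopifnot(all(regions %in% rownames(counts)))
  conditions <- unique(samples$condition)
  nrm <- log2(sweep(counts[regions, , drop = FALSE], 2,
                    size_factors[colnames(counts)], "/") + 1)
  cond <- samples$condition[match(colnames(counts), samples$sample_id)]
  out <- vapply(conditions, function(cc) {
    ix <- which(cond == cc)
    if (length(ix) == 0) stop("condition has zero samples: ", cc)
    rowMeans(nrm[, ix, drop = FALSE])
  }, numeric(length(regions)))
  matrix(out, nrow = length(regions),
         dimnames = list(regions, conditions))
}

#' Row z-score normalization
#'
#' Subtracts each row's mean and divides by its (population) standard
#' deviation, removing baseline-accessibility differences between
#' regions. Zero-variance rows become all-zero and are flagged.
#'
#' @param m Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape; attribute `flagged_constant` holds
#'   indices of zero-variance rows.
#' @export
row_normalize <- function(m) {
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  flat <- sdev == 0
  sdev[flat] <- 1
  out <- (m - mu) / sdev
  out[flat, ] <- 0
  attr(out, "flagged_constant") <- which(flat)
  out
}

# k-means++ seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance to nearest center.
.kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((m - matrix(m[centers[1], ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) centers[j] <- sample.int(n, 1)
    else centers[j] <- sample.int(n, 1, prob = d2)
    nd <- rowSums((m - matrix(m[centers[j], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' Cluster row-normalized condition means into accessibility modules
#'
#' k-means with k-means++ initialization and multiple restarts; the
#' solution with the smallest within-cluster sum of squares is kept.
#' Cluster labels `A`, `B`, ... are assigned by descending cluster size
#' (ties: smallest member row index) so labels are reproducible.
#'
#' @param m Row-normalized matrix ([row_normalize()]); rownames are
#'   region ids.
#' @param k Number of modules (default 4).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param restarts Independent initializations (default 10).
#' @return Object of class `module_assignment`: list with `labels` (named
#'   character vector region_id -> label), `k`, `seed`, `centers`, and the
#'   clustered `matrix`.
#' @export
kmeans_modules <- function(m, k = 4, seed = 1, restarts = 10) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(m) < k) stop("fewer rows than clusters")
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    init <- .kmeanspp_centers(m, k)
    fit <- suppressWarnings(kmeans(m, centers = init, iter.max = 100L))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  sizes <- tabulate(best$cluster, nbins = k)
  first_member <- vapply(seq_len(k), function(j) min(which(best$cluster == j)), 0L)
  ord <- order(-sizes, first_member)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- LETTERS[relabel[best$cluster]]
  structure(list(labels = stats::setNames(labels, rownames(m)),
                 k = k, seed = seed,
                 centers = best$centers[ord, , drop = FALSE],
                 matrix = m),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment: k =", x$k, "\n")
  print(table(x$labels))
  invisible(x)
}
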