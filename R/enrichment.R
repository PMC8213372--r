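# Hypergeometric fold enrichment of accessibility modules against
# exhaustion-state region categories (orthologous mouse ChAR classes).

#' Exhaustion-state category labels
#' @export
EXHAUSTION_CATEGORIES <- c("naive", "effector", "memory",
                           "early_exhaustion", "late_exhaustion")

#' Load a region-category annotation
#'
#' Accepts a TSV with either (`region_id`, `category`) or
#' (`chrom`, `start`, `end`, `category`) columns (headerless, in that
#' order). Coordinate rows are matched to universe regions by midpoint
#' containment; unmatched rows are dropped with a message. Every universe
#' region not named by the file is labelled `"none"`. Each region carries
#' at most one category; on duplicate assignments the first row wins with
#' a warning.
#'
#' @param path TSV path, or a `data.frame` in either layout.
#' @param universe A [peak_universe()].
#' @param categories Allowed category strings (besides `"none"`).
#' @return Named character vector: region_id -> category, covering the
#'   whole universe.
#' @export
load_category_annotation <- function(path, universe,
                                     categories = EXHAUSTION_CATEGORIES) {
  df <- if (is.data.frame(path)) path
        else read.table(path, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) == 2) {
    names(df) <- c("region_id", "category")
    matched <- match(df$region_id, universe$region_ids)
  } else if (ncol(df) >= 4) {
    names(df)[1:4] <- c("chrom", "start", "end", "category")
    mid <- (as.integer(df$start) + as.integer(df$end)) %/% 2L
    matched <- .region_index(universe, df$chrom, mid)
  } else stop("annotation needs 2 (region_id, category) or 4+ (chrom, start, end, category) columns")
  bad <- setdiff(unique(df$category), c(categories, "none"))
  if (length(bad))
    stop("unknown category string(s): ", paste(bad, collapse = ", "))
  unmatched <- is.na(matched)
  if (mean(unmatched) > 0.5)
    stop("more than half of annotation rows match no universe region; ",
         "check coordinate conventions")
  if (any(unmatched))
    message(sum(unmatched), " annotation row(s) matched no universe region and were dropped")
  ann <- stats::setNames(rep("none", length(universe)), universe$region_ids)
  mi <- matched[!unmatched]
  ci <- df$category[!unmatched]
  dup <- duplicated(mi)
  if (any(dup & ci[match(mi, mi)] != ci))
    warning("regions with conflicting category assignments; first listed wins")
  ann[mi[!dup]] <- ci[!dup]
  ann
}

#' Hypergeometric fold enrichment of one region set vs one category
#'
#' Fold enrichment is `(k/n) / (K/N)`: the category rate inside the set
#' over its rate in the background. The p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param cluster_regions Character vector of region ids (non-empty).
#' @param annotation From [load_category_annotation()].
#' @param category Category string.
#' @param background `"universe"` (default) or a character vector of
#'   region ids to use as background.
#' @return One-row `data.frame`: `category`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`. When the category is absent from the
#'   background (`K = 0`), `fold_enrichment` is `NA` and `p_value` 1.
#' @export
fold_enrichment <- function(cluster_regions, annotation, category,
                            background = "universe") {
  stopifnot(length(cluster_regions) >= 1)
  bg <- if (identical(background, "universe")) annotation
        else annotation[background]
  stopifnot(all(cluster_regions %in% names(bg)))
  N <- length(bg)
  K <- sum(bg == category)
  n <- length(cluster_regions)
  k <- sum(bg[cluster_regions] == category)
  fe <- if (K == 0) NA_real_ else (k / n) / (K / N)
  p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(category = category, k = k, n = n, K = K, N = N,
             fold_enrichment = fe, p_value = p, stringsAsFactors = FALSE)
}

#' Module-by-category enrichment table
#'
#' One [fold_enrichment()] row per (module x category), cluster-major —
#' the quantitation behind category-enrichment bar panels.
#'
#' @param modules A `module_assignment` (or named character vector
#'   region_id -> label).
#' @param annotation From [load_category_annotation()].
#' @param categories Categories to score (default the five
#'   exhaustion-state classes).
#' @param background Passed to [fold_enrichment()].
#' @return `data.frame` with a `cluster` column prepended.
#' @export
enrichment_table <- function(modules, annotation,
                             categories = EXHAUSTION_CATEGORIES,
                             background = "universe") {
  labels <- if (inherits(modules, "module_assignment")) modules$labels else modules
  rows <- lapply(sort(unique(labels)), function(cl) {
    regs <- names(labels)[labels == cl]
    do.call(rbind, lapply(categories, function(cat) {
      cbind(cluster = cl,
            fold_enrichment(regs, annotation, cat, background = background))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
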