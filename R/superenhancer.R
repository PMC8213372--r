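# Super-enhancer-associated gene calling: GREAT basal-plus-extension
# regulatory domains, region-to-gene assignment by midpoint containment,
# and elbow detection on the unit-scaled ranked gene/region-count curve.

#' Read a gene/TSS annotation table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, with header.
#' @return `data.frame` with those columns.
#' @export
read_genes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id; one TSS per gene required")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  df
}

#' GREAT-style basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal domain (`basal_up` bp upstream
#' to `basal_down` bp downstream of the TSS) extended on each side to the
#' nearer of `extension_max` from the TSS or the adjacent gene's basal
#' domain boundary; extension never shrinks the basal domain. Coordinates
#' clip at 0.
#'
#' @param genes Gene table ([read_genes()] layout).
#' @param basal_up Upstream basal extent in bp (default 5000).
#' @param basal_down Downstream basal extent in bp (default 1000).
#' @param extension_max Maximum extension from the TSS in bp (default 1e6).
#' @return `data.frame`: `gene_id`, `chrom`, `tss`, `strand`,
#'   `basal_start`, `basal_end`, `ext_start`, `ext_end` (all 0-based
#'   half-open).
#' @export
build_domains <- function(genes, basal_up = 5000L, basal_down = 1000L,
                          extension_max = 1e6) {
  g <- genes[order(genes$chrom, genes$tss, method = "radix"), , drop = FALSE]
  up <- ifelse(g$strand == "+", basal_up, basal_down)
  down <- ifelse(g$strand == "+", basal_down, basal_up)
  g$basal_start <- pmax(g$tss - up, 0)
  g$basal_end <- g$tss + down
  g$ext_start <- g$basal_start
  g$ext_end <- g$basal_end
  for (ch in unique(g$chrom)) {
    ix <- which(g$chrom == ch)
    bs <- g$basal_start[ix]; be <- g$basal_end[ix]; tss <- g$tss[ix]
    n <- length(ix)
    # nearest basal boundary of any preceding/following gene (by TSS order)
    prev_end <- c(0, cummax(be[-n]))
    next_start <- rev(c(Inf, cummin(rev(bs)[-n])))
    g$ext_start[ix] <- pmin(bs, pmax(tss - extension_max, prev_end, 0))
    g$ext_end[ix] <- pmax(be, pmin(tss + extension_max, next_start))
  }
  rownames(g) <- NULL
  g
}

#' Assign differential regions to genes
#'
#' A region is assigned to every gene whose extended regulatory domain
#' contains the region midpoint (multi-assignment allowed). Zero-count
#' genes are retained.
#'
#' @param regions Interval table of differential regions (or a
#'   [peak_universe()] subset).
#' @param domains From [build_domains()].
#' @return `data.frame`: `gene_id`, `n_regions`.
#' @export
assign_regions <- function(regions, domains) {
  if (inherits(regions, "peak_universe")) regions <- regions$regions
  counts <- stats::setNames(integer(nrow(domains)), domains$gene_id)
  if (nrow(regions) > 0) {
    mid <- (regions$start + regions$end) %/% 2L
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      di <- which(domains$chrom == ch)
      if (length(di) == 0) next
      hits <- IRanges::findOverlaps(
        .as_iranges(mid[ri], mid[ri] + 1L),
        .as_iranges(as.integer(domains$ext_start[di]),
                    as.integer(pmin(domains$ext_end[di], .Machine$integer.max))))
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(di))
      counts[di] <- counts[di] + tab
    }
  }
  data.frame(gene_id = domains$gene_id, n_regions = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Rank genes and unit-scale the region-count curve
#'
#' Drops zero-count genes, sorts descending by count (ties broken by
#' gene_id), and scales rank to `x = (rank - 1) / (n - 1)` and count to
#' `y = count / max(count)`.
#'
#' @param counts `data.frame` from [assign_regions()].
#' @return `data.frame`: `gene_id`, `n_regions`, `rank`, `x`, `y`;
#'   attribute `degenerate` flags an all-equal-count curve.
#' @export
rank_and_scale <- function(counts) {
  nz <- counts[counts$n_regions > 0, , drop = FALSE]
  if (nrow(nz) < 3) stop("curve too short for elbow detection (< 3 genes with regions)")
  nz <- nz[order(-nz$n_regions, nz$gene_id, method = "radix"), , drop = FALSE]
  n <- nrow(nz)
  nz$rank <- seq_len(n)
  nz$x <- (nz$rank - 1) / (n - 1)
  nz$y <- nz$n_regions / max(nz$n_regions)
  rownames(nz) <- NULL
  attr(nz, "degenerate") <- length(unique(nz$n_regions)) == 1
  nz
}

#' Detect the elbow of a unit-scaled ranked curve
#'
#' Chord method: the elbow is the point of maximum perpendicular distance
#' to the straight line through the first and last scaled points. Ties go
#' to the smallest index. A collinear curve (maximum distance ~0) is
#' flagged; its elbow index is 1 and the SE set is empty by convention.
#'
#' @param curve From [rank_and_scale()] (columns `x`, `y`; `y`
#'   non-increasing).
#' @return List: `index`, `distance`, `collinear`.
#' @export
find_elbow <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  if (any(diff(curve$y) > 1e-12)) stop("curve y values must be non-increasing")
  x <- curve$x; y <- curve$y
  n <- length(x)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + x[n] * y[1] - y[n] * x[1]) / sqrt(dx^2 + dy^2)
  if (max(d) < 1e-12) return(list(index = 1L, distance = 0, collinear = TRUE))
  list(index = which.max(d), distance = max(d), collinear = FALSE)
}

#' Call super-enhancer-associated genes
#'
#' Genes whose raw associated-region count is strictly greater than the
#' count at the elbow gene.
#'
#' @param curve From [rank_and_scale()].
#' @param elbow From [find_elbow()] (computed when `NULL`).
#' @return Object of class `elbow_result`: list with `curve`,
#'   `elbow_index`, `elbow_count`, `collinear`, `se_genes`.
#' @export
call_se_genes <- function(curve, elbow = NULL) {
  if (is.null(elbow)) elbow <- find_elbow(curve)
  se <- if (elbow$collinear) character(0)
        else curve$gene_id[curve$n_regions > curve$n_regions[elbow$index]]
  structure(list(curve = curve, elbow_index = elbow$index,
                 elbow_count = if (elbow$collinear) NA_integer_
                               else curve$n_regions[elbow$index],
                 collinear = elbow$collinear, se_genes = se),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf("elbow_result: %d ranked genes, elbow at rank %d (count %s), %d SE gene(s)\n",
              nrow(x$curve), x$elbow_index, x$elbow_count, length(x$se_genes)))
  invisible(x)
}

#' Direction-specific super-enhancer gene calling
#'
#' Convenience wrapper tying the differential results to the SE caller:
#' selects regions significant in one comparison with the requested fold
#' change sign, assigns them to regulatory domains, and runs elbow
#' detection.
#'
#' @param result One comparison's [test_pairwise()] table.
#' @param universe A [peak_universe()].
#' @param genes Gene table.
#' @param direction `"up"` (log2FC > 0, second condition more accessible)
#'   or `"down"`.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param ... Passed to [build_domains()].
#' @return An `elbow_result`.
#' @export
se_genes_for_direction <- function(result, universe, genes,
                                   direction = c("up", "down"),
                                   fdr_threshold = 0.05, ...) {
  direction <- match.arg(direction)
  sig <- !is.na(result$q_value) & result$q_value < fdr_threshold &
    (if (direction == "up") result$log2_fold_change > 0
     else result$log2_fold_change < 0)
  regs <- universe$regions[match(result$region_id[sig], universe$region_ids), ,
                           drop = FALSE]
  domains <- build_domains(genes, ...)
  call_se_genes(rank_and_scale(assign_regions(regs, domains)))
}

#' Binned cut-site coverage track for a locus
#'
#' Cut-site pileup over a viewing interval, binned at a configurable
#' width, suitable for bedGraph export; the total cut-site count in view
#' is attached.
#'
#' @param frags Fragment table.
#' @param chrom,start,end Viewing interval (0-based half-open).
#' @param bin Bin width in bp (default 10).
#' @return `data.frame`: `chrom`, `start`, `end`, `count`; attribute
#'   `n_in_view` is the total cut sites in the interval.
#' @export
locus_track <- function(frags, chrom, start, end, bin = 10L) {
  if (start >= end) stop("empty viewing interval")
  cs <- fragment_to_cutsites(frags)
  inview <- cs$chrom == chrom & cs$pos >= start & cs$pos < end
  pos <- cs$pos[inview]
  breaks <- seq(start, end, by = bin)
  if (breaks[length(breaks)] < end) breaks <- c(breaks, end)
  bidx <- findInterval(pos, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bidx, nbins = length(breaks) - 1L)
  out <- data.frame(chrom = chrom, start = breaks[-length(breaks)],
                    end = breaks[-1], count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "n_in_view") <- length(pos)
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track From [locus_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
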