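#' @importFrom stats median phyper pnorm pt rnbinom rpois runif rnorm
#'   kmeans p.adjust sd rbinom
#' @importFrom utils read.table write.table combn
NULL

# All coordinates in this package are BED-style: 0-based, half-open
# [start, end). IRanges is 1-based closed, so conversion happens at the
# boundary of every IRanges call and nowhere else.

.as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Construct a genomic-interval table
#'
#' The elementary data structure of the package: a data frame of 0-based,
#' half-open genomic intervals sorted by (chrom, start, end).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, exclusive end coordinates; must satisfy
#'   `0 <= start < end` elementwise.
#' @param name Optional identifiers (recycled `NA` if missing).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."`.
#' @param sort Sort the result by (chrom, start, end)? Default `TRUE`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = NULL, strand = NULL,
                              sort = TRUE) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (n > 0 && any(is.na(start) | is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(start >= end)) stop("interval with start >= end")
  name <- if (is.null(name)) rep(NA_character_, n) else as.character(name)
  strand <- if (is.null(strand)) rep(".", n) else as.character(strand)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = name, strand = strand, stringsAsFactors = FALSE)
  if (sort && n > 1) df <- .sort_intervals(df)
  df
}

.sort_intervals <- function(df) {
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a peak set
#'
#' A set of called peaks for one biological condition, e.g. one MACS2
#' narrowPeak file from condition-merged alignments.
#'
#' @param intervals Interval table from [genomic_intervals()] or
#'   [read_bed()].
#' @param condition Condition label.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(intervals, condition = NA_character_) {
  structure(list(condition = condition, intervals = .sort_intervals(intervals)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chromosome(s)\n",
              x$condition, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Read a BED-family file
#'
#' Reads BED3, BED6 or ENCODE narrowPeak (BED6+4). Coordinates are taken
#' verbatim (the formats are already 0-based half-open). Lines starting
#' with `#`, `track` or `browser`, and blank lines, are skipped.
#' narrowPeak columns beyond the interval extent (signal, p/q, summit)
#' are parsed for validity but not retained.
#'
#' @param path File path (plain text or gzip).
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param condition Condition label attached to the returned peak set;
#'   defaults to the file name without extension.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak"),
                     condition = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(condition))
    condition <- sub("\\.(bed|narrowPeak)(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  min_fields <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  keep <- !(grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines)))
  idx <- which(keep)
  if (length(idx) == 0)
    return(peak_set(genomic_intervals(), condition))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop(sprintf("line %d: expected >= %d tab-separated fields, got %d",
                 idx[bad[1]], min_fields, nf[bad[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinate", idx[bad[1]]))
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("line %d: invalid interval [%d, %d)",
                 idx[bad[1]], start[bad[1]], end[bad[1]]))
  name <- if (min_fields >= 6L) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (min_fields >= 6L) {
    s <- vapply(fields, `[[`, "", 6L)
    s[!s %in% c("+", "-")] <- "."
    s
  } else NULL
  peak_set(genomic_intervals(chrom, start, end, name = name, strand = strand),
           condition)
}

#' Write intervals as BED
#'
#' Writes BED3 (no names) or BED4 when names are present, as used for the
#' region universe (`region_id` in column 4).
#'
#' @param intervals Interval table or [peak_universe()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "peak_universe")) {
    df <- intervals$regions
    df$name <- intervals$region_ids
  } else df <- intervals
  cols <- c("chrom", "start", "end")
  if (!all(is.na(df$name))) cols <- c(cols, "name")
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and bookended intervals
#'
#' Intervals merge iff they overlap by >= 1 bp or are bookended
#' (`end == next start`); intervals on different chromosomes never merge.
#' The union of covered bases is preserved.
#'
#' @param intervals Interval table (need not be sorted).
#' @return Sorted, pairwise non-overlapping interval table.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(genomic_intervals())
  parts <- split(intervals, intervals$chrom)
  out <- lapply(names(parts), function(ch) {
    red <- IRanges::reduce(.as_iranges(parts[[ch]]$start, parts[[ch]]$end))
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), name = NA_character_, strand = ".",
               stringsAsFactors = FALSE)
  })
  .sort_intervals(do.call(rbind, out))
}

#' Build the peak universe
#'
#' The region universe is the union of peaks across all biological
#' conditions with overlapping regions merged. Every input peak is fully
#' contained in exactly one universe region. Region identifiers are
#' `"chrom:start-end"` from the final merged coordinates.
#'
#' @param peaksets List of [peak_set()] objects (or a single one).
#' @param blacklist Optional interval table; when `subtract_blacklist` is
#'   `TRUE`, blacklisted stretches are removed from universe regions.
#' @param subtract_blacklist Apply region-level blacklist subtraction?
#'   Default `FALSE` (read-level blacklist removal is the primary filter).
#' @return An object of class `peak_universe` with elements `regions`
#'   (interval table) and `region_ids`.
#' @export
build_universe <- function(peaksets, blacklist = NULL,
                           subtract_blacklist = FALSE) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  stopifnot(length(peaksets) >= 1)
  all_iv <- do.call(rbind, lapply(peaksets, function(ps) ps$intervals))
  if (is.null(all_iv) || nrow(all_iv) == 0)
    stop("all peak sets are empty; cannot build a region universe")
  regions <- merge_intervals(all_iv)
  if (subtract_blacklist && !is.null(blacklist) && nrow(blacklist) > 0) {
    bl <- merge_intervals(blacklist)
    parts <- split(regions, regions$chrom)
    kept <- lapply(names(parts), function(ch) {
      blc <- bl[bl$chrom == ch, , drop = FALSE]
      if (nrow(blc) == 0) return(parts[[ch]])
      d <- IRanges::setdiff(.as_iranges(parts[[ch]]$start, parts[[ch]]$end),
                            .as_iranges(blc$start, blc$end))
      if (length(d) == 0) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(d) - 1L,
                 end = IRanges::end(d), name = NA_character_, strand = ".",
                 stringsAsFactors = FALSE)
    })
    regions <- .sort_intervals(do.call(rbind, kept))
    if (nrow(regions) == 0) stop("blacklist subtraction removed every region")
  }
  peak_universe(regions)
}

#' Construct a peak universe from merged regions
#'
#' @param regions Sorted, non-overlapping interval table.
#' @return A `peak_universe`.
#' @export
peak_universe <- function(regions) {
  regions <- .sort_intervals(regions)
  if (nrow(regions) > 1) {
    same <- regions$chrom[-1] == regions$chrom[-nrow(regions)]
    if (any(same & regions$start[-1] < regions$end[-nrow(regions)]))
      stop("universe regions must be pairwise non-overlapping")
  }
  ids <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  regions$name <- ids
  structure(list(regions = regions, region_ids = ids), class = "peak_universe")
}

#' @export
print.peak_universe <- function(x, ...) {
  cat(sprintf("peak_universe: %d regions, %d chromosome(s), %d bp covered\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              sum(x$regions$end - x$regions$start)))
  invisible(x)
}

#' @export
length.peak_universe <- function(x) nrow(x$regions)

# Vectorized point -> containing-region lookup; NA where no region
# contains the point. Points are 0-based; a point equal to a region end
# is outside (half-open).
.region_index <- function(universe, chrom, pos) {
  idx <- rep(NA_integer_, length(chrom))
  regs <- universe$regions
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    si <- which(regs$chrom == ch)
    if (length(si) == 0) next
    hits <- IRanges::findOverlaps(
      .as_iranges(pos[qi], pos[qi] + 1L),
      .as_iranges(regs$start[si], regs$end[si]))
    idx[qi[S4Vectors::queryHits(hits)]] <- si[S4Vectors::subjectHits(hits)]
  }
  idx
}

#' Locate the universe region containing a point or interval
#'
#' Points use half-open semantics: a point equal to a region's `end` is
#' outside it. For an interval query the region must fully contain the
#' interval.
#'
#' @param universe A [peak_universe()].
#' @param chrom Chromosome name(s).
#' @param pos 0-based point position(s), or interval start(s) when `end`
#'   is given.
#' @param end Optional exclusive end(s) for interval queries.
#' @return Integer vector of region indices (`NA` where uncontained).
#' @export
overlap_query <- function(universe, chrom, pos, end = NULL) {
  if (is.null(end)) return(.region_index(universe, chrom, pos))
  i1 <- .region_index(universe, chrom, pos)
  i2 <- .region_index(universe, chrom, end - 1L)
  ifelse(!is.na(i1) & !is.na(i2) & i1 == i2, i1, NA_integer_)
}
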