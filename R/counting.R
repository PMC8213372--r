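# Fragment ingestion, Tn5 cut-site extraction and per-region counting.
#
# A fragment table is a data.frame (chrom, start, end) carrying the
# attribute "shift_applied": whether the +4/-5 Tn5 offset has been applied
# (directly or upstream). Cut sites are the two Tn5 insertion points of a
# fragment: its first base and its last base (end - 1).

#' Construct a fragment table
#'
#' @param chrom,start,end Fragment coordinates (0-based half-open).
#' @param shifted Has the Tn5 +4/-5 offset already been applied (or is the
#'   file declared pre-shifted)? Default `TRUE`, the common case for
#'   fragment files emitted by alignment pipelines.
#' @param max_fragment_length Fragments longer than this are rejected.
#' @return Fragment `data.frame` with attribute `shift_applied`.
#' @export
fragments <- function(chrom = character(), start = integer(), end = integer(),
                      shifted = TRUE, max_fragment_length = 1000L) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("fragment with start >= end")
  if (any(start < 0L)) stop("negative fragment coordinate")
  if (any(end - start > max_fragment_length))
    stop("fragment longer than max_fragment_length (", max_fragment_length, ")")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  attr(df, "shift_applied") <- shifted
  df
}

#' Read a BED3 fragment file
#'
#' @param path BED3 path (plain or gzipped); columns chrom, start, end.
#' @param apply_shift Apply the Tn5 +4/-5 shift on load (the file holds
#'   unshifted fragments)? Default `FALSE`.
#' @param assume_shifted When `apply_shift` is `FALSE`, treat the file as
#'   pre-shifted (default `TRUE`).
#' @param max_fragment_length Drop fragments longer than this (default
#'   1000 bp, the maximum included fragment length).
#' @return Fragment table; over-long fragments are dropped with a message.
#' @export
read_fragments <- function(path, apply_shift = FALSE, assume_shifted = TRUE,
                           max_fragment_length = 1000L) {
  if (!file.exists(path)) stop("no such fragment file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer"),
                   col.names = c("chrom", "start", "end"), comment.char = "#")
  too_long <- df$end - df$start > max_fragment_length
  if (any(too_long)) {
    message(sum(too_long), " fragment(s) exceed ", max_fragment_length,
            " bp and were dropped")
    df <- df[!too_long, , drop = FALSE]
  }
  fr <- fragments(df$chrom, df$start, df$end,
                  shifted = !apply_shift && assume_shifted,
                  max_fragment_length = max_fragment_length)
  if (apply_shift) fr <- tn5_shift(fr) else fr
}

#' Apply the Tn5 +4/-5 coordinate shift
#'
#' Moves each fragment start +4 bp and end -5 bp so coordinates mark the
#' transposase insertion centers. Fragments that collapse (shifted start >=
#' shifted end) are dropped and tallied.
#'
#' @param frags Fragment table with `shift_applied = FALSE`.
#' @return Shifted fragment table; attribute `n_shift_dropped` records the
#'   number of collapsed fragments removed.
#' @export
tn5_shift <- function(frags) {
  if (isTRUE(attr(frags, "shift_applied")))
    stop("tn5_shift: shift already applied to these fragments")
  start <- frags$start + 4L
  end <- frags$end - 5L
  keep <- start < end
  if (any(!keep))
    message(sum(!keep), " fragment(s) collapsed under the +4/-5 shift and were dropped")
  out <- data.frame(chrom = frags$chrom[keep], start = start[keep],
                    end = end[keep], stringsAsFactors = FALSE)
  attr(out, "shift_applied") <- TRUE
  attr(out, "n_shift_dropped") <- sum(!keep)
  out
}

#' Expand fragments to Tn5 cut sites
#'
#' Each fragment contributes two cut sites: its first covered base
#' (`start`) and its last covered base (`end - 1`). A 1-bp fragment yields
#' the same position twice; both are counted.
#'
#' @param frags Shifted (or declared pre-shifted) fragment table.
#' @return `data.frame` with columns `chrom`, `pos` and `2 * nrow(frags)`
#'   rows.
#' @export
fragment_to_cutsites <- function(frags) {
  if (!isTRUE(attr(frags, "shift_applied")))
    stop("fragments must be Tn5-shifted (or declared pre-shifted) before cut-site extraction")
  data.frame(chrom = rep(frags$chrom, 2L),
             pos = c(frags$start, frags$end - 1L),
             stringsAsFactors = FALSE)
}

#' Remove fragments overlapping blacklisted regions
#'
#' A fragment is removed iff it overlaps any blacklist interval by at
#' least 1 bp (half-open semantics: a fragment starting exactly at a
#' blacklist interval's end does not overlap it).
#'
#' @param frags Fragment table.
#' @param blacklist Interval table of blacklisted regions.
#' @return Filtered fragment table; attribute `n_blacklisted` records
#'   removals.
#' @export
filter_blacklist <- function(frags, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    attr(frags, "n_blacklisted") <- 0L
    return(frags)
  }
  bl <- merge_intervals(blacklist)
  drop <- rep(FALSE, nrow(frags))
  for (ch in unique(frags$chrom)) {
    fi <- which(frags$chrom == ch)
    bi <- which(bl$chrom == ch)
    if (length(bi) == 0) next
    ov <- IRanges::overlapsAny(
      .as_iranges(frags$start[fi], frags$end[fi]),
      .as_iranges(bl$start[bi], bl$end[bi]))
    drop[fi] <- ov
  }
  out <- frags[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shift_applied") <- attr(frags, "shift_applied")
  attr(out, "n_blacklisted") <- sum(drop)
  if (sum(drop) > 0)
    message(sum(drop), " fragment(s) removed by blacklist filter")
  out
}

#' Construct a sample table
#'
#' @param sample_id Unique sample identifiers.
#' @param condition Condition label per sample.
#' @param subject_id Optional biological-replicate (patient) identifier.
#' @return `data.frame` with those columns.
#' @export
sample_table <- function(sample_id, condition, subject_id = NA_character_) {
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  data.frame(sample_id = as.character(sample_id),
             condition = as.character(condition),
             subject_id = as.character(subject_id),
             stringsAsFactors = FALSE)
}

#' Count Tn5 cut sites per universe region
#'
#' Entry (r, s) is the number of cut sites from sample s whose position
#' falls inside universe region r (start inclusive, end exclusive); cut
#' sites outside all regions are ignored.
#'
#' @param fragment_sources Named list: `sample_id` -> fragment table, or
#'   `sample_id` -> fragment file path (read via [read_fragments()]).
#' @param universe A [peak_universe()].
#' @param samples A [sample_table()]; every row must have a source.
#' @param blacklist Optional blacklist interval table applied per sample.
#' @param ... Passed to [read_fragments()] when sources are paths.
#' @return Integer matrix with `rownames = region_ids`,
#'   `colnames = sample_id`.
#' @export
count_matrix <- function(fragment_sources, universe, samples,
                         blacklist = NULL, ...) {
  stopifnot(length(universe) > 0)
  missing <- setdiff(samples$sample_id, names(fragment_sources))
  if (length(missing))
    stop("no fragment source for sample(s): ", paste(missing, collapse = ", "))
  m <- matrix(0L, nrow = length(universe), ncol = nrow(samples),
              dimnames = list(universe$region_ids, samples$sample_id))
  for (s in samples$sample_id) {
    src <- fragment_sources[[s]]
    fr <- if (is.character(src)) read_fragments(src, ...) else src
    if (!is.null(blacklist)) fr <- filter_blacklist(fr, blacklist)
    cs <- fragment_to_cutsites(fr)
    idx <- .region_index(universe, cs$chrom, cs$pos)
    tab <- tabulate(idx[!is.na(idx)], nbins = length(universe))
    m[, s] <- as.integer(tab)
  }
  m
}

#' Fraction of cut sites in peak regions (FRiP)
#'
#' @param frags Fragment table (>= 1 fragment).
#' @param universe A [peak_universe()].
#' @return Fraction in `[0, 1]` of cut sites falling inside any universe
#'   region.
#' @export
frip <- function(frags, universe) {
  if (nrow(frags) == 0) stop("FRiP undefined for zero fragments")
  cs <- fragment_to_cutsites(frags)
  idx <- .region_index(universe, cs$chrom, cs$pos)
  mean(!is.na(idx))
}

#' TSS enrichment score
#'
#' Aggregates cut-site counts over a +/- `window` bp profile around all
#' TSSs (minus-strand profiles reversed), smooths the profile with a
#' centered moving average, and scores the maximum smoothed count over the
#' background, where background is the mean raw count across the outermost
#' `flank` positions on each side. A well-behaved library peaks sharply at
#' the TSS; uniform background scores ~1.
#'
#' @param frags Fragment table.
#' @param tss `data.frame` with columns `chrom`, `pos` (0-based TSS
#'   position) and `strand` (`"+"`/`"-"`).
#' @param window Half-width of the profile in bp (default 1000).
#' @param flank Number of outermost positions per side used as background
#'   (default 100).
#' @param smooth Moving-average width in bp, odd (default 51); `1`
#'   disables smoothing.
#' @return Scalar enrichment score; the aggregate profile is attached as
#'   attribute `profile`.
#' @export
tss_enrichment <- function(frags, tss, window = 1000L, flank = 100L,
                           smooth = 51L) {
  stopifnot(nrow(tss) >= 1, smooth >= 1, smooth %% 2 == 1)
  cs <- fragment_to_cutsites(frags)
  width <- 2L * window + 1L
  profile <- numeric(width)
  for (ch in unique(tss$chrom)) {
    ti <- which(tss$chrom == ch)
    ci <- which(cs$chrom == ch)
    if (length(ci) == 0) next
    hits <- IRanges::findOverlaps(
      .as_iranges(cs$pos[ci], cs$pos[ci] + 1L),
      .as_iranges(pmax(tss$pos[ti] - window, 0L), tss$pos[ti] + window + 1L))
    if (length(hits) == 0) next
    q <- ci[S4Vectors::queryHits(hits)]
    s <- ti[S4Vectors::subjectHits(hits)]
    off <- cs$pos[q] - tss$pos[s]
    off <- ifelse(tss$strand[s] == "-", -off, off)
    keep <- abs(off) <= window
    profile <- profile + tabulate(off[keep] + window + 1L, nbins = width)
  }
  if (sum(profile) == 0) stop("no TSS-proximal signal")
  bg <- mean(c(profile[seq_len(flank)], profile[width - seq_len(flank) + 1L]))
  if (bg == 0) stop("zero background in TSS flanks; cannot form enrichment ratio")
  sm <- if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    as.numeric(stats::filter(profile, k, sides = 2))
  } else profile
  score <- max(sm, na.rm = TRUE) / bg
  attr(score, "profile") <- profile
  score
}

#' Per-sample QC report
#'
#' @param fragment_sources Named list as in [count_matrix()].
#' @param universe A [peak_universe()].
#' @param samples A [sample_table()].
#' @param tss Optional TSS table for [tss_enrichment()].
#' @param blacklist Optional blacklist intervals.
#' @param ... Passed to [tss_enrichment()].
#' @return `data.frame` with `sample_id`, `n_fragments`, `frip`,
#'   `tss_enrichment` (NA when no TSS table given).
#' @export
qc_report <- function(fragment_sources, universe, samples, tss = NULL,
                      blacklist = NULL, ...) {
  rows <- lapply(samples$sample_id, function(s) {
    src <- fragment_sources[[s]]
    fr <- if (is.character(src)) read_fragments(src) else src
    if (!is.null(blacklist)) fr <- filter_blacklist(fr, blacklist)
    data.frame(sample_id = s, n_fragments = nrow(fr),
               frip = frip(fr, universe),
               tss_enrichment = if (is.null(tss)) NA_real_
                                else as.numeric(tss_enrichment(fr, tss, ...)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
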