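# Synthetic ATAC-seq study generator with planted ground truth.
#
# Emulates the study design the pipeline targets: 4 conditions (naive
# cells, antigen-specific cells at baseline, after one year of therapy,
# and one year untreated), ~4 replicates each, negative-binomial cut-site
# counts over a non-overlapping region universe, four planted
# accessibility-module archetypes, planted exhaustion-category
# enrichment, and designated super-enhancer genes carrying an excess of
# differential regions in their regulatory domains.

#' Default condition labels of the generator
#' @export
SYNTH_CONDITIONS <- c("naive", "baseline", "art_1yr", "untreated_1yr")

# module -> per-condition multiplier of the planted log2 effect
.MODULE_TEMPLATES <- rbind(
  A = c(1, 0, 0, 0),    # most accessible in naive cells
  B = c(0, 1, 0, 1),    # accessible at baseline and untreated
  C = c(0, 0, 1, 0),    # accessible after therapy
  D = c(0, 1, 0.75, 1)) # baseline + untreated, partially retained on therapy
colnames(.MODULE_TEMPLATES) <- SYNTH_CONDITIONS

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate a toy genome and gene annotation
#'
#' Genes are placed uniformly per chromosome subject to a minimum TSS
#' spacing (so regulatory domains have non-trivial neighbor structure);
#' strands are random.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 5e6).
#' @param n_genes Total genes (default 200).
#' @param min_spacing Minimum distance between adjacent TSSs (default
#'   20000 bp).
#' @param seed RNG seed.
#' @return List: `genome` (`chrom`, `length`) and `genes`
#'   (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
make_genome_and_genes <- function(n_chrom = 2, chrom_length = 5e6,
                                  n_genes = 200, min_spacing = 20000,
                                  seed = 1) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 0, min_spacing > 0)
  genome <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = as.integer(chrom_length),
                       stringsAsFactors = FALSE)
  .with_seed(seed, {
    per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    genes <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      n <- per[i]
      if (n == 0) return(NULL)
      avail <- chrom_length - n * min_spacing
      if (avail <= 0)
        stop("genes do not fit on chromosome at min_spacing = ", min_spacing)
      u <- sort(runif(n, 0, avail))
      tss <- as.integer(floor(u) + (seq_len(n) - 1L) * min_spacing +
                          min_spacing %/% 2L)
      data.frame(gene_id = sprintf("gene_%s_%03d", genome$chrom[i], seq_len(n)),
                 chrom = genome$chrom[i], tss = tss,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(genes))
      genes <- data.frame(gene_id = character(), chrom = character(),
                          tss = integer(), strand = character(),
                          stringsAsFactors = FALSE)
    list(genome = genome, genes = genes)
  })
}

# non-overlapping region placement on a grid of pitch (width + gap);
# returns the grid cell indices used so more regions can be added later
.grid_regions <- function(genome, cells, region_width) {
  data.frame(chrom = cells$chrom,
             start = as.integer(cells$cell_start),
             end = as.integer(cells$cell_start + region_width),
             name = NA_character_, strand = ".",
             stringsAsFactors = FALSE)
}

#' Generate a region universe with planted accessibility modules
#'
#' Regions are non-overlapping intervals on a fixed-pitch grid. Each
#' region carries a true module label: one of the four archetypes (`A`
#' naive-high, `B` baseline/untreated-high, `C` therapy-high, `D`
#' baseline/untreated plus partial therapy signal) or `"none"`
#' (non-differential background).
#'
#' @param genome From [make_genome_and_genes()].
#' @param n_regions Number of regions (default 2000).
#' @param module_proportions Named proportions for modules A-D; the
#'   remainder is background (default `c(A=.1, B=.2, C=.1, D=.1)`).
#' @param region_width Region width in bp (default 500).
#' @param min_gap Minimum gap between adjacent regions (default 300 bp).
#' @param exclude Optional interval table; no region is placed overlapping
#'   these (used to keep background regions out of gene basal domains so
#'   super-enhancer planting has deterministic room).
#' @param seed RNG seed.
#' @return List: `universe` (a [peak_universe()]), `module` (named vector
#'   region_id -> label), `grid` (placement bookkeeping for later region
#'   insertion).
#' @export
make_universe_and_modules <- function(genome, n_regions = 2000,
                                      module_proportions =
                                        c(A = 0.1, B = 0.2, C = 0.1, D = 0.1),
                                      region_width = 500, min_gap = 300,
                                      exclude = NULL, seed = 1) {
  stopifnot(sum(module_proportions) <= 1, all(module_proportions >= 0))
  pitch <- region_width + min_gap
  .with_seed(seed, {
    per <- diff(round(seq(0, n_regions, length.out = nrow(genome) + 1)))
    cells <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      n_cells <- (genome$length[i] - min_gap) %/% pitch
      cand <- seq_len(n_cells)
      if (!is.null(exclude)) {
        exc <- exclude[exclude$chrom == genome$chrom[i], , drop = FALSE]
        if (nrow(exc) > 0) {
          cell_start <- min_gap + (cand - 1L) * pitch
          bad <- IRanges::overlapsAny(
            .as_iranges(cell_start, cell_start + region_width),
            .as_iranges(as.integer(exc$start), as.integer(exc$end)))
          cand <- cand[!bad]
        }
      }
      if (per[i] > length(cand)) stop("regions do not fit on ", genome$chrom[i])
      picked <- sort(sample(cand, per[i]))
      data.frame(chrom = genome$chrom[i],
                 cell = picked,
                 cell_start = min_gap + (picked - 1L) * pitch,
                 stringsAsFactors = FALSE)
    }))
    regions <- .grid_regions(genome, cells, region_width)
    universe <- peak_universe(regions)
    labels <- sample(c(names(module_proportions), "none"),
                     length(universe), replace = TRUE,
                     prob = c(module_proportions, 1 - sum(module_proportions)))
    list(universe = universe,
         module = stats::setNames(labels, universe$region_ids),
         grid = list(pitch = pitch, region_width = region_width,
                     min_gap = min_gap,
                     used = paste(cells$chrom, cells$cell)))
  })
}

#' Simulate the cut-site count matrix
#'
#' Counts are negative binomial with `variance = mu + alpha * mu^2`;
#' region baseline accessibility is log-normal, condition means follow
#' the module templates (`mu = depth * baseline * 2^(template * lfc)`),
#' and per-sample log-normal size multipliers exercise normalization.
#' `alpha = 0` gives Poisson counts.
#'
#' @param truth List with `universe` and `module` (from
#'   [make_universe_and_modules()] or [simulate_dataset()]).
#' @param n_per_condition Replicates per condition (default 4).
#' @param depth Mean background count per region (default 50).
#' @param alpha NB dispersion (default 0.2).
#' @param lfc Planted log2 effect size (default 2).
#' @param size_sdlog Log-sd of sample size multipliers (default 0.25).
#' @param conditions Condition labels (default [SYNTH_CONDITIONS]).
#' @param seed RNG seed.
#' @return List: `counts` (matrix), `samples` (a [sample_table()]),
#'   `true_size` (planted sample multipliers), `baseline` (per-region
#'   baseline means).
#' @export
simulate_counts <- function(truth, n_per_condition = 4, depth = 50,
                            alpha = 0.2, lfc = 2, size_sdlog = 0.25,
                            conditions = SYNTH_CONDITIONS, seed = 1) {
  stopifnot(depth > 0, alpha >= 0)
  labels <- truth$module
  n_regions <- length(labels)
  tmpl <- matrix(0, n_regions, length(conditions),
                 dimnames = list(names(labels), conditions))
  known <- labels %in% rownames(.MODULE_TEMPLATES)
  tmpl[known, ] <- .MODULE_TEMPLATES[labels[known], conditions, drop = FALSE]
  .with_seed(seed, {
    baseline <- exp(rnorm(n_regions, 0, 0.5))
    cond <- rep(conditions, each = n_per_condition)
    sample_id <- paste0(cond, "_s", rep(seq_len(n_per_condition),
                                        times = length(conditions)))
    subject <- paste0("subj_", rep(seq_len(n_per_condition),
                                   times = length(conditions)))
    sizes <- exp(rnorm(length(sample_id), 0, size_sdlog))
    mu <- (depth * baseline) * 2^(tmpl[, cond, drop = FALSE] * lfc)
    mu <- sweep(mu, 2, sizes, "*")
    counts <- if (alpha == 0) {
      matrix(rpois(length(mu), lambda = mu), nrow = n_regions)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha), nrow = n_regions)
    }
    dimnames(counts) <- list(names(labels), sample_id)
    list(counts = counts,
         samples = sample_table(sample_id, cond, subject),
         true_size = stats::setNames(sizes, sample_id),
         baseline = baseline)
  })
}

#' Simulate a fragment file
#'
#' A fraction `frip_target` of fragments is placed fully inside universe
#' regions (uniformly across regions, so both cut sites fall in peaks);
#' the remainder is placed fully outside all regions. Fragment lengths
#' are drawn from a three-component mixture (sub-nucleosomal,
#' mono-nucleosomal, di-nucleosomal) capped at `max_fragment_length`.
#'
#' @param truth List with `universe` and (for the background space) a
#'   `genome` table; [simulate_dataset()] output qualifies.
#' @param frip_target Fraction of cut sites inside regions (0 < f < 1,
#'   or exactly 1).
#' @param n_fragments Number of fragments (default 1e5).
#' @param max_fragment_length Length cap (default 1000).
#' @param seed RNG seed.
#' @return Fragment table (`shift_applied = TRUE`).
#' @export
simulate_fragments <- function(truth, frip_target = 0.6, n_fragments = 1e5,
                               max_fragment_length = 1000, seed = 1) {
  stopifnot(frip_target > 0, frip_target <= 1)
  universe <- truth$universe
  genome <- truth$genome
  regs <- universe$regions
  .with_seed(seed, {
    lens <- round(c(rnorm(n_fragments, 80, 20), rnorm(n_fragments, 200, 40),
                    rnorm(n_fragments, 400, 60)))
    lens <- sample(lens, n_fragments)
    lens <- pmax(pmin(lens, max_fragment_length), 20L)
    in_peak <- runif(n_fragments) < frip_target
    chrom <- character(n_fragments); start <- integer(n_fragments)
    n_in <- sum(in_peak)
    if (n_in > 0) {
      ri <- sample.int(nrow(regs), n_in, replace = TRUE)
      w <- regs$end[ri] - regs$start[ri]
      lens[in_peak] <- pmin(lens[in_peak], w)  # keep both cut sites inside
      chrom[in_peak] <- regs$chrom[ri]
      start[in_peak] <- regs$start[ri] +
        floor(runif(n_in) * (w - lens[in_peak] + 1))
    }
    n_out <- n_fragments - n_in
    if (n_out > 0) {
      # rejection-sample background placements until outside all regions
      need <- which(!in_peak)
      while (length(need) > 0) {
        gi <- sample.int(nrow(genome), length(need), replace = TRUE)
        st <- floor(runif(length(need)) * (genome$length[gi] - lens[need]))
        ch <- genome$chrom[gi]
        i1 <- .region_index(universe, ch, as.integer(st))
        i2 <- .region_index(universe, ch, as.integer(st + lens[need] - 1L))
        ok <- is.na(i1) & is.na(i2)
        chrom[need[ok]] <- ch[ok]
        start[need[ok]] <- as.integer(st[ok])
        need <- need[!ok]
      }
    }
    fragments(chrom, start, start + lens, shifted = TRUE,
              max_fragment_length = max_fragment_length)
  })
}

#' Plant exhaustion categories and super-enhancer genes
#'
#' Category labels are assigned so that the target module's
#' `late_exhaustion` rate is `enrichment_factor` times the universe-wide
#' rate (the quantity the hypergeometric fold enrichment estimates); the
#' other four categories are uniform at `base_rate`. Designated SE genes
#' receive `se_regions_per_gene` additional differential regions of
#' module `se_module`, tiled inside the gene's basal regulatory domain
#' (where region-to-gene assignment is unambiguous), roughly 10x the
#' background per-gene count of same-direction differential regions.
#'
#' @param truth List from [make_universe_and_modules()] plus `genome` and
#'   `genes` (see [simulate_dataset()]).
#' @param enrichment_factor Planted fold enrichment (>= 1, default 3).
#' @param target_module Module receiving the category enrichment
#'   (default "B").
#' @param base_rate Universe-wide rate of each category (default 0.08).
#' @param se_gene_count Number of SE genes (default 5).
#' @param se_module Module label given to planted SE regions (default
#'   "C", the therapy-high archetype, whose direction-specific background
#'   is sparsest).
#' @param se_regions_per_gene Extra regions per SE gene (default 10, ~10x the per-gene background of one promoter region).
#' @param se_region_width,se_region_gap Geometry of the planted regions
#'   (default 150/50 bp; finer than the background grid so they fit in
#'   the basal domain).
#' @param basal_up,basal_down Basal-domain extents used for placement;
#'   must match the analysis configuration (defaults 5000/1000).
#' @param seed RNG seed.
#' @return Updated `truth` with `universe`, `module`, `category` (named
#'   vector) and `se_genes`.
#' @export
plant_categories_and_se <- function(truth, enrichment_factor = 3,
                                    target_module = "B", base_rate = 0.08,
                                    se_gene_count = 5, se_module = "C",
                                    se_regions_per_gene = 10,
                                    se_region_width = 120,
                                    se_region_gap = 40,
                                    basal_up = 5000, basal_down = 1000,
                                    seed = 1) {
  stopifnot(enrichment_factor >= 1)
  .with_seed(seed, {
    # --- plant SE regions first (they join the universe and module map)
    if (se_gene_count > 0) {
      genes <- truth$genes
      if (se_gene_count > nrow(genes)) stop("fewer genes than se_gene_count")
      se_genes <- sort(sample(genes$gene_id, se_gene_count))
      dom <- build_domains(genes, basal_up = basal_up,
                           basal_down = basal_down)
      regs <- truth$universe$regions
      pitch <- se_region_width + se_region_gap
      new_rows <- list()
      for (g in se_genes) {
        gi <- which(dom$gene_id == g)
        # stay strictly inside the basal domain so neighbor extensions
        # cannot claim the planted regions
        lo <- dom$basal_start[gi] + se_region_gap
        hi <- dom$basal_end[gi] - se_region_gap
        win <- .as_iranges(as.integer(lo), as.integer(hi))
        here <- regs[regs$chrom == dom$chrom[gi], , drop = FALSE]
        free <- IRanges::setdiff(win, .as_iranges(here$start - se_region_gap,
                                                  here$end + se_region_gap))
        starts <- unlist(lapply(seq_along(free), function(j) {
          s <- IRanges::start(free)[j] - 1L
          w <- IRanges::width(free)[j]
          n_fit <- (w - se_region_gap) %/% pitch
          if (n_fit <= 0) integer(0) else s + (seq_len(n_fit) - 1L) * pitch
        }))
        if (length(starts) < se_regions_per_gene)
          stop("basal domain of gene ", g, " has room for only ",
               length(starts), " planted regions (requested ",
               se_regions_per_gene, ")")
        picked <- sort(starts[order(abs(starts - dom$tss[gi]))][
          seq_len(se_regions_per_gene)])
        new_rows[[g]] <- data.frame(
          chrom = dom$chrom[gi], start = as.integer(picked),
          end = as.integer(picked + se_region_width),
          name = NA_character_, strand = ".", stringsAsFactors = FALSE)
      }
      new_regions <- do.call(rbind, new_rows)
      all_regions <- rbind(truth$universe$regions[, names(new_regions)],
                           new_regions)
      new_universe <- peak_universe(all_regions)
      new_ids <- sprintf("%s:%d-%d", new_regions$chrom, new_regions$start,
                         new_regions$end)
      module <- stats::setNames(rep(NA_character_, length(new_universe)),
                                new_universe$region_ids)
      module[names(truth$module)] <- truth$module
      module[new_ids] <- se_module
      truth$universe <- new_universe
      truth$module <- module[new_universe$region_ids]
      truth$se_genes <- se_genes
    } else truth$se_genes <- character(0)

    # --- plant categories with exact universe-relative enrichment
    labels <- truth$module
    N <- length(labels)
    n_mod <- sum(labels == target_module)
    p_target <- enrichment_factor * base_rate
    p_other <- base_rate * (N - enrichment_factor * n_mod) / (N - n_mod)
    if (p_other < 0 || p_target + 4 * base_rate > 1)
      stop("requested enrichment infeasible; factor must be <= ",
           round(min(N / n_mod, (1 - 4 * base_rate) / base_rate), 2))
    cats <- character(N)
    in_mod <- labels == target_module
    draw <- function(n, p_late) {
      probs <- c(rep(base_rate, 4), p_late)
      sample(c(EXHAUSTION_CATEGORIES[EXHAUSTION_CATEGORIES != "late_exhaustion"],
               "late_exhaustion", "none"),
             n, replace = TRUE, prob = c(probs, 1 - sum(probs)))
    }
    cats[in_mod] <- draw(sum(in_mod), p_target)
    cats[!in_mod] <- draw(sum(!in_mod), p_other)
    truth$category <- stats::setNames(cats, names(labels))
    truth
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the whole generator with one master seed and writes every input
#' the pipeline consumes: `genome.tsv`, `genes.tsv`, `tss.tsv`,
#' `universe_truth.bed`, per-condition `peaks_<condition>.narrowPeak`
#' (jittered resamples of the truth regions, so universe reconstruction
#' is exercised), per-sample `fragments_<sample>.bed`, `samples.tsv`,
#' `counts.tsv`, `annotation.tsv` and `truth.json`. Identical seeds
#' reproduce identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_regions,module_proportions,n_per_condition,depth,alpha,lfc
#'   Generator parameters (see the stage functions).
#' @param enrichment_factor,se_gene_count,se_regions_per_gene Planting
#'   parameters.
#' @param n_genes,n_fragments,frip_target Further stage parameters.
#' @param write_fragments Write per-sample fragment files (default TRUE;
#'   counts are always written, so differential stages can run without
#'   fragment-level input).
#' @return Invisibly, the `truth` list (also serialized as JSON).
#' @export
simulate_dataset <- function(out_dir, seed = 1, n_regions = 2000,
                             module_proportions =
                               c(A = 0.1, B = 0.2, C = 0.1, D = 0.1),
                             n_per_condition = 4, depth = 50, alpha = 0.2,
                             lfc = 2, enrichment_factor = 3,
                             se_gene_count = 5, se_regions_per_gene = 10,
                             n_genes = 200, n_fragments = 2e4,
                             frip_target = 0.6, write_fragments = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed + seq_len(7) * 1000L
  # genes live on chr1; bulk (distal) regions on the gene-free chr2, so a
  # gene's associated-region count is driven only by its own TSS-proximal
  # regions and any planted super-enhancer excess
  gg <- make_genome_and_genes(n_chrom = 1, n_genes = n_genes,
                              seed = seeds[1])
  gg$genome <- rbind(gg$genome,
                     data.frame(chrom = "chr2", length = gg$genome$length[1]))
  # one promoter region per gene, centered on the TSS inside the basal
  # domain (where region-to-gene assignment is unambiguous)
  um <- make_universe_and_modules(gg$genome[2, , drop = FALSE],
                                  n_regions = n_regions - n_genes,
                                  module_proportions = module_proportions,
                                  seed = seeds[2])
  prom <- .with_seed(seeds[7], {
    jitter <- sample(-100:100, n_genes, replace = TRUE)
    data.frame(chrom = gg$genes$chrom,
               start = pmax(gg$genes$tss - 250L + jitter, 0L),
               end = pmax(gg$genes$tss - 250L + jitter, 0L) + 500L,
               name = NA_character_, strand = ".", stringsAsFactors = FALSE)
  })
  prom_labels <- .with_seed(seeds[7] + 1L, {
    sample(c(names(module_proportions), "none"), n_genes, replace = TRUE,
           prob = c(module_proportions, 1 - sum(module_proportions)))
  })
  universe <- peak_universe(rbind(um$universe$regions[, names(prom)], prom))
  prom_ids <- sprintf("%s:%d-%d", prom$chrom, prom$start, prom$end)
  module <- stats::setNames(rep("none", length(universe)),
                            universe$region_ids)
  module[names(um$module)] <- um$module
  module[prom_ids] <- prom_labels
  truth <- c(gg, list(universe = universe,
                      module = module[universe$region_ids]))
  truth <- plant_categories_and_se(truth,
                                   enrichment_factor = enrichment_factor,
                                   se_gene_count = se_gene_count,
                                   se_regions_per_gene = se_regions_per_gene,
                                   seed = seeds[3])
  sim <- simulate_counts(truth, n_per_condition = n_per_condition,
                         depth = depth, alpha = alpha, lfc = lfc,
                         seed = seeds[4])
  truth$params <- list(seed = seed, n_regions = n_regions,
                       module_proportions = as.list(module_proportions),
                       n_per_condition = n_per_condition, depth = depth,
                       alpha = alpha, lfc = lfc,
                       enrichment_factor = enrichment_factor,
                       se_gene_count = se_gene_count,
                       se_regions_per_gene = se_regions_per_gene,
                       n_genes = n_genes, n_fragments = n_fragments,
                       frip_target = frip_target)

  write.table(truth$genome, file.path(out_dir, "genome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$genes, file.path(out_dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tss <- data.frame(chrom = truth$genes$chrom, pos = truth$genes$tss,
                    strand = truth$genes$strand)
  write.table(tss, file.path(out_dir, "tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(truth$universe, file.path(out_dir, "universe_truth.bed"))

  # per-condition peak calls: jittered resamples of the truth regions
  regs <- truth$universe$regions
  .with_seed(seeds[5], {
    for (cc in SYNTH_CONDITIONS) {
      keep <- runif(nrow(regs)) < 0.85
      jit_s <- pmax(regs$start[keep] + sample(-50:50, sum(keep), TRUE), 0)
      jit_e <- regs$end[keep] + sample(-50:50, sum(keep), TRUE)
      ok <- jit_s < jit_e
      pk <- data.frame(chrom = regs$chrom[keep][ok], start = jit_s[ok],
                       end = jit_e[ok],
                       name = sprintf("%s_peak_%d", cc, seq_len(sum(ok))),
                       score = 0L, strand = ".", signalValue = 1,
                       pValue = -1, qValue = -1, peak = -1L)
      write.table(pk, file.path(out_dir, sprintf("peaks_%s.narrowPeak", cc)),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  })

  write.table(sim$samples, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts_out <- data.frame(region_id = rownames(sim$counts), sim$counts,
                           check.names = FALSE)
  write.table(counts_out, file.path(out_dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann <- data.frame(region_id = names(truth$category),
                    category = truth$category)
  write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  if (write_fragments) {
    for (i in seq_len(nrow(sim$samples))) {
      fr <- simulate_fragments(truth, frip_target = frip_target,
                               n_fragments = n_fragments,
                               seed = seeds[6] + i)
      write.table(fr, file.path(out_dir,
                                sprintf("fragments_%s.bed",
                                        sim$samples$sample_id[i])),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }

  truth$counts <- sim$counts
  truth$samples <- sim$samples
  truth$true_size <- sim$true_size
  truth$baseline <- sim$baseline
  json_truth <- list(params = truth$params,
                     region_ids = truth$universe$region_ids,
                     module = as.list(truth$module),
                     category = as.list(truth$category),
                     se_genes = truth$se_genes)
  jsonlite::write_json(json_truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
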