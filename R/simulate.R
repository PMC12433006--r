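#' Configuration for the synthetic MSP dataset generator
#'
#' Defaults emulate a realistic small discovery design: three tumor and
#' three control samples, CpG islands of mean length 777 nt (minimum 200)
#' and ~67% GC embedded in AT-rich background, half the islands planted as
#' differentially methylated (DM), tumor methylation probability 0.9 diluted
#' by a per-sample tumor purity drawn from 0.70-0.80, control probability
#' 0.02, and overdispersed (negative-binomial) coverage with mean 15.
#'
#' @param n_islands Number of CpG islands.
#' @param island_len_mean,island_len_min Island length distribution:
#'   `island_len_min + Exponential(mean = island_len_mean - island_len_min)`.
#' @param island_gc Island GC target in percent.
#' @param cpg_spacing Nucleotides between planted CpG starts inside islands.
#' @param dm_fraction Fraction of islands planted as DM.
#' @param p_meth_tumor,p_meth_control Per-read methylation probability of a
#'   DM-island CpG in pure tumor tissue, and of any CpG in control tissue.
#' @param purity_min,purity_max Per-tumor-sample purity range (uniform).
#' @param depth_mean,depth_dispersion Negative-binomial coverage: mean and
#'   size (smaller size = more overdispersion).
#' @param n_tumor,n_control Samples per group.
#' @param split_strands Emit strand-specific records (`+` row at the C,
#'   `-` row at the G) as real pileups do; [aggregate_cpg_strands()] merges
#'   them downstream.
#' @param gap_min,gap_max Uniform background gap between islands, nt.
#' @param qpcr_base_delta,qpcr_slope,qpcr_sigma,ct_ref_mean,ct_ref_sd,censor_ct
#'   CT model: `ct_ref ~ N(ct_ref_mean, ct_ref_sd)`;
#'   `ct_target = ct_ref + base_delta - slope * methylation_fraction +
#'   N(0, sigma)`, censored above `censor_ct` cycles.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_islands = 50L, island_len_mean = 777,
                              island_len_min = 200, island_gc = 67,
                              cpg_spacing = 8L, dm_fraction = 0.5,
                              p_meth_tumor = 0.9, p_meth_control = 0.02,
                              purity_min = 0.70, purity_max = 0.80,
                              depth_mean = 15, depth_dispersion = 10,
                              n_tumor = 3L, n_control = 3L,
                              split_strands = TRUE,
                              gap_min = 600, gap_max = 2500,
                              qpcr_base_delta = 20, qpcr_slope = 18,
                              qpcr_sigma = 1, ct_ref_mean = 20,
                              ct_ref_sd = 0.5, censor_ct = 43) {
  cfg <- as.list(environment())
  for (p in c("dm_fraction", "p_meth_tumor", "p_meth_control",
              "purity_min", "purity_max"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) .stopf("%s must be in [0, 1]", p)
  if (cfg$purity_min > cfg$purity_max) .stopf("purity_min > purity_max")
  if (cfg$island_len_min >= cfg$island_len_mean)
    .stopf("island_len_min must be below island_len_mean")
  if (cfg$n_tumor < 1L || cfg$n_control < 1L)
    .stopf("need >= 1 tumor and >= 1 control sample")
  structure(cfg, class = "simulation_config")
}

#' Simulate a reference chromosome with CpG islands
#'
#' Builds one chromosome of AT-rich background with GC-rich islands whose
#' CpGs are planted at `cpg_spacing` nt; a configured fraction of islands is
#' flagged DM (their CpGs will be hypermethylated in tumor samples by
#' [simulate_bedmethyl()]). Deterministic given `seed`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `chrom`, `sequence` (character), `chrom_sizes` (named
#'   vector), `islands` (interval `data.frame` with `dm` logical column).
#' @export
simulate_reference <- function(cfg = simulation_config(), seed = 1L) {
  .with_seed(seed, {
    n <- cfg$n_islands
    island_len <- round(cfg$island_len_min +
                          rexp(n, 1 / (cfg$island_len_mean - cfg$island_len_min)))
    gaps <- round(runif(n + 1L, cfg$gap_min, cfg$gap_max))
    dm <- logical(n)
    dm[sample.int(n, round(cfg$dm_fraction * n))] <- TRUE
    # filler base frequencies hitting the island GC target given the
    # planted CG dinucleotide every cpg_spacing nt
    gc_fill <- max(0, min(1, (cfg$island_gc / 100 * cfg$cpg_spacing - 2) /
                            (cfg$cpg_spacing - 2)))
    bg_chunk <- function(len) sample(c("A", "T", "G", "C"), len, replace = TRUE,
                                     prob = c(0.4, 0.4, 0.1, 0.1))
    island_chunk <- function(len) {
      chars <- sample(c("G", "C", "A", "T"), len, replace = TRUE,
                      prob = c(gc_fill / 2, gc_fill / 2,
                               (1 - gc_fill) / 2, (1 - gc_fill) / 2))
      at <- seq(1L, len - 1L, by = cfg$cpg_spacing)
      chars[at] <- "C"; chars[at + 1L] <- "G"
      chars
    }
    pieces <- character(2L * n + 1L)
    starts <- numeric(n); ends <- numeric(n)
    cursor <- 0
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- paste(bg_chunk(gaps[i]), collapse = "")
      cursor <- cursor + gaps[i]
      starts[i] <- cursor
      pieces[2L * i] <- paste(island_chunk(island_len[i]), collapse = "")
      cursor <- cursor + island_len[i]
      ends[i] <- cursor
    }
    pieces[2L * n + 1L] <- paste(bg_chunk(gaps[n + 1L]), collapse = "")
    sequence <- paste(pieces, collapse = "")
    islands <- data.frame(chrom = "chrSim", start = starts, end = ends,
                          name = sprintf("island_%03d", seq_len(n)),
                          strand = ".", dm = dm, stringsAsFactors = FALSE)
    list(chrom = "chrSim", sequence = sequence,
         chrom_sizes = c(chrSim = nchar(sequence)), islands = islands)
  })
}

#' Simulate per-sample bedmethyl records from a reference truth
#'
#' Every `CG` dinucleotide in the reference sequence becomes a measured
#' site. Coverage is negative-binomial; the methylated-call count is
#' binomial with probability `purity * p_meth_tumor +
#' (1 - purity) * p_meth_control` for tumor samples at DM-island CpGs and
#' `p_meth_control` everywhere else (the linear two-population purity
#' model). With `split_strands`, coverage is thinned binomially onto the
#' two strands and emitted as a `+` record at the C and a `-` record at the
#' following G.
#'
#' @param reference Result of [simulate_reference()].
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `records` (combined measurement `data.frame` with
#'   `sample_id`), `manifest` (`sample_id`, `group`, `purity`, `path` `NA`
#'   until written), `cpg_positions` (0-based site positions).
#' @export
simulate_bedmethyl <- function(reference, cfg = simulation_config(), seed = 1L) {
  .with_seed(seed, {
    pos <- as.integer(gregexpr("CG", reference$sequence, fixed = TRUE)[[1]])
    pos <- pos[pos > 0] - 1L   # 0-based position of the C
    isl <- reference$islands
    dm_site <- vapply(pos, function(p)
      any(isl$dm & isl$start <= p & p < isl$end), logical(1))
    ids <- c(sprintf("tumor_%02d", seq_len(cfg$n_tumor)),
             sprintf("control_%02d", seq_len(cfg$n_control)))
    groups <- rep(c("tumor", "control"), c(cfg$n_tumor, cfg$n_control))
    purity <- ifelse(groups == "tumor",
                     runif(length(ids), cfg$purity_min, cfg$purity_max), NA)
    per_sample <- lapply(seq_along(ids), function(s) {
      p <- rep(cfg$p_meth_control, length(pos))
      if (groups[s] == "tumor")
        p[dm_site] <- purity[s] * cfg$p_meth_tumor +
          (1 - purity[s]) * cfg$p_meth_control
      depth <- rnbinom(length(pos), size = cfg$depth_dispersion,
                       mu = cfg$depth_mean)
      if (cfg$split_strands) {
        d_plus <- rbinom(length(pos), depth, 0.5)
        d_minus <- depth - d_plus
        m_plus <- rbinom(length(pos), d_plus, p)
        m_minus <- rbinom(length(pos), d_minus, p)
        rec <- rbind(
          data.frame(chrom = reference$chrom, pos = pos, strand = "+",
                     depth = d_plus,
                     meth_pct = ifelse(d_plus > 0, 100 * m_plus / d_plus, 0),
                     stringsAsFactors = FALSE),
          data.frame(chrom = reference$chrom, pos = pos + 1L, strand = "-",
                     depth = d_minus,
                     meth_pct = ifelse(d_minus > 0, 100 * m_minus / d_minus, 0),
                     stringsAsFactors = FALSE))
      } else {
        m <- rbinom(length(pos), depth, p)
        rec <- data.frame(chrom = reference$chrom, pos = pos, strand = "+",
                          depth = depth,
                          meth_pct = ifelse(depth > 0, 100 * m / depth, 0),
                          stringsAsFactors = FALSE)
      }
      rec <- rec[rec$depth > 0, , drop = FALSE]
      rec$sample_id <- ids[s]
      rec[order(rec$chrom, rec$pos), , drop = FALSE]
    })
    records <- do.call(rbind, per_sample)
    rownames(records) <- NULL
    manifest <- data.frame(sample_id = ids, group = groups, purity = purity,
                           path = NA_character_, stringsAsFactors = FALSE)
    list(records = records, manifest = manifest, cpg_positions = pos)
  })
}

# modbam2bed-dialect serialization of measurement records
write_bedmethyl <- function(records, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- sprintf("%s\t%s\t%s\t5mC\t%d\t%s\t%s\t%s\t0,0,0\t%s\t%.2f",
                   records$chrom, fmt(records$pos), fmt(records$pos + 1),
                   pmin(1000L, as.integer(records$depth)), records$strand,
                   fmt(records$pos), fmt(records$pos + 1),
                   fmt(records$depth), records$meth_pct)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a qPCR CT table with methylation-dependent signal
#'
#' One measurement per sample and marker. The reference assay cycles
#' threshold is normal; the target assay amplifies earlier the more
#' methylated template is present:
#' `ct_target = ct_ref + base_delta - slope * methylation_fraction + noise`,
#' censored (no amplification, `NA`) above `censor_ct` cycles.
#'
#' @param markers `data.frame` with columns `marker` and `dm` (logical):
#'   the regions assayed and whether they are truly DM.
#' @param manifest Sample manifest with `sample_id`, `group` and (for tumor
#'   samples) `purity`; e.g. from [simulate_bedmethyl()].
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return CT `data.frame`: `sample_id`, `marker`, `ct_target` (`NA` when
#'   censored), `ct_ref`, plus the latent `methylation_fraction`.
#' @export
simulate_qpcr <- function(markers, manifest, cfg = simulation_config(),
                          seed = 1L) {
  .with_seed(seed, {
    grid <- expand.grid(sample_id = manifest$sample_id,
                        marker = markers$marker,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grp <- manifest$group[match(grid$sample_id, manifest$sample_id)]
    pur <- manifest$purity[match(grid$sample_id, manifest$sample_id)]
    dm <- markers$dm[match(grid$marker, markers$marker)]
    mf <- ifelse(grp == "tumor" & dm,
                 pur * cfg$p_meth_tumor + (1 - pur) * cfg$p_meth_control,
                 cfg$p_meth_control)
    ct_ref <- rnorm(nrow(grid), cfg$ct_ref_mean, cfg$ct_ref_sd)
    ct_target <- ct_ref + cfg$qpcr_base_delta - cfg$qpcr_slope * mf +
      rnorm(nrow(grid), 0, cfg$qpcr_sigma)
    censored <- ct_target > cfg$censor_ct
    data.frame(sample_id = grid$sample_id, marker = grid$marker,
               ct_target = ifelse(censored, NA_real_, ct_target),
               ct_ref = ct_ref, methylation_fraction = mf,
               stringsAsFactors = FALSE)
  })
}

#' Simulate and write a complete MSP discovery dataset
#'
#' Orchestrates [simulate_reference()], [simulate_bedmethyl()] and
#' [simulate_qpcr()] (markers = all islands) and writes every pipeline
#' input: `reference.fa`, `chrom.sizes`, `islands.bed`, `truth_dm.bed`
#' (the DM islands only), one `<sample>.bedmethyl` per sample,
#' `manifest.tsv` and `qpcr_ct.tsv`. Byte-identical across runs with the
#' same seed and configuration.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; stage seeds are derived from it.
#' @return Invisibly, a list with the in-memory objects and file `paths`.
#' @export
simulate_msp_dataset <- function(dir, cfg = simulation_config(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg, .derive_seed(seed, 1L))
  bm <- simulate_bedmethyl(ref, cfg, .derive_seed(seed, 2L))
  markers <- data.frame(marker = ref$islands$name, dm = ref$islands$dm,
                        stringsAsFactors = FALSE)
  ct <- simulate_qpcr(markers, bm$manifest, cfg, .derive_seed(seed, 3L))
  paths <- list(reference = file.path(dir, "reference.fa"),
                chrom_sizes = file.path(dir, "chrom.sizes"),
                islands = file.path(dir, "islands.bed"),
                truth = file.path(dir, "truth_dm.bed"),
                manifest = file.path(dir, "manifest.tsv"),
                ct_table = file.path(dir, "qpcr_ct.tsv"))
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- ref$chrom
  Biostrings::writeXStringSet(dna, paths$reference)
  writeLines(sprintf("%s\t%d", ref$chrom, nchar(ref$sequence)),
             paths$chrom_sizes)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  isl <- ref$islands
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t.", isl$chrom, fmt(isl$start),
                     fmt(isl$end), isl$name), paths$islands)
  dm <- isl[isl$dm, , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t.", dm$chrom, fmt(dm$start),
                     fmt(dm$end), dm$name), paths$truth)
  bm$manifest$path <- file.path(dir, paste0(bm$manifest$sample_id,
                                            ".bedmethyl"))
  for (s in seq_len(nrow(bm$manifest)))
    write_bedmethyl(bm$records[bm$records$sample_id ==
                                 bm$manifest$sample_id[s], , drop = FALSE],
                    bm$manifest$path[s])
  write.table(bm$manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ct, paths$ct_table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = ref, bedmethyl = bm, markers = markers,
                 ct = ct, paths = paths))
}
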