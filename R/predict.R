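#' Configuration for MSP region prediction
#'
#' Defaults follow the conventional parameterization of CpG-density-aware
#' differential-methylation primer-region calling: at least `min_cpgs`
#' differential CpGs inside a primer-sized window of 18-24 nt, controls at
#' most 10% methylated, amplicon span 60-400 nt.
#'
#' @param min_cpgs Minimum eligible CpGs per primer site window (default 3).
#' @param max_meth_control Maximum percent methylation allowed in every
#'   control sample for a CpG to count as differential (default 10).
#' @param min_primer_len,max_primer_len Primer-site window length bounds in
#'   nt (defaults 18 and 24).
#' @param min_amplicon_len,max_amplicon_len Bounds on the outer span from
#'   forward-site start to reverse-site end (defaults 60 and 400).
#' @param min_meth_tumor Percent methylation at least one tumor sample must
#'   reach (default 50, a conventional hemimethylation midpoint; the
#'   requirement "methylated in at least one tumor sample" is not otherwise
#'   quantified - tune to your tumor purity).
#' @param min_site_depth Minimum valid-call depth required in every sample at
#'   a CpG (default 5).
#' @param score_threshold Regions scoring below this are discarded before
#'   cluster selection (default 0 = keep all; the score scale is
#'   data-dependent, see [score_msp_regions()]).
#' @return A validated list of class `prediction_config`.
#' @export
prediction_config <- function(min_cpgs = 3L, max_meth_control = 10,
                              min_primer_len = 18L, max_primer_len = 24L,
                              min_amplicon_len = 60L, max_amplicon_len = 400L,
                              min_meth_tumor = 50, min_site_depth = 5L,
                              score_threshold = 0) {
  cfg <- list(min_cpgs = as.integer(min_cpgs),
              max_meth_control = max_meth_control,
              min_primer_len = as.integer(min_primer_len),
              max_primer_len = as.integer(max_primer_len),
              min_amplicon_len = as.integer(min_amplicon_len),
              max_amplicon_len = as.integer(max_amplicon_len),
              min_meth_tumor = min_meth_tumor,
              min_site_depth = min_site_depth,
              score_threshold = score_threshold)
  if (cfg$min_cpgs < 1L) .stopf("min_cpgs must be >= 1")
  if (cfg$min_primer_len > cfg$max_primer_len)
    .stopf("min_primer_len > max_primer_len")
  if (cfg$min_amplicon_len > cfg$max_amplicon_len)
    .stopf("min_amplicon_len > max_amplicon_len")
  for (p in c("max_meth_control", "min_meth_tumor"))
    if (cfg[[p]] < 0 || cfg[[p]] > 100) .stopf("%s must be in [0, 100]", p)
  if (cfg$min_site_depth < 0) .stopf("min_site_depth must be >= 0")
  structure(cfg, class = "prediction_config")
}

#' Classify one CpG site across samples
#'
#' A CpG is `eligible` for MSP primer placement when every control sample is
#' at most `max_meth_control` percent methylated, at least one tumor sample
#' is at least `min_meth_tumor` percent methylated, and every sample covers
#' the site with at least `min_site_depth` valid calls. Failures are labeled
#' by the first violated criterion, checked in the order `low_depth`,
#' `control_methylated`, `tumor_unmethylated`.
#'
#' @param site `data.frame` with one row per sample: columns `group`
#'   (`tumor`/`control`), `depth`, `meth_pct`.
#' @param cfg A [prediction_config()].
#' @return One of `"eligible"`, `"low_depth"`, `"control_methylated"`,
#'   `"tumor_unmethylated"`.
#' @export
classify_cpg_status <- function(site, cfg = prediction_config()) {
  if (!any(site$group == "tumor") || !any(site$group == "control"))
    .stopf("site needs measurements for >= 1 tumor and >= 1 control sample")
  if (any(site$depth < cfg$min_site_depth)) return("low_depth")
  if (any(site$meth_pct[site$group == "control"] > cfg$max_meth_control))
    return("control_methylated")
  if (!any(site$meth_pct[site$group == "tumor"] >= cfg$min_meth_tumor))
    return("tumor_unmethylated")
  "eligible"
}

# Vectorized site classification over a full record table. A site must be
# measured in every manifest sample; missing measurements count as depth 0.
.classify_sites <- function(records, manifest, cfg) {
  n_samples <- nrow(manifest)
  grp <- manifest$group[match(records$sample_id, manifest$sample_id)]
  if (anyNA(grp))
    .stopf("records contain sample_id absent from manifest: %s",
           records$sample_id[which(is.na(grp))[1]])
  site <- paste(records$chrom, records$pos, sep = "\r")
  f <- factor(site)
  n_present <- tabulate(f, nlevels(f))
  min_depth <- vapply(split(records$depth, f), min, 0)
  ctrl_max <- vapply(split(ifelse(grp == "control", records$meth_pct, -Inf), f),
                     max, 0)
  tum_max <- vapply(split(ifelse(grp == "tumor", records$meth_pct, -Inf), f),
                    max, 0)
  status <- rep("eligible", nlevels(f))
  status[tum_max < cfg$min_meth_tumor] <- "tumor_unmethylated"
  status[ctrl_max > cfg$max_meth_control] <- "control_methylated"
  status[min_depth < cfg$min_site_depth | n_present < n_samples] <- "low_depth"
  first <- !duplicated(f)
  data.frame(chrom = records$chrom[first][match(levels(f), f[first])],
             pos = records$pos[first][match(levels(f), f[first])],
             status = status, stringsAsFactors = FALSE)
}

#' Find candidate MSP primer sites from eligible CpG positions
#'
#' Scans one chromosome's sorted eligible CpG positions for maximal groups
#' of at least `min_cpgs` CpGs whose dinucleotides fit inside a single
#' window of at most `max_primer_len` nt. Each maximal group is reported
#' once, as a window anchored at its first CpG and extended to cover the
#' last CpG (padded to `min_primer_len` where the CpG span is shorter), so
#' the first and last CpG always lie inside the window.
#'
#' @param positions Sorted ascending 0-based positions of the C of each
#'   eligible CpG on one chromosome.
#' @param cfg A [prediction_config()].
#' @param chrom Chromosome label attached to the output.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_cpgs`, `cpgs` (comma-separated CpG positions).
#' @export
find_primer_sites <- function(positions, cfg = prediction_config(),
                              chrom = NA_character_) {
  out <- .empty_sites()
  if (length(positions) < cfg$min_cpgs) return(out)
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = TRUE))
    .stopf("positions must be sorted strictly ascending")
  n <- length(positions)
  # j_max[i]: last CpG whose dinucleotide (pos .. pos+1) fits in a
  # max_primer_len window starting at positions[i]
  j_max <- findInterval(positions[] + cfg$max_primer_len - 2, positions)
  j_of <- integer(0); i_of <- integer(0)
  prev_j <- 0L
  for (i in seq_len(n)) {
    j <- j_max[i]
    if (j - i + 1L >= cfg$min_cpgs && j > prev_j) {
      i_of <- c(i_of, i); j_of <- c(j_of, j)
      prev_j <- j
    }
  }
  if (!length(i_of)) return(out)
  start <- positions[i_of]
  span <- positions[j_of] + 2 - start
  end <- start + pmax(cfg$min_primer_len, span)
  cpgs <- vapply(seq_along(i_of), function(k)
    paste(format(positions[i_of[k]:j_of[k]], scientific = FALSE, trim = TRUE),
          collapse = ","), "")
  data.frame(chrom = chrom, start = start, end = end,
             n_cpgs = j_of - i_of + 1L, cpgs = cpgs, stringsAsFactors = FALSE)
}

.empty_sites <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             n_cpgs = integer(), cpgs = character(), stringsAsFactors = FALSE)
}

#' Pair primer sites into amplicon-sized candidate regions
#'
#' Every ordered pair of non-overlapping sites on the same chromosome whose
#' outer span (forward-site start to reverse-site end) lies within the
#' amplicon length bounds yields one unscored candidate region.
#'
#' @param sites Primer-site `data.frame` from [find_primer_sites()], sorted
#'   by start.
#' @param cfg A [prediction_config()].
#' @return MSP region `data.frame` with columns `chrom`, `start`, `end`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `fwd_cpgs`, `rev_cpgs`,
#'   `score` (`NA` until scored).
#' @export
pair_sites_to_regions <- function(sites, cfg = prediction_config()) {
  out <- empty_msp_regions()
  if (nrow(sites) < 2L) return(out)
  out_list <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    s <- sites[idx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    n <- nrow(s)
    # candidate partners by start position, then exact filtering vectorized
    lo <- findInterval(s$end - 1e-9, s$start) + 1L
    hi <- findInterval(s$start + cfg$max_amplicon_len, s$start)
    cnt <- pmax(0L, hi - lo + 1L)
    a <- rep.int(seq_len(n), cnt)
    b <- unlist(lapply(which(cnt > 0L), function(i) lo[i]:hi[i]),
                use.names = FALSE)
    if (!length(a)) return(NULL)
    span <- s$end[b] - s$start[a]
    keep <- s$start[b] >= s$end[a] &
      span >= cfg$min_amplicon_len & span <= cfg$max_amplicon_len
    a <- a[keep]; b <- b[keep]
    if (!length(a)) return(NULL)
    data.frame(chrom = s$chrom[a], start = s$start[a], end = s$end[b],
               fwd_start = s$start[a], fwd_end = s$end[a],
               rev_start = s$start[b], rev_end = s$end[b],
               fwd_cpgs = s$cpgs[a], rev_cpgs = s$cpgs[b],
               score = NA_real_, stringsAsFactors = FALSE)
  })
  out_list <- out_list[!vapply(out_list, is.null, logical(1))]
  if (!length(out_list)) return(out)
  out <- do.call(rbind, out_list)
  out <- out[order(out$chrom, out$start, out$end, out$rev_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidate MSP regions on tumor methylation and depth
#'
#' The score of a region is the sum, over tumor samples and over the CpGs of
#' both primer sites, of `meth_pct/100 * depth`: non-negative and monotone
#' non-decreasing in every tumor methylation percentage and depth, so highly
#' methylated, well-covered tumor regions score highest. The scale is
#' data-dependent (it grows with depth and sample count); thresholds should
#' be chosen per dataset, e.g. from the empirical score distribution.
#'
#' @param regions MSP region `data.frame`.
#' @param records Aggregated measurement `data.frame` covering all tumor
#'   samples at every site CpG (missing measurements raise an error).
#' @param manifest Sample manifest `data.frame`.
#' @return `regions` with the `score` column filled.
#' @export
score_msp_regions <- function(regions, records, manifest) {
  if (!nrow(regions)) return(regions)
  tumor_ids <- manifest$sample_id[manifest$group == "tumor"]
  if (!length(tumor_ids)) .stopf("manifest has no tumor samples")
  tum <- records[records$sample_id %in% tumor_ids, , drop = FALSE]
  key <- paste(tum$chrom, tum$pos, sep = "\r")
  contrib <- tum$meth_pct / 100 * tum$depth
  f <- factor(key)
  per_site <- as.vector(rowsum(contrib, f))
  n_at_site <- tabulate(f, nlevels(f))
  site_keys <- levels(f)
  # one flat lookup over all regions' site CpGs (fwd and rev sites are
  # disjoint, so concatenation has no duplicates)
  cpg_str <- paste(regions$fwd_cpgs, regions$rev_cpgs, sep = ",")
  cpgs <- strsplit(cpg_str, ",", fixed = TRUE)
  idx <- rep.int(seq_len(nrow(regions)), lengths(cpgs))
  k <- paste(regions$chrom[idx], as.numeric(unlist(cpgs, use.names = FALSE)),
             sep = "\r")
  m <- match(k, site_keys)
  bad <- which(is.na(m) | n_at_site[m] < length(tumor_ids))
  if (length(bad))
    .stopf("missing tumor measurement at %s", gsub("\r", ":", k[bad[1]]))
  regions$score <- as.vector(rowsum(per_site[m], idx))
  regions
}

.split_pos <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

#' Threshold scored regions and pick cluster representatives
#'
#' Regions scoring below `score_threshold` are dropped; the remainder are
#' processed greedily in descending score order (ties broken by longer span,
#' then smaller start), suppressing any region whose span overlaps an
#' already-selected region. This deterministic rule replaces manual
#' highest-scoring-per-cluster curation.
#'
#' @param regions Scored MSP region `data.frame`.
#' @param score_threshold Minimum score kept (default from `cfg` users: 0).
#' @return Selected regions, sorted by `(chrom, start)`.
#' @export
cluster_and_select <- function(regions, score_threshold = 0) {
  regions <- regions[!is.na(regions$score) & regions$score >= score_threshold, ,
                     drop = FALSE]
  if (!nrow(regions)) return(regions)
  span <- regions$end - regions$start
  ord <- order(-regions$score, -span, regions$start)
  keep <- logical(nrow(regions))
  sel_chrom <- character(0); sel_start <- numeric(0); sel_end <- numeric(0)
  for (i in ord) {
    clash <- any(sel_chrom == regions$chrom[i] &
                   sel_start < regions$end[i] & sel_end > regions$start[i])
    if (!clash) {
      keep[i] <- TRUE
      sel_chrom <- c(sel_chrom, regions$chrom[i])
      sel_start <- c(sel_start, regions$start[i])
      sel_end <- c(sel_end, regions$end[i])
    }
  }
  out <- regions[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict MSP primer regions from bedmethyl files
#'
#' End-to-end caller: read each sample's bedmethyl file, merge CpG strands
#' (optional), classify CpGs as differential between tumor and control
#' groups, scan for primer-site windows, pair sites into amplicon-sized
#' regions, score on tumor methylation and depth, then threshold and select
#' cluster representatives. A per-stage count report mirrors the funnel.
#'
#' @param manifest Sample manifest `data.frame` (see
#'   [read_sample_manifest()]); `path` must point at each sample's bedmethyl
#'   file.
#' @param cfg A [prediction_config()].
#' @param islands Optional CpG-island interval `data.frame`; when supplied,
#'   the report includes the fraction of selected regions overlapping them.
#' @param aggregate_strands Merge `+`/`-` strand CpG records before
#'   classification (default `TRUE`; set `FALSE` to call on strand-specific
#'   records).
#' @param select Apply threshold + cluster selection (default `TRUE`; set
#'   `FALSE` to obtain all scored candidates, e.g. for oracle comparisons).
#' @return A list of class `msp_prediction`: `regions` (selected),
#'   `candidates` (all scored, pre-clustering), `sites`, `report`
#'   (per-stage counts and `island_overlap_fraction`).
#' @export
predict_msp_regions <- function(manifest, cfg = prediction_config(),
                                islands = NULL, aggregate_strands = TRUE,
                                select = TRUE) {
  manifest <- validate_manifest(manifest)
  recs <- lapply(seq_len(nrow(manifest)), function(i)
    read_bedmethyl(manifest$path[i], sample_id = manifest$sample_id[i]))
  n_parsed <- sum(vapply(recs, attr, 0L, "n_parsed"))
  n_dropped <- sum(vapply(recs, attr, 0L, "n_dropped_min_depth"))
  records <- do.call(rbind, recs)
  if (aggregate_strands) records <- aggregate_cpg_strands(records)
  sites_status <- .classify_sites(records, manifest, cfg)
  eligible <- sites_status[sites_status$status == "eligible", , drop = FALSE]
  site_list <- lapply(split(eligible, eligible$chrom), function(d)
    find_primer_sites(sort(d$pos), cfg, chrom = d$chrom[1]))
  sites <- if (length(site_list)) do.call(rbind, site_list) else .empty_sites()
  rownames(sites) <- NULL
  cand_list <- lapply(split(sites, sites$chrom), pair_sites_to_regions, cfg = cfg)
  candidates <- if (length(cand_list)) do.call(rbind, cand_list)
                else empty_msp_regions()
  rownames(candidates) <- NULL
  candidates <- score_msp_regions(candidates, records, manifest)
  regions <- if (select) cluster_and_select(candidates, cfg$score_threshold)
             else candidates
  report <- list(
    n_records_parsed = n_parsed,
    n_records_dropped_min_depth = n_dropped,
    n_sites_total = nrow(sites_status),
    n_sites_eligible = nrow(eligible),
    n_primer_sites = nrow(sites),
    n_candidate_regions = nrow(candidates),
    n_regions_selected = nrow(regions),
    island_overlap_fraction = .overlap_fraction(regions, islands))
  structure(list(regions = regions, candidates = candidates, sites = sites,
                 report = report), class = "msp_prediction")
}

#' @export
print.msp_prediction <- function(x, ...) {
  cat("MSP region prediction\n")
  for (k in names(x$report))
    cat(sprintf("  %-28s %s\n", k, format(x$report[[k]])))
  invisible(x)
}

#' Re-validate predicted regions against raw records and configuration
#'
#' Independent checker used by the test-suite and available to users:
#' verifies, directly from the measurement table, every structural bound of
#' each region (site window lengths, CpG counts, amplicon span, site
#' non-overlap) and the CpG eligibility criteria.
#'
#' @inheritParams score_msp_regions
#' @param cfg A [prediction_config()].
#' @return `TRUE`, or an error describing the first violated constraint.
#' @export
validate_msp_regions <- function(regions, records, manifest, cfg) {
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (side in c("fwd", "rev")) {
      s <- r[[paste0(side, "_start")]]; e <- r[[paste0(side, "_end")]]
      len <- e - s
      if (len < cfg$min_primer_len || len > cfg$max_primer_len)
        .stopf("region %d: %s site length %d outside bounds", i, side, len)
      cpgs <- .split_pos(r[[paste0(side, "_cpgs")]])
      if (length(cpgs) < cfg$min_cpgs)
        .stopf("region %d: %s site has %d CpGs < min_cpgs", i, side, length(cpgs))
      if (any(cpgs < s | cpgs + 2 > e))
        .stopf("region %d: %s site CpG outside window", i, side)
      for (p in cpgs) {
        site <- records[records$chrom == r$chrom & records$pos == p, , drop = FALSE]
        site$group <- manifest$group[match(site$sample_id, manifest$sample_id)]
        if (nrow(site) < nrow(manifest) ||
            classify_cpg_status(site, cfg) != "eligible")
          .stopf("region %d: CpG at %s:%d not eligible", i, r$chrom, p)
      }
    }
    span <- r$end - r$start
    if (span < cfg$min_amplicon_len || span > cfg$max_amplicon_len)
      .stopf("region %d: span %d outside amplicon bounds", i, span)
    if (r$rev_start < r$fwd_end) .stopf("region %d: sites overlap", i)
  }
  TRUE
}
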