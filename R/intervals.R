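#' Read a BED file of genomic intervals
#'
#' Parses BED3+ (tab-separated, 0-based half-open). Columns beyond the sixth
#' are ignored; column 4 is taken as the interval name and column 6 as the
#' strand when present. `track`/`browser`/`#` header lines are skipped.
#' Reads gzip-compressed files transparently.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, sorted by `(chrom, start, end)`. Coordinates are 0-based
#'   half-open. Overlapping intervals are permitted.
#' @export
read_bed_intervals <- function(path) {
  lines <- read_lines_gz(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("BED line %d has %d columns, need >= 3", lineno[which(nf < 3L)[1]],
           nf[which(nf < 3L)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .as_num(vapply(fields, `[[`, "", 2L), "start", lineno)
  end <- .as_num(vapply(fields, `[[`, "", 3L), "end", lineno)
  bad <- which(start >= end | start < 0)
  if (length(bad))
    .stopf("BED line %d: invalid interval [%s, %s)", lineno[bad[1]],
           start[bad[1]], end[bad[1]])
  name <- vapply(seq_along(fields), function(i)
    if (nf[i] >= 4L) fields[[i]][4L] else NA_character_, "")
  strand <- vapply(seq_along(fields), function(i)
    if (nf[i] >= 6L) fields[[i]][6L] else ".", "")
  if (!all(strand %in% c("+", "-", ".")))
    .stopf("BED line %d: invalid strand '%s'",
           lineno[which(!strand %in% c("+", "-", "."))[1]],
           strand[which(!strand %in% c("+", "-", "."))[1]])
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    strand = strand, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), strand = character(), stringsAsFactors = FALSE)
}

#' Expand target intervals by a buffer and merge overlaps
#'
#' Grows each interval by `buffer` nucleotides on both sides (the
#' adaptive-sampling target expansion; 2000 nt is the conventional buffer
#' around CpG islands), clips to chromosome bounds, and merges overlapping or
#' abutting results per chromosome.
#'
#' @param intervals Interval `data.frame` as from [read_bed_intervals()].
#' @param buffer Non-negative number of nucleotides added on each side.
#' @param chrom_sizes Named numeric vector (or two-column data.frame
#'   `chrom`, `size`) of chromosome lengths. Every chromosome present in
#'   `intervals` must be listed.
#' @return Merged interval `data.frame` (columns as [read_bed_intervals()]),
#'   sorted, non-overlapping, within `[0, chrom size]`.
#' @export
expand_target_regions <- function(intervals, buffer, chrom_sizes) {
  stopifnot(is.numeric(buffer), length(buffer) == 1L, buffer >= 0)
  if (is.data.frame(chrom_sizes)) {
    sizes <- chrom_sizes[[2L]]
    names(sizes) <- chrom_sizes[[1L]]
    chrom_sizes <- sizes
  }
  if (!nrow(intervals)) return(empty_intervals())
  missing <- setdiff(unique(intervals$chrom), names(chrom_sizes))
  if (length(missing))
    .stopf("chromosome(s) absent from chrom_sizes: %s",
           paste(missing, collapse = ", "))
  start <- pmax(0, intervals$start - buffer)
  end <- pmin(chrom_sizes[intervals$chrom], intervals$end + buffer)
  out <- lapply(split(seq_len(nrow(intervals)), intervals$chrom), function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1L,
                                           end = end[idx]))
    data.frame(chrom = intervals$chrom[idx[1]],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               name = NA_character_, strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length (no header),
#'   e.g. the `.fai`-derived `chrom.sizes` convention.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_lines_gz(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) .stopf("chrom-sizes line with < 2 columns")
  sizes <- .as_num(vapply(fields, `[[`, "", 2L), "chromosome size")
  names(sizes) <- vapply(fields, `[[`, "", 1L)
  sizes
}

#' Mean CpG-site depth per region
#'
#' Summarizes sequencing depth over the CpG sites falling inside each region
#' (a site-level stand-in for windowed depth tools).
#'
#' @param records CpG measurement `data.frame` (see [read_bedmethyl()]).
#' @param regions Interval `data.frame`.
#' @return `regions` with added columns `n_sites` and `mean_depth`
#'   (`NA` for regions containing no CpG site).
#' @export
mean_region_depth <- function(records, regions) {
  regions$n_sites <- 0L
  regions$mean_depth <- NA_real_
  if (!nrow(regions) || !nrow(records)) return(regions)
  for (i in seq_len(nrow(regions))) {
    hit <- records$chrom == regions$chrom[i] &
      records$pos >= regions$start[i] & records$pos < regions$end[i]
    regions$n_sites[i] <- sum(hit)
    if (any(hit)) regions$mean_depth[i] <- mean(records$depth[hit])
  }
  regions
}

# 0..1000 clamp for the BED score column; raw score kept in an extra column
.bed_score <- function(score) as.integer(pmax(0, pmin(1000, round(score))))

#' Write predicted MSP regions as BED6+ and read them back
#'
#' Column 5 carries the score clamped to the BED 0-1000 convention; extra
#' columns 7+ carry the raw score, both primer-site intervals and their CpG
#' position lists so that [read_regions_bed()] round-trips losslessly.
#'
#' @param regions MSP region `data.frame` as from [pair_sites_to_regions()] /
#'   [predict_msp_regions()]. A `score` column is optional (0 assumed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- c("chrom", "start", "end", "fwd_start", "fwd_end", "rev_start",
            "rev_end", "fwd_cpgs", "rev_cpgs")
  if (nrow(regions) && !all(cols %in% names(regions)))
    .stopf("regions are missing columns: %s",
           paste(setdiff(cols, names(regions)), collapse = ", "))
  if (!nrow(regions)) {
    ok <- file.create(path)
    if (!ok) .stopf("cannot write to %s", path)
    return(invisible(path))
  }
  score <- if ("score" %in% names(regions)) regions$score else 0
  name <- sprintf("msp_region_%d", seq_len(nrow(regions)))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  bed <- data.frame(regions$chrom, fmt(regions$start), fmt(regions$end),
                    name, .bed_score(score), ".",
                    sprintf("%.10g", score),
                    fmt(regions$fwd_start), fmt(regions$fwd_end),
                    fmt(regions$rev_start), fmt(regions$rev_end),
                    regions$fwd_cpgs, regions$rev_cpgs)
  ok <- tryCatch({
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) .stopf("cannot write to %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  lines <- read_lines_gz(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_msp_regions())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 13L))
    .stopf("regions BED line %d has < 13 columns", which(lengths(fields) < 13L)[1])
  g <- function(k) vapply(fields, `[[`, "", k)
  out <- data.frame(
    chrom = g(1), start = .as_num(g(2), "start"), end = .as_num(g(3), "end"),
    fwd_start = .as_num(g(8), "fwd_start"), fwd_end = .as_num(g(9), "fwd_end"),
    rev_start = .as_num(g(10), "rev_start"), rev_end = .as_num(g(11), "rev_end"),
    fwd_cpgs = g(12), rev_cpgs = g(13),
    score = .as_num(g(7), "score"), stringsAsFactors = FALSE)
  out
}

empty_msp_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             fwd_start = numeric(), fwd_end = numeric(),
             rev_start = numeric(), rev_end = numeric(),
             fwd_cpgs = character(), rev_cpgs = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

# fraction of regions overlapping any interval in `islands`
.overlap_fraction <- function(regions, islands) {
  if (!nrow(regions)) return(NA_real_)
  if (is.null(islands) || !nrow(islands)) return(NA_real_)
  hit <- vapply(seq_len(nrow(regions)), function(i) {
    any(islands$chrom == regions$chrom[i] &
          islands$start < regions$end[i] &
          islands$end > regions$start[i])
  }, logical(1))
  mean(hit)
}
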