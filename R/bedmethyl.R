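#' Read a bedmethyl file of per-CpG methylation calls
#'
#' Parses the extended-BED methylation pileup dialect written by nanopore
#' modified-base tooling (BED9+2): column 10 is the count of valid
#' modification calls at the position and column 11 the percent of those
#' calls that were methylated. Rows are strand-tagged (column 6); use
#' [aggregate_cpg_strands()] to merge the two strands of a CpG. Reads
#' gzip-compressed files transparently.
#'
#' @param path Path to a bedmethyl file.
#' @param min_depth Rows with fewer than `min_depth` valid calls are dropped
#'   and counted in the parse report (default 1: zero-coverage rows are
#'   removed; analysis-level depth thresholds belong in
#'   [prediction_config()]).
#' @param sample_id Optional sample label attached to every record.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based position of
#'   the measured cytosine), `strand`, `depth`, `meth_pct`, `sample_id`,
#'   carrying attributes `n_parsed` (rows read) and `n_dropped_min_depth`.
#' @export
read_bedmethyl <- function(path, min_depth = 1L, sample_id = NA_character_) {
  stopifnot(is.numeric(min_depth), length(min_depth) == 1L, min_depth >= 0)
  lines <- read_lines_gz(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- .empty_cpg_records()
    attr(out, "n_parsed") <- 0L
    attr(out, "n_dropped_min_depth") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[1]
    .stopf("bedmethyl line %d has %d columns, need >= 11", lineno[i], nf[i])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- .as_num(vapply(fields, `[[`, "", 2L), "position", lineno)
  strand <- vapply(fields, `[[`, "", 6L)
  if (!all(strand %in% c("+", "-", "."))) {
    i <- which(!strand %in% c("+", "-", "."))[1]
    .stopf("bedmethyl line %d: invalid strand '%s'", lineno[i], strand[i])
  }
  depth <- .as_num(vapply(fields, `[[`, "", 10L), "coverage", lineno)
  meth_pct <- .as_num(vapply(fields, `[[`, "", 11L), "percent methylation", lineno)
  if (any(depth < 0)) {
    i <- which(depth < 0)[1]
    .stopf("bedmethyl line %d: negative coverage %s", lineno[i], depth[i])
  }
  bad <- which(meth_pct < 0 | meth_pct > 100)
  if (length(bad))
    .stopf("bedmethyl line %d: percent methylation %s outside [0, 100]",
           lineno[bad[1]], meth_pct[bad[1]])
  keep_depth <- depth >= min_depth
  out <- data.frame(chrom = chrom[keep_depth], pos = pos[keep_depth],
                    strand = strand[keep_depth], depth = depth[keep_depth],
                    meth_pct = meth_pct[keep_depth],
                    sample_id = rep(sample_id, sum(keep_depth)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_parsed") <- length(lines)
  attr(out, "n_dropped_min_depth") <- sum(!keep_depth)
  out
}

.empty_cpg_records <- function() {
  data.frame(chrom = character(), pos = numeric(), strand = character(),
             depth = numeric(), meth_pct = numeric(), sample_id = character(),
             stringsAsFactors = FALSE)
}

#' Merge the two strand records of a CpG dinucleotide
#'
#' CpG methylation is largely symmetric, so by default the `+`-strand call at
#' position p and the `-`-strand call at p+1 are merged into one site at p
#' with summed depth and a depth-weighted mean percent methylation. Unpaired
#' records (and `.`-strand records) pass through unchanged. Total read
#' counts are conserved.
#'
#' @param records Strand-tagged measurement `data.frame` from
#'   [read_bedmethyl()], sorted by `(chrom, pos)` within each sample.
#' @return A `data.frame` with the same columns; merged sites carry
#'   strand `"."`.
#' @export
aggregate_cpg_strands <- function(records) {
  if (!nrow(records)) return(records)
  out <- lapply(split(records, records$sample_id), .aggregate_one_sample)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.aggregate_one_sample <- function(rec) {
  ord <- order(rec$chrom, rec$pos)
  if (any(ord != seq_len(nrow(rec))))
    .stopf("records for sample '%s' are not sorted by (chrom, pos)",
           rec$sample_id[1])
  plus <- which(rec$strand == "+")
  minus <- which(rec$strand == "-")
  key <- function(chrom, pos) paste(chrom, pos, sep = "\r")
  partner <- match(key(rec$chrom[minus], rec$pos[minus] - 1),
                   key(rec$chrom[plus], rec$pos[plus]))
  m_paired <- minus[!is.na(partner)]
  p_paired <- plus[partner[!is.na(partner)]]
  if (length(p_paired)) {
    d1 <- rec$depth[p_paired]; d2 <- rec$depth[m_paired]
    tot <- d1 + d2
    wmean <- ifelse(tot > 0,
                    (d1 * rec$meth_pct[p_paired] + d2 * rec$meth_pct[m_paired]) / tot,
                    (rec$meth_pct[p_paired] + rec$meth_pct[m_paired]) / 2)
    rec$depth[p_paired] <- tot
    rec$meth_pct[p_paired] <- wmean
    rec$strand[p_paired] <- "."
    rec <- rec[-m_paired, , drop = FALSE]
  }
  rec
}

#' Read a sample manifest
#'
#' @param path TSV with header columns `sample_id`, `group`
#'   (`tumor`/`control`) and `path` (per-sample bedmethyl file). Relative
#'   paths are resolved against the manifest's directory.
#' @return Validated `data.frame` with those columns: unique sample ids and
#'   at least one sample per group.
#' @export
read_sample_manifest <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab)))
    .stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  if (!"path" %in% names(tab)) tab$path <- NA_character_
  rel <- !is.na(tab$path) & !grepl("^(/|~)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  validate_manifest(tab)
}

#' @rdname read_sample_manifest
#' @param manifest A manifest `data.frame` to validate.
#' @export
validate_manifest <- function(manifest) {
  if (!all(manifest$group %in% c("tumor", "control")))
    .stopf("manifest groups must be 'tumor' or 'control', got: %s",
           paste(setdiff(manifest$group, c("tumor", "control")), collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    .stopf("duplicated sample_id in manifest: %s",
           manifest$sample_id[duplicated(manifest$sample_id)][1])
  if (!any(manifest$group == "tumor") || !any(manifest$group == "control"))
    .stopf("manifest needs >= 1 tumor and >= 1 control sample")
  manifest
}
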