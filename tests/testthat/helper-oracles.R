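# Fixture builders and independent brute-force oracles. Oracles deliberately
# recompute everything from first principles (enumeration over all windows,
# all substring pairs, all thresholds) and never call the code paths they
# check.

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# base-R reverse complement, independent of both Biostrings and the package
fast_rc <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")

rand_dna <- function(n, p_gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - p_gc) / 2, (1 - p_gc) / 2, p_gc / 2, p_gc / 2)),
        collapse = "")
}

make_records <- function(pos, depth, meth_pct, chrom = "chr1", strand = "+",
                         sample_id = "s1") {
  data.frame(chrom = chrom, pos = pos, strand = strand, depth = depth,
             meth_pct = meth_pct, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# Write a manifest + per-sample bedmethyl files for a set of CpGs with given
# per-group methylation levels. `eligible` marks CpGs made differential;
# the rest get high control methylation (ineligible).
write_dm_fixture <- function(dir, positions, eligible,
                             n_tumor = 3, n_control = 3, depth = 20,
                             meth_tumor = 90, meth_control = 2,
                             chrom = "chrT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c(sprintf("t%02d", seq_len(n_tumor)),
           sprintf("c%02d", seq_len(n_control)))
  groups <- rep(c("tumor", "control"), c(n_tumor, n_control))
  paths <- file.path(dir, paste0(ids, ".bedmethyl"))
  for (s in seq_along(ids)) {
    meth <- if (groups[s] == "tumor") ifelse(eligible, meth_tumor, meth_tumor)
            else ifelse(eligible, meth_control, 50)
    rec <- make_records(positions, depth, meth, chrom = chrom,
                        sample_id = ids[s])
    nanomsp:::write_bedmethyl(rec, paths[s])
  }
  data.frame(sample_id = ids, group = groups, path = paths,
             stringsAsFactors = FALSE)
}

# --- region-prediction oracles -------------------------------------------

# All achievable CpG runs by scanning every window of length min..max primer
# length; maximal runs anchored at their first CpG.
oracle_primer_sites <- function(positions, cfg = prediction_config()) {
  positions <- sort(positions)
  sets <- list()
  starts <- unique(unlist(lapply(positions, function(p)
    (p - cfg$max_primer_len):p)))
  for (L in cfg$min_primer_len:cfg$max_primer_len) {
    for (s in starts) {
      inside <- positions[positions >= s & positions + 2 <= s + L]
      if (length(inside) >= cfg$min_cpgs)
        sets[[paste(inside, collapse = ",")]] <- inside
    }
  }
  if (!length(sets))
    return(data.frame(start = numeric(), end = numeric(), cpgs = character(),
                      stringsAsFactors = FALSE))
  keep <- vapply(seq_along(sets), function(i)
    !any(vapply(seq_along(sets), function(j)
      j != i && length(sets[[j]]) > length(sets[[i]]) &&
        all(sets[[i]] %in% sets[[j]]), logical(1))), logical(1))
  sets <- sets[keep]
  df <- do.call(rbind, lapply(sets, function(cp) {
    start <- cp[1]
    end <- start + max(cfg$min_primer_len, cp[length(cp)] + 2 - start)
    data.frame(start = start, end = end,
               cpgs = paste(cp, collapse = ","), stringsAsFactors = FALSE)
  }))
  df <- unique(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# All (site, site) pairs with in-bounds outer span and no overlap.
oracle_regions <- function(positions, cfg = prediction_config()) {
  sites <- oracle_primer_sites(positions, cfg)
  rows <- list()
  n <- nrow(sites)
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    if (sites$start[b] < sites$end[a]) next
    span <- sites$end[b] - sites$start[a]
    if (span < cfg$min_amplicon_len || span > cfg$max_amplicon_len) next
    rows[[length(rows) + 1L]] <- data.frame(
      fwd_start = sites$start[a], fwd_end = sites$end[a],
      rev_start = sites$start[b], rev_end = sites$end[b],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(fwd_start = numeric(), fwd_end = numeric(),
                      rev_start = numeric(), rev_end = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$fwd_start, out$rev_start), , drop = FALSE]
}

# --- design oracles -------------------------------------------------------

oracle_wallace <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

# Brute-force primer enumeration straight from the template strings.
oracle_enumerate <- function(template, window, orientation,
                             cons = design_constraints()) {
  src <- strsplit(template$source_seq, "")[[1]]
  conv <- strsplit(template$converted_seq, "")[[1]]
  cpg <- which(src == "C" & c(src[-1], "") == "G" & conv == "C")
  convc <- which(src == "C" & conv == "T")
  rows <- list()
  for (L in cons$min_len:cons$max_len) {
    if (window[2] - window[1] + 1 < L) next
    for (s in window[1]:(window[2] - L + 1)) {
      e <- s + L - 1
      n_cpg <- sum(cpg >= s & cpg + 1 <= e)
      n_conv <- sum(convc >= s & convc <= e)
      if (n_cpg < cons$min_cpg || n_conv < cons$min_converted_c) next
      oligo <- paste(conv[s:e], collapse = "")
      if (orientation == "rev") oligo <- fast_rc(oligo)
      gc <- 100 * sum(strsplit(oligo, "")[[1]] %in% c("G", "C")) / L
      if (gc < cons$gc_min || gc > cons$gc_max) next
      tm <- oracle_wallace(oligo)
      if (tm < cons$tm_min || tm > cons$tm_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, sequence = oligo, n_cpg = n_cpg,
        n_converted_c = n_conv, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), n_cpg = integer(),
                      n_converted_c = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# Naive sliding-window complementarity: longest k with some substring of a
# equal to the reverse complement of some substring of b. anchor_3p
# restricts to runs ending at a's 3' terminal base.
oracle_comp_run <- function(a, b, anchor_3p = FALSE) {
  rc <- fast_rc
  n <- nchar(a); m <- nchar(b)
  for (k in min(n, m):1) {
    is <- if (anchor_3p) n - k + 1 else 1:(n - k + 1)
    for (i in is) for (j in 1:(m - k + 1)) {
      if (substr(a, i, i + k - 1) == rc(substr(b, j, j + k - 1))) return(k)
    }
  }
  0L
}

# Re-validation of emitted pairs directly against the constraint list.
oracle_validate_pairs <- function(pairs, template, cons = design_constraints()) {
  src <- strsplit(template$source_seq, "")[[1]]
  conv <- strsplit(template$converted_seq, "")[[1]]
  cpg <- which(src == "C" & c(src[-1], "") == "G" & conv == "C")
  convc <- which(src == "C" & conv == "T")
  rc <- fast_rc
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    ok <- p$fwd_seq == paste(conv[p$fwd_start:p$fwd_end], collapse = "") &&
      p$rev_seq == rc(paste(conv[p$rev_start:p$rev_end], collapse = "")) &&
      nchar(p$fwd_seq) >= cons$min_len && nchar(p$fwd_seq) <= cons$max_len &&
      nchar(p$rev_seq) >= cons$min_len && nchar(p$rev_seq) <= cons$max_len &&
      sum(cpg >= p$fwd_start & cpg + 1 <= p$fwd_end) >= cons$min_cpg &&
      sum(cpg >= p$rev_start & cpg + 1 <= p$rev_end) >= cons$min_cpg &&
      sum(convc >= p$fwd_start & convc <= p$fwd_end) >= cons$min_converted_c &&
      sum(convc >= p$rev_start & convc <= p$rev_end) >= cons$min_converted_c &&
      p$rev_end - p$fwd_start + 1 >= cons$min_amplicon_len &&
      p$rev_end - p$fwd_start + 1 <= cons$max_amplicon_len &&
      sum(cpg >= p$fwd_start & cpg + 1 <= p$rev_end) >= cons$min_amplicon_cpg &&
      abs(oracle_wallace(p$fwd_seq) - oracle_wallace(p$rev_seq)) <
        cons$max_tm_diff &&
      oracle_comp_run(p$fwd_seq, p$rev_seq) <= cons$dimer_run_max &&
      oracle_comp_run(p$fwd_seq, p$rev_seq, anchor_3p = TRUE) <=
        cons$dimer_run_3p_max &&
      oracle_comp_run(p$rev_seq, p$fwd_seq, anchor_3p = TRUE) <=
        cons$dimer_run_3p_max &&
      oracle_comp_run(p$fwd_seq, p$fwd_seq) < cons$self_run_max &&
      oracle_comp_run(p$rev_seq, p$rev_seq) < cons$self_run_max
    if (!ok) return(FALSE)
  }
  TRUE
}

oracle_validate_probes <- function(probes, pair, template,
                                   cons = design_constraints()) {
  conv <- template$converted_seq
  tm_primer <- max(oracle_wallace(pair$fwd_seq), oracle_wallace(pair$rev_seq))
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, ]
    tm <- oracle_wallace(p$sequence)
    ok <- p$sequence == substr(conv, p$start, p$end) &&
      p$length >= cons$probe_min_len && p$length <= cons$probe_max_len &&
      substr(p$sequence, 1, 1) != "G" &&
      !is_palindrome(p$sequence, cons$probe_palindrome_min) &&
      p$start > pair$fwd_end &&
      p$start - pair$fwd_end - 1 <= cons$probe_max_offset &&
      p$end < pair$rev_start &&
      tm >= tm_primer + cons$probe_tm_above[1] &&
      tm <= tm_primer + cons$probe_tm_above[2] &&
      oracle_comp_run(p$sequence, pair$fwd_seq) <= cons$dimer_run_max &&
      oracle_comp_run(p$sequence, pair$rev_seq) <= cons$dimer_run_max &&
      oracle_comp_run(p$sequence, p$sequence) <= cons$dimer_run_max
    if (!ok) return(FALSE)
  }
  TRUE
}

# --- statistics oracles ---------------------------------------------------

oracle_auc <- function(tumor, control) {
  w <- suppressWarnings(stats::wilcox.test(control, tumor))$statistic
  unname(w) / (length(tumor) * length(control))
}

oracle_best_j <- function(tumor, control) {
  cand <- c(-Inf, sort(unique(c(tumor, control))), Inf)
  max(vapply(cand, function(c)
    mean(tumor <= c) + mean(control > c) - 1, 0))
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

# RC-palindromic template over {A, T, CG}: the converted methylated-allele
# sequence equals the source, and both are their own reverse complement.
palindromic_source <- function(n_units, p_cg = 0.6, seed = 1) {
  withr::with_seed(seed, {
    units <- sample(c("CG", "A", "T"), n_units, replace = TRUE,
                    prob = c(p_cg, (1 - p_cg) / 2, (1 - p_cg) / 2))
    half <- paste(units, collapse = "")
    paste0(half, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(half))))
  })
}
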