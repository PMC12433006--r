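#' Constraint set for MSP primer and probe design
#'
#' Defaults encode the standard bisulfite-MSP design rules: primers of
#' 14-22 nt covering at least one CpG (so only the methylated allele is
#' amplified) and at least one converted C (so unconverted DNA is not),
#' GC near 60% (band 50-70), amplicons of 80-400 bp with at least three
#' CpGs and ideally four converted cytosines, melting-temperature difference
#' under 5 degrees C, and probes of 20-30 nt placed just downstream of the
#' forward primer with Tm 5-10 degrees above the primers, GC near 50%, no
#' 5' guanine (which quenches reporter dyes) and no palindrome of 6+ nt.
#' Dimer screening uses ungapped complementarity runs (not thermodynamic
#' folding): fail above 8 bases overall, above 4 bases anchored at a 3' end.
#'
#' @param min_len,max_len Primer length bounds in nt.
#' @param min_cpg Minimum CpGs per primer (methylation specificity).
#' @param min_converted_c Minimum converted Cs per primer (bisulfite
#'   specificity).
#' @param gc_min,gc_max Primer GC band in percent.
#' @param tm_min,tm_max Primer Tm band in degrees C.
#' @param tm_method Tm estimator, see [melting_temperature()].
#' @param max_tm_diff Pair fails when `|Tm_fwd - Tm_rev|` reaches this.
#' @param min_amplicon_len,max_amplicon_len Amplicon length bounds in bp.
#' @param min_amplicon_cpg Minimum CpGs in the amplicon.
#' @param ideal_converted_c Converted-C count in the amplicon rewarded by
#'   ranking (soft, not a filter).
#' @param dimer_run_max,dimer_run_3p_max,self_run_max Complementarity-run
#'   fail thresholds (overall, 3'-anchored, self/hairpin).
#' @param probe_min_len,probe_max_len Probe length bounds in nt.
#' @param probe_max_offset Maximum gap in nt between the forward primer's 3'
#'   end and the probe's 5' end.
#' @param probe_tm_above Two-element band: probe Tm minus the hotter
#'   primer's Tm must fall inside it.
#' @param probe_palindrome_min Minimum palindrome length rejected in probes.
#' @param probe_gc_target Probe ranking targets this GC percent.
#' @param flank Reference context in nt extracted on each side of a
#'   predicted region for design.
#' @return A validated list of class `design_constraints`.
#' @export
design_constraints <- function(min_len = 14L, max_len = 22L, min_cpg = 1L,
                               min_converted_c = 1L, gc_min = 50, gc_max = 70,
                               tm_min = 50, tm_max = 70,
                               tm_method = c("wallace", "nearest_neighbor"),
                               max_tm_diff = 5,
                               min_amplicon_len = 80L, max_amplicon_len = 400L,
                               min_amplicon_cpg = 3L, ideal_converted_c = 4L,
                               dimer_run_max = 8L, dimer_run_3p_max = 4L,
                               self_run_max = 8L,
                               probe_min_len = 20L, probe_max_len = 30L,
                               probe_max_offset = 10L,
                               probe_tm_above = c(5, 10),
                               probe_palindrome_min = 6L,
                               probe_gc_target = 50, flank = 200L) {
  cfg <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
              min_cpg = as.integer(min_cpg),
              min_converted_c = as.integer(min_converted_c),
              gc_min = gc_min, gc_max = gc_max, tm_min = tm_min, tm_max = tm_max,
              tm_method = match.arg(tm_method), max_tm_diff = max_tm_diff,
              min_amplicon_len = as.integer(min_amplicon_len),
              max_amplicon_len = as.integer(max_amplicon_len),
              min_amplicon_cpg = as.integer(min_amplicon_cpg),
              ideal_converted_c = as.integer(ideal_converted_c),
              dimer_run_max = as.integer(dimer_run_max),
              dimer_run_3p_max = as.integer(dimer_run_3p_max),
              self_run_max = as.integer(self_run_max),
              probe_min_len = as.integer(probe_min_len),
              probe_max_len = as.integer(probe_max_len),
              probe_max_offset = as.integer(probe_max_offset),
              probe_tm_above = probe_tm_above,
              probe_palindrome_min = as.integer(probe_palindrome_min),
              probe_gc_target = probe_gc_target, flank = as.integer(flank))
  if (cfg$min_len > cfg$max_len) .stopf("min_len > max_len")
  if (cfg$min_amplicon_len > cfg$max_amplicon_len)
    .stopf("min_amplicon_len > max_amplicon_len")
  if (cfg$probe_min_len > cfg$probe_max_len) .stopf("probe_min_len > probe_max_len")
  if (length(cfg$probe_tm_above) != 2L || diff(cfg$probe_tm_above) < 0)
    .stopf("probe_tm_above must be an increasing length-2 band")
  structure(cfg, class = "design_constraints")
}

#' Enumerate candidate primers on a bisulfite template
#'
#' All substrings of the converted sequence with length inside the primer
#' bounds whose interval lies inside `window` are evaluated; forward
#' candidates read the converted strand as-is, reverse candidates are
#' reverse-complemented (they prime the complementary strand synthesized in
#' the first PCR cycle). Candidates must cover at least `min_cpg` full CpG
#' dinucleotides and `min_converted_c` converted Cs and fall inside the GC
#' and Tm bands. CpG bases are emitted as the methylated-allele base (C/G).
#'
#' @param template A [bisulfite_convert()] result (methylated allele for MSP).
#' @param window Length-2 integer vector, 1-based inclusive positions in the
#'   template string delimiting where candidates may lie. Default: whole
#'   template.
#' @param orientation `"fwd"` or `"rev"`.
#' @param constraints A [design_constraints()].
#' @return `data.frame`, one row per candidate: `start`, `end` (1-based
#'   inclusive template positions), `length`, `orientation`, `sequence`
#'   (5'->3'), `gc_pct`, `tm`, `n_cpg`, `n_converted_c`, `ends_on_c`, and
#'   genomic 0-based `gstart`/`gend` when the template carries an offset.
#' @export
enumerate_primers <- function(template, window = NULL,
                              orientation = c("fwd", "rev"),
                              constraints = design_constraints()) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(template, "bisulfite_template"))
  n <- nchar(template$converted_seq)
  if (is.null(window)) window <- c(1L, n)
  w1 <- max(1L, as.integer(window[1])); w2 <- min(n, as.integer(window[2]))
  rows <- list()
  cpg <- template$cpg_positions
  conv <- template$converted_positions
  if (w2 >= w1) {
    for (L in constraints$min_len:constraints$max_len) {
      if (w2 - w1 + 1L < L) next
      for (s in w1:(w2 - L + 1L)) {
        e <- s + L - 1L
        n_cpg <- sum(cpg >= s & cpg + 1L <= e)
        if (n_cpg < constraints$min_cpg) next
        n_conv <- sum(conv >= s & conv <= e)
        if (n_conv < constraints$min_converted_c) next
        sub <- substr(template$converted_seq, s, e)
        oligo <- if (orientation == "fwd") sub else revcomp(sub)
        gc <- gc_content(oligo)
        if (gc < constraints$gc_min || gc > constraints$gc_max) next
        tm <- melting_temperature(oligo, constraints$tm_method)
        if (tm < constraints$tm_min || tm > constraints$tm_max) next
        rows[[length(rows) + 1L]] <- list(start = s, end = e, length = L,
          orientation = orientation, sequence = oligo, gc_pct = gc, tm = tm,
          n_cpg = n_cpg, n_converted_c = n_conv,
          ends_on_c = substr(oligo, L, L) == "C")
      }
    }
  }
  out <- if (length(rows))
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  else
    data.frame(start = integer(), end = integer(), length = integer(),
               orientation = character(), sequence = character(),
               gc_pct = numeric(), tm = numeric(), n_cpg = integer(),
               n_converted_c = integer(), ends_on_c = logical(),
               stringsAsFactors = FALSE)
  if (!is.na(template$offset)) {
    if (template$strand == "OT") {
      out$gstart <- template$offset + out$start - 1
      out$gend <- template$offset + out$end
    } else {  # flipped space: template position i sits at genomic end - i
      out$gstart <- template$source_end - out$end
      out$gend <- template$source_end - out$start + 1
    }
  }
  out
}

#' Primer-pair cross-compatibility report
#'
#' Checks (a) melting-temperature difference (fail at `max_tm_diff` or
#' above), (b) the longest ungapped complementary run anywhere between the
#' two oligos (fail above `dimer_run_max`), (c) the longest complementary
#' run anchored at either 3' end (fail above `dimer_run_3p_max`; 3'-end
#' duplexes are extensible by polymerase and the main primer-dimer source),
#' and (d) self-complementarity of each oligo (hairpin/self-dimer proxy;
#' fail at `self_run_max` or above).
#'
#' @param fwd,rev One-row `data.frame`s (or lists) with `sequence` and `tm`,
#'   as produced by [enumerate_primers()].
#' @param constraints A [design_constraints()].
#' @return A one-row `data.frame`: `tm_diff`, `dimer_run`, `dimer_run_3p`,
#'   `self_run_fwd`, `self_run_rev`, per-check logical `pass_*` columns and
#'   overall `pass`.
#' @export
check_pair_compatibility <- function(fwd, rev,
                                     constraints = design_constraints()) {
  tm_diff <- abs(fwd$tm - rev$tm)
  cross <- .comp_runs(fwd$sequence, rev$sequence)
  cross_rev <- .comp_runs(rev$sequence, fwd$sequence)
  dimer_run <- max(cross$max, cross_rev$max)
  dimer_run_3p <- max(cross$max_end_a, cross_rev$max_end_a)
  self_f <- .comp_runs(fwd$sequence, fwd$sequence)$max
  self_r <- .comp_runs(rev$sequence, rev$sequence)$max
  out <- data.frame(
    tm_diff = tm_diff, dimer_run = dimer_run, dimer_run_3p = dimer_run_3p,
    self_run_fwd = self_f, self_run_rev = self_r,
    pass_tm = tm_diff < constraints$max_tm_diff,
    pass_dimer = dimer_run <= constraints$dimer_run_max,
    pass_dimer_3p = dimer_run_3p <= constraints$dimer_run_3p_max,
    pass_self = self_f < constraints$self_run_max &
      self_r < constraints$self_run_max)
  out$pass <- out$pass_tm & out$pass_dimer & out$pass_dimer_3p & out$pass_self
  out
}

#' Design ranked MSP primer pairs for a predicted region
#'
#' Extracts the region span plus `flank` nt of reference context, builds the
#' methylated-allele bisulfite template, enumerates forward candidates over
#' the left flank through the predicted forward site (+5 nt boundary slack)
#' and reverse candidates from the predicted reverse site (-5 nt) through
#' the right flank, then applies the hard filters: amplicon length bounds,
#' `min_amplicon_cpg`, Tm difference, and the full compatibility screen.
#' Survivors are ranked (descending) by a deterministic score rewarding at
#' least `ideal_converted_c` converted Cs in the amplicon, both primers
#' ending on C, more amplicon CpGs, and GC close to 60%; ties break by
#' shorter amplicon, then leftmost forward start, then leftmost reverse end.
#'
#' @param region One-row MSP region `data.frame` (columns `chrom`, `start`,
#'   `end`, optionally the `fwd_*`/`rev_*` site columns).
#' @param reference A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param constraints A [design_constraints()].
#' @param strand Template strand, `"OT"` (default) or `"OB"`.
#' @return Ranked `data.frame` of pairs (sequences, template and genomic
#'   coordinates, lengths, GC, Tm, CpG/converted-C counts, compatibility
#'   metrics, `rank_score`), with attribute `diagnostics`: candidate and
#'   per-filter failure counts. Empty with diagnostics when nothing passes.
#' @export
design_primer_pairs <- function(region, reference,
                                constraints = design_constraints(),
                                strand = c("OT", "OB")) {
  strand <- match.arg(strand)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  chrom_names <- sub("\\s.*$", "", names(reference))
  k <- match(region$chrom, chrom_names)
  if (is.na(k)) .stopf("chromosome '%s' not in reference", region$chrom)
  chrom_len <- Biostrings::width(reference)[k]
  tstart <- max(0, region$start - constraints$flank)   # 0-based
  tend <- min(chrom_len, region$end + constraints$flank)
  seq <- as.character(Biostrings::subseq(reference[[k]], tstart + 1, tend))
  template <- bisulfite_convert(seq, "methylated", strand, offset = tstart)
  tlen <- nchar(seq)
  # genomic -> template coordinates (1-based), honoring OB flip
  to_tpl <- function(g0) if (strand == "OT") g0 - tstart + 1 else tend - g0
  has_sites <- all(c("fwd_end", "rev_start") %in% names(region)) &&
    !is.na(region$fwd_end) && !is.na(region$rev_start)
  if (has_sites) {
    b1 <- sort(c(to_tpl(region$start), to_tpl(region$fwd_end - 1)))
    b2 <- sort(c(to_tpl(region$rev_start), to_tpl(region$end - 1)))
    if (strand == "OB") { tmp <- b1; b1 <- b2; b2 <- tmp }
    left_win <- c(1L, min(tlen, b1[2] + 5L))
    right_win <- c(max(1L, b2[1] - 5L), tlen)
  } else {
    mid <- to_tpl(floor((region$start + region$end) / 2))
    left_win <- c(1L, max(1L, min(tlen, mid)))
    right_win <- c(max(1L, min(tlen, mid)), tlen)
  }
  fwd <- enumerate_primers(template, left_win, "fwd", constraints)
  rev <- enumerate_primers(template, right_win, "rev", constraints)
  diag <- list(n_fwd_candidates = nrow(fwd), n_rev_candidates = nrow(rev),
               fail_orientation = 0L, fail_amplicon_len = 0L,
               fail_amplicon_cpg = 0L, fail_tm_diff = 0L, fail_compat = 0L)
  out <- .empty_pairs()
  if (nrow(fwd) && nrow(rev)) {
    # vectorized cheap filters over the full cross join ...
    i <- rep(seq_len(nrow(fwd)), each = nrow(rev))
    j <- rep.int(seq_len(nrow(rev)), nrow(fwd))
    ok <- rev$start[j] > fwd$end[i]
    diag$fail_orientation <- sum(!ok)
    i <- i[ok]; j <- j[ok]
    amp_len <- rev$end[j] - fwd$start[i] + 1L
    ok <- amp_len >= constraints$min_amplicon_len &
      amp_len <= constraints$max_amplicon_len
    diag$fail_amplicon_len <- sum(!ok)
    i <- i[ok]; j <- j[ok]; amp_len <- amp_len[ok]
    # CpGs with the full dinucleotide inside [fwd_start, rev_end]
    cpg_sorted <- sort(template$cpg_positions)
    n_cpg_upto <- function(x) findInterval(x, cpg_sorted)
    amp_cpg <- n_cpg_upto(rev$end[j] - 1L) - n_cpg_upto(fwd$start[i] - 1L)
    ok <- amp_cpg >= constraints$min_amplicon_cpg
    diag$fail_amplicon_cpg <- sum(!ok)
    i <- i[ok]; j <- j[ok]; amp_len <- amp_len[ok]; amp_cpg <- amp_cpg[ok]
    tm_diff <- abs(fwd$tm[i] - rev$tm[j])
    ok <- tm_diff < constraints$max_tm_diff
    diag$fail_tm_diff <- sum(!ok)
    i <- i[ok]; j <- j[ok]; amp_len <- amp_len[ok]; amp_cpg <- amp_cpg[ok]
    # ... then the dimer screen (dynamic programming) on survivors only,
    # with self-complementarity cached per candidate
    if (length(i)) {
      self_f <- vapply(fwd$sequence, function(s) .comp_runs(s, s)$max, 0L)
      self_r <- vapply(rev$sequence, function(s) .comp_runs(s, s)$max, 0L)
      ok <- logical(length(i))
      dimer_run <- integer(length(i)); dimer_3p <- integer(length(i))
      for (k in seq_along(i)) {
        if (self_f[i[k]] >= constraints$self_run_max ||
            self_r[j[k]] >= constraints$self_run_max) next
        cross <- .comp_runs(fwd$sequence[i[k]], rev$sequence[j[k]])
        back <- .comp_runs(rev$sequence[j[k]], fwd$sequence[i[k]])
        dimer_run[k] <- max(cross$max, back$max)
        dimer_3p[k] <- max(cross$max_end_a, back$max_end_a)
        ok[k] <- dimer_run[k] <= constraints$dimer_run_max &&
          dimer_3p[k] <= constraints$dimer_run_3p_max
      }
      diag$fail_compat <- sum(!ok)
      keep <- which(ok)
      if (length(keep)) {
        i <- i[keep]; j <- j[keep]
        conv_sorted <- sort(template$converted_positions)
        amp_conv <- findInterval(rev$end[j], conv_sorted) -
          findInterval(fwd$start[i] - 1L, conv_sorted)
        out <- data.frame(
          chrom = region$chrom,
          fwd_seq = fwd$sequence[i], rev_seq = rev$sequence[j],
          fwd_start = fwd$start[i], fwd_end = fwd$end[i],
          rev_start = rev$start[j], rev_end = rev$end[j],
          fwd_gstart = fwd$gstart[i], fwd_gend = fwd$gend[i],
          rev_gstart = rev$gstart[j], rev_gend = rev$gend[j],
          amplicon_len = amp_len[keep], amplicon_n_cpg = amp_cpg[keep],
          amplicon_n_converted_c = amp_conv,
          fwd_len = fwd$length[i], rev_len = rev$length[j],
          fwd_gc = fwd$gc_pct[i], rev_gc = rev$gc_pct[j],
          fwd_tm = fwd$tm[i], rev_tm = rev$tm[j],
          fwd_n_cpg = fwd$n_cpg[i], rev_n_cpg = rev$n_cpg[j],
          fwd_n_converted_c = fwd$n_converted_c[i],
          rev_n_converted_c = rev$n_converted_c[j],
          fwd_ends_on_c = fwd$ends_on_c[i],
          rev_ends_on_c = rev$ends_on_c[j],
          tm_diff = abs(fwd$tm[i] - rev$tm[j]),
          dimer_run = dimer_run[keep], dimer_run_3p = dimer_3p[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(out)) {
    gc_prox <- 1 - (abs(out$fwd_gc - 60) + abs(out$rev_gc - 60)) / 2 / 40
    out$rank_score <- 2 * (out$amplicon_n_converted_c >=
                             constraints$ideal_converted_c) +
      0.5 * out$fwd_ends_on_c + 0.5 * out$rev_ends_on_c +
      0.1 * out$amplicon_n_cpg + gc_prox
    out <- out[order(-out$rank_score, out$amplicon_len, out$fwd_start,
                     out$rev_end), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "diagnostics") <- diag
  attr(out, "template") <- template
  out
}

.empty_pairs <- function() {
  cols <- c("chrom", "fwd_seq", "rev_seq", "fwd_start", "fwd_end", "rev_start",
            "rev_end", "fwd_gstart", "fwd_gend", "rev_gstart", "rev_gend",
            "amplicon_len", "amplicon_n_cpg", "amplicon_n_converted_c",
            "fwd_len", "rev_len", "fwd_gc", "rev_gc", "fwd_tm", "rev_tm",
            "fwd_n_cpg", "rev_n_cpg", "fwd_n_converted_c", "rev_n_converted_c",
            "fwd_ends_on_c", "rev_ends_on_c", "tm_diff", "dimer_run",
            "dimer_run_3p")
  out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  out$rank_score <- numeric(0); out$rank <- integer(0)
  out
}

#' Design ranked hydrolysis probes for a primer pair
#'
#' Candidates are substrings of the converted template on the forward
#' primer's strand, 20-30 nt long, starting at most `probe_max_offset` nt
#' after the forward primer's 3' end and ending before the reverse primer's
#' binding site. Hard filters: no 5' guanine, no reverse-complement
#' palindrome of `probe_palindrome_min`+ nt, Tm inside
#' `max(primer Tms) + probe_tm_above`, and no complementarity run above
#' `dimer_run_max` against either primer or itself. Ranked by GC proximity
#' to `probe_gc_target`, ties by shorter length then leftmost start.
#'
#' @param pair One-row pair `data.frame` from [design_primer_pairs()].
#' @param template The `bisulfite_template` the pair was designed on (also
#'   attached to the pair table as attribute `"template"`).
#' @param constraints A [design_constraints()].
#' @param label Reporter dye label recorded with each probe (default FAM).
#' @return Ranked probe `data.frame` (`sequence`, `start`, `end`, `length`,
#'   `offset_from_fwd`, `gc_pct`, `tm`, `label`, `rank`), with attribute
#'   `diagnostics` counting candidates and per-filter failures.
#' @export
design_probe <- function(pair, template, constraints = design_constraints(),
                         label = "FAM") {
  stopifnot(inherits(template, "bisulfite_template"))
  tm_primer <- max(pair$fwd_tm, pair$rev_tm)
  tm_lo <- tm_primer + constraints$probe_tm_above[1]
  tm_hi <- tm_primer + constraints$probe_tm_above[2]
  diag <- list(n_candidates = 0L, fail_5prime_g = 0L, fail_palindrome = 0L,
               fail_tm_band = 0L, fail_dimer = 0L)
  rows <- list()
  first_start <- pair$fwd_end + 1L
  for (s in first_start:(first_start + constraints$probe_max_offset)) {
    for (L in constraints$probe_min_len:constraints$probe_max_len) {
      e <- s + L - 1L
      if (e >= pair$rev_start) next   # must stay inside the amplicon interior
      diag$n_candidates <- diag$n_candidates + 1L
      seq <- substr(template$converted_seq, s, e)
      if (substr(seq, 1L, 1L) == "G") {
        diag$fail_5prime_g <- diag$fail_5prime_g + 1L; next
      }
      if (is_palindrome(seq, constraints$probe_palindrome_min)) {
        diag$fail_palindrome <- diag$fail_palindrome + 1L; next
      }
      tm <- melting_temperature(seq, constraints$tm_method)
      if (tm < tm_lo || tm > tm_hi) {
        diag$fail_tm_band <- diag$fail_tm_band + 1L; next
      }
      run_f <- .comp_runs(seq, pair$fwd_seq)$max
      run_r <- .comp_runs(seq, pair$rev_seq)$max
      run_s <- .comp_runs(seq, seq)$max
      if (max(run_f, run_r, run_s) > constraints$dimer_run_max) {
        diag$fail_dimer <- diag$fail_dimer + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq, start = s, end = e, length = L,
        offset_from_fwd = s - pair$fwd_end - 1L,
        gc_pct = gc_content(seq), tm = tm, label = label,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sequence = character(), start = integer(), end = integer(),
                  length = integer(), offset_from_fwd = integer(),
                  gc_pct = numeric(), tm = numeric(), label = character(),
                  stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- out[order(abs(out$gc_pct - constraints$probe_gc_target),
                     out$length, out$start), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "diagnostics") <- diag
  out
}
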