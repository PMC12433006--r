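test_that("bisulfite conversion follows the CpG retention rules", {
  t1 <- bisulfite_convert("ACGTCC", "methylated", "OT")
  expect_equal(t1$converted_seq, "ACGTTT")
  expect_equal(t1$cpg_positions, 2L)
  expect_equal(t1$converted_positions, c(5L, 6L))

  expect_equal(bisulfite_convert("ACGTCC", "unmethylated", "OT")$converted_seq,
               "ATGTTT")
  expect_equal(bisulfite_convert("GGGG", "methylated")$converted_seq, "GGGG")
  # OB operates on the reverse complement
  ob <- bisulfite_convert("ACGTCC", "methylated", "OB")
  expect_equal(ob$source_seq, "GGACGT")
  expect_equal(ob$converted_seq, "GGACGT")  # only CpG C, retained
  expect_error(bisulfite_convert("ACGX"), "invalid characters")
})

test_that("conversion properties hold on random sequences", {
  withr::local_seed(99)
  for (rep in 1:50) {
    seq <- rand_dna(sample(10:200, 1), runif(1, 0.2, 0.8))
    chars <- strsplit(seq, "")[[1]]
    cpg <- which(chars == "C" & c(chars[-1], "") == "G")

    um <- bisulfite_convert(seq, "unmethylated")
    expect_false(grepl("C", um$converted_seq, fixed = TRUE))

    me <- bisulfite_convert(seq, "methylated")
    conv_chars <- strsplit(me$converted_seq, "")[[1]]
    expect_equal(which(conv_chars == "C"), cpg)
    expect_equal(sort(c(me$cpg_positions, me$converted_positions)),
                 which(chars == "C"))
    expect_equal(nchar(me$converted_seq), nchar(seq))
  }
})

test_that("gc_content and melting_temperature match hand values", {
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AATT"), 0)
  expect_error(gc_content(""), "empty")

  expect_equal(melting_temperature("ACGT"), 12)
  expect_equal(melting_temperature("AAAA"), 8)
  expect_equal(melting_temperature("GCGC"), 16)
  # nearest-neighbor stays in a plausible range for a primer-like oligo
  nn <- melting_temperature("ACGTACGTACGTACGTACGT", "nearest_neighbor")
  expect_true(nn > 30 && nn < 80)
})

test_that("is_palindrome detects reverse-complement palindromes", {
  expect_true(is_palindrome("GAATTC", 6))       # EcoRI site
  expect_false(is_palindrome("AAAAAA", 6))
  expect_false(is_palindrome("ACGT", 6))        # too short
  expect_true(is_palindrome("TTGAATTCTT", 6))   # embedded
})

test_that("enumerate_primers equals the substring brute force", {
  withr::local_seed(21)
  cons <- design_constraints()
  for (rep in 1:12) {
    seq <- rand_dna(sample(80:300, 1), 0.6)
    tpl <- bisulfite_convert(seq, "methylated")
    win <- c(1, nchar(seq))
    for (orient in c("fwd", "rev")) {
      got <- enumerate_primers(tpl, win, orient, cons)
      got <- got[order(got$start, got$end), , drop = FALSE]
      want <- oracle_enumerate(tpl, win, orient, cons)
      expect_equal(got[c("start", "end", "sequence", "n_cpg",
                         "n_converted_c")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("enumerate_primers edge cases: no CpGs, vacuous constraints", {
  no_cpg <- bisulfite_convert(paste(rep("AT", 40), collapse = ""))
  expect_equal(nrow(enumerate_primers(no_cpg)), 0L)

  # all-passing template: every substring counted
  vac <- design_constraints(min_cpg = 0, min_converted_c = 0,
                            gc_min = 0, gc_max = 100, tm_min = -Inf,
                            tm_max = Inf)
  seq <- rand_dna(60, 0.5)
  tpl <- bisulfite_convert(seq, "methylated")
  win_len <- 40
  got <- enumerate_primers(tpl, c(1, win_len), "fwd", vac)
  expect_equal(nrow(got), sum(win_len - (14:22) + 1))
})

test_that("pair compatibility flags Tm gaps and 3' complementarity", {
  cons <- design_constraints()
  mk <- function(seq, tm) list(sequence = seq, tm = tm)
  # Tm difference of 6 fails the < 5 rule
  rep1 <- check_pair_compatibility(mk("AAAAAAAAAAAAAA", 60),
                                   mk("AAAAAAAAAAAAAA", 66), cons)
  expect_false(rep1$pass_tm)

  # rev ends 3' on ACGTA, fwd contains TACGT -> 5-base 3'-anchored run
  fwd <- mk("AAAATACGTAAAAA", 40)
  rev <- mk("TTTTTTTTTACGTA", 38)
  rep2 <- check_pair_compatibility(fwd, rev, cons)
  expect_gte(rep2$dimer_run_3p, 5)
  expect_false(rep2$pass_dimer_3p)
  expect_equal(rep2$dimer_run_3p,
               max(oracle_comp_run(rev$sequence, fwd$sequence, TRUE),
                   oracle_comp_run(fwd$sequence, rev$sequence, TRUE)))

  # poly-A oligos cannot anneal to each other at all
  pa <- mk(strrep("A", 16), 32)
  rep3 <- check_pair_compatibility(pa, pa, cons)
  expect_equal(rep3$dimer_run, 0L)
  expect_equal(rep3$self_run_fwd, 0L)
  expect_true(rep3$pass_dimer && rep3$pass_dimer_3p && rep3$pass_self)
})

test_that("complementarity runs match the naive oracle on random oligos", {
  withr::local_seed(31)
  for (rep in 1:20) {
    a <- rand_dna(sample(10:25, 1))
    b <- rand_dna(sample(10:25, 1))
    runs <- nanomsp:::.comp_runs(a, b)
    expect_equal(runs$max, oracle_comp_run(a, b))
    expect_equal(runs$max_end_a, oracle_comp_run(a, b, anchor_3p = TRUE))
  }
})

# a synthetic fully methylation-eligible island: CpG-dense GC-rich center
make_design_fixture <- function(seed = 5) {
  withr::with_seed(seed, {
    unit <- function(n) paste(replicate(n,
      paste0("CG", rand_dna(4, 0.5))), collapse = "")
    paste0(rand_dna(220, 0.35), unit(40), rand_dna(220, 0.35))
  })
}

test_that("design_primer_pairs emits only constraint-satisfying pairs", {
  seq <- make_design_fixture()
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chrF"
  region <- data.frame(chrom = "chrF", start = 260, end = 420,
                       fwd_start = 260, fwd_end = 280,
                       rev_start = 400, rev_end = 420,
                       fwd_cpgs = "", rev_cpgs = "", score = 1,
                       stringsAsFactors = FALSE)
  cons <- design_constraints(flank = 60)
  pairs <- design_primer_pairs(region, ref, cons)
  expect_gt(nrow(pairs), 0)
  check <- rbind(utils::head(pairs, 20), utils::tail(pairs, 20))
  expect_true(oracle_validate_pairs(check, attr(pairs, "template"), cons))
  # deterministic total order: identical rerun, strictly ranked
  again <- design_primer_pairs(region, ref, cons)
  expect_identical(pairs, again)
  expect_equal(pairs$rank, seq_len(nrow(pairs)))
})

test_that("flanks without enough CpGs yield empty output plus diagnostics", {
  seq <- paste0(rand_dna(300, 0.4), "CG", rand_dna(300, 0.4))
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chrF"
  region <- data.frame(chrom = "chrF", start = 290, end = 320,
                       fwd_start = 290, fwd_end = 308, rev_start = 302,
                       rev_end = 320, fwd_cpgs = "", rev_cpgs = "",
                       score = 1, stringsAsFactors = FALSE)
  pairs <- design_primer_pairs(region, ref)
  expect_equal(nrow(pairs), 0L)
  diag <- attr(pairs, "diagnostics")
  expect_true(is.list(diag) && all(c("n_fwd_candidates", "fail_amplicon_cpg")
                                   %in% names(diag)))
})

test_that("OT and OB designs map to the same genomic amplicons on a
           palindromic fixture", {
  src <- palindromic_source(80, 0.6, seed = 13)
  n <- nchar(src)
  ref <- Biostrings::DNAStringSet(src); names(ref) <- "chrP"
  # symmetric region around the palindrome center with mirrored sites
  fwd_start <- n / 2 - 60; fwd_end <- fwd_start + 20
  rev_end <- n - fwd_start; rev_start <- n - fwd_end
  region <- data.frame(chrom = "chrP", start = fwd_start, end = rev_end,
                       fwd_start = fwd_start, fwd_end = fwd_end,
                       rev_start = rev_start, rev_end = rev_end,
                       fwd_cpgs = "", rev_cpgs = "", score = 1,
                       stringsAsFactors = FALSE)
  # a palindromic A/T/CpG fixture is inherently self-complementary and has
  # no convertible (non-CpG) cytosines; disable the dimer screens and the
  # converted-C requirement to isolate the coordinate-mapping property
  cons <- design_constraints(dimer_run_max = 999, dimer_run_3p_max = 999,
                             self_run_max = 999, min_converted_c = 0,
                             flank = 60, min_len = 16, max_len = 18,
                             tm_min = 52, tm_max = 62)
  ot <- design_primer_pairs(region, ref, cons, strand = "OT")
  ob <- design_primer_pairs(region, ref, cons, strand = "OB")
  expect_gt(nrow(ot), 0)
  expect_equal(nrow(ot), nrow(ob))
  amp <- function(p) sort(paste(pmin(p$fwd_gstart, p$rev_gstart),
                                pmax(p$fwd_gend, p$rev_gend)))
  expect_equal(amp(ot), amp(ob))
})

test_that("probe design applies the 5'G, palindrome and Tm-band filters", {
  seq <- make_design_fixture(seed = 8)
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chrF"
  region <- data.frame(chrom = "chrF", start = 260, end = 420,
                       fwd_start = 260, fwd_end = 280,
                       rev_start = 400, rev_end = 420,
                       fwd_cpgs = "", rev_cpgs = "", score = 1,
                       stringsAsFactors = FALSE)
  cons <- design_constraints(flank = 60)
  pairs <- design_primer_pairs(region, ref, cons)
  expect_gt(nrow(pairs), 0)
  tpl <- attr(pairs, "template")
  probes <- design_probe(pairs[1, ], tpl, cons)
  diag <- attr(probes, "diagnostics")
  expect_gt(diag$n_candidates, 0)
  if (nrow(probes)) {
    expect_true(oracle_validate_probes(probes, pairs[1, ], tpl, cons))
    expect_false(any(substr(probes$sequence, 1, 1) == "G"))
    expect_true(all(probes$tm >= max(pairs$fwd_tm[1], pairs$rev_tm[1]) + 5 &
                      probes$tm <= max(pairs$fwd_tm[1], pairs$rev_tm[1]) + 10))
  }
})

test_that("an amplicon engineered for exactly one probe returns it", {
  # hand-built converted-space amplicon: fwd primer, then a single valid
  # probe window, then Gs (rejected as probe starts), then rev site
  fwd_seq <- "ATTGTATGTCGTATTG"                 # 16 nt
  probe_seq <- "ATCGGATTATTCGGTATTACGGAT"       # 24 nt, starts A, Tm 70
  spacer <- strrep("G", 12)
  rev_bind <- "ATTACGTTATTGTTAG"
  src <- paste0("TT", fwd_seq, probe_seq, spacer, rev_bind, "TT")
  # the string is already conversion-stable for the methylated allele
  # (every C sits in a CpG)
  tpl <- bisulfite_convert(src, "methylated")
  expect_equal(tpl$converted_seq, src)
  fwd_start <- 3L
  pair <- data.frame(
    fwd_seq = fwd_seq, rev_seq = revcomp_chr(rev_bind),
    fwd_start = fwd_start, fwd_end = fwd_start + nchar(fwd_seq) - 1L,
    rev_start = fwd_start + nchar(fwd_seq) + nchar(probe_seq) +
      nchar(spacer),
    rev_end = fwd_start + nchar(fwd_seq) + nchar(probe_seq) +
      nchar(spacer) + nchar(rev_bind) - 1L,
    fwd_tm = melting_temperature(fwd_seq),
    rev_tm = melting_temperature(rev_bind), stringsAsFactors = FALSE)
  cons <- design_constraints(probe_tm_above = c(
    melting_temperature(probe_seq) - max(pair$fwd_tm, pair$rev_tm) - 1,
    melting_temperature(probe_seq) - max(pair$fwd_tm, pair$rev_tm) + 1),
    probe_min_len = 24, probe_max_len = 24, probe_max_offset = 0)
  probes <- design_probe(pair, tpl, cons)
  expect_equal(nrow(probes), 1L)
  expect_equal(probes$sequence, probe_seq)
})
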