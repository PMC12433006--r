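#' In-silico bisulfite conversion of a DNA sequence
#'
#' Bisulfite treatment deaminates unmethylated cytosines to uracil (read as
#' thymine after PCR) while 5-methylcytosine is retained as cytosine. For
#' the methylated-allele template, every C outside a CpG context is
#' converted and every CpG C is retained; for the unmethylated allele, every
#' C is converted. `strand = "OB"` designs on the original bottom strand:
#' the input is reverse-complemented first and all positions refer to that
#' flipped sequence.
#'
#' @param seq DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive). `N`
#'   passes through unchanged and never counts as a CpG partner.
#' @param allele `"methylated"` (CpG Cs retained) or `"unmethylated"`
#'   (all Cs converted).
#' @param strand `"OT"` (original top: operate on `seq` as given) or `"OB"`
#'   (operate on the reverse complement).
#' @param offset Optional 0-based genomic start of `seq` on the forward
#'   strand, kept for coordinate mapping of designed oligos.
#' @return An object of class `bisulfite_template`: a list with
#'   `source_seq` (the operated-on strand), `converted_seq`, `strand`,
#'   `allele`, `cpg_positions` (1-based positions of retained Cs),
#'   `converted_positions` (1-based positions of C-to-T conversions),
#'   `offset`, `source_end` (0-based genomic end, for OB mapping).
#' @export
bisulfite_convert <- function(seq, allele = c("methylated", "unmethylated"),
                              strand = c("OT", "OB"), offset = NA_real_) {
  allele <- match.arg(allele)
  strand <- match.arg(strand)
  seq <- .check_dna(seq)
  work <- if (strand == "OB") revcomp(seq) else seq
  chars <- strsplit(work, "")[[1]]
  c_pos <- which(chars == "C")
  in_cpg <- c_pos[c_pos < length(chars) & chars[pmin(c_pos + 1L, length(chars))] == "G"]
  retained <- if (allele == "methylated") in_cpg else integer(0)
  converted <- setdiff(c_pos, retained)
  chars[converted] <- "T"
  structure(list(source_seq = work, converted_seq = paste(chars, collapse = ""),
                 strand = strand, allele = allele,
                 cpg_positions = as.integer(retained),
                 converted_positions = as.integer(converted),
                 offset = offset,
                 source_end = if (is.na(offset)) NA_real_
                              else offset + nchar(work)),
            class = "bisulfite_template")
}

#' @export
print.bisulfite_template <- function(x, ...) {
  cat(sprintf("bisulfite template (%s allele, %s strand), %d nt\n",
              x$allele, x$strand, nchar(x$source_seq)))
  cat(sprintf("  retained CpG Cs: %d; converted Cs: %d\n",
              length(x$cpg_positions), length(x$converted_positions)))
  invisible(x)
}

#' GC content of a sequence in percent
#'
#' `N`s count toward the length but not toward GC.
#'
#' @param seq Non-empty DNA string.
#' @return `100 * (#G + #C) / length`.
#' @export
gc_content <- function(seq) {
  seq <- .check_dna(seq)
  if (nchar(seq) == 0L) .stopf("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Oligo melting temperature
#'
#' `wallace`: the Wallace rule `2(A+T) + 4(G+C)` degrees C, the standard
#' quick estimate for short primers and the package default (exact and
#' deterministic). `nearest_neighbor`: SantaLucia (1998) unified
#' nearest-neighbor thermodynamics with 50 mM monovalent salt and 500 nM
#' oligo, for users wanting a thermodynamic estimate.
#'
#' @param seq Non-empty DNA string over `A`,`C`,`G`,`T`.
#' @param method `"wallace"` (default) or `"nearest_neighbor"`.
#' @return Temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, method = c("wallace", "nearest_neighbor")) {
  method <- match.arg(method)
  seq <- .check_dna(seq, allow_n = FALSE)
  if (nchar(seq) == 0L) .stopf("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  if (method == "wallace")
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  .tm_nearest_neighbor(chars)
}

# SantaLucia 1998 unified parameters: dH kcal/mol, dS cal/(mol K)
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

.tm_nearest_neighbor <- function(chars, conc = 5e-7, na = 0.05) {
  if (length(chars) < 2L) .stopf("nearest-neighbor Tm needs >= 2 nt")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  steps <- paste0(chars[-length(chars)], chars[-1L])
  canon <- ifelse(steps %in% names(.nn_dh), steps,
                  vapply(steps, function(s) {
                    r <- paste0(comp[substr(s, 2, 2)], comp[substr(s, 1, 1)])
                    r
                  }, ""))
  dh <- sum(.nn_dh[canon])
  ds <- sum(.nn_ds[canon])
  # initiation with terminal penalties
  for (term in chars[c(1L, length(chars))]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds + (-2.8) }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(chars) - 1) * log(na)
  dh * 1000 / (ds + 1.987 * log(conc / 4)) - 273.15
}

#' Does a sequence contain a reverse-complement palindrome?
#'
#' @param seq DNA string.
#' @param min_len Minimum palindrome length (default 6; e.g. `GAATTC`).
#' @return `TRUE` iff some substring of length `>= min_len` equals its own
#'   reverse complement.
#' @export
is_palindrome <- function(seq, min_len = 6L) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  if (n < min_len) return(FALSE)
  # reverse-complement palindromes have even length; a longer one always
  # contains one of the minimal even length
  L <- if (min_len %% 2 == 0) min_len else min_len + 1L
  if (n < L) return(FALSE)
  rc <- revcomp(seq)  # substring s..e is an RC-palindrome iff it equals the
                      # mirrored substring of the whole-sequence RC
  for (s in 1:(n - L + 1L)) {
    e <- s + L - 1L
    sub <- substr(seq, s, e)
    if (!grepl("N", sub, fixed = TRUE) &&
        sub == substr(rc, n - e + 1L, n - s + 1L)) return(TRUE)
  }
  FALSE
}

# Longest ungapped complementary run between oligos a and b (both 5'->3'),
# i.e. longest common substring of a and revcomp(b); also the longest such
# run ending exactly at a's 3' terminal base.
.comp_runs <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(revcomp(toupper(b)), "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(list(max = 0L, max_end_a = 0L))
  best <- 0L; best_end <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match_j <- which(y == x[i])
    for (j in match_j) cur[j] <- (if (j > 1L) prev[j - 1L] else 0L) + 1L
    if (length(match_j)) {
      mx <- max(cur)
      if (mx > best) best <- mx
      if (i == n) best_end <- max(cur)
    }
    prev <- cur
  }
  list(max = best, max_end_a = best_end)
}
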