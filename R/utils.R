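# Internal helpers shared across modules.

# gz-transparent line reader: gzfile() reads plain text and gzip alike.
read_lines_gz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# numeric coercion that refuses NAs introduced by coercion
.as_num <- function(x, what, line = NULL) {
  suppressWarnings(out <- as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    where <- if (is.null(line)) bad[1] else line[bad[1]]
    .stopf("non-numeric %s at line %d: '%s'", what, where, x[bad[1]])
  }
  out
}

# plain-character reverse complement; hot path, so no Biostrings round-trip
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", seq), "")[[1]]),
        collapse = "")
}

.check_dna <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), strsplit(alphabet, "")[[1]])
  if (length(bad))
    .stopf("invalid characters in sequence: %s", paste(bad, collapse = ", "))
  seq
}

# deterministic sub-seed derivation, kept below 2^31
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
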