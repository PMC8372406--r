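# Low-level sequence and interval helpers shared across modules.
# Internal coordinates are 0-based half-open throughout; conversion to the
# 1-based inclusive conventions of GenBank/GFF3 happens only at I/O
# boundaries.  An interval on the circle is stored as c(start, end) with
# 0 <= start < n and start < end <= start + n; end > n means it wraps.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

complement_chars <- function(v) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v])
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# substring of a circular sequence; interval may wrap (end > n)
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 0, start < n, end > start, end <= start + n)
  if (end <= n) {
    substr(seq, start + 1, end)
  } else {
    paste0(substr(seq, start + 1, n), substr(seq, 1, end - n))
  }
}

interval_len <- function(iv) iv[2] - iv[1]

# does circular interval iv (0-based half-open, possibly wrapping) contain
# position p (0 <= p < n)?
interval_contains <- function(iv, p, n) {
  if (iv[2] <= n) return(p >= iv[1] && p < iv[2])
  p >= iv[1] || p < (iv[2] - n)
}

# positions covered by a (possibly wrapping) interval, 0-based
interval_positions <- function(iv, n) {
  (seq.int(iv[1], iv[2] - 1L)) %% n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize a gene symbol for cross-annotation comparison: case-insensitive
# except the canonical camel-case, trailing copy suffixes stripped
# ("rpl2-A", "rpl2_1" -> "rpl2"); tRNAs keyed by isotype+anticodon when given
normalize_gene_name <- function(x) {
  x <- sub("[-_]([A-Za-z]|[0-9]+)$", "", x)
  x <- sub("^TRN", "trn", x)
  ifelse(grepl("^trn", x, ignore.case = TRUE), x, tolower(x))
}

# stop codons on the coding strand
STOP_CODONS <- c("TAA", "TAG", "TGA")

NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                         paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# split a coding sequence into codons
codon_split <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

has_internal_stop <- function(cds) {
  if (nchar(cds) < 6 || nchar(cds) %% 3 != 0) return(FALSE)
  cod <- codon_split(cds)
  any(cod[-length(cod)] %in% STOP_CODONS)
}
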