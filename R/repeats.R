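# Repeat profiling with the three classes and parameter conventions of
# plastome surveys: perfect SSRs with per-motif-length copy thresholds,
# a simplified tandem-repeat scanner, and maximal dispersed repeats of the
# four kinds (Forward, Reverse, Complement, Palindromic) under a Hamming
# budget. Repeats are computed on the full genome including both IR copies,
# so an IR-scale Palindromic hit is expected.

as_seq <- function(x) {
  if (inherits(x, "plastome_record")) x$sequence else toupper(x)
}

#' Find simple sequence repeats (SSRs)
#'
#' Reports every maximal perfect run of a primitive 1-6 bp motif meeting the
#' copy threshold for its motif length, exactly once. Motifs are reported
#' as-literal (A and T are distinct classes, as are AT and TA); a run is
#' labelled by its leftmost phase. Runs spanning the circular origin are
#' detected.
#'
#' @param x A [plastome_record()] or DNA string.
#' @param thresholds Minimum copy numbers by motif length (defaults: 10 for
#'   mononucleotide, 6 for di, 5 for tri- through hexanucleotide).
#' @param circular Treat the sequence as circular (default: record's flag).
#' @return Data frame with `motif`, `copies`, `start` (0-based), `length`
#'   (full maximal run, including any partial trailing unit).
#' @export
find_ssrs <- function(x, thresholds = c(10, 6, 5, 5, 5, 5),
                      circular = NULL) {
  if (is.null(circular))
    circular <- if (inherits(x, "plastome_record")) x$circular else FALSE
  .ssr_scan_cpp(as_seq(x), as.integer(thresholds), isTRUE(circular))
}

#' Find tandem repeat arrays (simplified scanner)
#'
#' Scans every candidate period for runs of offset-`period` self-matches,
#' merges runs interrupted by up to 3 mismatch positions, builds a
#' per-phase majority consensus and scores the array as
#' `match * matches - mismatch * mismatches - indel * indel_bases` minus one
#' perfect unit's credit (so a perfect array of length T and period p scores
#' `match * (T - p)`). This is a documented simplification of the classic
#' heuristic tandem-repeat finder, not a bit-compatible reimplementation;
#' in particular the scanner itself introduces no indels, so an indel inside
#' an array splits it.
#'
#' @param x A [plastome_record()] or DNA string.
#' @param match,mismatch,indel Alignment weights (defaults 2, 7, 7).
#' @param min_score Minimum reported score (default 80).
#' @param max_period Maximum period size (default 500).
#' @param min_copies Minimum copy number of an array (default 2).
#' @return Data frame with `period`, `start` (0-based), `length`,
#'   `copy_number`, `score`, `consensus`.
#' @export
find_tandem <- function(x, match = 2, mismatch = 7, indel = 7,
                        min_score = 80, max_period = 500, min_copies = 2) {
  .tandem_scan_cpp(as_seq(x), as.integer(match), as.integer(mismatch),
                   as.integer(indel), as.integer(min_score),
                   as.integer(max_period), min_copies)
}

#' Find dispersed repeats
#'
#' Seed-and-extend search for maximal repeat pairs of the four kinds --
#' Forward (copy), Reverse (reversed copy), Complement (complemented copy)
#' and Palindromic (reverse complement) -- allowing up to `max_hamming`
#' substitutions (no indels). Hits shorter than `min_len` are dropped;
#' mirror duplicates and hits nested inside a longer hit of the same kind
#' are deduplicated. The result equals a brute-force enumeration over all
#' position pairs (`.dispersed_brute_cpp`, the test oracle).
#'
#' @param x A [plastome_record()] or DNA string.
#' @param min_len Minimum repeat length (default 30 bp).
#' @param max_hamming Mismatch budget (default 3).
#' @return Data frame with `kind`, `start1`, `start2` (0-based), `length`,
#'   `mismatches`.
#' @export
find_dispersed <- function(x, min_len = 30, max_hamming = 3) {
  .dispersed_scan_cpp(as_seq(x), as.integer(min_len), as.integer(max_hamming))
}
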