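# Core containers: plastome_record (circular annotated sequence) and
# gene_feature (named, stranded, possibly multi-exon annotation).

#' Create a gene feature
#'
#' A feature is a named annotation with one or more exon parts on a circular
#' genome. Parts are 0-based half-open intervals in transcription order; a
#' part may wrap the origin, in which case its end exceeds the genome length
#' (positions are taken modulo the length).
#'
#' @param name Gene symbol, e.g. `"rbcL"`, `"trnH-GUG"`.
#' @param category One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param strand `"+"` or `"-"`.
#' @param parts Integer matrix with columns `start`, `end` (0-based
#'   half-open), rows in transcription order.
#' @param pseudo Logical pseudogene flag (from annotation).
#' @return A `gene_feature` object.
#' @export
gene_feature <- function(name, category = c("CDS", "tRNA", "rRNA", "other"),
                         strand = c("+", "-"), parts, pseudo = FALSE) {
  category <- match.arg(category)
  strand <- match.arg(strand)
  if (is.vector(parts)) parts <- matrix(parts, ncol = 2, byrow = TRUE)
  storage.mode(parts) <- "integer"
  colnames(parts) <- c("start", "end")
  stopifnot(nzchar(name), nrow(parts) >= 1, all(parts[, 2] > parts[, 1]))
  structure(list(name = name, category = category, strand = strand,
                 parts = parts, pseudo = isTRUE(pseudo)),
            class = "gene_feature")
}

#' Create a plastome record
#'
#' The shared container for an annotated (circular) plastid genome. The
#' sequence is stored linearized at an explicit origin; features may wrap it.
#'
#' @param id Record identifier.
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param features List of [gene_feature()] annotations.
#' @param circular Logical; plastomes are circular molecules.
#' @param source Free-text provenance (file name, accession, "synthetic").
#' @return A `plastome_record`.
#' @export
plastome_record <- function(id, sequence, features = list(), circular = TRUE,
                            source = "") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  rec <- structure(list(id = as.character(id), sequence = sequence,
                        circular = isTRUE(circular), features = features,
                        source = source),
                   class = "plastome_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec) {
  n <- nchar(rec$sequence)
  for (f in rec$features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature")
    if (!nzchar(f$name)) stop("feature with empty name")
    if (any(f$parts[, 1] < 0) || any(f$parts[, 1] >= n))
      stop(sprintf("feature '%s': part start outside [0, length)", f$name))
    if (any(f$parts[, 2] <= f$parts[, 1]))
      stop(sprintf("feature '%s': empty part", f$name))
    if (any(f$parts[, 2] > f$parts[, 1] + n))
      stop(sprintf("feature '%s': part longer than genome", f$name))
    # parts non-overlapping within the feature
    if (nrow(f$parts) > 1) {
      cov <- unlist(lapply(seq_len(nrow(f$parts)), function(i)
        interval_positions(f$parts[i, ], n)))
      if (anyDuplicated(cov))
        stop(sprintf("feature '%s': overlapping parts", f$name))
    }
    if (f$category == "CDS" && !f$pseudo &&
        sum(f$parts[, 2] - f$parts[, 1]) < 3)
      stop(sprintf("CDS '%s' shorter than one codon", f$name))
  }
  invisible(rec)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features (%s)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$features), x$source))
  invisible(x)
}

feature_names <- function(rec) {
  vapply(rec$features, `[[`, character(1), "name")
}

feature_span <- function(f) {
  c(min(f$parts[, 1]), max(f$parts[, 2]))
}

# concatenated coding/mature sequence of a feature in transcription order
feature_sequence <- function(rec, f) {
  pieces <- vapply(seq_len(nrow(f$parts)), function(i)
    circ_substr(rec$sequence, f$parts[i, 1], f$parts[i, 2]), character(1))
  if (f$strand == "+") paste(pieces, collapse = "")
  else paste(revcomp(pieces), collapse = "")
}

# Rotate the record so that old coordinate `offset` becomes 0.
rotate_record <- function(rec, offset) {
  n <- nchar(rec$sequence)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(rec)
  rec$sequence <- paste0(substr(rec$sequence, offset + 1, n),
                         substr(rec$sequence, 1, offset))
  rec$features <- lapply(rec$features, function(f) {
    p <- f$parts
    s <- (p[, 1] - offset) %% n
    e <- s + (p[, 2] - p[, 1])
    f$parts <- cbind(start = as.integer(s), end = as.integer(e))
    f
  })
  rec
}

# Reverse-complement the whole record (origin maps to origin; coordinates
# reflect).
revcomp_record <- function(rec) {
  n <- nchar(rec$sequence)
  rec$sequence <- revcomp(rec$sequence)
  rec$features <- lapply(rec$features, function(f) {
    p <- f$parts
    # part [s, e) -> [n - e, n - s) (mod n for wrapping parts)
    s2 <- (n - p[, 2]) %% n
    e2 <- s2 + (p[, 2] - p[, 1])
    f$parts <- cbind(start = as.integer(s2), end = as.integer(e2))[
      rev(seq_len(nrow(p))), , drop = FALSE]
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
  rec
}
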