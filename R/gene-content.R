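# Gene content: classify each reference gene per genome as single-copy,
# IR-duplicated, pseudogene or lost; produce per-species category counts
# (every annotated copy counted, so IR expansion inflates counts) and a
# species x gene loss/pseudogenization matrix.

# longest open reading frame (ATG..stop, either strand, any frame) in bp
longest_orf <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    v <- seq_chars(s)
    n <- length(v)
    for (frame in 0:2) {
      idx <- seq.int(1 + frame, n - 2, by = 3)
      if (length(idx) < 2) next
      cod <- paste0(v[idx], v[idx + 1], v[idx + 2])
      open <- NA_integer_
      for (i in seq_along(cod)) {
        if (is.na(open) && cod[i] == "ATG") open <- i
        if (!is.na(open) && cod[i] %in% STOP_CODONS) {
          best <- max(best, (i - open + 1L) * 3L)
          open <- NA_integer_
        }
      }
    }
  }
  best
}

# interval between the nearest annotated reference-neighbours of `gene`
syntenic_interval <- function(record, gene, reference) {
  ord <- reference$name
  gi <- match(gene, ord)
  nm <- feature_names(record)
  prev_i <- NULL
  for (d in seq_len(length(ord) - 1)) {
    cand <- ord[((gi - 1 - d) %% length(ord)) + 1]
    if (cand %in% nm) { prev_i <- which(nm == cand)[1]; break }
  }
  next_i <- NULL
  for (d in seq_len(length(ord) - 1)) {
    cand <- ord[((gi - 1 + d) %% length(ord)) + 1]
    if (cand %in% nm) { next_i <- which(nm == cand)[1]; break }
  }
  if (is.null(prev_i) || is.null(next_i)) return(NULL)
  n <- nchar(record$sequence)
  a <- feature_span(record$features[[prev_i]])[2] %% n
  b <- feature_span(record$features[[next_i]])[1] %% n
  if (b < a) b <- b + n
  if (b - a < 3 || b - a > 20000) return(NULL)
  c(a, b)
}

#' Classify one gene in one genome
#'
#' Status rules: **lost** if no annotated copy exists and no open reading
#' frame of at least 30% of the reference length remains at the syntenic
#' position; **pseudo** if annotated as pseudo, the translated CDS has an
#' internal stop, the coding length is not a multiple of 3, or it is shorter
#' than 50% of the reference; **duplicated** if two or more copies are
#' annotated (flag `in_IR` when they fall in the inverted repeats); otherwise
#' **single**.
#'
#' @param record A [plastome_record()].
#' @param structure Its `quadripartite_structure`.
#' @param gene Gene symbol; must be in the reference set.
#' @param reference_length Reference coding/mature length in bp (looked up in
#'   `reference` when omitted).
#' @param reference Reference gene table ([default_gene_template()] layout).
#' @return `list(gene, status, copies, evidence)`.
#' @export
classify_gene <- function(record, structure, gene, reference_length = NULL,
                          reference = default_gene_template()) {
  ri <- match(gene, reference$name)
  if (is.na(ri)) stop(sprintf("unknown gene symbol '%s'", gene))
  if (is.null(reference_length)) reference_length <- reference$length[ri]
  nm <- feature_names(record)
  idx <- which(normalize_gene_name(nm) == normalize_gene_name(gene))
  copies <- length(idx)
  evidence <- character(0)
  if (copies == 0) {
    iv <- syntenic_interval(record, gene, reference)
    orf <- if (is.null(iv)) 0L
           else longest_orf(circ_substr(record$sequence, iv[1], iv[2]))
    if (orf >= 0.3 * reference_length) {
      return(list(gene = gene, status = "pseudo", copies = 0L,
                  evidence = c("missing_annotation", "orf_remnant")))
    }
    return(list(gene = gene, status = "lost", copies = 0L,
                evidence = "missing"))
  }
  is_pseudo <- FALSE
  for (k in idx) {
    f <- record$features[[k]]
    if (f$pseudo) { evidence <- c(evidence, "annotated_pseudo"); is_pseudo <- TRUE }
    len <- sum(f$parts[, 2] - f$parts[, 1])
    if (f$category == "CDS") {
      if (len %% 3 != 0) { evidence <- c(evidence, "frameshift"); is_pseudo <- TRUE }
      else if (has_internal_stop(feature_sequence(record, f))) {
        evidence <- c(evidence, "internal_stop"); is_pseudo <- TRUE
      }
    }
    if (len < 0.5 * reference_length) {
      evidence <- c(evidence, "truncated"); is_pseudo <- TRUE
    }
  }
  if (copies >= 2 && !is.null(structure$irb)) {
    in_ir <- vapply(idx, function(k) {
      p <- record$features[[k]]$parts[1, 1]
      region_of_position(structure, p) %in% c("IRA", "IRB")
    }, logical(1))
    if (sum(in_ir) >= 2) evidence <- c(evidence, "in_IR")
  }
  status <- if (is_pseudo) "pseudo" else if (copies >= 2) "duplicated"
            else "single"
  list(gene = gene, status = status, copies = as.integer(copies),
       evidence = unique(evidence))
}

#' Gene content matrix across genomes
#'
#' Applies [classify_gene()] to every reference gene in every genome and
#' tabulates per-species counts with every annotated copy counted once
#' (IR expansion therefore inflates the totals, matching the convention of
#' published plastome summary tables).
#'
#' @param records List of [plastome_record()]s.
#' @param structures List of matching structures ([detect_ir()] output).
#' @param reference Reference gene table; defaults to the built-in template
#'   restricted to genes annotated in at least one record.
#' @return A `gene_content_matrix`: status and copy matrices plus a count
#'   table.
#' @export
content_matrix <- function(records, structures, reference = NULL) {
  stopifnot(length(records) >= 1, length(records) == length(structures))
  if (is.null(reference)) {
    reference <- default_gene_template()
    seen <- unique(unlist(lapply(records, feature_names)))
    reference <- reference[normalize_gene_name(reference$name) %in%
                             normalize_gene_name(seen), , drop = FALSE]
  }
  ids <- vapply(records, function(r) r$id, character(1))
  genes <- reference$name
  status <- matrix(NA_character_, length(records), length(genes),
                   dimnames = list(ids, genes))
  copies <- matrix(0L, length(records), length(genes),
                   dimnames = list(ids, genes))
  details <- list()
  for (i in seq_along(records)) {
    for (j in seq_along(genes)) {
      cl <- classify_gene(records[[i]], structures[[i]], genes[j],
                          reference = reference)
      status[i, j] <- cl$status
      copies[i, j] <- cl$copies
      details[[paste(ids[i], genes[j], sep = "|")]] <- cl$evidence
    }
  }
  cat_of <- stats::setNames(reference$category, reference$name)
  counts <- data.frame(
    species = ids,
    n_genes = rowSums(copies),
    n_cds = rowSums(copies[, cat_of[genes] == "CDS", drop = FALSE]),
    n_trna = rowSums(copies[, cat_of[genes] == "tRNA", drop = FALSE]),
    n_rrna = rowSums(copies[, cat_of[genes] == "rRNA", drop = FALSE]),
    n_loss_pseudo = rowSums(status == "lost" | status == "pseudo"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(status = status, copies = copies, counts = counts,
                 evidence = details, reference = reference),
            class = "gene_content_matrix")
}

#' @export
print.gene_content_matrix <- function(x, ...) {
  cat(sprintf("<gene_content_matrix> %d species x %d genes\n",
              nrow(x$status), ncol(x$status)))
  print(x$counts)
  invisible(x)
}
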