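# Marker screening: syntenic intergenic/intron locus extraction across
# genomes, progressive alignment, the sequence-variability (SV) statistic
#   SV = (mutations + indel events) / (conserved + mutations + indel events)
# and top-k ranking of candidate markers.

# per-genome loci: list of (id, kind, interval, seq)
enumerate_loci <- function(record, structure) {
  if (length(record$features) == 0)
    stop(sprintf("record '%s' is unannotated", record$id))
  n <- nchar(record$sequence)
  keep <- vapply(record$features, function(f) {
    if (is.null(structure$ira)) return(TRUE)
    sp <- feature_span(f)
    !(interval_contains(structure$ira, sp[1] %% n, n) &&
        interval_contains(structure$ira, (sp[2] - 1) %% n, n))
  }, logical(1))
  feats <- record$features[keep]
  spans <- lapply(feats, feature_span)
  ord <- order(vapply(spans, `[`, numeric(1), 1))
  feats <- feats[ord]
  spans <- spans[ord]
  out <- list()
  # intergenic spacers between consecutive genes (canonical orientation)
  for (i in seq_along(feats)) {
    j <- if (i == length(feats)) 1L else i + 1L
    a <- spans[[i]][2] %% n
    b <- spans[[j]][1] %% n
    len <- (b - a) %% n
    if (len <= 0) next
    # skip spacers overlapping the removed IRA copy (including the spacer
    # that would span the whole of it)
    if (!is.null(structure$ira)) {
      ira <- structure$ira
      spacer <- c(a, a + len)
      if (interval_contains(structure$ira, a, n) ||
          interval_contains(structure$ira, (b - 1) %% n, n) ||
          interval_contains(spacer, ira[1] %% n, n)) next
    }
    id <- paste0(feats[[i]]$name, "--", feats[[j]]$name)
    out[[length(out) + 1]] <- list(id = id, kind = "spacer",
                                   interval = c(a, a + len),
                                   seq = circ_substr(record$sequence, a,
                                                     a + len))
  }
  # introns between consecutive exons (transcription order)
  for (f in feats) {
    if (nrow(f$parts) < 2) next
    for (k in seq_len(nrow(f$parts) - 1)) {
      if (f$strand == "+") {
        iv <- c(f$parts[k, 2], f$parts[k + 1, 1])
      } else {
        iv <- c(f$parts[k + 1, 2], f$parts[k, 1])
      }
      if (iv[2] <= iv[1]) next
      s <- circ_substr(record$sequence, iv[1], iv[2])
      if (f$strand == "-") s <- revcomp(s)
      out[[length(out) + 1]] <- list(id = sprintf("%s_intron%d", f$name, k),
                                     kind = "intron", interval = iv, seq = s)
    }
  }
  out
}

#' Extract syntenic intergenic and intron loci across genomes
#'
#' A locus is kept when the same flanking gene pair (or the same host
#' gene/intron index) is present exactly once in every genome and the mean
#' unaligned length is at least `min_len` (default 150 bp, the conventional
#' cutoff below which loci are discarded). Loci inside the IR are collapsed
#' to the IRB instance.
#'
#' @param records List of annotated [plastome_record()]s (>= 2).
#' @param structures Matching structures.
#' @param min_len Minimum mean unaligned length.
#' @return A `syntenic_locus_set`: list of loci, each with `id`, `kind` and
#'   per-species sequences and intervals.
#' @export
extract_syntenic_loci <- function(records, structures, min_len = 150) {
  stopifnot(length(records) >= 2, length(records) == length(structures))
  ids <- vapply(records, function(r) r$id, character(1))
  per <- lapply(seq_along(records), function(i)
    enumerate_loci(records[[i]], structures[[i]]))
  tabs <- lapply(per, function(loci)
    table(vapply(loci, `[[`, character(1), "id")))
  all_ids <- unique(unlist(lapply(tabs, names)))
  keep <- Filter(function(id)
    all(vapply(tabs, function(tb) isTRUE(tb[id] == 1), logical(1))), all_ids)
  loci <- list()
  for (id in keep) {
    entries <- lapply(per, function(lx)
      lx[[which(vapply(lx, `[[`, character(1), "id") == id)]])
    lens <- vapply(entries, function(e) nchar(e$seq), numeric(1))
    if (mean(lens) < min_len) next
    loci[[length(loci) + 1]] <- list(
      id = id, kind = entries[[1]]$kind,
      seqs = stats::setNames(vapply(entries, `[[`, character(1), "seq"), ids),
      intervals = stats::setNames(lapply(entries, `[[`, "interval"), ids))
  }
  structure(loci, class = "syntenic_locus_set")
}

# ---------------------------------------------------------------- aligner ---

kmer_distance_matrix <- function(seqs, k = 6) {
  ss <- Biostrings::DNAStringSet(gsub("N", "A", seqs))
  f <- Biostrings::oligonucleotideFrequency(ss, width = k)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sh <- sum(pmin(f[i, ], f[j, ]))
      tot <- max(1, min(sum(f[i, ]), sum(f[j, ])))
      d[i, j] <- d[j, i] <- 1 - sh / tot
    }
  }
  d
}

#' Progressive multiple alignment of a locus
#'
#' Pairwise-profile progressive alignment with affine gaps (match +2,
#' mismatch -1, gap open -4, gap extend -1), guide tree from shared-k-mer
#' distances (average linkage). Deterministic given the input order; no
#' all-gap columns are produced.
#'
#' @param x A locus from [extract_syntenic_loci()] (one element), or a named
#'   character vector of >= 2 sequences (each <= 20 kb).
#' @return Character matrix of aligned rows, named by sequence.
#' @export
align_locus <- function(x) {
  seqs <- if (is.list(x) && !is.null(x$seqs)) x$seqs else x
  if (length(seqs) < 2) stop("need at least two sequences")
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (any(nchar(seqs) > 20000)) stop("sequence longer than 20 kb")
  nms <- names(seqs) %||% paste0("seq", seq_along(seqs))
  if (length(seqs) == 2) {
    al <- .align_profiles_cpp(seqs[1], seqs[2], 2, -1, -4, -1)
    m <- do.call(rbind, lapply(al, seq_chars))
    rownames(m) <- nms
    return(m)
  }
  d <- kmer_distance_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- as.list(seq_along(seqs))         # leaves hold row indices
  profiles <- lapply(seqs, identity)
  merged <- vector("list", nrow(hc$merge))
  rows_of <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(z) {
      if (z < 0) list(prof = unname(seqs[-z]), rows = -z)
      else list(prof = merged[[z]], rows = rows_of[[z]])
    }
    a <- pick(hc$merge[s, 1])
    b <- pick(hc$merge[s, 2])
    al <- .align_profiles_cpp(a$prof, b$prof, 2, -1, -4, -1)
    merged[[s]] <- as.character(al)
    rows_of[[s]] <- c(a$rows, b$rows)
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- rows_of[[nrow(hc$merge)]]
  m <- do.call(rbind, lapply(final, seq_chars))
  m <- m[order(ord), , drop = FALSE]
  rownames(m) <- nms
  m
}

#' Trim gappy alignment columns
#'
#' Removes columns whose gap fraction exceeds `max_gap_fraction` (a fixed
#' stand-in for heuristic gap-distribution trimming modes).
#'
#' @param aln Character matrix (rows = sequences).
#' @param max_gap_fraction Columns with a larger gap fraction are dropped.
#' @return The trimmed matrix, with the logical keep mask (length = input
#'   columns) in `attr(, "mask")`.
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5) {
  if (length(aln) == 0 || ncol(aln) == 0) stop("empty alignment")
  gapfrac <- colMeans(aln == "-")
  mask <- gapfrac <= max_gap_fraction
  if (!any(mask)) stop("all columns removed by trimming")
  out <- aln[, mask, drop = FALSE]
  attr(out, "mask") <- mask
  out
}

#' Sequence variability of a locus alignment
#'
#' `SV = (mutations + indel events) / (conserved + mutations + indel
#' events)`. Conserved sites are gap-free single-state columns; mutations
#' are counted as (distinct bases - 1) per gap-free column (the
#' minimum-mutation, "total mutations" convention, so multi-allelic columns
#' count multiply); an indel event is a maximal gap run, with runs sharing
#' identical (start, end) in different sequences counted once. Columns
#' containing gaps contribute only through indel events. `N` is treated as
#' missing.
#'
#' @param aln Character matrix (rows = sequences, >= 2).
#' @param id Optional locus id carried into the result.
#' @return List with `locus`, `n_mutations`, `n_indel_events`,
#'   `n_conserved`, `sv`, `mean_len`.
#' @export
compute_sv <- function(aln, id = NA_character_) {
  if (is.null(dim(aln))) aln <- do.call(rbind, lapply(aln, seq_chars))
  if (nrow(aln) < 2) stop("need at least two aligned sequences")
  if (ncol(aln) == 0) stop("alignment has zero length")
  gap <- aln == "-"
  gapfree <- colSums(gap) == 0
  n_mut <- 0L
  n_cons <- 0L
  for (j in which(gapfree)) {
    b <- aln[, j]
    b <- b[b != "N"]
    k <- length(unique(b))
    if (k <= 1) n_cons <- n_cons + 1L
    else n_mut <- n_mut + (k - 1L)
  }
  runs <- character(0)
  for (r in seq_len(nrow(aln))) {
    g <- gap[r, ]
    if (!any(g)) next
    rl <- rle(g)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    w <- which(rl$values)
    runs <- c(runs, paste(starts[w], ends[w], sep = "-"))
  }
  n_ind <- length(unique(runs))
  denom <- n_cons + n_mut + n_ind
  if (denom == 0) stop("alignment has no scorable columns")
  list(locus = id, n_mutations = n_mut, n_indel_events = n_ind,
       n_conserved = n_cons, sv = (n_mut + n_ind) / denom,
       mean_len = mean(rowSums(!gap)))
}

#' Rank candidate marker loci by sequence variability
#'
#' Descending SV; ties broken by longer mean locus length, then
#' lexicographic id.
#'
#' @param results List of [compute_sv()] results.
#' @param k Number of top loci to return (all if `k` exceeds the count).
#' @return Data frame of the top `k` loci (class `sv_result_set`).
#' @export
rank_markers <- function(results, k = 10) {
  stopifnot(length(results) >= 1)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(locus = r$locus, n_mutations = r$n_mutations,
               n_indel_events = r$n_indel_events, n_conserved = r$n_conserved,
               sv = r$sv, mean_len = r$mean_len, stringsAsFactors = FALSE)))
  ord <- order(-df$sv, -df$mean_len, df$locus)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  out <- head(df, k)
  class(out) <- c("sv_result_set", "data.frame")
  out
}

#' One-call marker screen
#'
#' Extracts syntenic loci, aligns each, computes SV and ranks the markers.
#'
#' @inheritParams extract_syntenic_loci
#' @param k Top-k loci to report.
#' @return `list(ranking, loci, alignments, sv)`.
#' @export
screen_markers <- function(records, structures, min_len = 150, k = 10) {
  loci <- extract_syntenic_loci(records, structures, min_len = min_len)
  alns <- lapply(loci, align_locus)
  sv <- lapply(seq_along(loci), function(i)
    compute_sv(alns[[i]], id = loci[[i]]$id))
  list(ranking = rank_markers(sv, k = k), loci = loci, alignments = alns,
       sv = sv)
}
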