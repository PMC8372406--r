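# Signed gene-order comparison between two plastomes: collinear blocks and
# inversion / relocation calls (the gene-level counterpart of an LCB
# alignment), plus windowed percent identity for pairwise alignments.

#' Signed gene order of a plastome
#'
#' One IR copy (IRA) is removed, genes are listed in circular order starting
#' at the IRA/LSC junction (or the record origin when no IR is present), and
#' each gene carries its strand as orientation.
#'
#' @param record A [plastome_record()].
#' @param structure Its `quadripartite_structure`.
#' @return A data frame (`signed_gene_order`) with columns `gene`, `strand`,
#'   `region`, `start`.
#' @export
gene_order <- function(record, structure) {
  n <- nchar(record$sequence)
  keep <- vapply(record$features, function(f) {
    if (is.null(structure$ira)) return(TRUE)
    sp <- feature_span(f)
    # drop the IRA copy of duplicated genes
    !(interval_contains(structure$ira, sp[1] %% n, n) &&
        interval_contains(structure$ira, (sp[2] - 1) %% n, n))
  }, logical(1))
  feats <- record$features[keep]
  origin <- if (!is.null(structure$junctions)) structure$junctions[["JLA"]]
            else 0
  starts <- vapply(feats, function(f) feature_span(f)[1], numeric(1))
  ord <- order((starts - origin) %% n)
  feats <- feats[ord]
  df <- data.frame(
    gene = vapply(feats, `[[`, character(1), "name"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    region = vapply(feats, function(f)
      region_of_position(structure, feature_span(f)[1] %% n), character(1)),
    start = starts[ord],
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("signed_gene_order", "data.frame")
  df
}

# maximum-weight subset of plus-sign blocks preserving circular order in both
# genomes (weights = gene counts); returns indices into `blocks`
backbone_blocks <- function(ref_idx, qpos, sign, weight) {
  B <- length(ref_idx)
  plus <- which(sign > 0)
  if (!length(plus)) return(integer(0))
  best <- integer(0)
  best_w <- -1
  for (s in plus) {
    # linearize both circles at block s
    seq_ref <- order((ref_idx - ref_idx[s]) %% B)   # ref circular order from s
    v <- (qpos - qpos[s]) %% B
    # DP over ref order: strictly increasing v, plus-sign blocks only
    ord <- seq_ref
    dp <- rep(-Inf, B)
    prev <- rep(NA_integer_, B)
    for (ii in seq_len(B)) {
      b <- ord[ii]
      if (!(b %in% plus)) next
      if (b == s) { dp[b] <- weight[b]; next }
      cand_w <- weight[b]
      bestp <- NA_integer_
      bestw <- -Inf
      for (jj in seq_len(ii - 1)) {
        a <- ord[jj]
        if (is.finite(dp[a]) && v[a] < v[b] && dp[a] > bestw) {
          bestw <- dp[a]; bestp <- a
        }
      }
      if (is.finite(bestw)) { dp[b] <- bestw + cand_w; prev[b] <- bestp }
    }
    b <- which.max(replace(dp, !is.finite(dp), -Inf))
    if (!is.finite(dp[b])) next
    chain <- integer(0)
    while (!is.na(b)) { chain <- c(b, chain); b <- prev[b] }
    w <- sum(weight[chain])
    if (w > best_w) { best_w <- w; best <- chain }
  }
  best
}

#' Collinear blocks and rearrangement events between two gene orders
#'
#' Chains maximal runs of genes that are consecutive and equioriented in both
#' circular orders (restricted to the shared gene set). Each non-backbone
#' block is classified: orientation flipped in place = `inversion`; position
#' changed = `relocation`; both = `inverted_relocation`. Region labels come
#' with each gene order, so calls like "relocated from the LSC into the IR"
#' are reproducible.
#'
#' @param ref,query `signed_gene_order` objects (see [gene_order()]).
#' @return A data frame (one row per block) with the gene list, relative
#'   orientation, kind, and region labels in both genomes.
#' @export
find_blocks <- function(ref, query) {
  shared <- intersect(ref$gene, query$gene)
  if (length(shared) == 0) stop("no shared genes between the two orders")
  r <- ref[ref$gene %in% shared, , drop = FALSE]
  q <- query[query$gene %in% shared, , drop = FALSE]
  m <- nrow(r)
  qpos <- match(r$gene, q$gene)              # query index of ref gene i
  relsign <- ifelse(r$strand == q$strand[qpos], 1L, -1L)
  if (m == 1) {
    out <- data.frame(block = 1L, n_genes = 1L, genes = r$gene,
                      rel_sign = relsign, kind = "collinear",
                      ref_region = r$region, query_region = q$region[qpos],
                      stringsAsFactors = FALSE)
    return(out)
  }
  # breakpoint between ref position i and i+1 (circular)
  brk <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    if (relsign[i] != relsign[j]) return(TRUE)
    if (relsign[i] > 0) (qpos[i] %% m) + 1L != qpos[j]
    else (qpos[j] %% m) + 1L != qpos[i]
  }, logical(1))
  if (!any(brk)) {
    out <- data.frame(block = 1L, n_genes = m,
                      genes = paste(r$gene, collapse = ","),
                      rel_sign = 1L, kind = "collinear",
                      ref_region = paste(unique(r$region), collapse = "/"),
                      query_region = paste(unique(q$region[qpos]),
                                           collapse = "/"),
                      stringsAsFactors = FALSE)
    return(out)
  }
  # blocks: runs starting after each breakpoint
  starts <- (which(brk) %% m) + 1L
  starts <- sort(starts)
  blocks <- list()
  for (z in seq_along(starts)) {
    from <- starts[z]
    to <- if (z < length(starts)) starts[z + 1] - 1L else starts[1] - 1L + m
    idx <- ((seq.int(from, to) - 1L) %% m) + 1L
    blocks[[z]] <- idx
  }
  B <- length(blocks)
  bsign <- vapply(blocks, function(ix) relsign[ix[1]], integer(1))
  bweight <- vapply(blocks, length, integer(1))
  bref <- vapply(blocks, `[`, integer(1), 1)          # ref pos of block head
  bq <- vapply(blocks, function(ix) min(qpos[ix]), integer(1))
  # order blocks along the query circle by their smallest query position
  qrank <- rank(bq)
  backbone <- backbone_blocks(rank(bref), qrank, bsign, bweight)
  in_place <- function(b) {
    if (!length(backbone)) return(TRUE)
    # nearest backbone neighbours of b in ref circular order
    refr <- rank(bref)
    off <- (refr - refr[b]) %% B
    succ <- backbone[which.min((refr[backbone] - refr[b]) %% B)]
    pred <- backbone[which.min((refr[b] - refr[backbone]) %% B)]
    if (pred == succ) return(TRUE)  # single backbone block: any slot fits
    # does b sit between pred and succ on the query circle too?
    dq <- function(a, c) (qrank[c] - qrank[a]) %% B
    dq(pred, b) < dq(pred, succ)
  }
  kind <- character(B)
  for (b in seq_len(B)) {
    if (b %in% backbone) { kind[b] <- "collinear"; next }
    if (bsign[b] > 0) { kind[b] <- "relocation"; next }
    kind[b] <- if (in_place(b)) "inversion" else "inverted_relocation"
  }
  out <- data.frame(
    block = seq_len(B),
    n_genes = bweight,
    genes = vapply(blocks, function(ix) paste(r$gene[ix], collapse = ","),
                   character(1)),
    rel_sign = bsign,
    kind = kind,
    ref_region = vapply(blocks, function(ix)
      paste(unique(r$region[ix]), collapse = "/"), character(1)),
    query_region = vapply(blocks, function(ix)
      paste(unique(q$region[qpos[ix]]), collapse = "/"), character(1)),
    stringsAsFactors = FALSE)
  out
}

#' Windowed percent identity along a pairwise alignment
#'
#' Per window: `100 * matches / (aligned columns excluding columns that are
#' gaps in both sequences)`; a gap against a base counts as a non-match.
#'
#' @param aln Character matrix with 2 rows (or list/vector of 2 equal-length
#'   strings).
#' @param window,step Window size and step in alignment columns; a window
#'   longer than the alignment collapses to one whole-length window.
#' @return Data frame with `midpoint` (0-based column) and `identity`.
#' @export
windowed_identity <- function(aln, window = 100, step = 25) {
  if (is.matrix(aln)) {
    a <- aln[1, ]; b <- aln[2, ]
  } else {
    a <- seq_chars(aln[[1]]); b <- seq_chars(aln[[2]])
  }
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  L <- length(a)
  if (window > L) { window <- L; step <- L }
  starts <- seq(1, L - window + 1, by = step)
  mid <- starts - 1 + window / 2
  ident <- vapply(starts, function(s) {
    i <- s:(s + window - 1)
    dual <- a[i] == "-" & b[i] == "-"
    denom <- sum(!dual)
    if (denom == 0) return(NA_real_)
    100 * sum(a[i] == b[i] & a[i] != "-" & !dual) / denom
  }, numeric(1))
  data.frame(midpoint = mid, identity = ident)
}
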