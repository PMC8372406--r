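# Desk-scale phylogenetics: pairwise-deletion distances (p, JC69, K2P),
# neighbor-joining with deterministic tie-breaking, column-resampling
# bootstrap support, alignment concatenation with a partition table, and
# Robinson-Foulds topology comparison.

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  m <- do.call(rbind, lapply(aln, seq_chars))
  rownames(m) <- names(aln)
  m
}

#' Pairwise distance matrix from an alignment
#'
#' Gap and `N` sites are pairwise-deleted. Models: `p` (proportion of
#' differing sites), `JC69` (`-3/4 log(1 - 4p/3)`), `K2P` (from transition /
#' transversion proportions). Saturated pairs (`p >= 3/4` under JC69, or the
#' analogous K2P condition) raise an error naming the pair.
#'
#' @param aln Character matrix (rows = taxa) or named character vector.
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @return Symmetric numeric matrix with a `model` attribute.
#' @export
distance_matrix <- function(aln, model = c("JC69", "p", "K2P")) {
  model <- match.arg(model)
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  bin <- ape::as.DNAbin(tolower(m))
  amod <- c(p = "raw", JC69 = "JC69", K2P = "K80")[model]
  d <- ape::dist.dna(bin, model = amod, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop(sprintf("saturated distance between '%s' and '%s' under %s",
                 rownames(m)[bad[1]], rownames(m)[bad[2]], model))
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Standard Q-criterion agglomeration. Ties are broken by the smallest index
#' pair; a negative branch length is clamped to zero with the deficit moved
#' to the sibling edge. Returns an unrooted tree.
#'
#' @param dm Symmetric distance matrix with row/column names.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", max(0, x))
  node <- labels                       # newick fragment per active cluster
  act <- seq_len(n)
  d <- dm
  while (length(act) > 3) {
    na <- length(act)
    r <- rowSums(d[act, act])
    best <- c(NA, NA); bestq <- Inf
    for (ii in seq_len(na - 1)) {
      for (jj in (ii + 1):na) {
        i <- act[ii]; j <- act[jj]
        q <- (na - 2) * d[i, j] - r[ii] - r[jj]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ri <- sum(d[i, act]); rj <- sum(d[j, act])
    li <- 0.5 * d[i, j] + (ri - rj) / (2 * (na - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(0, li); lj <- max(0, lj)
    new <- nrow(d) + 1
    d <- rbind(cbind(d, 0), 0)
    for (k in act) {
      if (k == i || k == j) next
      d[new, k] <- d[k, new] <- 0.5 * (d[i, k] + d[j, k] - d[i, j])
    }
    node <- c(node, sprintf("(%s:%s,%s:%s)", node[i], fmt(li),
                            node[j], fmt(lj)))
    act <- c(setdiff(act, c(i, j)), new)
  }
  i <- act[1]; j <- act[2]; k <- act[3]
  li <- (d[i, j] + d[i, k] - d[j, k]) / 2
  lj <- (d[i, j] + d[j, k] - d[i, k]) / 2
  lk <- (d[i, k] + d[j, k] - d[i, j]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[i], fmt(li), node[j], fmt(lj),
                 node[k], fmt(lk))
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions as canonical strings (side not containing the
# alphabetically first tip)
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (ch > ntip) {
      side <- below[[ch]]
      if (length(side) >= 2 && length(side) <= ntip - 2) {
        if (tips[1] %in% side) side <- setdiff(tips, side)
        keys <- c(keys, paste(sort(side), collapse = "|"))
      }
    }
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (unnormalized).
#'
#' @param tree1,tree2 `ape::phylo` trees over the same tip set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label))
    stop("trees must share the same tip set")
  b1 <- bipartition_keys(ape::unroot(tree1))
  b2 <- bipartition_keys(ape::unroot(tree2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Columns are resampled with replacement; each replicate is re-analysed with
#' the same distance model and NJ; the support of an internal edge of the
#' original tree is the percentage of replicates containing its bipartition.
#'
#' @param aln Character matrix (rows = taxa).
#' @param model Distance model (see [distance_matrix()]).
#' @param replicates Bootstrap replicates (desk-scale default 200).
#' @param seed Integer seed.
#' @return `list(tree, support)`: the NJ tree with `node.label` support
#'   values, and a table of bipartition keys with support in `[0, 100]`.
#' @export
bootstrap_support <- function(aln, model = "JC69", replicates = 200,
                              seed = 1) {
  m <- as_alignment_matrix(aln)
  if (ncol(m) < 10) stop("alignment has fewer than 10 columns")
  base_tree <- neighbor_joining(distance_matrix(m, model))
  keys <- bipartition_keys(base_tree)
  hits <- stats::setNames(numeric(length(keys)), keys)
  done <- 0
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tb <- tryCatch(
        neighbor_joining(distance_matrix(m[, cols, drop = FALSE], model)),
        error = function(e) NULL)
      if (is.null(tb)) next
      done <- done + 1
      kb <- bipartition_keys(tb)
      hits[keys %in% kb] <- hits[keys %in% kb] + 1
    }
  })
  if (done == 0) stop("all bootstrap replicates failed")
  support <- 100 * hits / done
  tree <- ape::makeNodeLabel(base_tree, method = "number")
  # attach supports to internal edges via bipartition matching
  lab <- rep(NA_real_, tree$Nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  tips <- sort(tr$tip.label)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (ch > ntip) {
      side <- below[[ch]]
      if (length(side) >= 2 && length(side) <= ntip - 2) {
        if (tips[1] %in% side) side <- setdiff(tips, side)
        key <- paste(sort(side), collapse = "|")
        if (key %in% names(support)) lab[ch - ntip] <- support[[key]]
      }
    }
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  tree$node.label <- ifelse(is.na(lab), "", sprintf("%.1f", lab))
  list(tree = tree,
       support = data.frame(bipartition = keys, support = unname(support),
                            stringsAsFactors = FALSE),
       replicates = done)
}

#' Concatenate gene alignments
#'
#' Tip sets are unioned; a tip missing from a locus is padded with gaps and
#' flagged. Duplicate locus names are an error.
#'
#' @param alignments Named list of character matrices.
#' @param names Optional locus names (default `names(alignments)`).
#' @return `list(alignment, partitions, padded)`; `partitions` has 0-based
#'   half-open `start`, `end` per locus.
#' @export
concatenate_alignments <- function(alignments, names = NULL) {
  if (is.null(names)) names <- base::names(alignments)
  if (is.null(names)) names <- paste0("locus", seq_along(alignments))
  if (anyDuplicated(names) > 0) stop("duplicate gene names")
  mats <- lapply(alignments, as_alignment_matrix)
  tips <- unique(unlist(lapply(mats, rownames)))
  padded <- character(0)
  out <- NULL
  parts <- data.frame(gene = names, start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  at <- 0L
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    full <- matrix("-", length(tips), ncol(m),
                   dimnames = list(tips, NULL))
    full[rownames(m), ] <- m
    miss <- setdiff(tips, rownames(m))
    if (length(miss)) padded <- c(padded, paste(names[i], miss, sep = ":"))
    out <- if (is.null(out)) full else cbind(out, full)
    parts$start[i] <- at
    parts$end[i] <- at + ncol(m)
    at <- at + ncol(m)
  }
  list(alignment = out, partitions = parts, padded = padded)
}
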