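# Per-site substitution-rate estimation on a fixed ultrametric tree
# (Jukes-Cantor pruning likelihood, 1-D ML per site) and phylogenetic
# informativeness profiling on a relative-time axis: a site with rate lambda
# contributes rho(t) = 16 lambda^2 t exp(-4 lambda t), the four-state
# Poisson informativeness, which peaks at t = 1/(4 lambda).

#' Ultrametricize a tree to relative time (tips 0, root 1)
#'
#' Node ages by mean-path-length smoothing: each node's age is the mean
#' distance to its descendant tips, with a parent forced to be at least
#' `eps` older than its oldest child; ages are then rescaled so the root sits
#' at exactly 1. Unrooted input is midpoint-rooted; a root polytomy is
#' resolved arbitrarily (deterministically) with zero-length branches.
#'
#' @param tree `ape::phylo` with branch lengths (not all zero).
#' @param eps Minimum parent-child age gap before rescaling.
#' @return An ultrametric `phylo` with root age 1.
#' @export
ultrametricize <- function(tree, eps = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop("tree has no usable branch lengths")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  age <- numeric(ntip + nnode)
  ntips_below <- integer(ntip + nnode)
  sumdist <- numeric(ntip + nnode)            # sum of distances to tips below
  ntips_below[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    ntips_below[par] <- ntips_below[par] + ntips_below[ch]
    sumdist[par] <- sumdist[par] + sumdist[ch] + t * ntips_below[ch]
  }
  # postorder pass: mean path length, parent >= child + eps
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  for (nd in unique(tr$edge[, 1])) {          # postorder parents
    age[nd] <- sumdist[nd] / ntips_below[nd]
    mx <- max(age[kids[[as.character(nd)]]])
    if (age[nd] < mx + eps) age[nd] <- mx + eps
  }
  root <- ntip + 1L
  age <- age / age[root]
  tr$edge.length <- age[tr$edge[, 1]] - age[tr$edge[, 2]]
  ape::reorder.phylo(tr, "cladewise")
}

# log-likelihood of one site column under JC at rate lambda on a fixed tree
# (Felsenstein pruning); `prep` comes from prune_prep()
jc_column_loglik <- function(prep, states, lambda) {
  part <- prep$init
  known <- which(!is.na(states))
  part[known, ] <- 0
  part[cbind(known, states[known])] <- 1
  e <- exp(-4 * lambda * prep$elen / 3)
  ps <- 0.25 + 0.75 * e
  pd <- 0.25 - 0.25 * e
  for (k in seq_along(prep$parent)) {
    ch <- prep$child[k]
    x <- part[ch, ]
    s <- sum(x)
    cont <- pd[k] * s + (ps[k] - pd[k]) * x
    part[prep$parent[k], ] <- part[prep$parent[k], ] * cont
  }
  log(sum(0.25 * part[prep$root, ]))
}

prune_prep <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  list(parent = tr$edge[, 1], child = tr$edge[, 2], elen = tr$edge.length,
       root = ntip + 1L, ntip = ntip, tips = tr$tip.label,
       init = matrix(1, nn, 4))
}

#' Estimate per-site substitution rates on a fixed tree
#'
#' For each alignment column, the rate `lambda` maximizing the Jukes-Cantor
#' pruning likelihood on the fixed (ultrametric) tree, by bounded 1-D
#' optimization on `[0, lambda_max]`. Gaps and `N` are missing data
#' (all-ones partials); invariant columns get rate 0; all-missing columns
#' are flagged `NA`.
#'
#' @param aln Character matrix, rows named by tip (a subset of the tree's
#'   tips is an error).
#' @param tree Ultrametric `phylo` (see [ultrametricize()]).
#' @param lambda_max Upper bound of the search (default 20).
#' @param tol Optimizer tolerance (default 1e-6).
#' @param genes Optional partition table (`gene`, `start`, `end`, 0-based
#'   half-open) mapping sites to genes.
#' @return A `rate_profile`: list with `rates` (per site), `flagged`
#'   (all-missing sites) and `genes`.
#' @export
estimate_site_rates <- function(aln, tree, lambda_max = 20, tol = 1e-6,
                                genes = NULL) {
  stopifnot(is.matrix(aln))
  missing_tips <- setdiff(rownames(aln), tree$tip.label)
  if (length(missing_tips))
    stop("alignment tips not in tree: ", paste(missing_tips, collapse = ", "))
  if (length(setdiff(tree$tip.label, rownames(aln))))
    tree <- ape::keep.tip(tree, rownames(aln))
  prep <- prune_prep(tree)
  aln <- aln[prep$tips, , drop = FALSE]
  L <- ncol(aln)
  codes <- matrix(match(aln, DNA_BASES), nrow(aln), L)  # NA for gap/N
  rates <- numeric(L)
  flagged <- logical(L)
  for (j in seq_len(L)) {
    st <- codes[, j]
    obs <- st[!is.na(st)]
    if (length(obs) == 0) { rates[j] <- NA_real_; flagged[j] <- TRUE; next }
    if (length(unique(obs)) <= 1) { rates[j] <- 0; next }
    f <- function(l) jc_column_loglik(prep, st, l)
    opt <- stats::optimize(f, c(0, lambda_max), maximum = TRUE, tol = tol)
    rates[j] <- opt$maximum
  }
  structure(list(rates = rates, flagged = flagged, genes = genes,
                 tree = tree),
            class = "rate_profile")
}

#' Phylogenetic informativeness profiles
#'
#' Per site `rho(t) = 16 lambda^2 t exp(-4 lambda t)` on a relative-time
#' grid over (0, 1]; per-gene net PI is the sum over the gene's sites and
#' per-site PI the net divided by the gene alignment length (removing the
#' confounding effect of gene length). The constant 16 is a convention; all
#' rankings are invariant to it.
#'
#' @param rates A `rate_profile` (or numeric vector of per-site rates).
#' @param t_grid Relative-time grid, default 200 points on (0, 1].
#' @param genes Optional partition table (`gene`, `start`, `end`, 0-based
#'   half-open); defaults to the one in `rates`, else one pooled gene.
#' @return A `pi_profile`: grid, per-gene net and per-site PI matrices and a
#'   summary table (`gene`, `length`, `max_per_site_pi`, `argmax_t`).
#' @export
pi_profile <- function(rates, t_grid = seq(0.005, 1, length.out = 200),
                       genes = NULL) {
  if (inherits(rates, "rate_profile")) {
    if (is.null(genes)) genes <- rates$genes
    rates <- rates$rates
  }
  L <- length(rates)
  if (is.null(genes))
    genes <- data.frame(gene = "all", start = 0, end = L)
  rho <- function(l, t) 16 * l^2 * t * exp(-4 * l * t)
  net <- matrix(0, nrow(genes), length(t_grid),
                dimnames = list(genes$gene, NULL))
  persite <- net
  for (i in seq_len(nrow(genes))) {
    idx <- (genes$start[i] + 1):genes$end[i]
    lam <- rates[idx]
    lam <- lam[!is.na(lam)]
    for (ti in seq_along(t_grid))
      net[i, ti] <- sum(rho(lam, t_grid[ti]))
    persite[i, ] <- net[i, ] / (genes$end[i] - genes$start[i])
  }
  summary <- data.frame(
    gene = genes$gene,
    length = genes$end - genes$start,
    max_per_site_pi = apply(persite, 1, max),
    argmax_t = t_grid[apply(persite, 1, which.max)],
    stringsAsFactors = FALSE)
  structure(list(t_grid = t_grid, net = net, per_site = persite,
                 summary = summary),
            class = "pi_profile")
}

#' Rank genes by maximum per-site phylogenetic informativeness
#'
#' @param profile A `pi_profile`.
#' @return The summary table ordered by decreasing max per-site PI (ties by
#'   gene name), with a `rank` column.
#' @export
rank_genes <- function(profile) {
  stopifnot(inherits(profile, "pi_profile"))
  df <- profile$summary
  df <- df[order(-df$max_per_site_pi, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
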