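# Shared fixtures and independent oracles for the test suite.

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# a small quadripartite ancestor shared across tests (memoized)
small_ancestor <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_ancestor(ancestor_spec(lsc_len = 30000, ssc_len = 9000,
                                             ir_len = 8000, seed = 101))
    cache
  }
})

# definition-driven SSR oracle (R, independent of the C++ scanner):
# for every start and motif length, decide "run start" and count the run by
# direct character comparison
ssr_oracle <- function(seq, thresholds = c(10, 6, 5, 5, 5, 5),
                       circular = FALSE) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  base <- c("A", "C", "G", "T")
  hits <- list()
  for (mlen in seq_along(thresholds)) {
    thr <- thresholds[mlen]
    if (n <= mlen) next
    span <- if (circular) n else n - mlen
    xs <- 0:(span - 1)
    eq <- v[xs + 1] == v[((xs + mlen) %% n) + 1] & v[xs + 1] %in% base
    if (circular && all(eq)) {
      motif <- paste(v[1:mlen], collapse = "")
      primitive <- !any(vapply(seq_len(mlen - 1), function(d)
        mlen %% d == 0 &&
          paste(rep(substr(motif, 1, d), mlen / d), collapse = "") == motif,
        logical(1)))
      if (n %/% mlen >= thr && primitive)
        hits[[length(hits) + 1]] <- data.frame(
          motif = motif, copies = n %/% mlen, start = 0L, length = n,
          stringsAsFactors = FALSE)
      next
    }
    for (x0 in 0:(span - 1)) {
      if (!eq[x0 + 1]) next
      left <- if (x0 == 0) {
        if (circular) eq[span] else FALSE
      } else eq[x0]
      if (left) next                       # not a run start
      t <- 0
      while (t < span) {
        idx <- if (circular) ((x0 + t) %% span) + 1 else x0 + t + 1
        if (!circular && x0 + t >= span) break
        if (!eq[idx]) break
        t <- t + 1
      }
      total <- min(t + mlen, n)
      copies <- total %/% mlen
      motif <- paste(v[((x0 + 0:(mlen - 1)) %% n) + 1], collapse = "")
      primitive <- !any(vapply(seq_len(mlen - 1), function(d)
        mlen %% d == 0 &&
          paste(rep(substr(motif, 1, d), mlen / d), collapse = "") == motif,
        logical(1)))
      if (copies >= thr && primitive)
        hits[[length(hits) + 1]] <- data.frame(
          motif = motif, copies = copies, start = x0, length = total,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), copies = integer(),
                      start = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

sort_hits <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$start, nchar(df$motif), df$motif), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force JC likelihood by summation over internal node states
brute_jc_loglik <- function(tree, states_by_label, lambda) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  Pm <- function(t) {
    e <- exp(-4 * lambda * t / 3)
    m <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(m) <- 0.25 + 0.75 * e
    m
  }
  mats <- lapply(tr$edge.length, Pm)
  ints <- (ntip + 1):nn
  grid <- expand.grid(rep(list(1:4), length(ints)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- states_by_label[tr$tip.label]
    st[ints] <- as.integer(grid[g, ])
    pr <- 0.25
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * mats[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
    total <- total + pr
  }
  log(total)
}

# sum-of-pairs score of an alignment under the locus-aligner scoring
sp_score <- function(aln, match = 2, mismatch = -1, gap_open = -4,
                     gap_ext = -1) {
  n <- nrow(aln)
  sc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- aln[i, ]; b <- aln[j, ]
      both <- a != "-" & b != "-"
      sc <- sc + sum(both & a == b) * match + sum(both & a != b) * mismatch
      # affine gap cost of the pairwise projection (columns with a gap in
      # exactly one row), dual-gap columns dropped
      keep <- !(a == "-" & b == "-")
      ga <- a[keep] == "-"
      gb <- b[keep] == "-"
      runcost <- function(g) {
        if (!any(g)) return(0)
        r <- rle(g)
        sum(ifelse(r$values, gap_open + (r$lengths - 1) * gap_ext, 0))
      }
      sc <- sc + runcost(ga) + runcost(gb)
    }
  }
  sc
}
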