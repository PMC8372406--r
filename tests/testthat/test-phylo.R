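test_that("distances follow the closed forms with pairwise deletion", {
  a <- strsplit("ACGTACGTAC", "")[[1]]
  b <- a
  expect_equal(unname(distance_matrix(rbind(x = a, y = b), "p")["x", "y"]), 0)
  b[c(2, 5)] <- c("G", "T")
  d <- distance_matrix(rbind(x = a, y = b), "p")
  expect_equal(unname(d["x", "y"]), 0.2)
  expect_equal(d, t(d))
  dj <- distance_matrix(rbind(x = a, y = b), "JC69")
  expect_equal(unname(dj["x", "y"]), -0.75 * log(1 - 0.8 / 3),
               tolerance = 1e-9)
  # gap/N sites are pairwise-deleted: the two changed sites over 8 valid
  b2 <- b
  b2[c(9, 10)] <- c("-", "N")
  d2 <- distance_matrix(rbind(x = a, y = b2), "p")
  expect_equal(unname(d2["x", "y"]), 2 / 8)
  # saturation is an error under JC69
  sat <- rbind(x = c("A", "C", "G", "T"), y = c("C", "A", "T", "G"))
  expect_error(distance_matrix(sat, "JC69"), "saturated")
})

test_that("neighbor joining is exact on additive matrices", {
  # hand-built additive matrix from the tree ((A:2,B:3):1,(C:4,D:5):2)
  dm <- matrix(c(0, 5, 9, 10,
                 5, 0, 10, 11,
                 9, 10, 0, 9,
                 10, 11, 9, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(dm)
  truth <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2);")
  expect_equal(rf_distance(tr, truth), 0)
  expect_equal(sum(tr$edge.length), sum(truth$edge.length))
  # recovered pairwise path lengths equal the input distances
  got <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(got, dm, tolerance = 1e-9)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("3 taxa resolve by the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["C"]), (4 + 5 - 3) / 2)
})

test_that("NJ recovers random additive trees (property, vs independent NJ)", {
  set.seed(91)
  for (trial in 1:25) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr0)
    mine <- neighbor_joining(dm)
    expect_equal(rf_distance(mine, tr0), 0, info = paste("trial", trial))
    # cross-check against the reference implementation
    expect_equal(rf_distance(mine, ape::nj(dm)), 0)
  }
})

test_that("rf_distance matches brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "tip set")
  set.seed(92)
  for (trial in 1:20) {
    a <- ape::rtree(8)
    b <- ape::rtree(8)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a),
                                              ape::unroot(b))))
    # metric properties on the tested set
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, a), 0)
  }
})

test_that("concatenation builds the partition table and pads missing tips", {
  set.seed(93)
  a1 <- matrix(sample(c("A", "C"), 300, TRUE), 3, 100,
               dimnames = list(c("x", "y", "z"), NULL))
  a2 <- matrix(sample(c("G", "T"), 400, TRUE), 2, 200,
               dimnames = list(c("x", "y"), NULL))
  a3 <- matrix(sample(c("A", "T"), 900, TRUE), 3, 300,
               dimnames = list(c("x", "y", "z"), NULL))
  cc <- concatenate_alignments(list(g1 = a1, g2 = a2, g3 = a3))
  expect_equal(ncol(cc$alignment), 600)
  expect_equal(cc$partitions$start, c(0, 100, 300))
  expect_equal(cc$partitions$end, c(100, 300, 600))
  expect_equal(cc$padded, "g2:z")
  expect_true(all(cc$alignment["z", 101:300] == "-"))
  # round trip: splitting by the partition table recovers the inputs
  for (i in 1:3) {
    sub <- cc$alignment[, (cc$partitions$start[i] + 1):cc$partitions$end[i],
                        drop = FALSE]
    orig <- list(a1, a2, a3)[[i]]
    expect_equal(sub[rownames(orig), ], orig, ignore_attr = TRUE)
  }
  expect_error(concatenate_alignments(list(g = a1, g = a2)), "duplicate")
})

test_that("bootstrap support is bounded and behaves on degenerate input", {
  set.seed(94)
  tt <- ape::read.tree(text = "((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  aln <- simulate_alignment_jc(tt, lambda = 1, n_sites = 800, seed = 95)
  bs <- bootstrap_support(aln, replicates = 100, seed = 96)
  expect_true(all(bs$support$support >= 0 & bs$support$support <= 100))
  expect_gte(max(bs$support$support), 90)  # the deep AB|CD split
  # no variation at all: every replicate is identical; supports still defined
  flat <- matrix("A", 4, 50, dimnames = list(c("A", "B", "C", "D"), NULL))
  bs0 <- bootstrap_support(flat, replicates = 20, seed = 97)
  expect_true(all(bs0$support$support >= 0 & bs0$support$support <= 100))
})
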