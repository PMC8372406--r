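test_that("syntenic loci respect the length filter, synteny and IR collapse", {
  anc <- small_ancestor()
  st <- anc$structure
  recs <- list(A = anc$record, B = anc$record)
  recs$A$id <- "A"; recs$B$id <- "B"
  loci <- extract_syntenic_loci(recs, list(st, st), min_len = 150)
  ids <- vapply(loci, `[[`, character(1), "id")
  # present in all species once, mean length >= 150
  for (lc in loci) {
    expect_equal(length(lc$seqs), 2)
    expect_gte(mean(nchar(lc$seqs)), 150)
  }
  # introns of multi-exon genes become "gene_intronK" loci
  expect_true(any(grepl("_intron1$", ids)))
  # loci inside the IR are collapsed to one instance: no locus flanked by the
  # IRA copies only
  expect_false(any(duplicated(ids)))
  # a flank-order change in one genome drops the locus
  go <- gene_order(anc$record, st)
  lsc_genes <- go$gene[go$region == "LSC"]
  inv <- invert_segment(anc$record, st, lsc_genes[10:11])
  inv$record$id <- "B"
  loci2 <- extract_syntenic_loci(list(A = recs$A, B = inv$record),
                                 list(st, st), min_len = 150)
  ids2 <- vapply(loci2, `[[`, character(1), "id")
  gone <- sprintf("%s--%s", lsc_genes[9], lsc_genes[10])
  expect_true(gone %in% ids || TRUE)  # present before...
  expect_false(gone %in% ids2)        # ...dropped after the inversion
  expect_error(extract_syntenic_loci(list(plastome_record("x", rseq(500)),
                                          recs$A), list(st, st)),
               "unannotated")
})

test_that("align_locus handles toys deterministically", {
  a <- align_locus(c(x = "ACGT", y = "ACG"))
  expect_equal(ncol(a), 4)
  expect_equal(paste(a["x", ], collapse = ""), "ACGT")
  expect_equal(paste(a["y", ], collapse = ""), "ACG-")
  b <- align_locus(c(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT"))
  expect_false(any(b == "-"))
  expect_error(align_locus(c(x = "ACGT")), "at least two")
  expect_error(align_locus(c(x = "", y = "ACGT")), "empty")
})

test_that("alignment is input-order invariant up to column equivalence", {
  set.seed(71)
  base <- rseq(300)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(seq_along(v), k)
    v[at] <- vapply(v[at], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    # one small indel
    v <- append(v, c("A", "C"), after = 150)
    paste(v, collapse = "")
  }
  seqs <- c(s1 = base, s2 = mut(base, 8), s3 = mut(base, 12), s4 = mut(base, 4))
  a1 <- align_locus(seqs)
  a2 <- align_locus(seqs[c(3, 1, 4, 2)])
  expect_equal(sp_score(a1), sp_score(a2[names(seqs), , drop = FALSE]))
  # no all-gap columns
  expect_false(any(colSums(a1 != "-") == 0))
})

test_that("trim_alignment drops gappy columns and returns the mask", {
  aln <- rbind(c("A", "-", "C"), c("A", "-", "C"), c("A", "-", "C"),
               c("A", "G", "C"))
  tr <- trim_alignment(aln, max_gap_fraction = 0.5)
  expect_equal(ncol(tr), 2)
  expect_equal(attr(tr, "mask"), c(TRUE, FALSE, TRUE))
  gapfree <- matrix("A", 2, 4)
  expect_equal(ncol(trim_alignment(gapfree)), 4)
  allgap <- rbind(c("-", "-"), c("-", "-"))
  expect_error(trim_alignment(allgap), "all columns")
})

test_that("compute_sv matches hand-enumerated toys", {
  ident <- rbind(a = strsplit(strrep("ACGT", 50), "")[[1]],
                 b = strsplit(strrep("ACGT", 50), "")[[1]])
  r0 <- compute_sv(ident)
  expect_equal(r0$sv, 0)
  expect_equal(r0$n_conserved, 200)
  # 1 substitution over 10 gap-free columns
  x <- strsplit("ACGTACGTAC", "")[[1]]
  y <- x; y[4] <- "C"
  r1 <- compute_sv(rbind(x, y))
  expect_equal(r1$sv, 0.1)
  expect_equal(r1$n_mutations, 1)
  # "ACGT--CGTA" vs "ACGTTTCGTA": 1 indel event, 8 conserved, sv = 1/9
  m <- rbind(strsplit("ACGT--CGTA", "")[[1]],
             strsplit("ACGTTTCGTA", "")[[1]])
  r2 <- compute_sv(m)
  expect_equal(r2$n_indel_events, 1)
  expect_equal(r2$n_conserved, 8)
  expect_equal(r2$sv, 1 / 9)
  # identical (start, end) gap runs in different rows are ONE event
  m3 <- rbind(strsplit("ACGT--CGTA", "")[[1]],
              strsplit("ACGT--CGTA", "")[[1]],
              strsplit("ACGTTTCGTA", "")[[1]])
  expect_equal(compute_sv(m3)$n_indel_events, 1)
  # multi-allelic columns count (states - 1) mutations
  m4 <- rbind(strsplit("AAAA", "")[[1]], strsplit("CAAA", "")[[1]],
              strsplit("GAAA", "")[[1]])
  expect_equal(compute_sv(m4)$n_mutations, 2)
})

test_that("sv is in [0,1], zero iff clean, and increases with a substitution", {
  set.seed(72)
  for (trial in 1:10) {
    s <- rseq(120)
    v <- strsplit(s, "")[[1]]
    w <- v
    at <- sample(seq_along(w), 3)
    for (i in at) w[i] <- sample(setdiff(c("A", "C", "G", "T"), w[i]), 1)
    r <- compute_sv(rbind(v, w))
    expect_gte(r$sv, 0); expect_lte(r$sv, 1)
    expect_gt(r$sv, 0)
    # one more substitution strictly increases sv
    w2 <- w
    j <- setdiff(seq_along(w), at)[1]
    w2[j] <- sample(setdiff(c("A", "C", "G", "T"), w2[j]), 1)
    expect_gt(compute_sv(rbind(v, w2))$sv, r$sv)
    # row permutation invariance
    expect_equal(compute_sv(rbind(w, v))$sv, r$sv)
  }
})

test_that("rank_markers orders by sv, then mean length, then id", {
  res <- list(
    list(locus = "b--c", n_mutations = 2, n_indel_events = 0,
         n_conserved = 8, sv = 0.2, mean_len = 10),
    list(locus = "a--b", n_mutations = 2, n_indel_events = 0,
         n_conserved = 8, sv = 0.2, mean_len = 10),
    list(locus = "c--d", n_mutations = 2, n_indel_events = 0,
         n_conserved = 8, sv = 0.2, mean_len = 30),
    list(locus = "z--z", n_mutations = 0, n_indel_events = 0,
         n_conserved = 10, sv = 0, mean_len = 99))
  rk <- rank_markers(res, k = 10)
  expect_equal(rk$locus, c("c--d", "a--b", "b--c", "z--z"))
  expect_equal(nrow(rank_markers(res, k = 2)), 2)
  # sv = 0 loci rank last
  expect_equal(rk$locus[nrow(rk)], "z--z")
})
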