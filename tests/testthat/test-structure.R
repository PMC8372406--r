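test_that("detect_ir reports IR absent on random sequence, agreeing with brute force", {
  set.seed(31)
  rec <- plastome_record("rand", rseq(10000))
  st <- detect_ir(rec, min_len = 100)
  expect_null(st$irb)
  oracle <- plastomics:::.ir_brute_cpp(rec$sequence, 100L, 0L)
  expect_false(oracle$found)
})

test_that("region labels follow marker content, not arc size", {
  set.seed(32)
  mkrec <- function(long_genes, short_genes, long_len = 9000,
                    short_len = 2500, ir_len = 600) {
    ir <- rseq(ir_len)
    long_arc <- rseq(long_len)
    short_arc <- rseq(short_len)
    seqs <- paste0(long_arc, ir, short_arc, rc(ir))
    feats <- list()
    for (i in seq_along(long_genes))
      feats[[length(feats) + 1]] <- gene_feature(
        long_genes[i], "CDS", "+", c(100 * i, 100 * i + 90))
    for (i in seq_along(short_genes))
      feats[[length(feats) + 1]] <- gene_feature(
        short_genes[i], "CDS", "+",
        c(long_len + ir_len + 100 * i, long_len + ir_len + 100 * i + 90))
    plastome_record("toy", seqs, feats)
  }
  n <- 9000 + 2500 + 2 * 600
  ivs <- list(c(9000, 9600), c(12100, 12700))
  # ndh suite on the SHORT arc: normal case
  r1 <- mkrec(c("psbA", "rbcL", "matK"), c("ndhF", "ndhA", "ccsA"))
  s1 <- assign_regions(r1, ivs)
  expect_equal(plastomics:::interval_len(s1$ssc), 2500)
  # ndh suite on the LONG arc: content beats size
  r2 <- mkrec(c("ndhF", "ndhA", "ccsA"), c("psbA", "rbcL", "matK"))
  s2 <- assign_regions(r2, ivs)
  expect_equal(plastomics:::interval_len(s2$ssc), 9000)
  expect_equal(plastomics:::interval_len(s2$lsc), 2500)
  # unannotated: fallback to size
  r3 <- plastome_record("bare", r1$sequence)
  s3 <- assign_regions(r3, ivs)
  expect_equal(plastomics:::interval_len(s3$ssc), 2500)
  # both marker sets on one arc: pathological annotation
  r4 <- mkrec(c("psbA", "rbcL", "ndhF", "ndhA"), character(0))
  expect_error(assign_regions(r4, ivs), "pathological")
})

test_that("canonicalization is rotation- and strand-invariant, and idempotent", {
  anc <- small_ancestor()
  for (off in c(5000, 31337)) {
    rot <- plastomics:::rotate_record(anc$record, off)
    st <- detect_ir(rot)
    expect_false(isTRUE(st$canonical_orientation))
    can <- canonicalize_record(rot, st)
    expect_identical(can$record$sequence, anc$record$sequence)
    expect_identical(can$structure$junctions, anc$structure$junctions)
    # idempotence
    again <- canonicalize_record(can$record, can$structure)
    expect_identical(again$structure$junctions, can$structure$junctions)
    expect_identical(again$record$sequence, can$record$sequence)
  }
  # flipped strand: rbcL on minus triggers a reverse complement
  flip <- plastomics:::revcomp_record(anc$record)
  st <- detect_ir(flip)
  can <- canonicalize_record(flip, st)
  expect_identical(can$record$sequence, anc$record$sequence)
})

test_that("junction_report measures genes spanning and flanking junctions", {
  anc <- small_ancestor()
  st <- anc$structure
  rec <- anc$record
  # plant a gene spanning JLB: 120 bp in the LSC, 80 bp in the IRB
  jlb <- st$junctions[["JLB"]]
  rec$features[[length(rec$features) + 1]] <-
    gene_feature("spanny", "CDS", "+", c(jlb - 120, jlb + 81), pseudo = TRUE)
  jr <- junction_report(rec, st)
  row <- jr[jr$junction == "JLB", ]
  expect_true(row$spans_junction)
  expect_equal(row$gene, "spanny")
  expect_equal(row$bp_upstream, 120)
  expect_equal(row$bp_downstream, 81)
  # a spacer junction reports nearest genes and exact gap lengths
  row2 <- jr[jr$junction == "JSB", ]
  expect_false(row2$spans_junction)
  sp <- lapply(rec$features, plastomics:::feature_span)
  jsb <- st$junctions[["JSB"]]
  gl <- min((jsb - vapply(sp, `[`, numeric(1), 2)) %% st$n)
  gr <- min((vapply(sp, `[`, numeric(1), 1) - jsb) %% st$n)
  expect_equal(row2$gap_left, gl)
  expect_equal(row2$gap_right, gr)
  expect_match(row2$gene, "--")
})

test_that("classify_shift separates large-scale IR shifts (Group B)", {
  mk <- function(L, I, S) plastomics:::canonical_structure(L, I, S)
  a <- classify_shift(mk(90309, 26590, 17023))
  expect_equal(a$group, "A")
  expect_length(a$reasons, 0)
  b1 <- classify_shift(mk(94275, 355, 41645))
  expect_equal(b1$group, "B")
  expect_match(b1$reasons, "ir_len", all = FALSE)
  b2 <- classify_shift(mk(83278, 43573, 8226))
  expect_equal(b2$group, "B")
  expect_true(any(grepl("> 35000", b2$reasons)))
  b3 <- classify_shift(mk(85524, 43088, 3360))
  expect_true(any(grepl("ssc", b3$reasons)))
})

test_that("gc_content follows the N-excluding definition", {
  expect_equal(gc_content("ACGT"), 50.0)
  expect_equal(gc_content("AAAA"), 0.0)
  expect_equal(gc_content("GGNNAA"), 50.0)  # N excluded from both terms
  expect_error(gc_content("NNNN"), "all N")
  anc <- small_ancestor()
  expect_equal(gc_content(anc$record, anc$structure$irb),
               gc_content(substr(anc$record$sequence,
                                 anc$structure$irb[1] + 1,
                                 anc$structure$irb[2])))
})

test_that("regions tile the genome", {
  anc <- small_ancestor()
  st <- detect_ir(anc$record)
  expect_equal(plastomics:::interval_len(st$lsc) +
                 plastomics:::interval_len(st$ssc) + 2 * st$ir_len, st$n)
})
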