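test_that("build_ancestor assembles an exact quadripartite genome", {
  spec <- ancestor_spec(lsc_len = 8000, ssc_len = 2000, ir_len = 1500,
                        seed = 1)
  anc <- build_ancestor(spec)
  n <- nchar(anc$record$sequence)
  expect_equal(n, 8000 + 2000 + 2 * 1500)
  st <- anc$structure
  irb <- substr(anc$record$sequence, st$irb[1] + 1, st$irb[2])
  ira <- substr(anc$record$sequence, st$ira[1] + 1, st$ira[2])
  expect_identical(ira, rc(irb))
  # detector recovers the construction exactly
  det <- detect_ir(anc$record)
  expect_identical(det$junctions, st$junctions)
  expect_equal(det$ir_len, 1500)
  # every non-pseudo CDS is a clean ORF
  for (f in anc$record$features) {
    if (f$category != "CDS") next
    cds <- plastomics:::feature_sequence(anc$record, f)
    expect_equal(nchar(cds) %% 3, 0)
    expect_match(cds, "^ATG")
    expect_false(plastomics:::has_internal_stop(cds))
  }
})

test_that("ir_len = 0 gives a genome without an IR", {
  anc <- build_ancestor(ancestor_spec(lsc_len = 8000, ssc_len = 2000,
                                      ir_len = 0, seed = 2))
  expect_equal(nchar(anc$record$sequence), 10000)
  st <- detect_ir(anc$record, min_len = 100)
  expect_null(st$irb)
  expect_equal(st$ir_len, 0)
})

test_that("same spec and seed reproduce the genome byte for byte", {
  a <- build_ancestor(ancestor_spec(lsc_len = 7000, ssc_len = 2000,
                                    ir_len = 1200, seed = 33))
  b <- build_ancestor(ancestor_spec(lsc_len = 7000, ssc_len = 2000,
                                    ir_len = 1200, seed = 33))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$features, b$record$features)
})

test_that("an explicit template that overflows its region errors", {
  tpl <- default_gene_template()
  expect_error(
    build_ancestor(ancestor_spec(lsc_len = 5000, ssc_len = 2000,
                                 ir_len = 1500, gene_template = tpl,
                                 seed = 1)),
    "overflow")
})

test_that("all-zero rates leave every tip identical to the ancestor", {
  anc <- small_ancestor()
  ev <- evolve_plastomes(anc, "((A:0.1,B:0.1):0.05,C:0.15);",
                         rates = list(sub_rate = 0, indel_rate = 0),
                         seed = 4)
  for (r in ev$records)
    expect_identical(r$sequence, anc$record$sequence)
})

test_that("substitution counts match the closed-form JC expectation", {
  anc <- small_ancestor()
  r <- 1
  t <- 0.08
  ev <- evolve_plastomes(anc, sprintf("(A:%g,B:0);", t),
                         rates = list(sub_rate = r), seed = 6)
  p <- 0.75 * (1 - exp(-4 * r * t / 3))
  # count on the LSC only (the unique region without mirroring)
  L <- plastomics:::interval_len(anc$structure$lsc)
  a <- strsplit(substr(ev$records$A$sequence, 1, L), "")[[1]]
  b <- strsplit(substr(anc$record$sequence, 1, L), "")[[1]]
  d <- sum(a != b)
  expected <- p * (L - 2)  # two LSC wall positions are held fixed
  sd3 <- 3 * sqrt(L * p * (1 - p))
  expect_lt(abs(d - expected), sd3)
  # B sat on a zero-length branch
  expect_identical(ev$records$B$sequence, anc$record$sequence)
})

test_that("concerted evolution keeps IRA the exact revcomp of IRB", {
  anc <- small_ancestor()
  ev <- evolve_plastomes(anc, "(A:0.1,B:0.05);",
                         rates = list(sub_rate = 1, indel_rate = 2e-4),
                         seed = 8)
  for (tp in names(ev$records)) {
    st <- ev$truth$tips[[tp]]$structure
    s <- ev$records[[tp]]$sequence
    irb <- substr(s, st$irb[1] + 1, st$irb[2])
    ira <- substr(s, st$ira[1] + 1, st$ira[2])
    expect_identical(ira, rc(irb))
  }
})

test_that("same evolve seed reproduces every tip exactly", {
  anc <- small_ancestor()
  rates <- list(sub_rate = 1, indel_rate = 1e-4,
                event_rates = list(ir_expand = 5, plant_ssr = 10))
  e1 <- evolve_plastomes(anc, "((A:0.05,B:0.05):0.02,C:0.07);", rates, seed = 9)
  e2 <- evolve_plastomes(anc, "((A:0.05,B:0.05):0.02,C:0.07);", rates, seed = 9)
  expect_identical(lapply(e1$records, `[[`, "sequence"),
                   lapply(e2$records, `[[`, "sequence"))
})

test_that("negative branch lengths are rejected", {
  anc <- small_ancestor()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  tr$edge.length[1] <- -0.01
  expect_error(evolve_plastomes(anc, tr, seed = 1), "negative")
})

test_that("genome length changes equal the signed sum of event effects", {
  anc <- small_ancestor()
  ev <- evolve_plastomes(
    anc, "((A:0.04,B:0.04):0.02,(C:0.04,D:0.04):0.02);",
    rates = list(sub_rate = 0.5, indel_rate = 5e-4,
                 event_rates = list(ir_expand = 10, ir_contract = 10,
                                    gene_loss = 10, inversion = 10,
                                    plant_ssr = 20, plant_tandem = 10,
                                    plant_dispersed = 10)),
    seed = 12)
  for (tp in names(ev$records)) {
    deltas <- sum(vapply(ev$truth$tips[[tp]]$events,
                         function(e) e$delta, numeric(1)))
    expect_equal(nchar(ev$records[[tp]]$sequence) -
                   nchar(anc$record$sequence), deltas, info = tp)
  }
})

test_that("junction shift grows the IR and the genome by exactly k", {
  anc <- small_ancestor()
  for (j in c("JLB", "JSB", "JSA", "JLA")) {
    res <- apply_junction_shift(anc$record, anc$structure, j, 700)
    expect_equal(nchar(res$record$sequence),
                 nchar(anc$record$sequence) + 700, info = j)
    det <- detect_ir(res$record)
    expect_equal(det$ir_len, anc$structure$ir_len + 700, info = j)
    expect_identical(det$junctions, res$structure$junctions, info = j)
    # shift +k then -k restores all region lengths
    back <- apply_junction_shift(res$record, res$structure, j, -700)
    expect_equal(back$structure$ir_len, anc$structure$ir_len, info = j)
    expect_equal(nchar(back$record$sequence), nchar(anc$record$sequence),
                 info = j)
  }
})

test_that("expansion duplicates the genes it engulfs", {
  anc <- small_ancestor()
  st <- anc$structure
  nm <- vapply(anc$record$features, `[[`, character(1), "name")
  # genes in the SSC margin next to JSB
  sp <- lapply(anc$record$features, plastomics:::feature_span)
  margin <- which(vapply(sp, function(x)
    x[1] >= st$ssc[1] && x[2] <= st$ssc[1] + 3000, logical(1)))
  stopifnot(length(margin) >= 1)
  res <- apply_junction_shift(anc$record, st, "JSB", 3200)
  nm2 <- vapply(res$record$features, `[[`, character(1), "name")
  for (g in nm[margin])
    expect_equal(sum(nm2 == g), sum(nm == g) + 1, info = g)
})

test_that("junction shift respects the single-copy bound", {
  anc <- small_ancestor()
  S <- plastomics:::interval_len(anc$structure$ssc)
  expect_error(apply_junction_shift(anc$record, anc$structure, "JSB", S),
               "entire single-copy")
  expect_error(apply_junction_shift(anc$record, anc$structure, "JSB",
                                    -anc$structure$ir_len),
               "exceeds the IR")
})

test_that("pseudogenize plants a detectable internal stop, reproducibly", {
  anc <- small_ancestor()
  rec <- pseudogenize(anc$record, "rbcL", seed = 21)
  f <- rec$features[[which(vapply(rec$features, `[[`, character(1),
                                  "name") == "rbcL")]]
  cds <- plastomics:::feature_sequence(rec, f)
  expect_true(plastomics:::has_internal_stop(cds))
  expect_false(f$pseudo)  # the annotation is NOT flagged
  cl <- classify_gene(rec, anc$structure, "rbcL")
  expect_equal(cl$status, "pseudo")
  expect_true("internal_stop" %in% cl$evidence)
  rec2 <- pseudogenize(anc$record, "rbcL", seed = 21)
  expect_identical(rec$sequence, rec2$sequence)
  expect_error(pseudogenize(anc$record, "nosuchgene"), "absent")
})

test_that("pseudogenize keeps IR duplicates concerted", {
  anc <- small_ancestor()
  g <- "rpl2"   # IR-duplicated, multi-exon, minus strand
  rec <- pseudogenize(anc$record, g, seed = 5)
  st <- detect_ir(rec)
  expect_equal(st$ir_len, anc$structure$ir_len)  # still a perfect IR
})

test_that("planted repeats are found with exact coordinates", {
  anc <- build_ancestor(ancestor_spec(lsc_len = 12000, ssc_len = 3000,
                                      ir_len = 2000, seed = 55))
  set.seed(77)
  ps <- plant_ssr(anc$record, anc$structure, "AT", 8)
  got <- find_ssrs(ps$record)
  expect_true(any(got$motif == "AT" & got$start == ps$hit$start &
                    got$length == ps$hit$length & got$copies == 8))
  pt <- plant_tandem(ps$record, ps$structure, "ACGTTGCAGT", 9)
  tand <- find_tandem(pt$record)
  expect_true(any(tand$period == 10 & tand$start == pt$hit$start &
                    tand$length == pt$hit$length))
  for (kind in c("Forward", "Reverse", "Complement", "Palindromic")) {
    pd <- plant_dispersed(pt$record, pt$structure, kind, length = 42,
                          mismatches = 3)
    pt <- pd
    hits <- find_dispersed(pd$record)
    h <- pd$hit
    expect_true(any(hits$kind == h$kind & hits$start1 == h$start1 &
                      hits$start2 == h$start2 & hits$length == h$length &
                      hits$mismatches == h$mismatches),
                info = kind)
  }
})
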