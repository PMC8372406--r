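test_that("SSR thresholds and literal motif classes follow the conventions", {
  set.seed(61)
  pad1 <- rseq(40); pad2 <- rseq(40)
  s10 <- paste0(pad1, "G", strrep("A", 10), "C", pad2)
  hits <- find_ssrs(s10, circular = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "A")
  expect_equal(hits$copies, 10)
  s9 <- paste0(pad1, "G", strrep("A", 9), "C", pad2)
  expect_equal(nrow(find_ssrs(s9, circular = FALSE)), 0)
  # leftmost phase: an AT run is AT, never TA; A and T stay distinct classes
  sat <- paste0("G", strrep("AT", 6), "GG")
  h2 <- find_ssrs(sat, circular = FALSE)
  expect_equal(h2$motif, "AT")
  expect_equal(h2$copies, 6)
})

test_that("circular SSR runs spanning the origin are detected", {
  set.seed(62)
  s <- paste0("AAAAA", rseq(60), "CAAAAA")  # run wraps: 5 + 5 around origin
  h <- find_ssrs(s, circular = TRUE)
  expect_true(any(h$motif == "A" & h$copies == 10 & h$start == 66))
  expect_equal(nrow(find_ssrs(s, circular = FALSE)), 0)
})

test_that("SSR scanner equals the definition-driven oracle on random input", {
  set.seed(63)
  th <- c(5, 3, 3, 3, 3, 3)  # low thresholds so random 300-mers have hits
  for (trial in 1:25) {
    s <- rseq(300)
    got <- sort_hits(find_ssrs(s, thresholds = th, circular = FALSE))
    want <- sort_hits(ssr_oracle(s, thresholds = th, circular = FALSE))
    expect_equal(got, want, info = paste("trial", trial))
  }
})

test_that("tandem scoring matches the spec arithmetic", {
  t1 <- find_tandem(strrep("ACGT", 30))
  expect_equal(nrow(t1), 1)
  expect_equal(t1$period, 4)
  expect_equal(t1$copy_number, 30)
  expect_equal(t1$score, 2 * (120 - 4))
  # 4 copies of a 10-mer score 2*30 = 60 < 80: below threshold
  expect_equal(nrow(find_tandem(strrep("ACGTTGCAGT", 4))), 0)
  # one substitution costs match + mismatch = 9
  arr <- strrep("ACGTTGCAGT", 30)
  substr(arr, 55, 55) <- "C"
  t2 <- find_tandem(arr)
  expect_equal(t2$score[1], 2 * (300 - 10) - 9)
})

test_that("dispersed kinds, lengths and Hamming budget behave as defined", {
  set.seed(64)
  g0 <- rseq(2000)
  seg <- substr(g0, 101, 140)
  # planted exact reverse complement elsewhere -> one palindromic hit
  g <- paste0(substr(g0, 1, 1000), "CC", rc(seg), "GG", substr(g0, 1043, 2000))
  hits <- find_dispersed(g, min_len = 40, max_hamming = 0)
  pal <- hits[hits$kind == "Palindromic" & hits$length >= 40, ]
  expect_gte(nrow(pal), 1)
  expect_true(any(pal$start1 == 100 & pal$length == 40 & pal$mismatches == 0))
  # forward copy with 3 substitutions is one hit; with 4 it breaks apart
  mangle <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- round(seq(8, nchar(s) - 8, length.out = k))
    for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  g3 <- paste0(substr(g0, 1, 1000), "CC", mangle(seg, 3), "GG",
               substr(g0, 1043, 2000))
  h3 <- find_dispersed(g3, min_len = 40, max_hamming = 3)
  expect_true(any(h3$kind == "Forward" & h3$length >= 40 & h3$start1 <= 100 &
                    h3$mismatches <= 3))
  g4 <- paste0(substr(g0, 1, 1000), "CC", mangle(seg, 4), "GG",
               substr(g0, 1043, 2000))
  h4 <- find_dispersed(g4, min_len = 40, max_hamming = 3)
  expect_false(any(h4$kind == "Forward" & h4$length >= 40 &
                     h4$start1 >= 95 & h4$start1 <= 105))
})

test_that("dispersed scanner equals the brute-force oracle on random input", {
  set.seed(65)
  for (trial in 1:10) {
    s <- rseq(500)
    got <- find_dispersed(s, min_len = 12, max_hamming = 2)
    want <- plastomics:::.dispersed_brute_cpp(s, 12L, 2L)
    expect_equal(got, want, info = paste("trial", trial))
  }
})

test_that("repeat calls are reverse-complement invariant with kinds exchanged", {
  set.seed(66)
  for (trial in 1:5) {
    s <- paste0(rseq(400), substr(rseq(400), 1, 60), rseq(200))
    a <- find_dispersed(s, min_len = 14, max_hamming = 1)
    b <- find_dispersed(rc(s), min_len = 14, max_hamming = 1)
    cnt <- function(df) c(Forward = sum(df$kind == "Forward"),
                          Palindromic = sum(df$kind == "Palindromic"),
                          Reverse = sum(df$kind == "Reverse"),
                          Complement = sum(df$kind == "Complement"))
    ca <- cnt(a); cb <- cnt(b)
    expect_equal(cb[["Forward"]], ca[["Forward"]])
    expect_equal(cb[["Palindromic"]], ca[["Palindromic"]])
    expect_equal(cb[["Reverse"]], ca[["Reverse"]])
    expect_equal(cb[["Complement"]], ca[["Complement"]])
    # SSR counts are preserved with A<->T, C<->G motif classes exchanged
    sa <- find_ssrs(s, thresholds = c(5, 3, 3, 3, 3, 3), circular = FALSE)
    sb <- find_ssrs(rc(s), thresholds = c(5, 3, 3, 3, 3, 3), circular = FALSE)
    expect_equal(nrow(sa), nrow(sb))
  }
})

test_that("the IR pair surfaces as one maximal palindromic hit", {
  anc <- build_ancestor(ancestor_spec(lsc_len = 9000, ssc_len = 2500,
                                      ir_len = 1500, seed = 9))
  # with a zero Hamming budget the hit IS the IR, exactly
  h0 <- find_dispersed(anc$record, max_hamming = 0)
  big0 <- h0[h0$length >= 1500, ]
  expect_equal(nrow(big0), 1)
  expect_equal(big0$kind, "Palindromic")
  expect_equal(big0$length, 1500)
  expect_equal(big0$start1, unname(anc$structure$irb[1]))
  expect_equal(big0$start2, unname(anc$structure$ira[1]))
  # under the default budget the maximal hit may absorb up to max_hamming
  # flanking mismatches but still contains the IR
  h3 <- find_dispersed(anc$record)
  big3 <- h3[h3$length >= 1500 & h3$kind == "Palindromic", ]
  expect_gte(nrow(big3), 1)
  expect_true(all(big3$length <= 1500 + 2 * 3 + 2))
})
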