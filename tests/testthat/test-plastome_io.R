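toy_genbank <- function(path) {
  seq120 <- paste(rep("acgtacgtac", 12), collapse = "")
  writeLines(c(
    "LOCUS       toy01                120 bp    DNA     circular PLN 01-JAN-2020",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..18",
    '                     /gene="genA"',
    "     CDS             complement(join(5..10,20..25))",
    '                     /gene="genB"',
    "     tRNA            30..41",
    '                     /gene="trnX-ABC"',
    "                     /pseudo",
    "     rRNA            join(50..61,70..81)",
    '                     /product="rrnToy"',
    "ORIGIN",
    paste("        1", paste(substring(seq120, seq(1, 111, 10),
                                       seq(10, 120, 10)), collapse = " ")),
    "//"), path)
  path
}

test_that("read_genbank converts coordinates, strands, joins and pseudo flags", {
  gb <- toy_genbank(withr::local_tempfile(fileext = ".gb"))
  rec <- read_genbank(gb)
  expect_s3_class(rec, "plastome_record")
  expect_equal(nchar(rec$sequence), 120)
  expect_true(rec$circular)
  nm <- vapply(rec$features, `[[`, character(1), "name")
  a <- rec$features[[which(nm == "genA")]]
  expect_equal(unname(a$parts[1, ]), c(9, 18))   # 10..18 -> [9, 18)
  expect_equal(a$strand, "+")
  b <- rec$features[[which(nm == "genB")]]
  expect_equal(b$strand, "-")
  # transcription order for a minus-strand join: downstream exon first
  expect_equal(unname(b$parts), matrix(c(19, 25, 4, 10), 2, 2, byrow = TRUE))
  expect_true(rec$features[[which(nm == "trnX-ABC")]]$pseudo)
  r <- rec$features[[which(nm == "rrnToy")]]
  expect_equal(r$category, "rRNA")
  expect_equal(nrow(r$parts), 2)
})

test_that("read_genbank agrees with Biopython on the toy record", {
  gb <- toy_genbank(withr::local_tempfile(fileext = ".gb"))
  py <- sprintf(paste0(
    "import json\nfrom Bio import SeqIO\n",
    "r = SeqIO.read(%s, 'genbank')\n",
    "out = []\n",
    "for f in r.features:\n",
    "    if f.type == 'source': continue\n",
    "    parts = sorted([[int(p.start), int(p.end)] for p in f.location.parts])\n",
    "    out.append({'type': f.type, 'strand': f.location.strand,\n",
    "                'parts': parts,\n",
    "                'gene': f.qualifiers.get('gene', [None])[0]})\n",
    "print(json.dumps({'len': len(r.seq), 'seq': str(r.seq),",
    " 'features': out}))\n"), deparse(gb))
  res <- system2("python", "-", input = py, stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""),
                            simplifyDataFrame = FALSE)
  rec <- read_genbank(gb)
  expect_equal(nchar(rec$sequence), ref$len)
  expect_equal(rec$sequence, toupper(ref$seq))
  nm <- vapply(rec$features, `[[`, character(1), "name")
  for (f in ref$features) {
    if (is.null(f$gene)) next
    mine <- rec$features[[which(nm == f$gene)]]
    expect_equal(mine$strand, if (f$strand < 0) "-" else "+",
                 info = f$gene)
    # same part set (Biopython keeps file order; we keep transcription order)
    mine_parts <- mine$parts[order(mine$parts[, 1]), , drop = FALSE]
    ref_parts <- if (is.matrix(f$parts)) f$parts
                 else matrix(unlist(f$parts), ncol = 2, byrow = TRUE)
    expect_equal(unname(mine_parts), unname(ref_parts), info = f$gene)
  }
})

test_that("GenBank reader rejects malformed and multi-record input", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS a", "LOCUS b"), p)
  expect_error(read_genbank(p), "multi-record")
  writeLines(c("FEATURES", "ORIGIN"), p)
  expect_error(read_genbank(p), "LOCUS")
})

test_that("FASTA+GFF3 round trip reproduces the record", {
  set.seed(42)
  anc <- build_ancestor(ancestor_spec(lsc_len = 6000, ssc_len = 1800,
                                      ir_len = 1200, seed = 5))
  rec <- anc$record
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_output(rec, fa, "fasta")
  write_output(rec, gff, "gff3")
  back <- read_fasta_gff(fa, gff)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(length(back$features), length(rec$features))
  key <- function(r) {
    k <- vapply(r$features, function(f)
      paste(f$name, f$category, f$strand, f$pseudo,
            paste(t(f$parts[order(f$parts[, 1]), , drop = FALSE]),
                  collapse = ","), sep = "|"), character(1))
    sort(k)
  }
  expect_equal(key(back), key(rec))
})

test_that("GFF3 1-based inclusive coordinates map to 0-based half-open", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr1", strrep("ACGT", 25)), fa)
  writeLines(c("##gff-version 3",
               "chr1\t.\tCDS\t1\t4\t.\t+\t0\tID=g1;Name=genA",
               "chr1\t.\ttRNA\t11\t20\t.\t-\t.\tID=g2;Name=trnZ"), gff)
  rec <- read_fasta_gff(fa, gff)
  nm <- vapply(rec$features, `[[`, character(1), "name")
  expect_equal(unname(rec$features[[which(nm == "genA")]]$parts[1, ]),
               c(0, 4))
  expect_equal(rec$features[[which(nm == "trnZ")]]$strand, "-")
})

test_that("FASTA/GFF id mismatch and out-of-range coordinates error", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chrA", "ACGTACGT"), fa)
  writeLines(c("##gff-version 3",
               "chrB\t.\tCDS\t1\t4\t.\t+\t0\tID=g1"), gff)
  expect_error(read_fasta_gff(fa, gff), "does not match")
  writeLines(c("##gff-version 3",
               "chrA\t.\tCDS\t1\t400\t.\t+\t0\tID=g1"), gff)
  expect_error(read_fasta_gff(fa, gff), "outside")
})

test_that("structure BED output has one line per region, 0-based half-open", {
  anc <- small_ancestor()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_output(anc$structure, bed, "bed")
  lines <- read.delim(bed, header = FALSE)
  expect_equal(nrow(lines), 4)
  expect_setequal(lines$V4, c("LSC", "IRB", "SSC", "IRA"))
  expect_equal(lines$V2[lines$V4 == "LSC"], 0)
  expect_equal(lines$V3[lines$V4 == "IRA"], nchar(anc$record$sequence))
  # BED start = GFF3 start - 1 for the same interval
  expect_equal(lines$V2[lines$V4 == "IRB"],
               unname(anc$structure$irb[1] + 1) - 1)
})

test_that("newick output round-trips", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1,D:1):0.25);")
  p <- withr::local_tempfile(fileext = ".nwk")
  write_output(tr, p, "newick")
  back <- ape::read.tree(p)
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
})

test_that("SV tables are written sorted by SV descending", {
  res <- list(
    list(locus = "a--b", n_mutations = 1, n_indel_events = 0,
         n_conserved = 9, sv = 0.1, mean_len = 10),
    list(locus = "c--d", n_mutations = 3, n_indel_events = 1,
         n_conserved = 6, sv = 0.4, mean_len = 10))
  tab <- rank_markers(res, k = 10)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_output(tab, p, "tsv")
  got <- read.delim(p, comment.char = "#")
  expect_equal(got$locus, c("c--d", "a--b"))
})
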