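# Built-in canonical plastid gene template: ~110 entries in the typical
# gene order of a photosynthetic angiosperm plastome. Lengths are rounded
# plausible values (CDS lengths are multiples of 3); `introns` holds
# comma-separated intron lengths for the cis-spliced multi-exon genes.
# The rrn operon and its tRNAs sit in the IR; the ndh suite, ccsA and ycf1
# in or near the SSC; psbA, rbcL, matK and the atp/psa/psb/rpo clusters in
# the LSC. These placements are what the marker-gene region labelling of
# the structure module relies on.

template_row <- function(name, category, strand, length, region,
                         introns = "") {
  data.frame(name = name, category = category, strand = strand,
             length = as.integer(length), region = region,
             introns = introns, stringsAsFactors = FALSE)
}

#' Canonical plastid gene template
#'
#' The default gene complement used by [build_ancestor()]: an ordered table
#' of ~110 genes with category, strand, length, intron structure and home
#' region (LSC, SSC or IR).
#'
#' @return A data frame with columns `name`, `category`, `strand`, `length`,
#'   `region`, `introns`.
#' @export
default_gene_template <- function() {
  L <- list(
    # --- LSC, starting just after the canonical origin (JLA) ---
    template_row("trnH-GUG", "tRNA", "-", 75, "LSC"),
    template_row("psbA",  "CDS", "-", 1062, "LSC"),
    template_row("matK",  "CDS", "-", 1500, "LSC"),
    template_row("trnK-UUU", "tRNA", "-", 72, "LSC"),
    template_row("rps16", "CDS", "-", 261, "LSC", "860"),
    template_row("trnQ-UGG", "tRNA", "-", 72, "LSC"),
    template_row("psbK",  "CDS", "+", 186, "LSC"),
    template_row("psbI",  "CDS", "+", 111, "LSC"),
    template_row("trnS-GCU", "tRNA", "-", 88, "LSC"),
    template_row("trnG-UCC", "tRNA", "+", 71, "LSC"),
    template_row("trnR-UCU", "tRNA", "+", 72, "LSC"),
    template_row("atpA",  "CDS", "-", 1524, "LSC"),
    template_row("atpF",  "CDS", "-", 555, "LSC", "700"),
    template_row("atpH",  "CDS", "-", 246, "LSC"),
    template_row("atpI",  "CDS", "-", 744, "LSC"),
    template_row("rps2",  "CDS", "-", 711, "LSC"),
    template_row("rpoC2", "CDS", "-", 4140, "LSC"),
    template_row("rpoC1", "CDS", "-", 2052, "LSC"),
    template_row("rpoB",  "CDS", "-", 3213, "LSC"),
    template_row("trnC-GCA", "tRNA", "+", 71, "LSC"),
    template_row("petN",  "CDS", "+", 90, "LSC"),
    template_row("psbM",  "CDS", "-", 105, "LSC"),
    template_row("trnD-GUC", "tRNA", "-", 74, "LSC"),
    template_row("trnY-GUA", "tRNA", "-", 84, "LSC"),
    template_row("trnE-UUC", "tRNA", "-", 73, "LSC"),
    template_row("trnT-GGU", "tRNA", "+", 72, "LSC"),
    template_row("psbD",  "CDS", "+", 1062, "LSC"),
    template_row("psbC",  "CDS", "+", 1422, "LSC"),
    template_row("trnS-UGA", "tRNA", "-", 93, "LSC"),
    template_row("psbZ",  "CDS", "+", 189, "LSC"),
    template_row("trnG-GCC", "tRNA", "+", 71, "LSC"),
    template_row("trnfM-CAU", "tRNA", "-", 74, "LSC"),
    template_row("rps14", "CDS", "-", 303, "LSC"),
    template_row("psaB",  "CDS", "-", 2205, "LSC"),
    template_row("psaA",  "CDS", "-", 2253, "LSC"),
    template_row("ycf3",  "CDS", "-", 507, "LSC", "740,720"),
    template_row("trnS-GGA", "tRNA", "+", 87, "LSC"),
    template_row("rps4",  "CDS", "-", 606, "LSC"),
    template_row("trnT-UGU", "tRNA", "-", 73, "LSC"),
    template_row("trnL-UAA", "tRNA", "+", 85, "LSC", "500"),
    template_row("trnF-GAA", "tRNA", "+", 73, "LSC"),
    template_row("ndhJ",  "CDS", "-", 477, "LSC"),
    template_row("ndhK",  "CDS", "-", 678, "LSC"),
    template_row("ndhC",  "CDS", "-", 363, "LSC"),
    template_row("trnV-UAC", "tRNA", "-", 73, "LSC", "570"),
    template_row("trnM-CAU", "tRNA", "+", 73, "LSC"),
    template_row("atpE",  "CDS", "+", 402, "LSC"),
    template_row("atpB",  "CDS", "+", 1497, "LSC"),
    template_row("rbcL",  "CDS", "+", 1428, "LSC"),
    template_row("accD",  "CDS", "+", 1488, "LSC"),
    template_row("psaI",  "CDS", "+", 111, "LSC"),
    template_row("ycf4",  "CDS", "+", 555, "LSC"),
    template_row("cemA",  "CDS", "+", 690, "LSC"),
    template_row("petA",  "CDS", "+", 963, "LSC"),
    template_row("psbJ",  "CDS", "-", 123, "LSC"),
    template_row("psbL",  "CDS", "-", 117, "LSC"),
    template_row("psbF",  "CDS", "-", 120, "LSC"),
    template_row("psbE",  "CDS", "-", 252, "LSC"),
    template_row("petL",  "CDS", "+", 96, "LSC"),
    template_row("petG",  "CDS", "+", 114, "LSC"),
    template_row("trnW-CCA", "tRNA", "-", 74, "LSC"),
    template_row("trnP-UGG", "tRNA", "-", 74, "LSC"),
    template_row("psaJ",  "CDS", "+", 135, "LSC"),
    template_row("rpl33", "CDS", "+", 201, "LSC"),
    template_row("rps18", "CDS", "+", 306, "LSC"),
    template_row("rpl20", "CDS", "-", 354, "LSC"),
    template_row("clpP",  "CDS", "-", 591, "LSC", "800,620"),
    template_row("psbB",  "CDS", "+", 1527, "LSC"),
    template_row("psbT",  "CDS", "+", 108, "LSC"),
    template_row("psbN",  "CDS", "-", 132, "LSC"),
    template_row("psbH",  "CDS", "+", 222, "LSC"),
    template_row("petB",  "CDS", "+", 648, "LSC", "750"),
    template_row("petD",  "CDS", "+", 483, "LSC", "700"),
    template_row("rpoA",  "CDS", "-", 1014, "LSC"),
    template_row("rps11", "CDS", "-", 417, "LSC"),
    template_row("rpl36", "CDS", "-", 114, "LSC"),
    template_row("infA",  "CDS", "-", 234, "LSC"),
    template_row("rps8",  "CDS", "-", 405, "LSC"),
    template_row("rpl14", "CDS", "-", 369, "LSC"),
    template_row("rpl16", "CDS", "-", 408, "LSC", "1000"),
    template_row("rps3",  "CDS", "-", 657, "LSC"),
    template_row("rpl22", "CDS", "-", 462, "LSC"),
    template_row("rps19", "CDS", "-", 279, "LSC"),
    # --- IR (one copy listed; the builder mirrors it) ---
    template_row("rpl2",  "CDS", "-", 822, "IR", "660"),
    template_row("rpl23", "CDS", "-", 282, "IR"),
    template_row("trnI-CAU", "tRNA", "-", 74, "IR"),
    template_row("ycf2",  "CDS", "+", 6837, "IR"),
    template_row("trnL-CAA", "tRNA", "-", 81, "IR"),
    template_row("ndhB",  "CDS", "-", 1533, "IR", "680"),
    template_row("rps7",  "CDS", "-", 468, "IR"),
    template_row("trnV-GAC", "tRNA", "+", 72, "IR"),
    template_row("rrn16", "rRNA", "+", 1490, "IR"),
    template_row("trnI-GAU", "tRNA", "+", 72, "IR", "940"),
    template_row("trnA-UGC", "tRNA", "+", 73, "IR", "800"),
    template_row("rrn23", "rRNA", "+", 2810, "IR"),
    template_row("rrn4.5", "rRNA", "+", 103, "IR"),
    template_row("rrn5",  "rRNA", "+", 121, "IR"),
    template_row("trnR-ACG", "tRNA", "+", 74, "IR"),
    template_row("trnN-GUU", "tRNA", "-", 72, "IR"),
    # --- SSC ---
    template_row("ndhF",  "CDS", "-", 2241, "SSC"),
    template_row("rpl32", "CDS", "+", 171, "SSC"),
    template_row("trnL-UAG", "tRNA", "+", 80, "SSC"),
    template_row("ccsA",  "CDS", "+", 969, "SSC"),
    template_row("ndhD",  "CDS", "-", 1503, "SSC"),
    template_row("psaC",  "CDS", "-", 246, "SSC"),
    template_row("ndhE",  "CDS", "-", 306, "SSC"),
    template_row("ndhG",  "CDS", "-", 531, "SSC"),
    template_row("ndhI",  "CDS", "-", 504, "SSC"),
    template_row("ndhA",  "CDS", "-", 1092, "SSC", "1080"),
    template_row("ndhH",  "CDS", "-", 1182, "SSC"),
    template_row("rps15", "CDS", "-", 273, "SSC"),
    template_row("ycf1",  "CDS", "+", 5100, "SSC")
  )
  do.call(rbind, L)
}

# marker sets used for region labelling (structure module) and protected
# from loss events in the simulator
SSC_MARKERS <- c("ndhF", "ndhA", "ndhD", "ccsA", "ycf1")
LSC_MARKERS <- c("psbA", "rbcL", "matK", "atpA")
IR_CORE <- c("rrn16", "rrn23", "rrn4.5", "rrn5", "rpl2", "rpl23",
             "trnI-CAU", "trnA-UGC", "trnI-GAU")

# genomic span of one template gene (coding length + introns)
template_span <- function(row) {
  intr <- if (nzchar(row$introns))
    sum(as.integer(strsplit(row$introns, ",")[[1]])) else 0L
  row$length + intr
}

# Scale the default template to the requested region sizes: fit the marker
# and IR-core genes first (smallest first, so that small regions still get
# some region-labelling markers), then add the remaining genes in template
# order while they fit alongside `gap_mean` bp of intergenic DNA per gap.
scale_template <- function(template, lsc_len, ssc_len, ir_len,
                           gap_mean = 150) {
  spans <- vapply(seq_len(nrow(template)), function(i)
    template_span(template[i, ]), numeric(1))
  keep <- logical(nrow(template))
  priority <- template$name %in% c(SSC_MARKERS, LSC_MARKERS, IR_CORE)
  for (region in c("LSC", "SSC", "IR")) {
    cap <- switch(region, LSC = lsc_len, SSC = ssc_len, IR = ir_len)
    rows <- which(template$region == region)
    if (length(rows) == 0 || cap == 0) next
    pr <- rows[priority[rows]]
    pr <- pr[order(spans[pr])]
    ord <- c(pr, rows[!priority[rows]])
    used <- 0
    sel <- integer(0)
    for (i in ord) {
      need <- spans[i] + gap_mean
      if (used + need + gap_mean <= cap) {
        used <- used + need
        sel <- c(sel, i)
      }
    }
    if (length(sel) == 0 && cap > 0 && length(rows) > 0 && region != "IR")
      stop(sprintf("region %s (%d bp) cannot hold any template gene",
                   region, cap))
    keep[sel] <- TRUE
  }
  template[keep, , drop = FALSE]
}
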