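# Quadripartite structure: IR detection, LSC/SSC labelling by marker-gene
# content, junction characterization and large-scale shift classification.

new_structure <- function(n, lsc, irb = NULL, ssc = NULL, ira = NULL,
                          mismatches = 0L, canonical = NA, id = NULL) {
  lsc <- as.integer(lsc)
  if (!is.null(irb)) irb <- as.integer(irb)
  if (!is.null(ssc)) ssc <- as.integer(ssc)
  if (!is.null(ira)) ira <- as.integer(ira)
  ir_len <- if (is.null(irb)) 0L else as.integer(interval_len(irb))
  junctions <- if (is.null(irb)) NULL else
    as.integer(c(JLB = irb[1] %% n, JSB = ssc[1] %% n, JSA = ira[1] %% n,
                 JLA = lsc[1] %% n))
  if (!is.null(junctions))
    names(junctions) <- c("JLB", "JSB", "JSA", "JLA")
  structure(list(n = as.integer(n), lsc = lsc, irb = irb, ssc = ssc,
                 ira = ira, ir_len = ir_len, junctions = junctions,
                 mismatches = as.integer(mismatches),
                 canonical_orientation = canonical, id = id),
            class = "quadripartite_structure")
}

# canonical layout LSC | IRB | SSC | IRA with the origin at JLA
canonical_structure <- function(L, I, S, id = NULL) {
  n <- L + 2 * I + S
  if (I == 0) return(new_structure(n, lsc = c(0, n), canonical = TRUE,
                                   id = id))
  new_structure(n, lsc = c(0, L), irb = c(L, L + I),
                ssc = c(L + I, L + I + S), ira = c(L + I + S, n),
                mismatches = 0L, canonical = TRUE, id = id)
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  if (is.null(x$irb)) {
    cat(sprintf("<quadripartite_structure> %d bp, no IR detected\n", x$n))
    return(invisible(x))
  }
  cat(sprintf(
    "<quadripartite_structure> %d bp: LSC %d | IRB %d | SSC %d | IRA %d (mismatches %d)\n",
    x$n, interval_len(x$lsc), interval_len(x$irb), interval_len(x$ssc),
    interval_len(x$ira), x$mismatches))
  cat(sprintf("  junctions: JLB=%d JSB=%d JSA=%d JLA=%d (0-based)\n",
              x$junctions["JLB"], x$junctions["JSB"], x$junctions["JSA"],
              x$junctions["JLA"]))
  invisible(x)
}

#' Detect the inverted repeat and partition the genome
#'
#' Finds the maximal-length pair of disjoint intervals on the circle whose
#' sequences are reverse complements of each other (up to `max_mismatch`
#' differences), then labels the two single-copy arcs by marker-gene content
#' via [assign_regions()]. Ties are broken by fewer mismatches, then smaller
#' start coordinate. The search is k-mer seeded (subquadratic) but returns
#' the same answer as exhaustive search.
#'
#' @param record A [plastome_record()].
#' @param min_len Minimum IR length to report (default 100 bp, small enough
#'   to catch a 355 bp residual IR, large enough to ignore chance inverted
#'   matches).
#' @param max_mismatch Mismatch budget between the two copies (default 0:
#'   plastome assemblies have identical IRs).
#' @return A `quadripartite_structure`; IR absent is a valid result.
#' @export
detect_ir <- function(record, min_len = 100, max_mismatch = 0) {
  n <- nchar(record$sequence)
  if (n < 2 * min_len)
    stop("sequence shorter than twice min_len")
  hit <- .ir_detect_cpp(record$sequence, as.integer(min_len),
                        as.integer(max_mismatch))
  if (!hit$found)
    return(new_structure(n, lsc = c(0, n), canonical = NA, id = record$id))
  iv1 <- c(hit$start1, hit$start1 + hit$length)
  iv2 <- c(hit$start2, hit$start2 + hit$length)
  assign_regions(record, list(iv1, iv2), mismatches = hit$mismatches)
}

#' Label the single-copy arcs between two IR intervals
#'
#' The arc holding the majority of the SSC marker genes (`ndhF`, `ndhA`,
#' `ndhD`, `ccsA`, `ycf1`) is labelled SSC and the arc holding the majority
#' of the LSC markers (`psbA`, `rbcL`, `matK`, `atpA`) is labelled LSC;
#' content beats size, so a "small single copy" arc larger than the LSC is
#' still labelled SSC when the ndh suite lives there. Without informative
#' annotations the shorter arc is called SSC. The IR copy between LSC and
#' SSC (reading forward) is IRB.
#'
#' @param record A [plastome_record()].
#' @param ir_intervals List of the two disjoint IR intervals, each
#'   `c(start, end)` 0-based half-open (end may exceed the length for a
#'   wrapping interval).
#' @param mismatches Mismatch count between the copies (bookkeeping).
#' @return A `quadripartite_structure` in the record's coordinates.
#' @export
assign_regions <- function(record, ir_intervals, mismatches = 0) {
  n <- nchar(record$sequence)
  iv1 <- ir_intervals[[1]]
  iv2 <- ir_intervals[[2]]
  if (interval_len(iv1) != interval_len(iv2))
    stop("IR intervals must have equal length")
  arc <- function(from, to) {
    from <- from %% n
    to <- to %% n
    if (to >= from) c(from, to) else c(from, to + n)
  }
  arc1 <- arc(iv1[2], iv2[1])   # after copy 1, before copy 2
  arc2 <- arc(iv2[2], iv1[1])   # after copy 2, before copy 1
  pos_in <- function(p, a) interval_contains(a, p, n)
  votes <- c(ssc1 = 0, ssc2 = 0, lsc1 = 0, lsc2 = 0)
  for (f in record$features) {
    nm <- normalize_gene_name(f$name)
    p <- f$parts[1, 1]
    if (nm %in% normalize_gene_name(SSC_MARKERS)) {
      if (pos_in(p, arc1)) votes["ssc1"] <- votes["ssc1"] + 1
      if (pos_in(p, arc2)) votes["ssc2"] <- votes["ssc2"] + 1
    }
    if (nm %in% normalize_gene_name(LSC_MARKERS)) {
      if (pos_in(p, arc1)) votes["lsc1"] <- votes["lsc1"] + 1
      if (pos_in(p, arc2)) votes["lsc2"] <- votes["lsc2"] + 1
    }
  }
  ssc_is_1 <- NA
  if (votes["ssc1"] != votes["ssc2"])
    ssc_is_1 <- votes["ssc1"] > votes["ssc2"]
  lsc_is_1 <- NA
  if (votes["lsc1"] != votes["lsc2"])
    lsc_is_1 <- votes["lsc1"] > votes["lsc2"]
  if (isTRUE(ssc_is_1) && isTRUE(lsc_is_1) ||
      isFALSE(ssc_is_1) && isFALSE(lsc_is_1))
    stop(sprintf(
      "pathological annotation: SSC markers (%d/%d) and LSC markers (%d/%d) vote for the same arc",
      votes["ssc1"], votes["ssc2"], votes["lsc1"], votes["lsc2"]))
  if (is.na(ssc_is_1) && !is.na(lsc_is_1)) ssc_is_1 <- !lsc_is_1
  if (is.na(ssc_is_1)) {
    # fallback: the shorter arc is the SSC
    l1 <- interval_len(arc1)
    l2 <- interval_len(arc2)
    ssc_is_1 <- if (l1 != l2) l1 < l2 else arc1[1] %% n > arc2[1] %% n
  }
  ssc <- if (ssc_is_1) arc1 else arc2
  lsc <- if (ssc_is_1) arc2 else arc1
  # IRB immediately precedes the SSC reading forward
  irb <- if (ssc_is_1) iv1 else iv2
  ira <- if (ssc_is_1) iv2 else iv1
  canonical <- (lsc[1] %% n) == 0
  rb <- which(normalize_gene_name(feature_names(record)) == "rbcl")
  if (length(rb) > 0)
    canonical <- canonical && record$features[[rb[1]]]$strand == "+"
  new_structure(n, lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                mismatches = mismatches, canonical = canonical,
                id = record$id)
}

#' Rotate and flip a record into canonical orientation
#'
#' Re-orients the genome to the canonical order LSC-IRB-SSC-IRA with the
#' IRA/LSC junction (JLA) at the origin, and the strand chosen so that
#' `rbcL` (when annotated) lies on the forward strand. Applying it twice
#' yields identical coordinates.
#'
#' @param record A [plastome_record()].
#' @param structure Its `quadripartite_structure` (from [detect_ir()]).
#' @return `list(record, structure)` in canonical orientation.
#' @export
canonicalize_record <- function(record, structure) {
  n <- structure$n
  rb <- which(normalize_gene_name(feature_names(record)) == "rbcl")
  if (length(rb) > 0 && record$features[[rb[1]]]$strand == "-") {
    record <- revcomp_record(record)
    flip <- function(iv) {
      if (is.null(iv)) return(NULL)
      s <- (n - (iv[2] %% n)) %% n
      c(s, s + interval_len(iv))
    }
    structure <- new_structure(n, lsc = flip(structure$lsc),
                               irb = flip(structure$ira),
                               ssc = flip(structure$ssc),
                               ira = flip(structure$irb),
                               mismatches = structure$mismatches,
                               id = structure$id)
  }
  if (!is.null(structure$junctions)) {
    off <- structure$junctions[["JLA"]]
    if (off != 0) {
      record <- rotate_record(record, off)
      rot <- function(iv) {
        if (is.null(iv)) return(NULL)
        s <- (iv[1] - off) %% n
        c(s, s + interval_len(iv))
      }
      structure <- new_structure(n, lsc = rot(structure$lsc),
                                 irb = rot(structure$irb),
                                 ssc = rot(structure$ssc),
                                 ira = rot(structure$ira),
                                 mismatches = structure$mismatches,
                                 id = structure$id)
    }
  }
  structure$canonical_orientation <- TRUE
  list(record = record, structure = structure)
}

region_of_position <- function(structure, p) {
  n <- structure$n
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- structure[[r]]
    if (!is.null(iv) && interval_contains(iv, p %% n, n)) return(toupper(r))
  }
  NA_character_
}

#' Characterize the four IR-single-copy junctions
#'
#' For each junction (JLB = LSC/IRB, JSB = IRB/SSC, JSA = SSC/IRA,
#' JLA = IRA/LSC) reports the gene spanning it -- with the number of bases on
#' each side -- or, for a junction falling in a spacer, the nearest gene on
#' either side with the gap lengths, formatted `"geneX--geneY"`.
#'
#' @param record A [plastome_record()].
#' @param structure Its `quadripartite_structure`; must have an IR.
#' @return A data frame with one row per junction.
#' @export
junction_report <- function(record, structure) {
  if (is.null(structure$junctions)) stop("structure has no IR junctions")
  n <- structure$n
  spans <- lapply(record$features, feature_span)
  nm <- feature_names(record)
  rows <- lapply(names(structure$junctions), function(j) {
    pos <- structure$junctions[[j]]
    over <- NA_integer_
    for (i in seq_along(spans)) {
      sp <- spans[[i]]
      # strictly inside the span (a gene starting at the junction does not
      # span it)
      inside <- if (sp[2] <= n) (pos > sp[1] && pos < sp[2])
                else (pos > sp[1] || pos < sp[2] - n)
      if (inside) { over <- i; break }
    }
    if (!is.na(over)) {
      sp <- spans[[over]]
      up <- (pos - sp[1]) %% n
      down <- (sp[2] - pos) %% n
      data.frame(junction = j, position = pos, gene = nm[over],
                 spans_junction = TRUE, bp_upstream = up, bp_downstream = down,
                 gene_left = nm[over], gap_left = 0L,
                 gene_right = nm[over], gap_right = 0L,
                 stringsAsFactors = FALSE)
    } else {
      gl <- vapply(spans, function(sp) (pos - (sp[2] %% n)) %% n, numeric(1))
      gr <- vapply(spans, function(sp) (sp[1] - pos) %% n, numeric(1))
      il <- which.min(gl)
      ir <- which.min(gr)
      data.frame(junction = j, position = pos,
                 gene = paste0(nm[il], "--", nm[ir]),
                 spans_junction = FALSE, bp_upstream = NA_integer_,
                 bp_downstream = NA_integer_,
                 gene_left = nm[il], gap_left = as.integer(gl[il]),
                 gene_right = nm[ir], gap_right = as.integer(gr[ir]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Classify an IR shift as large-scale (Group B) or not (Group A)
#'
#' Group B means a large-scale IR expansion or contraction: the IR is shorter
#' than `ir_min`, longer than `ir_max`, or the SSC has shrunk below
#' `ssc_min`. Everything else is Group A. The defaults reproduce the
#' qualitative grouping of typical plastomes (IR around 25 kb, SSC around
#' 18 kb) versus residual-IR and giant-IR genomes.
#'
#' @param structure A `quadripartite_structure`.
#' @param ir_min,ir_max,ssc_min Thresholds in bp.
#' @return `list(group, reasons)`.
#' @export
classify_shift <- function(structure, ir_min = 1000, ir_max = 35000,
                           ssc_min = 10000) {
  reasons <- character(0)
  if (is.null(structure$irb)) {
    reasons <- "IR absent"
  } else {
    if (structure$ir_len < ir_min)
      reasons <- c(reasons, sprintf("ir_len %d < %d", structure$ir_len,
                                    ir_min))
    if (structure$ir_len > ir_max)
      reasons <- c(reasons, sprintf("ir_len %d > %d", structure$ir_len,
                                    ir_max))
    ssc_len <- if (is.null(structure$ssc)) 0L else interval_len(structure$ssc)
    if (ssc_len < ssc_min)
      reasons <- c(reasons, sprintf("ssc %d < %d", ssc_len, ssc_min))
  }
  list(group = if (length(reasons)) "B" else "A", reasons = reasons)
}

#' GC content in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from both the
#' numerator and the denominator. Reported to 0.1.
#'
#' @param x A [plastome_record()] or a DNA string.
#' @param interval Optional `c(start, end)` 0-based half-open interval.
#' @return Percent GC, rounded to one decimal.
#' @export
gc_content <- function(x, interval = NULL) {
  s <- if (inherits(x, "plastome_record")) x$sequence else toupper(x)
  if (!is.null(interval)) s <- circ_substr(s, interval[1], interval[2])
  counts <- table(factor(seq_chars(s), levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) stop("sequence is all N")
  round(100 * sum(counts[c("G", "C")]) / acgt, 1)
}
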