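# Seeded simulator of quadripartite plastome evolution: ancestor
# construction, junction shifts (IR expansion/contraction), gene loss,
# pseudogenization, segmental inversion/relocation, planted repeats, and
# Jukes-Cantor substitutions with concerted evolution of the IR copies,
# all along a clock tree, with a ground-truth log.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_cds <- function(length) {
  stopifnot(length %% 3 == 0, length >= 9)
  paste0("ATG",
         paste(sample(NONSTOP_CODONS, length / 3 - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Specify a synthetic ancestral plastome
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp; total genome length is
#'   `lsc_len + ssc_len + 2 * ir_len`. Defaults match a typical plastome
#'   (about 160 kb with a 26.5 kb IR).
#' @param gene_template Ordered gene table as in [default_gene_template()];
#'   `NULL` scales the built-in template to the requested region sizes. An
#'   explicit template must fit its regions or [build_ancestor()] errors.
#' @param intergenic_len_mean Target mean spacer length used when scaling the
#'   default template.
#' @param seed Integer seed; every stochastic choice of the builder derives
#'   from it.
#' @return An `ancestor_spec` list.
#' @export
ancestor_spec <- function(lsc_len = 87000, ssc_len = 18000, ir_len = 26500,
                          gene_template = NULL, intergenic_len_mean = 150,
                          seed = 1) {
  stopifnot(lsc_len > 0, ssc_len >= 0, ir_len >= 0)
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gene_template = gene_template,
                 intergenic_len_mean = intergenic_len_mean,
                 seed = as.integer(seed)),
            class = "ancestor_spec")
}

# lay out one region: returns list(seq, features (region-relative coords))
layout_region <- function(rows, region_len, min_gap = 8) {
  if (is.null(rows) || nrow(rows) == 0) {
    return(list(seq = random_dna(region_len), features = list()))
  }
  spans <- vapply(seq_len(nrow(rows)), function(i) template_span(rows[i, ]),
                  numeric(1))
  ngaps <- nrow(rows) + 1
  spare <- region_len - sum(spans) - ngaps * min_gap
  if (spare < 0)
    stop(sprintf("genes overflow region: need %d bp, have %d",
                 sum(spans) + ngaps * min_gap, region_len))
  extra <- if (spare > 0)
    as.vector(stats::rmultinom(1, spare, rep(1, ngaps))) else rep(0, ngaps)
  gaps <- min_gap + extra
  pieces <- character(0)
  features <- list()
  at <- 0L
  for (i in seq_len(nrow(rows))) {
    pieces <- c(pieces, random_dna(gaps[i]))
    at <- at + gaps[i]
    row <- rows[i, ]
    introns <- if (nzchar(row$introns))
      as.integer(strsplit(row$introns, ",")[[1]]) else integer(0)
    nex <- length(introns) + 1
    mature <- if (row$category == "CDS") random_cds(row$length)
              else random_dna(row$length)
    # split the mature sequence across exons (codon-unaligned splits are fine)
    cuts <- round(seq(0, nchar(mature), length.out = nex + 1))
    exons <- substring(mature, head(cuts, -1) + 1, cuts[-1])
    segs <- character(0)
    exon_iv <- matrix(0L, nrow = nex, ncol = 2)   # gene-relative offsets
    p <- 0L
    for (e in seq_len(nex)) {
      exon_iv[e, ] <- c(p, p + nchar(exons[e]))
      segs <- c(segs, exons[e])
      p <- p + nchar(exons[e])
      if (e <= length(introns)) {
        segs <- c(segs, random_dna(introns[e]))
        p <- p + introns[e]
      }
    }
    genomic <- paste(segs, collapse = "")
    if (row$strand == "-") {
      genomic <- revcomp(genomic)
      # reflecting the intervals within the gene span already leaves the
      # rows in transcription order (exon 1 at the high-coordinate end)
      span <- nchar(genomic)
      exon_iv <- cbind(span - exon_iv[, 2], span - exon_iv[, 1])
    }
    exon_iv <- exon_iv + at
    pieces <- c(pieces, genomic)
    at <- at + nchar(genomic)
    features[[length(features) + 1]] <- gene_feature(
      name = row$name, category = row$category, strand = row$strand,
      parts = exon_iv)
  }
  pieces <- c(pieces, random_dna(gaps[ngaps]))
  list(seq = paste(pieces, collapse = ""), features = features)
}

shift_feature <- function(f, offset) {
  f$parts <- f$parts + as.integer(offset)
  f
}

# mirror a feature from one IR copy into the other;
# irb, ira are the two intervals (non-wrapping, canonical coordinates)
mirror_feature <- function(f, irb, ira) {
  mirror_pos <- function(p) {
    if (p >= irb[1] && p <= irb[2]) return(ira[2] - (p - irb[1]))
    if (p >= ira[1] && p <= ira[2]) return(irb[2] - (p - ira[1]))
    stop("position outside both IR copies")
  }
  p <- f$parts
  m <- cbind(vapply(p[, 2], function(x) mirror_pos(x), numeric(1)),
             vapply(p[, 1], function(x) mirror_pos(x), numeric(1)))
  f$parts <- matrix(as.integer(m), ncol = 2)
  colnames(f$parts) <- c("start", "end")
  f$strand <- if (f$strand == "+") "-" else "+"
  f
}

# make sure the maximal inverted pair stops exactly at the constructed
# junctions: the base pairs flanking the IR on both sides must not extend it
enforce_junction_walls <- function(seqv, st) {
  if (is.null(st$irb)) return(seqv)
  n <- st$n
  fix <- function(i_keep, i_fix) {
    # require seqv[i_fix] != complement(seqv[i_keep])
    bad <- complement_chars(seqv[i_keep + 1])
    if (seqv[i_fix + 1] == bad)
      seqv[i_fix + 1] <<- setdiff(DNA_BASES, bad)[1]
  }
  L <- st$lsc; S <- st$ssc
  fix(L[2] - 1, L[1])          # outer: LSC last vs LSC first
  if (interval_len(S) >= 2) fix(S[2] - 1, S[1])  # inner: SSC first vs last
  seqv
}

wall_positions <- function(st) {
  if (is.null(st$irb)) return(integer(0))
  c(st$lsc[1], st$lsc[2] - 1, st$ssc[1], st$ssc[2] - 1)
}

#' Build a synthetic ancestral plastome
#'
#' Assembles `LSC + IRB + SSC + IRA` with `IRA` the exact reverse complement
#' of `IRB`, genes placed in their template regions (IR genes present in both
#' copies), valid start/stop codons and intron structure, and single-base
#' "walls" at the four junctions so that the maximal inverted-repeat pair of
#' the sequence equals the constructed IR exactly.
#'
#' @param spec An [ancestor_spec()].
#' @return `list(record, structure, truth)` where `truth` holds the per-gene
#'   status table.
#' @export
build_ancestor <- function(spec) {
  stopifnot(inherits(spec, "ancestor_spec"))
  with_seed(spec$seed, {
    template <- spec$gene_template
    if (is.null(template)) {
      template <- scale_template(default_gene_template(), spec$lsc_len,
                                 spec$ssc_len, spec$ir_len,
                                 gap_mean = spec$intergenic_len_mean)
    }
    lsc <- layout_region(template[template$region == "LSC", , drop = FALSE],
                         spec$lsc_len)
    ssc <- if (spec$ssc_len > 0)
      layout_region(template[template$region == "SSC", , drop = FALSE],
                    spec$ssc_len)
    else list(seq = "", features = list())
    irb <- if (spec$ir_len > 0)
      layout_region(template[template$region == "IR", , drop = FALSE],
                    spec$ir_len)
    else list(seq = "", features = list())

    L <- spec$lsc_len; I <- spec$ir_len; S <- spec$ssc_len
    st <- canonical_structure(L, I, S)
    seqs <- paste0(lsc$seq, irb$seq, ssc$seq,
                   if (I > 0) revcomp(irb$seq) else "")
    features <- c(lsc$features,
                  lapply(irb$features, shift_feature, offset = L),
                  lapply(ssc$features, shift_feature, offset = L + I))
    if (I > 0) {
      ira_feats <- lapply(lapply(irb$features, shift_feature, offset = L),
                          mirror_feature, irb = st$irb, ira = st$ira)
      features <- c(features, ira_feats)
    }
    seqv <- seq_chars(seqs)
    seqv <- enforce_junction_walls(seqv, st)
    rec <- plastome_record(id = sprintf("synthetic_seed%d", spec$seed),
                           sequence = paste(seqv, collapse = ""),
                           features = features, circular = TRUE,
                           source = "synthetic")
    st$id <- rec$id
    truth <- list(gene_status = gene_status_from_record(rec, template),
                  template = template, planted = list(), events = list())
    list(record = rec, structure = st, truth = truth)
  })
}

# per-gene realized status straight from the generator's own product
gene_status_from_record <- function(rec, template) {
  nm <- feature_names(rec)
  rows <- lapply(seq_len(nrow(template)), function(i) {
    g <- template$name[i]
    idx <- which(nm == g)
    copies <- length(idx)
    status <- if (copies == 0) "lost"
    else if (any(vapply(idx, function(k) {
      f <- rec$features[[k]]
      f$pseudo ||
        (f$category == "CDS" && {
          cds <- feature_sequence(rec, f)
          nchar(cds) %% 3 != 0 || has_internal_stop(cds)
        })
    }, logical(1)))) "pseudo"
    else if (copies >= 2) "duplicated"
    else "single"
    data.frame(gene = g, category = template$category[i], copies = copies,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ------------------------------------------------------- junction shifts ----

# insert `text` at `pos`; features with parts touching pos are an error
# unless they lie fully on one side
insert_at <- function(rec, pos, text) {
  n <- nchar(rec$sequence)
  k <- nchar(text)
  for (f in rec$features) {
    if (any(f$parts[, 1] < pos & f$parts[, 2] > pos))
      stop(sprintf("insertion point %d splits gene '%s'", pos, f$name))
  }
  rec$sequence <- paste0(substr(rec$sequence, 1, pos), text,
                         substr(rec$sequence, pos + 1, n))
  rec$features <- lapply(rec$features, function(f) {
    f$parts <- f$parts + as.integer(k) * (f$parts >= pos)
    f
  })
  rec
}

# delete [pos, pos+k); feature copies overlapping the zone are dropped
delete_at <- function(rec, pos, k) {
  n <- nchar(rec$sequence)
  stopifnot(pos >= 0, pos + k <= n)
  keep <- vapply(rec$features, function(f) {
    !any(f$parts[, 1] < pos + k & f$parts[, 2] > pos)
  }, logical(1))
  rec$features <- rec$features[keep]
  rec$sequence <- paste0(substr(rec$sequence, 1, pos),
                         substr(rec$sequence, pos + k + 1, n))
  rec$features <- lapply(rec$features, function(f) {
    f$parts <- f$parts - as.integer(k) * (f$parts >= pos + k)
    f
  })
  rec
}

# duplicate features fully inside `zone` as mirrored IR copies
dup_mirrored <- function(rec, zone, irb, ira) {
  adds <- list()
  for (f in rec$features) {
    sp <- feature_span(f)
    if (sp[1] >= zone[1] && sp[2] <= zone[2])
      adds[[length(adds) + 1]] <- mirror_feature(f, irb, ira)
  }
  rec$features <- c(rec$features, adds)
  rec
}

fix_walls_record <- function(rec, st) {
  seqv <- seq_chars(rec$sequence)
  seqv2 <- enforce_junction_walls(seqv, st)
  if (!identical(seqv, seqv2))
    rec$sequence <- paste(seqv2, collapse = "")
  rec
}

#' Shift an IR-single-copy junction (IR expansion or contraction)
#'
#' A positive shift copies `shift_bp` bases of the adjacent single-copy
#' region into both IR copies: the IR grows by `shift_bp`, that single-copy
#' region shrinks by `shift_bp`, and the genome grows by `shift_bp` (one
#' extra duplicated stretch). Genes fully inside the shifted margin become
#' IR-duplicated; genes crossing the new boundary become IR-spanning. A
#' negative shift returns IR margin to single copy (one copy retained); a
#' feature copy cut by the contraction is dropped from the annotation.
#' The record must be in canonical orientation.
#'
#' @param record A canonical [plastome_record()].
#' @param structure Its `quadripartite_structure`.
#' @param junction One of `"JLB"`, `"JSB"`, `"JSA"`, `"JLA"`.
#' @param shift_bp Signed shift in bp; `abs(shift_bp)` must stay inside the
#'   adjacent single-copy region (expansion) or the IR (contraction).
#' @return `list(record, structure)`.
#' @export
apply_junction_shift <- function(record, structure,
                                 junction = c("JLB", "JSB", "JSA", "JLA"),
                                 shift_bp) {
  junction <- match.arg(junction)
  if (is.null(structure$irb)) stop("structure has no IR")
  if (!isTRUE(structure$canonical_orientation))
    stop("record must be in canonical orientation (see canonicalize_record)")
  L <- interval_len(structure$lsc)
  I <- structure$ir_len
  S <- interval_len(structure$ssc)
  k <- abs(shift_bp)
  if (shift_bp == 0) stop("shift_bp must be non-zero")
  if (shift_bp > 0) {
    sc_len <- if (junction %in% c("JSB", "JSA")) S else L
    if (k >= sc_len)
      stop("shift consumes an entire single-copy region")
  } else {
    if (k >= I) stop("contraction exceeds the IR length")
  }
  rec <- record
  if (shift_bp > 0) {
    if (junction == "JSB") {
      chunk <- substr(rec$sequence, L + I + 1, L + I + k)   # SSC head
      rec <- insert_at(rec, L + I + S, revcomp(chunk))      # prepend to IRA
      st2 <- canonical_structure(L, I + k, S - k)
      rec <- dup_mirrored(rec, zone = c(L + I, L + I + k),
                          irb = st2$irb, ira = st2$ira)
    } else if (junction == "JSA") {
      chunk <- substr(rec$sequence, L + I + S - k + 1, L + I + S)  # SSC tail
      rec <- insert_at(rec, L + I, revcomp(chunk))          # append to IRB
      st2 <- canonical_structure(L, I + k, S - k)
      rec <- dup_mirrored(rec, zone = c(L + I + S, L + I + S + k),
                          irb = st2$irb, ira = st2$ira)
    } else if (junction == "JLB") {
      chunk <- substr(rec$sequence, L - k + 1, L)            # LSC tail
      rec <- insert_at(rec, L + 2 * I + S, revcomp(chunk))   # append to IRA
      st2 <- canonical_structure(L - k, I + k, S)
      rec <- dup_mirrored(rec, zone = c(L - k, L),
                          irb = st2$irb, ira = st2$ira)
    } else {                                                 # JLA
      chunk <- substr(rec$sequence, 1, k)                    # LSC head
      rec <- insert_at(rec, L, revcomp(chunk))               # prepend to IRB
      # the grabbed chunk now tails the IRA across the origin; rotate so the
      # shortened LSC starts at 0, then mirror genes inside the chunk
      rec <- rotate_record(rec, k)
      st2 <- canonical_structure(L - k, I + k, S)
      rec <- dup_mirrored(rec, zone = c(st2$n - k, st2$n),
                          irb = st2$irb, ira = st2$ira)
    }
  } else {
    if (junction == "JSB") {
      # IRB loses its tail to the SSC; IRA loses its head
      rec <- delete_at(rec, L + I + S, k)
      st2 <- canonical_structure(L, I - k, S + k)
    } else if (junction == "JSA") {
      # IRA loses its head to the SSC; IRB loses its tail
      rec <- delete_at(rec, L + I - k, k)
      st2 <- canonical_structure(L, I - k, S + k)
    } else if (junction == "JLB") {
      # IRB loses its head to the LSC; IRA loses its tail
      rec <- delete_at(rec, L + 2 * I + S - k, k)
      st2 <- canonical_structure(L + k, I - k, S)
    } else {                                                 # JLA
      # IRA loses its tail to the LSC (across the origin); IRB its head
      rec <- delete_at(rec, L, k)
      n2 <- nchar(rec$sequence)
      rec <- rotate_record(rec, n2 - k)
      st2 <- canonical_structure(L + k, I - k, S)
    }
  }
  st2$id <- structure$id
  rec <- fix_walls_record(rec, st2)
  list(record = rec, structure = st2)
}

# ------------------------------------------------------------ gene events ---

# coding-position -> genomic-position map (1-based vector of 0-based positions)
coding_position_map <- function(f, n) {
  out <- integer(0)
  for (r in seq_len(nrow(f$parts))) {
    s <- f$parts[r, 1]; e <- f$parts[r, 2]
    pos <- seq.int(s, e - 1) %% n
    if (f$strand == "-") pos <- rev(pos)
    out <- c(out, pos)
  }
  out
}

#' Introduce a premature stop codon into a gene
#'
#' Writes a `TAA` at a random internal codon (seeded). Every annotated copy
#' is edited at the same codon, so IR-duplicated genes stay concerted. The
#' annotation's pseudogene flag is NOT set: detecting the degradation is the
#' classifier's job.
#'
#' @param record A [plastome_record()].
#' @param gene Gene symbol of an intact CDS.
#' @param seed Optional seed for the codon choice.
#' @return The edited record.
#' @export
pseudogenize <- function(record, gene, seed = NULL) {
  idx <- which(feature_names(record) == gene)
  idx <- idx[vapply(record$features[idx], function(f) f$category == "CDS",
                    logical(1))]
  if (length(idx) == 0) stop(sprintf("gene '%s' absent or not a CDS", gene))
  n <- nchar(record$sequence)
  cds <- feature_sequence(record, record$features[[idx[1]]])
  if (nchar(cds) %% 3 != 0 || has_internal_stop(cds))
    stop(sprintf("gene '%s' is not an intact CDS", gene))
  ncod <- nchar(cds) / 3
  pick <- function() sample(2:(ncod - 1), 1)
  codon <- if (is.null(seed)) pick() else with_seed(seed, pick())
  seqv <- seq_chars(record$sequence)
  stopv <- c("T", "A", "A")
  for (k in idx) {
    f <- record$features[[k]]
    # pmap[i] is the genomic position of coding position i (strand-aware)
    pmap <- coding_position_map(f, n)
    for (i in 1:3) {
      g <- pmap[3 * (codon - 1) + i]
      seqv[g + 1] <- if (f$strand == "+") stopv[i] else
        complement_chars(stopv[i])
    }
  }
  record$sequence <- paste(seqv, collapse = "")
  record
}

#' Delete a single-copy gene and its sequence
#'
#' @param record Canonical [plastome_record()].
#' @param structure Its `quadripartite_structure`.
#' @param gene Symbol of a single-copy gene lying fully in the LSC or SSC.
#' @return `list(record, structure, deleted_bp)`.
#' @export
lose_gene <- function(record, structure, gene) {
  idx <- which(feature_names(record) == gene)
  if (length(idx) == 0) stop(sprintf("gene '%s' absent", gene))
  if (length(idx) > 1)
    stop(sprintf("gene '%s' is duplicated; loss of IR genes not supported",
                 gene))
  sp <- feature_span(record$features[[idx]])
  r1 <- region_of_position(structure, sp[1])
  r2 <- region_of_position(structure, sp[2] - 1)
  if (!identical(r1, r2) || !r1 %in% c("LSC", "SSC"))
    stop(sprintf("gene '%s' is not contained in a single-copy region", gene))
  k <- sp[2] - sp[1]
  record <- delete_at(record, sp[1], k)
  L <- interval_len(structure$lsc); I <- structure$ir_len
  S <- if (is.null(structure$ssc)) 0L else interval_len(structure$ssc)
  st2 <- if (I == 0) {
    new_structure(structure$n - k, lsc = c(0, structure$n - k),
                  canonical = TRUE, id = structure$id)
  } else if (r1 == "LSC") canonical_structure(L - k, I, S)
  else canonical_structure(L, I, S - k)
  st2$id <- structure$id
  list(record = record, structure = st2, deleted_bp = k)
}

# contiguous run of single-copy genes -> segment interval with spacer-mid
# boundaries
segment_interval <- function(record, structure, genes) {
  idx <- match(genes, feature_names(record))
  if (anyNA(idx)) stop("gene(s) absent: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  spans <- lapply(record$features[idx], feature_span)
  a0 <- min(vapply(spans, `[`, numeric(1), 1))
  b0 <- max(vapply(spans, `[`, numeric(1), 2))
  reg <- region_of_position(structure, a0)
  if (!identical(reg, region_of_position(structure, b0 - 1)) ||
      !reg %in% c("LSC", "SSC"))
    stop("segment must lie inside one single-copy region")
  riv <- structure[[tolower(reg)]]
  # nearest flanking feature boundaries within the region
  others <- setdiff(seq_along(record$features), idx)
  left <- riv[1] + 2
  right <- riv[2] - 2
  for (k in others) {
    sp <- feature_span(record$features[[k]])
    if (sp[2] <= a0 && sp[2] > left) left <- sp[2]
    if (sp[1] >= b0 && sp[1] < right) right <- sp[1]
  }
  if (left > a0 || right < b0) stop("segment flanked by overlapping genes")
  a <- floor((left + a0) / 2)
  b <- ceiling((b0 + right) / 2)
  c(a, b)
}

#' Invert a block of genes in place
#'
#' Reverse-complements the segment spanned by a contiguous run of
#' single-copy genes (boundaries at the midpoints of the flanking spacers)
#' and remaps the contained annotations.
#'
#' @param record Canonical [plastome_record()].
#' @param structure Its structure.
#' @param genes Character vector of adjacent gene symbols.
#' @return `list(record, structure, interval)`.
#' @export
invert_segment <- function(record, structure, genes) {
  iv <- segment_interval(record, structure, genes)
  a <- iv[1]; b <- iv[2]
  n <- nchar(record$sequence)
  seg <- substr(record$sequence, a + 1, b)
  record$sequence <- paste0(substr(record$sequence, 1, a), revcomp(seg),
                            substr(record$sequence, b + 1, n))
  record$features <- lapply(record$features, function(f) {
    sp <- feature_span(f)
    if (sp[1] >= a && sp[2] <= b) {
      p <- f$parts
      f$parts <- cbind(start = as.integer(a + b - p[, 2]),
                       end = as.integer(a + b - p[, 1]))
      # keep parts in transcription order
      f$parts <- f$parts[rev(seq_len(nrow(p))), , drop = FALSE]
      f$strand <- if (f$strand == "+") "-" else "+"
    } else if (sp[1] < b && sp[2] > a) {
      stop(sprintf("gene '%s' straddles the inversion boundary", f$name))
    }
    f
  })
  list(record = record, structure = structure, interval = c(a, b))
}

#' Relocate (optionally inverting) a block of genes
#'
#' Cuts the segment spanned by a contiguous gene run and reinserts it at the
#' midpoint of another intergenic spacer in the same single-copy region.
#'
#' @param record Canonical [plastome_record()].
#' @param structure Its structure.
#' @param genes Character vector of adjacent gene symbols.
#' @param after_gene Gene symbol after whose spacer the block is reinserted.
#' @param invert Also flip the block.
#' @return `list(record, structure, from, to)`.
#' @export
relocate_segment <- function(record, structure, genes, after_gene,
                             invert = FALSE) {
  iv <- segment_interval(record, structure, genes)
  a <- iv[1]; b <- iv[2]
  k <- b - a
  idx <- match(genes, feature_names(record))
  seg <- substr(record$sequence, a + 1, b)
  moved <- lapply(record$features[idx], function(f) {
    f$parts <- f$parts - as.integer(a)
    f
  })
  record <- delete_at(record, a, k)
  ai <- which(feature_names(record) == after_gene)
  if (length(ai) == 0) stop(sprintf("destination gene '%s' absent",
                                    after_gene))
  sp <- feature_span(record$features[[ai[1]]])
  reg <- region_of_position(structure, sp[1])
  if (!reg %in% c("LSC", "SSC"))
    stop("destination gene must lie in a single-copy region")
  riv <- structure[[tolower(reg)]]
  others <- vapply(record$features, function(f) feature_span(f)[1],
                   numeric(1))
  nxt <- suppressWarnings(min(c(others[others >= sp[2]], riv[2] - 4)))
  p <- floor((sp[2] + nxt) / 2)
  if (invert) {
    seg <- revcomp(seg)
    moved <- lapply(moved, function(f) {
      q <- f$parts
      f$parts <- cbind(start = as.integer(k - q[, 2]),
                       end = as.integer(k - q[, 1]))
      f$parts <- f$parts[rev(seq_len(nrow(q))), , drop = FALSE]
      f$strand <- if (f$strand == "+") "-" else "+"
      f
    })
  }
  record <- insert_at(record, p, seg)
  moved <- lapply(moved, function(f) { f$parts <- f$parts + as.integer(p); f })
  record$features <- c(record$features, moved)
  list(record = record, structure = structure, from = c(a, b),
       to = c(p, p + k))
}

# ---------------------------------------------------------- repeat plants ---

# intergenic intervals of the single-copy regions, shrunk by `margin`
intergenic_gaps <- function(record, structure, margin = 5) {
  gaps <- list()
  for (reg in c("lsc", "ssc")) {
    riv <- structure[[reg]]
    if (is.null(riv) || interval_len(riv) < 2 * margin) next
    spans <- lapply(record$features, feature_span)
    inside <- Filter(function(sp) sp[1] >= riv[1] && sp[2] <= riv[2], spans)
    starts <- sort(c(riv[1] + 2,
                     vapply(inside, `[`, numeric(1), 2)))
    ends <- sort(c(vapply(inside, `[`, numeric(1), 1), riv[2] - 2))
    for (i in seq_along(starts)) {
      g <- c(starts[i] + margin, ends[i] - margin)
      if (g[2] - g[1] >= 10) gaps[[length(gaps) + 1]] <- g
    }
  }
  gaps
}

random_gap_position <- function(record, structure, need = 1) {
  gaps <- intergenic_gaps(record, structure)
  gaps <- Filter(function(g) g[2] - g[1] >= need, gaps)
  if (length(gaps) == 0) return(NULL)
  w <- vapply(gaps, function(g) g[2] - g[1], numeric(1))
  g <- gaps[[sample.int(length(gaps), 1, prob = w)]]
  sample(seq.int(g[1], g[2] - 1), 1)
}

pick_wall <- function(forbidden) setdiff(DNA_BASES, forbidden)[1]

#' Plant a perfect SSR run
#'
#' Inserts `motif` repeated `copies` times at an intergenic position, with
#' single-base walls chosen so the run is exactly maximal.
#'
#' @param record,structure Canonical record and structure.
#' @param motif Primitive repeat unit (1-6 bp).
#' @param copies Number of copies.
#' @param at Insertion point (0-based); `NULL` picks a random spacer.
#' @return `list(record, structure, hit)` where `hit` holds the planted
#'   coordinates.
#' @export
plant_ssr <- function(record, structure, motif, copies, at = NULL) {
  mlen <- nchar(motif)
  run <- strrep(motif, copies)
  wl <- pick_wall(substr(motif, mlen, mlen))
  wr <- pick_wall(substr(motif, 1, 1))
  if (is.null(at)) at <- random_gap_position(record, structure,
                                             need = nchar(run) + 2)
  if (is.null(at)) stop("no intergenic room to plant the SSR")
  record <- insert_at(record, at, paste0(wl, run, wr))
  structure <- grow_structure(structure, at, nchar(run) + 2)
  hit <- data.frame(motif = motif, copies = copies, start = at + 1,
                    length = nchar(run), stringsAsFactors = FALSE)
  list(record = record, structure = structure, hit = hit)
}

#' Plant a perfect tandem array
#'
#' Inserts `unit` repeated `copies` times flanked by 4-base walls that break
#' the periodicity, so the detected array has exactly the planted
#' coordinates.
#'
#' @inheritParams plant_ssr
#' @param unit Repeat unit (period).
#' @return `list(record, structure, hit)`.
#' @export
plant_tandem <- function(record, structure, unit, copies, at = NULL) {
  p <- nchar(unit)
  arr <- strrep(unit, copies)
  uchr <- seq_chars(unit)
  wl <- vapply(0:3, function(i) pick_wall(uchr[((i - 4) %% p) + 1]),
               character(1))
  wr <- vapply(0:3, function(m) pick_wall(uchr[(m %% p) + 1]), character(1))
  text <- paste0(paste(wl, collapse = ""), arr, paste(wr, collapse = ""))
  # for very short periods make sure the wall bytes are not themselves
  # periodic with the array
  tc <- seq_chars(text)
  for (i in seq_len(4)) {
    if (i + p <= length(tc) && tc[i] == tc[i + p])
      tc[i] <- pick_wall(c(tc[i + p], if (i > p) tc[i - p]))
  }
  for (i in (length(tc) - 3):length(tc)) {
    if (i - p >= 1 && tc[i] == tc[i - p])
      tc[i] <- pick_wall(tc[i - p])
  }
  text <- paste(tc, collapse = "")
  if (is.null(at)) at <- random_gap_position(record, structure,
                                             need = nchar(text))
  if (is.null(at)) stop("no intergenic room to plant the tandem array")
  record <- insert_at(record, at, text)
  structure <- grow_structure(structure, at, nchar(text))
  hit <- data.frame(period = p, start = at + 4, length = nchar(arr),
                    copy_number = copies, stringsAsFactors = FALSE)
  list(record = record, structure = structure, hit = hit)
}

#' Plant a dispersed repeat pair
#'
#' Inserts a segment and its transformed copy (Forward / Reverse /
#' Complement / Palindromic) at two intergenic positions. The copy carries
#' `mismatches` internal substitutions and mismatching walls, so under a
#' Hamming budget equal to `mismatches` the planted pair is itself a maximal
#' hit with exact coordinates.
#'
#' @inheritParams plant_ssr
#' @param kind One of `"Forward"`, `"Reverse"`, `"Complement"`,
#'   `"Palindromic"`.
#' @param length Copy length in bp (>= 30 for the default detector).
#' @param mismatches Internal substitutions placed in the second copy.
#' @return `list(record, structure, hit)`.
#' @export
plant_dispersed <- function(record, structure,
                            kind = c("Forward", "Reverse", "Complement",
                                     "Palindromic"),
                            length = 40, mismatches = 3) {
  kind <- match.arg(kind)
  L <- length
  c1 <- random_dna(L)
  c2 <- switch(kind,
    Forward = c1,
    Reverse = paste(rev(seq_chars(c1)), collapse = ""),
    Complement = paste(complement_chars(seq_chars(c1)), collapse = ""),
    Palindromic = revcomp(c1))
  if (mismatches > 0) {
    pos <- unique(pmax(2, pmin(L - 1, round(L * seq_len(mismatches) /
                                              (mismatches + 1)))))
    v <- seq_chars(c2)
    for (t in pos) v[t] <- sample(setdiff(DNA_BASES, v[t]), 1)
    c2 <- paste(v, collapse = "")
    mismatches <- base::length(pos)
  }
  at1 <- random_gap_position(record, structure, need = L + 2)
  if (is.null(at1)) stop("no intergenic room for the first copy")
  record <- insert_at(record, at1, paste0("A", c1, "A"))
  structure <- grow_structure(structure, at1, L + 2)
  repeat {
    at2 <- random_gap_position(record, structure, need = L + 2)
    if (is.null(at2)) stop("no intergenic room for the second copy")
    if (at2 > at1 + L + 2 || at2 < at1 - L - 2) break
  }
  record <- insert_at(record, at2, paste0("C", c2, "C"))
  structure <- grow_structure(structure, at2, L + 2)
  if (at2 < at1) at1 <- at1 + L + 2
  i <- min(at1, at2) + 1
  j <- max(at1, at2) + 1
  hit <- data.frame(kind = kind, start1 = i, start2 = j, length = L,
                    mismatches = mismatches, stringsAsFactors = FALSE)
  list(record = record, structure = structure, hit = hit)
}

# grow the region containing an insertion point by k
grow_structure <- function(st, at, k) {
  if (is.null(st$irb)) {
    st2 <- new_structure(st$n + k, lsc = c(0, st$n + k), canonical = TRUE,
                         id = st$id)
    return(st2)
  }
  L <- interval_len(st$lsc); I <- st$ir_len; S <- interval_len(st$ssc)
  reg <- region_of_position(st, at)
  st2 <- if (reg == "LSC") canonical_structure(L + k, I, S)
         else if (reg == "SSC") canonical_structure(L, I, S + k)
         else stop("insertion inside the IR is not supported")
  st2$id <- st$id
  st2
}

# --------------------------------------------------------------- evolve -----

add_event <- function(state, ...) {
  state$events[[length(state$events) + 1]] <- list(...)
  state
}

PROTECTED_GENES <- c(SSC_MARKERS, LSC_MARKERS, IR_CORE)

apply_random_event <- function(state, kind) {
  rec <- state$record
  st <- state$structure
  nm <- feature_names(rec)
  if (kind == "ir_expand") {
    if (is.null(st$irb)) stop("no IR")
    j <- sample(c("JLB", "JSB", "JSA", "JLA"), 1)
    scl <- if (j %in% c("JSB", "JSA")) interval_len(st$ssc)
           else interval_len(st$lsc)
    kmax <- min(3000, scl - 600)
    if (kmax < 300) stop("single-copy region too small to expand into")
    k <- sample(300:kmax, 1)
    res <- apply_junction_shift(rec, st, j, k)
    state$record <- res$record; state$structure <- res$structure
    return(add_event(state, kind = kind, junction = j, shift_bp = k,
                     delta = k))
  }
  if (kind == "ir_contract") {
    if (is.null(st$irb)) stop("no IR")
    kmax <- min(2500, st$ir_len - 450)
    if (kmax < 200) stop("IR too small to contract")
    k <- sample(200:kmax, 1)
    j <- sample(c("JLB", "JSB", "JSA", "JLA"), 1)
    res <- apply_junction_shift(rec, st, j, -k)
    state$record <- res$record; state$structure <- res$structure
    return(add_event(state, kind = kind, junction = j, shift_bp = -k,
                     delta = -k))
  }
  if (kind == "gene_loss") {
    singles <- names(which(table(nm) == 1))
    cand <- setdiff(singles, PROTECTED_GENES)
    cand <- Filter(function(g) {
      i <- which(nm == g)
      sp <- feature_span(rec$features[[i]])
      r1 <- region_of_position(st, sp[1])
      identical(r1, region_of_position(st, sp[2] - 1)) &&
        r1 %in% c("LSC", "SSC")
    }, cand)
    if (!length(cand)) stop("no candidate gene for loss")
    g <- sample(cand, 1)
    res <- lose_gene(rec, st, g)
    state$record <- res$record; state$structure <- res$structure
    return(add_event(state, kind = kind, gene = g, delta = -res$deleted_bp))
  }
  if (kind == "pseudogenize") {
    cand <- unique(nm[vapply(rec$features, function(f)
      f$category == "CDS" && !f$pseudo, logical(1))])
    cand <- Filter(function(g) {
      f <- rec$features[[which(nm == g)[1]]]
      cds <- feature_sequence(rec, f)
      nchar(cds) %% 3 == 0 && nchar(cds) >= 12 && !has_internal_stop(cds)
    }, cand)
    if (!length(cand)) stop("no intact CDS to pseudogenize")
    g <- sample(cand, 1)
    state$record <- pseudogenize(rec, g)
    return(add_event(state, kind = kind, gene = g, delta = 0))
  }
  if (kind %in% c("inversion", "relocation")) {
    reg <- sample(c("LSC", "SSC"), 1)
    riv <- st[[tolower(reg)]]
    if (is.null(riv)) stop("region absent")
    singles <- names(which(table(nm) == 1))
    idx <- which(nm %in% singles)
    inside <- idx[vapply(idx, function(i) {
      sp <- feature_span(rec$features[[i]])
      sp[1] >= riv[1] && sp[2] <= riv[2]
    }, logical(1))]
    if (length(inside) < 4) stop("too few genes in region")
    ord <- inside[order(vapply(rec$features[inside], function(f)
      feature_span(f)[1], numeric(1)))]
    len <- sample(2:min(4, length(ord) - 2), 1)
    s0 <- sample(seq_len(length(ord) - len + 1), 1)
    genes <- nm[ord[s0:(s0 + len - 1)]]
    if (kind == "inversion") {
      res <- invert_segment(rec, st, genes)
      state$record <- res$record
      return(add_event(state, kind = kind, genes = genes,
                       interval = res$interval, delta = 0))
    }
    dest <- setdiff(nm[ord], genes)
    if (!length(dest)) stop("no destination spacer")
    after <- sample(dest, 1)
    invert <- runif(1) < 0.5
    res <- relocate_segment(rec, st, genes, after, invert = invert)
    state$record <- res$record
    return(add_event(state, kind = kind, genes = genes, after = after,
                     inverted = invert, delta = 0))
  }
  if (kind == "plant_ssr") {
    mlen <- sample(1:3, 1, prob = c(0.6, 0.25, 0.15))
    repeat {
      motif <- paste(sample(DNA_BASES, mlen, replace = TRUE), collapse = "")
      if (mlen == 1) break
      if (length(unique(seq_chars(motif))) > 1) break
    }
    copies <- c(12L, 8L, 7L)[mlen] + sample(0:4, 1)
    res <- plant_ssr(rec, st, motif, copies)
    state$record <- res$record; state$structure <- res$structure
    state$planted$ssr <- rbind(state$planted$ssr, res$hit)
    return(add_event(state, kind = kind, motif = motif, copies = copies,
                     delta = nchar(motif) * copies + 2))
  }
  if (kind == "plant_tandem") {
    p <- sample(6:15, 1)
    unit <- random_dna(p)
    copies <- ceiling(80 / (2 * p)) + 2 + sample(0:3, 1)
    res <- plant_tandem(rec, st, unit, copies)
    state$record <- res$record; state$structure <- res$structure
    state$planted$tandem <- rbind(state$planted$tandem, res$hit)
    return(add_event(state, kind = kind, period = p, copies = copies,
                     delta = p * copies + 8))
  }
  if (kind == "plant_dispersed") {
    kd <- sample(c("Forward", "Reverse", "Complement", "Palindromic"), 1)
    L <- sample(35:55, 1)
    res <- plant_dispersed(rec, st, kd, length = L, mismatches = 3)
    state$record <- res$record; state$structure <- res$structure
    state$planted$dispersed <- rbind(state$planted$dispersed, res$hit)
    return(add_event(state, kind = kind, repeat_kind = kd, length = L,
                     delta = 2 * (L + 2)))
  }
  stop("unknown event kind: ", kind)
}

apply_substitutions <- function(state, sub_rate, t, gamma_shape = NULL) {
  st <- state$structure
  rec <- state$record
  n <- nchar(rec$sequence)
  uniq_end <- if (is.null(st$irb)) n else st$ira[1]
  seqv <- seq_chars(rec$sequence)
  elig <- setdiff(seq_len(uniq_end), wall_positions(st) + 1L)
  g <- if (is.null(gamma_shape)) 1
       else stats::rgamma(length(elig), shape = gamma_shape,
                          rate = gamma_shape)
  p <- 0.75 * (1 - exp(-4 * sub_rate * t * g / 3))
  hit <- elig[runif(length(elig)) < p]
  if (length(hit)) {
    code <- match(seqv[hit], DNA_BASES)
    keep <- !is.na(code)
    hit <- hit[keep]; code <- code[keep]
    off <- sample.int(3, length(hit), replace = TRUE)
    newb <- DNA_BASES[((code - 1 + off) %% 4) + 1]
    seqv[hit] <- newb
    if (!is.null(st$irb)) {
      in_ir <- (hit - 1) >= st$irb[1] & (hit - 1) < st$irb[2]
      if (any(in_ir)) {
        q <- st$ira[2] - 1 - ((hit[in_ir] - 1) - st$irb[1])
        seqv[q + 1] <- complement_chars(newb[in_ir])
      }
    }
    state$record$sequence <- paste(seqv, collapse = "")
    state <- add_event(state, kind = "substitution_batch",
                       count = length(hit), delta = 0)
  }
  state
}

apply_indels <- function(state, lambda) {
  gaps <- intergenic_gaps(state$record, state$structure)
  if (!length(gaps)) return(state)
  total <- sum(vapply(gaps, function(g) g[2] - g[1], numeric(1)))
  nev <- rpois(1, lambda * total)
  for (z in seq_len(nev)) {
    gaps <- intergenic_gaps(state$record, state$structure)
    gaps <- Filter(function(g) g[2] - g[1] >= 12, gaps)
    if (!length(gaps)) break
    w <- vapply(gaps, function(g) g[2] - g[1], numeric(1))
    g <- gaps[[sample.int(length(gaps), 1, prob = w)]]
    len <- 1 + min(stats::rgeom(1, 0.35), 9)
    if (runif(1) < 0.5) {
      pos <- sample(seq.int(g[1], g[2] - 1), 1)
      state$record <- insert_at(state$record, pos, random_dna(len))
      state$structure <- grow_structure(state$structure, pos, len)
      state <- add_event(state, kind = "indel", type = "insertion",
                         position = pos, delta = len)
    } else {
      len <- min(len, g[2] - g[1] - 2)
      pos <- sample(seq.int(g[1], g[2] - len), 1)
      state$record <- delete_at(state$record, pos, len)
      state$structure <- grow_structure(state$structure, pos, -len)
      state <- add_event(state, kind = "indel", type = "deletion",
                         position = pos, delta = -len)
    }
  }
  state
}

evolve_edge <- function(state, t, rates, er) {
  for (kind in names(er)) {
    if (er[[kind]] <= 0 || t <= 0) next
    nev <- rpois(1, er[[kind]] * t)
    for (z in seq_len(nev)) {
      state <- tryCatch(apply_random_event(state, kind), error = function(e) {
        add_event(state, kind = kind, skipped = TRUE,
                  reason = conditionMessage(e), delta = 0)
      })
    }
  }
  if (rates$sub_rate > 0 && t > 0)
    state <- apply_substitutions(state, rates$sub_rate, t, rates$gamma_shape)
  if (rates$indel_rate > 0 && t > 0)
    state <- apply_indels(state, rates$indel_rate * t)
  state
}

#' Evolve an ancestral plastome along a clock tree
#'
#' Substitutions follow the Jukes-Cantor model (exact per-branch transition
#' probabilities, optional gamma rate heterogeneity); substitutions falling
#' in the IR are applied to both copies, so `IRA` stays the exact reverse
#' complement of `IRB` (concerted evolution). Indels are restricted to
#' single-copy intergenic spacers. Structural events (IR junction shifts,
#' gene loss, pseudogenization, inversion, relocation, planted repeats) occur
#' as Poisson processes with the given per-unit-branch-length rates, and
#' every applied event is recorded in the truth log together with its signed
#' effect on genome length.
#'
#' @param ancestor Output of [build_ancestor()].
#' @param tree An `ape::phylo` tree, a newick string, or a newick file; tips
#'   uniquely named, branch lengths in expected substitutions per site.
#' @param rates `list(sub_rate, indel_rate, gamma_shape, event_rates)`;
#'   `event_rates` is a named list over the event kinds above (default all
#'   zero).
#' @param seed Integer seed governing all randomness.
#' @return `list(records, truth)`: one [plastome_record()] per tip plus a
#'   `plastome_truth` log (per-tip structure, events, planted repeats and
#'   realized gene status).
#' @export
evolve_plastomes <- function(ancestor, tree, rates = list(), seed = 1) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label) > 0) stop("tip labels must be unique")
  defaults <- list(sub_rate = 1, indel_rate = 0, gamma_shape = NULL,
                   event_rates = list())
  rates <- utils::modifyList(defaults, rates)
  er_def <- list(ir_expand = 0, ir_contract = 0, gene_loss = 0,
                 pseudogenize = 0, inversion = 0, relocation = 0,
                 plant_ssr = 0, plant_tandem = 0, plant_dispersed = 0)
  er <- utils::modifyList(er_def, rates$event_rates)
  bad <- setdiff(names(rates$event_rates), names(er_def))
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "))

  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1]] <- list(record = ancestor$record,
                             structure = ancestor$structure,
                             events = list(), planted = list())
  with_seed(seed, {
    for (e in seq_len(nrow(tr$edge))) {
      states[[tr$edge[e, 2]]] <- evolve_edge(states[[tr$edge[e, 1]]],
                                             tr$edge.length[e], rates, er)
    }
  })
  template <- ancestor$truth$template
  tips <- stats::setNames(vector("list", ntip), tr$tip.label)
  for (i in seq_len(ntip)) {
    s <- states[[i]]
    s$record$id <- tr$tip.label[i]
    s$structure$id <- tr$tip.label[i]
    s$gene_status <- gene_status_from_record(s$record, template)
    tips[[tr$tip.label[i]]] <- s
  }
  truth <- structure(list(ancestor = ancestor, tree = tr, tips = tips),
                     class = "plastome_truth")
  list(records = lapply(tips, `[[`, "record"), truth = truth)
}

#' Simulate a gap-free alignment under Jukes-Cantor on a tree
#'
#' Utility used to test distance, tree and per-site-rate estimators: each
#' site evolves independently at its own rate; per-branch transition
#' probabilities are the exact JC values.
#'
#' @param tree `ape::phylo` or newick string, branch lengths in expected
#'   substitutions per site (at rate 1).
#' @param lambda Per-site rate(s); recycled to the number of sites if
#'   `n_sites` is given.
#' @param n_sites Number of sites (defaults to `length(lambda)`).
#' @param seed Integer seed.
#' @return Character matrix of bases, rows named by tip.
#' @export
simulate_alignment_jc <- function(tree, lambda, n_sites = NULL, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!is.null(n_sites)) lambda <- rep_len(lambda, n_sites)
  L <- length(lambda)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  seqs <- vector("list", ntip + tr$Nnode)
  with_seed(seed, {
    seqs[[ntip + 1]] <- sample(DNA_BASES, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      par <- seqs[[tr$edge[e, 1]]]
      t <- tr$edge.length[e]
      p <- 0.75 * (1 - exp(-4 * lambda * t / 3))
      ch <- par
      hit <- which(runif(L) < p)
      if (length(hit)) {
        off <- sample.int(3, length(hit), replace = TRUE)
        ch[hit] <- DNA_BASES[((match(par[hit], DNA_BASES) - 1 + off) %% 4) + 1]
      }
      seqs[[tr$edge[e, 2]]] <- ch
    }
  })
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tr$tip.label
  m
}
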