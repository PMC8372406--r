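# Reading and writing the standard flat formats. GenBank flat files are
# parsed directly (no offline R parser exists for feature tables); FASTA goes
# through Biostrings and GFF3 through rtracklayer. All internal coordinates
# are 0-based half-open; GenBank/GFF3 coordinates (1-based inclusive) are
# converted exactly at this boundary.

GB_KEYS <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")

# parse a GenBank location string into list(strand, parts matrix in
# transcription order)
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  if (grepl("complement", loc))
    stop("unsupported location (nested complement): ", loc)
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1]]
  parts <- t(vapply(pieces, function(p) {
    if (grepl("\\.\\.", p)) {
      se <- as.numeric(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- c(as.numeric(p), as.numeric(p))
    }
    if (any(is.na(se))) stop("malformed location: ", p)
    c(se[1] - 1, se[2])  # 1-based inclusive -> 0-based half-open
  }, numeric(2)))
  colnames(parts) <- c("start", "end")
  if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
  list(strand = strand, parts = parts)
}

#' Read a single-record GenBank flat file
#'
#' Parses the sequence and the `CDS`, `tRNA` and `rRNA` entries of the feature
#' table into a [plastome_record()]. Feature names come from the `/gene=`
#' qualifier (falling back to `/product=`); `complement(join(...))` locations
#' become multi-part minus-strand features with parts in transcription order;
#' a `/pseudo` qualifier sets the pseudogene flag.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0) stop("not a GenBank flat file: no LOCUS line")
  if (length(locus) > 1) stop("multi-record GenBank files are not supported")
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus])), "[[:space:]]+")[[1]][1]
  circular <- grepl("circular", lines[locus], ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) != 1) stop("malformed record: missing ORIGIN (line ",
                                if (length(fstart)) fstart else 1, ")")
  seq_lines <- lines[(ostart + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- chartr("RYSWKMBDHVU", "NNNNNNNNNNT", sequence)

  features <- list()
  if (length(fstart) == 1) {
    ftab <- lines[(fstart + 1):(ostart - 1)]
    # group physical lines into logical feature entries
    is_key <- grepl("^ {5}\\S", ftab)
    idx <- cumsum(is_key)
    for (g in unique(idx[idx > 0])) {
      block <- ftab[idx == g]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (!key %in% names(GB_KEYS)) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ {21}/", block)
      loc_end <- if (length(qual_at)) min(qual_at) - 1 else length(block)
      loc <- paste(trimws(sub("^ {5}\\S+", "", block[1:loc_end])),
                   collapse = "")
      parsed <- tryCatch(parse_gb_location(loc), error = function(e)
        stop("parse error near feature table line ", which(idx == g)[1],
             ": ", conditionMessage(e)))
      quals <- paste(trimws(block[-(1:loc_end)]), collapse = " ")
      getq <- function(q) {
        m <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1]]
        if (length(m) == 2) m[2] else NA_character_
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("product")
      if (is.na(name)) next
      pseudo <- grepl("/pseudo(\\s|$|gene)", quals)
      features[[length(features) + 1]] <- gene_feature(
        name = name, category = GB_KEYS[[key]], strand = parsed$strand,
        parts = parsed$parts, pseudo = pseudo)
    }
  }
  plastome_record(id = id, sequence = sequence, features = features,
                  circular = circular, source = path)
}

#' Read a FASTA + GFF3 annotation pair
#'
#' @param fasta Single-sequence FASTA file.
#' @param gff GFF3 file whose `seqid` matches the FASTA header id.
#' @return A [plastome_record()].
#' @export
read_fasta_gff <- function(fasta, gff) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1) stop("expected a single FASTA record")
  id <- strsplit(names(ss)[1], "[[:space:]]+")[[1]][1]
  sequence <- as.character(ss[[1]])
  n <- nchar(sequence)
  gr <- rtracklayer::import(gff, format = "gff3")
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) && !all(seqids == id))
    stop(sprintf("GFF3 seqid '%s' does not match FASTA id '%s'",
                 seqids[seqids != id][1], id))
  md <- S4Vectors::mcols(gr)
  starts <- GenomicRanges::start(gr) - 1L   # GFF3 1-based inclusive
  ends <- GenomicRanges::end(gr)
  if (any(starts < 0) || any(ends > n))
    stop("GFF3 coordinate outside the sequence")
  type <- as.character(md$type)
  strand <- as.character(GenomicRanges::strand(gr))
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  idcol <- if ("ID" %in% names(md)) as.character(md$ID)
           else rep(NA_character_, length(gr))
  namecol <- if ("Name" %in% names(md)) as.character(md$Name)
             else rep(NA_character_, length(gr))
  pseudocol <- if ("pseudo" %in% names(md)) as.character(md$pseudo)
               else rep(NA_character_, length(gr))

  part_rows <- which(type %in% c("CDS", "tRNA", "rRNA", "exon"))
  key <- ifelse(is.na(parent[part_rows]), idcol[part_rows], parent[part_rows])
  key[is.na(key)] <- paste0("anon", part_rows[is.na(key)])
  features <- list()
  for (k in unique(key)) {
    rows <- part_rows[key == k]
    ty <- type[rows][1]
    category <- if (ty %in% c("CDS", "tRNA", "rRNA")) ty else "other"
    st <- strand[rows][1]
    if (!st %in% c("+", "-")) st <- "+"
    nm <- namecol[rows][1]
    if (is.na(nm)) {
      gi <- which(idcol == k)
      if (length(gi) && !is.na(namecol[gi[1]])) nm <- namecol[gi[1]]
    }
    if (is.na(nm)) nm <- sub("\\.[0-9]+$", "", k)
    ps <- any(pseudocol[rows] %in% c("true", "TRUE", "1"))
    gi <- which(idcol == k)
    if (length(gi)) ps <- ps || any(pseudocol[gi] %in% c("true", "TRUE", "1")) ||
        any(type[gi] == "pseudogene")
    p <- cbind(start = starts[rows], end = ends[rows])
    p <- p[order(p[, 1]), , drop = FALSE]
    if (st == "-") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    features[[length(features) + 1]] <- gene_feature(
      name = nm, category = category, strand = st, parts = p, pseudo = ps)
  }
  plastome_record(id = id, sequence = sequence, features = features,
                  circular = TRUE, source = paste(fasta, gff, sep = "+"))
}

# ----------------------------------------------------------------- writers --

write_record_fasta <- function(rec, path) {
  ss <- Biostrings::DNAStringSet(setNames(rec$sequence, rec$id))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

write_record_gff3 <- function(rec, path) {
  n <- nchar(rec$sequence)
  rows <- list()
  for (i in seq_along(rec$features)) {
    f <- rec$features[[i]]
    fid <- sprintf("%s.%d", f$name, i)
    # split parts that wrap the origin into two GFF lines
    p <- f$parts
    out <- NULL
    for (r in seq_len(nrow(p))) {
      s <- p[r, 1]; e <- p[r, 2]
      if (e <= n) out <- rbind(out, c(s, e))
      else out <- rbind(out, c(s, n), c(0, e - n))
    }
    span <- c(min(out[, 1]), max(out[, 2]))
    rows[[length(rows) + 1]] <- data.frame(
      start = span[1] + 1, end = span[2], type = "gene", strand = f$strand,
      ID = fid, Parent = NA_character_, Name = f$name,
      phase = NA_integer_,
      pseudo = if (f$pseudo) "true" else NA_character_)
    ty <- if (f$category %in% c("CDS", "tRNA", "rRNA")) f$category else "exon"
    # CDS phase: bases of the part that belong to the previous codon
    coding_before <- 0L
    for (r in seq_len(nrow(f$parts))) {   # parts in transcription order
      plen <- f$parts[r, 2] - f$parts[r, 1]
      phase <- if (ty == "CDS") (3L - coding_before %% 3L) %% 3L
               else NA_integer_
      coding_before <- coding_before + plen
      s <- f$parts[r, 1]; e <- f$parts[r, 2]
      segs <- if (e <= n) list(c(s, e)) else list(c(s, n), c(0, e - n))
      for (sg in segs) {
        rows[[length(rows) + 1]] <- data.frame(
          start = sg[1] + 1, end = sg[2], type = ty, strand = f$strand,
          ID = sprintf("%s.part%d", fid, length(rows)), Parent = fid,
          Name = f$name, phase = phase,
          pseudo = if (f$pseudo) "true" else NA_character_)
      }
    }
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = rec$id,
      ranges = IRanges::IRanges(start = df$start, end = df$end),
      strand = df$strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$ID <- df$ID
    S4Vectors::mcols(gr)$Name <- df$Name
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
    S4Vectors::mcols(gr)$phase <- df$phase
    S4Vectors::mcols(gr)$pseudo <- df$pseudo
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", rec$id, n)), path)
  }
  invisible(path)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline product to a standard format
#'
#' BED output is 0-based half-open, GFF3 1-based inclusive; TSVs carry a
#' header comment naming the columns; trees are written as newick.
#'
#' @param x A pipeline product (record, structure, data frame, tree,
#'   alignment...).
#' @param path Output file.
#' @param format One of `"fasta"`, `"gff3"`, `"tsv"`, `"json"`, `"newick"`,
#'   `"bed"`.
#' @return `path`, invisibly.
#' @export
write_output <- function(x, path,
                         format = c("fasta", "gff3", "tsv", "json", "newick",
                                    "bed")) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (inherits(x, "plastome_record")) return(write_record_fasta(x, path))
    if (is.matrix(x) && is.character(x)) {   # alignment: rows = taxa
      ss <- Biostrings::DNAStringSet(apply(x, 1, paste, collapse = ""))
      Biostrings::writeXStringSet(ss, filepath = path)
      return(invisible(path))
    }
    if (is.character(x) && !is.null(names(x))) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
      return(invisible(path))
    }
  }
  if (format == "gff3" && inherits(x, "plastome_record"))
    return(write_record_gff3(x, path))
  if (format == "bed" && inherits(x, "quadripartite_structure")) {
    n <- x$n
    rows <- list()
    add <- function(name, iv) {
      if (is.null(iv)) return()
      if (iv[2] <= n) rows[[length(rows) + 1]] <<- c(iv[1], iv[2], name)
      else {
        rows[[length(rows) + 1]] <<- c(iv[1], n, name)
        rows[[length(rows) + 1]] <<- c(0, iv[2] - n, name)
      }
    }
    add("LSC", x$lsc); add("IRB", x$irb); add("SSC", x$ssc); add("IRA", x$ira)
    df <- do.call(rbind, rows)
    writeLines(paste(x$id %||% "plastome", df[, 1], df[, 2], df[, 3],
                     sep = "\t"), path)
    return(invisible(path))
  }
  if (format == "tsv") {
    if (inherits(x, "sv_result_set")) {
      df <- as.data.frame(x)
      df <- df[order(-df$sv, df$locus), ]
      return(write_tsv(df, path, "syntenic loci sorted by SV (descending)"))
    }
    if (is.data.frame(x)) return(write_tsv(x, path))
  }
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(path))
  }
  if (format == "newick" && inherits(x, "phylo")) {
    ape::write.tree(x, file = path)
    return(invisible(path))
  }
  stop(sprintf("cannot write a %s as %s", paste(class(x), collapse = "/"),
               format))
}
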