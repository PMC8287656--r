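# GenBank/FASTA ingestion and the in-memory mitogenome data model.
#
# Coordinates are 1-based inclusive externally (GenBank convention).  A
# MitoGenome is an S3 list: id, sequence (uppercase ACGTN string), circular,
# features (list of GeneFeature, sorted by start), introns (list of
# IntronFeature), source.  GeneFeature exons are stored in coding order:
# for '-' strand multi-exon features the first exon is the most 3' in
# genome coordinates.

CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "rps3")

GENE_KINDS <- c("PCG", "rRNA", "tRNA", "intronic_ORF", "plasmid_derived",
                "unknown_ORF")

new_gene_feature <- function(name, kind, strand, exons, product = "") {
  stopifnot(kind %in% GENE_KINDS, strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("zero- or negative-length exon in feature ", name, call. = FALSE)
  }
  structure(list(name = name, kind = kind, strand = strand,
                 exons = exons, product = product),
            class = "GeneFeature")
}

new_intron_feature <- function(host_gene, index, start, end,
                               group = "unknown", encoded_orfs = character()) {
  structure(list(host_gene = host_gene, index = as.integer(index),
                 start = as.integer(start), end = as.integer(end),
                 group = group, encoded_orfs = encoded_orfs),
            class = "IntronFeature")
}

feature_start <- function(f) min(f$exons)
feature_end <- function(f) max(f$exons)
feature_span <- function(f) sum(f$exons[, 2L] - f$exons[, 1L] + 1L)

#' Construct a MitoGenome object
#'
#' @param id accession or label
#' @param sequence uppercase DNA string over ACGTN
#' @param circular logical, circular topology
#' @param features list of GeneFeature (genes, CDS, tRNA, rRNA)
#' @param introns list of IntronFeature
#' @param source path the record was read from, if any
#' @return an object of class `MitoGenome`
#' @export
MitoGenome <- function(id, sequence, circular = TRUE, features = list(),
                       introns = list(), source = NA_character_) {
  sequence <- validate_dna(sequence, paste0("sequence of ", id))
  len <- nchar(sequence)
  for (f in features) {
    if (feature_start(f) < 1L || feature_end(f) > len) {
      stop("feature ", f$name, " outside sequence bounds [1,", len, "]",
           call. = FALSE)
    }
  }
  ord <- order(vapply(features, feature_start, integer(1)))
  if (length(introns)) {
    iord <- order(vapply(introns, `[[`, character(1), "host_gene"),
                  vapply(introns, `[[`, integer(1), "start"))
    introns <- introns[iord]
  }
  structure(list(id = id, sequence = sequence,
                 circular = isTRUE(circular),
                 features = features[ord], introns = introns,
                 source = source),
            class = "MitoGenome")
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome %s: %d bp, %s, %d features, %d introns\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              length(x$features), length(x$introns)))
  invisible(x)
}

#' Length of a genome sequence in nucleotides
#' @param genome a [MitoGenome]
#' @return integer length
#' @export
genome_length <- function(genome) nchar(genome$sequence)

find_feature <- function(genome, gene) {
  for (f in genome$features) if (f$name == gene) return(f)
  NULL
}

## ---------------------------------------------------------------- GenBank

# Recursive location parser for the subset of the GenBank grammar used by
# organelle records: N..M, complement(...), join(...), with optional
# partial markers < and >.  Returns list(strand, exons) with exons in
# coding order.
parse_location <- function(loc, line = loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- parse_location(sub("\\)$", "", sub("^complement\\(", "", loc)), line)
    return(list(strand = if (inner$strand == "+") "-" else "+",
                exons = inner$exons[rev(seq_len(nrow(inner$exons))), , drop = FALSE]))
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("\\)$", "", sub("^join\\(", "", loc))
    parts <- character()
    depth <- 0L; start <- 1L
    cs <- strsplit(body, "", fixed = TRUE)[[1L]]
    for (i in seq_along(cs)) {
      if (cs[i] == "(") depth <- depth + 1L
      if (cs[i] == ")") depth <- depth - 1L
      if (cs[i] == "," && depth == 0L) {
        parts <- c(parts, substr(body, start, i - 1L)); start <- i + 1L
      }
    }
    parts <- c(parts, substr(body, start, nchar(body)))
    sub_locs <- lapply(parts, parse_location, line = line)
    strands <- vapply(sub_locs, `[[`, character(1), "strand")
    if (length(unique(strands)) != 1L) {
      stop("mixed-strand join() not supported: ", line, call. = FALSE)
    }
    return(list(strand = strands[1L],
                exons = do.call(rbind, lapply(sub_locs, `[[`, "exons"))))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
    return(list(strand = "+", exons = matrix(se, ncol = 2L)))
  }
  if (grepl("^[0-9]+$", loc)) {
    p <- as.integer(loc)
    return(list(strand = "+", exons = matrix(c(p, p), ncol = 2L)))
  }
  stop("cannot parse GenBank location: ", line, call. = FALSE)
}

format_location <- function(strand, exons) {
  # exons are in coding order; GenBank lists genome-ascending order inside
  # complement(join(...)).
  ex <- exons
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  spans <- paste0(ex[, 1L], "..", ex[, 2L])
  body <- if (length(spans) > 1L) paste0("join(", paste(spans, collapse = ","), ")") else spans
  if (strand == "-") paste0("complement(", body, ")") else body
}

classify_cds_kind <- function(name, product, intron_intervals) {
  nm <- tolower(name)
  if (nm %in% tolower(CORE_PCGS)) return("PCG")
  if (grepl("polymerase", tolower(product)) || grepl("^(dpo|rpo)", nm)) {
    return("plasmid_derived")
  }
  if (grepl("^orf", nm)) {
    if (nrow(intron_intervals)) {
      # positions resolved by caller; here a placeholder, refined later
      return("unknown_ORF")
    }
    return("unknown_ORF")
  }
  "PCG"
}

#' Read a GenBank flat file into a MitoGenome
#'
#' Parses LOCUS (length, circular/linear), the FEATURES table (CDS, tRNA,
#' rRNA and intron keys; `join()`/`complement()` locations are resolved to
#' oriented exon lists) and the ORIGIN sequence block.  Intron features
#' absent from the record are inferred as the gaps between consecutive CDS
#' exons of the same gene.  ORFs located inside intron intervals are
#' reclassified as intronic ORFs and attached to their host intron.
#'
#' @param path path to a GenBank flat file containing one record
#' @return a [MitoGenome] object
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path,
                             call. = FALSE)
  locus <- lines[locus_i[1L]]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  circular <- any(tolower(toks) == "circular")

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("GenBank record has no ORIGIN sequence block: ",
                            path, call. = FALSE)

  # --- sequence
  seq_lines <- lines[(orig_i[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- chartr("U", "T", sequence)

  # --- features
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]
    # fold continuation lines: a new feature starts at column 6 with a key
    key_re <- "^ {5}\\S"
    entries <- list(); cur <- NULL
    for (ln in block) {
      if (grepl(key_re, ln)) {
        if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
        cur <- ln
      } else if (!is.null(cur)) {
        cur <- c(cur, ln)
      }
    }
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

    for (e in entries) {
      head_toks <- strsplit(trimws(e[1L]), "[[:space:]]+")[[1L]]
      key <- head_toks[1L]
      rest <- paste(c(head_toks[-1L], ""), collapse = "")
      # location may continue onto lines before the first qualifier
      qual_start <- grep("^\\s*/", e)
      loc_lines <- if (length(qual_start)) {
        if (qual_start[1L] > 2L) e[2L:(qual_start[1L] - 1L)] else character()
      } else if (length(e) > 1L) e[-1L] else character()
      loc <- paste0(rest, paste(trimws(loc_lines), collapse = ""))
      quals <- character()
      if (length(qual_start)) {
        qlines <- trimws(e[qual_start[1L]:length(e)])
        # join wrapped qualifier values
        merged <- character()
        for (q in qlines) {
          if (startsWith(q, "/")) merged <- c(merged, q)
          else if (length(merged)) merged[length(merged)] <- paste(merged[length(merged)], q)
        }
        quals <- merged
      }
      getq <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return("")
        gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1L]))
      }
      if (!key %in% c("CDS", "tRNA", "rRNA", "intron", "gene")) next
      pl <- tryCatch(parse_location(loc),
                     error = function(e2) stop("format error in feature line: ",
                                               trimws(e[1L]), " (", conditionMessage(e2), ")",
                                               call. = FALSE))
      name <- getq("gene")
      if (name == "") name <- getq("label")
      if (name == "") name <- getq("product")
      feats[[length(feats) + 1L]] <- list(key = key, name = name,
                                          strand = pl$strand, exons = pl$exons,
                                          product = getq("product"),
                                          note = getq("note"))
    }
  }

  len <- nchar(sequence)
  for (f in feats) {
    if (min(f$exons) < 1L || max(f$exons) > len) {
      stop("coordinate error: feature ", f$name, " at ",
           min(f$exons), "..", max(f$exons), " outside 1..", len, call. = FALSE)
    }
  }

  # explicit intron features first
  introns <- list()
  for (f in feats) {
    if (f$key == "intron") {
      grp <- if (grepl("group ?II", f$note, ignore.case = TRUE)) "II"
             else if (grepl("group ?I", f$note, ignore.case = TRUE)) "I"
             else "unknown"
      introns[[length(introns) + 1L]] <-
        new_intron_feature(f$name, index = 0L, start = min(f$exons),
                           end = max(f$exons), group = grp)
    }
  }

  # gene features only supply names for keys we keep; skip them
  features <- list()
  cds_feats <- Filter(function(f) f$key == "CDS", feats)
  intron_ivs <- if (length(introns)) {
    cbind(vapply(introns, `[[`, integer(1), "start"),
          vapply(introns, `[[`, integer(1), "end"))
  } else matrix(integer(), ncol = 2L)

  inside_intron <- function(exons) {
    if (!nrow(intron_ivs)) return(FALSE)
    s <- min(exons); e <- max(exons)
    any(intron_ivs[, 1L] <= s & intron_ivs[, 2L] >= e)
  }

  for (f in feats) {
    kind <- switch(f$key,
      CDS = {
        k <- classify_cds_kind(f$name, f$product, intron_ivs)
        if (k == "unknown_ORF" && inside_intron(f$exons)) "intronic_ORF" else k
      },
      tRNA = "tRNA", rRNA = "rRNA", NULL)
    if (is.null(kind)) next
    features[[length(features) + 1L]] <-
      new_gene_feature(f$name, kind, f$strand, f$exons, f$product)
  }

  # infer introns from multi-exon CDS when the record declares none for
  # that gene
  declared_hosts <- vapply(introns, `[[`, character(1), "host_gene")
  for (f in features) {
    if (!f$kind %in% c("PCG", "plasmid_derived", "unknown_ORF")) next
    if (nrow(f$exons) < 2L) next
    ex <- f$exons[order(f$exons[, 1L]), , drop = FALSE]  # genome order
    for (i in seq_len(nrow(ex) - 1L)) {
      s <- ex[i, 2L] + 1L; e <- ex[i + 1L, 1L] - 1L
      if (e < s) next
      already <- any(declared_hosts == f$name &
                     vapply(introns, function(x) x$start == s && x$end == e,
                            logical(1)))
      if (f$name %in% declared_hosts) {
        # keep declared introns, but only add if this gap is not declared
        if (already) next
        declared_here <- any(vapply(introns, function(x) {
          x$host_gene == f$name && x$start <= s && x$end >= e
        }, logical(1)))
        if (declared_here) next
      }
      introns[[length(introns) + 1L]] <-
        new_intron_feature(f$name, 0L, s, e, group = "unknown")
    }
  }

  # ORFs inside inferred intron intervals are intronic ORFs too
  if (length(introns)) {
    iv <- cbind(vapply(introns, `[[`, integer(1), "start"),
                vapply(introns, `[[`, integer(1), "end"))
    for (j in seq_along(features)) {
      f <- features[[j]]
      if (f$kind != "unknown_ORF") next
      s <- feature_start(f); e <- feature_end(f)
      if (any(iv[, 1L] <= s & iv[, 2L] >= e)) features[[j]]$kind <- "intronic_ORF"
    }
  }

  # attach intronic ORFs and host genes to introns; index introns per host
  for (j in seq_along(introns)) {
    if (introns[[j]]$host_gene != "") next
    for (f in features) {
      ex <- f$exons
      if (nrow(ex) >= 2L && min(ex) <= introns[[j]]$start &&
          max(ex) >= introns[[j]]$end) {
        introns[[j]]$host_gene <- f$name
        break
      }
    }
  }
  for (j in seq_along(introns)) {
    orfs <- vapply(features, function(f) {
      f$kind == "intronic_ORF" && feature_start(f) >= introns[[j]]$start &&
        feature_end(f) <= introns[[j]]$end
    }, logical(1))
    introns[[j]]$encoded_orfs <- vapply(features[orfs], `[[`, character(1), "name")
  }
  if (length(introns)) {
    hosts <- vapply(introns, `[[`, character(1), "host_gene")
    starts <- vapply(introns, `[[`, integer(1), "start")
    ord <- order(hosts, starts)
    introns <- introns[ord]
    for (h in unique(hosts)) {
      idx <- which(vapply(introns, `[[`, character(1), "host_gene") == h)
      for (k in seq_along(idx)) introns[[idx[k]]]$index <- k
    }
  }

  MitoGenome(id = id, sequence = sequence, circular = circular,
             features = features, introns = introns, source = path)
}

#' Write a MitoGenome as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (gene/CDS/tRNA/rRNA/intron) and ORIGIN so that
#' `read_genbank()` round-trips every feature interval and strand.
#'
#' @param genome a [MitoGenome]
#' @param path output path
#' @return the path, invisibly
#' @export
write_genbank <- function(genome, path) {
  len <- genome_length(genome)
  top <- if (genome$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s%17d bp    DNA     %s   UNA 01-JAN-2000",
                   genome$id, len, top),
           sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$id),
           sprintf("ACCESSION   %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", len))

  emit <- function(key, loc, quals) {
    head <- sprintf("     %-16s%s", key, loc)
    c(head, sprintf("                     %s", quals))
  }
  for (f in genome$features) {
    loc <- format_location(f$strand, f$exons)
    key <- switch(f$kind, tRNA = "tRNA", rRNA = "rRNA", "CDS")
    quals <- sprintf("/gene=\"%s\"", f$name)
    if (nzchar(f$product)) quals <- c(quals, sprintf("/product=\"%s\"", f$product))
    if (key == "CDS") quals <- c(quals, "/transl_table=4")
    out <- c(out, emit(key, loc, quals))
  }
  for (it in genome$introns) {
    quals <- sprintf("/gene=\"%s\"", it$host_gene)
    if (it$group != "unknown") {
      quals <- c(quals, sprintf("/note=\"group %s intron\"", it$group))
    }
    out <- c(out, emit("intron", paste0(it$start, "..", it$end), quals))
  }

  out <- c(out, "ORIGIN")
  pos <- seq(1L, len, 60L)
  for (p in pos) {
    chunk_ends <- pmin(p + seq(0L, 50L, 10L) + 9L, len)
    chunk_starts <- p + seq(0L, 50L, 10L)
    keep <- chunk_starts <= len
    blocks <- substring(genome$sequence, chunk_starts[keep], chunk_ends[keep])
    out <- c(out, sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ------------------------------------------------------------------ FASTA

#' Read a FASTA file
#'
#' @param path FASTA text file, one or more records
#' @return named list of uppercase sequences (names are the first
#'   whitespace-delimited header token); 'U' is mapped to 'T'
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("FASTA record with empty sequence in ", path,
                                   call. = FALSE)
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  as.list(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or list of DNA/protein strings
#' @param path output path
#' @param width line-wrap width
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- unlist(seqs)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## ------------------------------------------------------------ CDS extract

#' Extract the spliced coding sequence of a gene
#'
#' Exons are spliced in coding order; minus-strand features are
#' reverse-complemented.  Translation uses the mold/protozoan mitochondrial
#' genetic code (NCBI table 4) by default.
#'
#' @param genome a [MitoGenome]
#' @param gene gene symbol
#' @param code NCBI genetic-code id (default "4")
#' @return a `CodingSequence`: list with genome_id, gene, nt, aa and
#'   exon_boundaries (CDS-coordinate offsets where exons join)
#' @export
extract_cds <- function(genome, gene, code = "4") {
  f <- find_feature(genome, gene)
  if (is.null(f)) stop("gene not found in ", genome$id, ": ", gene, call. = FALSE)
  if (!f$kind %in% c("PCG", "intronic_ORF", "plasmid_derived", "unknown_ORF")) {
    stop(gene, " is not protein-coding (kind ", f$kind, ")", call. = FALSE)
  }
  pieces <- character(nrow(f$exons))
  for (i in seq_len(nrow(f$exons))) {
    s <- substr(genome$sequence, f$exons[i, 1L], f$exons[i, 2L])
    pieces[i] <- if (f$strand == "-") revcomp(s) else s
  }
  nt <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  bounds <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] else integer()
  aa <- translate_cds(nt, code = code)
  structure(list(genome_id = genome$id, gene = gene, nt = nt, aa = aa,
                 exon_boundaries = as.integer(bounds)),
            class = "CodingSequence")
}

## -------------------------------------------------------------- summaries

#' Summarize the annotation of one genome
#'
#' Counts are partitioned by feature kind.  `n_pcg` counts conserved
#' protein-coding genes only; `n_pcg_all` additionally includes
#' plasmid-derived and unknown-function ORFs (but never intronic ORFs).
#'
#' @param genome a [MitoGenome]
#' @return list with counts, rRNA lengths and a per-gene length table
#' @export
summarize_annotation <- function(genome) {
  kinds <- vapply(genome$features, `[[`, character(1), "kind")
  lens <- vapply(genome$features, feature_span, integer(1))
  names(lens) <- vapply(genome$features, `[[`, character(1), "name")
  rna_len <- function(g) {
    f <- find_feature(genome, g)
    if (is.null(f)) NA_integer_ else feature_span(f)
  }
  list(
    genome_id = genome$id,
    length = genome_length(genome),
    n_pcg = sum(kinds == "PCG"),
    n_pcg_all = sum(kinds %in% c("PCG", "plasmid_derived", "unknown_ORF")),
    n_trna = sum(kinds == "tRNA"),
    n_rrna = sum(kinds == "rRNA"),
    n_intron = length(genome$introns),
    n_intronic_orf = sum(kinds == "intronic_ORF"),
    len_rns = rna_len("rns"),
    len_rnl = rna_len("rnl"),
    gene_lengths = lens
  )
}

#' Annotation-summary table for several genomes
#'
#' @param genomes list of [MitoGenome]
#' @return data.frame, one row per genome
#' @export
annotation_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    s <- summarize_annotation(g)
    data.frame(genome_id = s$genome_id, length = s$length, n_pcg = s$n_pcg,
               n_pcg_all = s$n_pcg_all, n_trna = s$n_trna, n_rrna = s$n_rrna,
               n_intron = s$n_intron, n_intronic_orf = s$n_intronic_orf,
               len_rns = s$len_rns, len_rnl = s$len_rnl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
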