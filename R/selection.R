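# Codon-aware alignment and Nei-Gojobori (1986) Ka/Ks.
#
# The estimator is classical NG86: per-codon synonymous/nonsynonymous site
# fractions, pathway-averaged difference counts, proportions computed
# against site counts averaged over the two sequences, and a Jukes-Cantor
# correction.  Pathways passing through stop codons are excluded from the
# average; if every pathway does, the average falls back to including them
# (a message is emitted).

#' Protein-guided codon alignment of two coding sequences
#'
#' Both CDS are translated (terminal stop dropped), globally aligned at the
#' protein level (Needleman-Wunsch, BLOSUM62, affine gaps) and the
#' alignment is back-threaded to nucleotides.  Columns containing a gap, an
#' ambiguous base, or a stop codon are removed.
#'
#' @param a,b `CodingSequence` objects (from [extract_cds()]) or plain CDS
#'   nucleotide strings
#' @param code NCBI genetic-code id
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment
#' @return a `CodonAlignment`: list with gene, ids, codons_a, codons_b
#'   (parallel character vectors of retained codon columns), n_codons,
#'   n_removed, and the nucleotide-level position maps `map_a_to_b`
#' @export
codon_align <- function(a, b, code = "4", gap_opening = 10, gap_extension = 0.5) {
  nt_a <- if (inherits(a, "CodingSequence")) a$nt else validate_dna(a)
  nt_b <- if (inherits(b, "CodingSequence")) b$nt else validate_dna(b)
  gene <- if (inherits(a, "CodingSequence")) a$gene else NA_character_
  id_a <- if (inherits(a, "CodingSequence")) a$genome_id else "a"
  id_b <- if (inherits(b, "CodingSequence")) b$genome_id else "b"

  gc <- genetic_code(code)
  strip_stop <- function(nt) {
    cods <- split_codons(nt)
    if (length(cods) && !is.na(gc[cods[length(cods)]]) &&
        gc[cods[length(cods)]] == "*") {
      cods <- cods[-length(cods)]
    }
    cods
  }
  cod_a <- strip_stop(nt_a)
  cod_b <- strip_stop(nt_b)
  aa_a <- vapply(cod_a, function(cd) {
    x <- gc[cd]; if (is.na(x)) "X" else unname(x)
  }, character(1))
  aa_b <- vapply(cod_b, function(cd) {
    x <- gc[cd]; if (is.na(x)) "X" else unname(x)
  }, character(1))
  if (!length(aa_a) || !length(aa_b)) {
    stop("empty protein after trimming; cannot align", call. = FALSE)
  }
  # internal stops would break the scoring matrix lookup
  aa_a[aa_a == "*"] <- "X"; aa_b[aa_b == "*"] <- "X"

  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(aa_a, collapse = "")),
    Biostrings::AAString(paste(aa_b, collapse = "")),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  pat <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(aln)))

  ia <- 0L; ib <- 0L
  keep_a <- integer(); keep_b <- integer()
  for (k in seq_along(pat)) {
    ga <- pat[k] == "-"; gb <- sub[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) { keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib) }
  }
  ca <- cod_a[keep_a]; cb <- cod_b[keep_b]
  clean <- !grepl("N", ca) & !grepl("N", cb) &
    !is.na(gc[ca]) & !is.na(gc[cb]) & gc[ca] != "*" & gc[cb] != "*"
  structure(list(gene = gene, id_a = id_a, id_b = id_b,
                 codons_a = unname(ca[clean]), codons_b = unname(cb[clean]),
                 codon_index_a = keep_a[clean], codon_index_b = keep_b[clean],
                 n_codons = sum(clean), n_removed = length(pat) - sum(clean),
                 aligned_aa_a = pat, aligned_aa_b = sub),
            class = "CodonAlignment")
}

# Map a nucleotide offset in sequence a's CDS to the homologous position in
# b's CDS through a CodonAlignment; offsets falling in b-gaps map to the
# nearest 5' aligned position.  Returns 0 when the offset precedes every
# aligned column.
map_position_through <- function(aln, q) {
  pat <- aln$aligned_aa_a; sub <- aln$aligned_aa_b
  ia <- 0L; ib <- 0L
  best <- 0L
  for (k in seq_along(pat)) {
    ga <- pat[k] == "-"; gb <- sub[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga) next
    # codon ia of a spans nt (3*ia-2)..(3*ia)
    for (off in 1:3) {
      p_a <- 3L * (ia - 1L) + off
      if (p_a > q) return(best)
      if (!gb) best <- 3L * (ib - 1L) + off
    }
  }
  best
}

## ----------------------------------------------------------------- NG86

#' Synonymous and nonsynonymous site fractions of a codon (NG86)
#'
#' Each of the nine single-nucleotide neighbours is classified; changes to
#' stop codons are excluded and the per-position denominator adjusted, so
#' `s + n == 3` exactly for every sense codon.
#'
#' @param codon a 3-mer sense codon
#' @param code NCBI genetic-code id
#' @return c(s = synonymous sites, n = nonsynonymous sites)
#' @export
ng86_sites <- function(codon, code = "4") {
  gc <- genetic_code(code)
  codon <- toupper(codon)
  aa0 <- gc[codon]
  if (is.na(aa0)) stop("not a codon: ", codon, call. = FALSE)
  if (aa0 == "*") stop("stop codon has no NG86 sites: ", codon, call. = FALSE)
  chars <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in DNA_BASES) {
      if (b == chars[pos]) next
      mut <- chars; mut[pos] <- b
      aa1 <- gc[paste(mut, collapse = "")]
      if (aa1 == "*") next
      valid <- valid + 1L
      if (aa1 == aa0) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at 2 or 3 positions are compared over all orderings of
#' the single changes (2 or 6 pathways); pathways passing through a stop
#' codon are dropped from the average, with a fallback to all pathways when
#' none survive.
#'
#' @param codon_a,codon_b sense codons
#' @param code NCBI genetic-code id
#' @return c(sd = synonymous differences, nd = nonsynonymous differences)
#' @export
ng86_differences <- function(codon_a, codon_b, code = "4") {
  gc <- genetic_code(code)
  a <- toupper(codon_a); b <- toupper(codon_b)
  if (is.na(gc[a]) || gc[a] == "*" || is.na(gc[b]) || gc[b] == "*") {
    stop("ng86_differences requires two sense codons, got ", a, ", ", b,
         call. = FALSE)
  }
  ca <- seq_chars(a); cb <- seq_chars(b)
  diff_pos <- which(ca != cb)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))

  perms <- switch(as.character(k),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- ca
    sd <- 0L; nd <- 0L; through_stop <- FALSE
    for (pos in order) {
      nxt <- cur; nxt[pos] <- cb[pos]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      if (aa_nxt == "*" || aa_cur == "*") through_stop <- TRUE
      if (identical(unname(aa_cur), unname(aa_nxt))) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, stop = through_stop)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  if (!any(ok)) {
    message("all mutational pathways between ", a, " and ", b,
            " pass through a stop codon; averaging over all of them")
    ok <- rep(TRUE, length(paths))
  }
  sd <- mean(vapply(paths[ok], `[[`, integer(1), "sd"))
  nd <- mean(vapply(paths[ok], `[[`, integer(1), "nd"))
  c(sd = sd, nd = nd)
}

#' NG86 Ka/Ks from a codon alignment
#'
#' Site counts are averaged over the two sequences; proportions receive the
#' Jukes-Cantor correction `-3/4 log(1 - 4p/3)`.  Undefined corrections
#' (p >= 3/4) and Ks == 0 yield NA, never a clamp.
#'
#' @param aln a `CodonAlignment` from [codon_align()]
#' @param code NCBI genetic-code id
#' @return list with S_sites, N_sites, Sd, Nd, Ka, Ks, ka_raw, ks_raw,
#'   ratio, positive_selection
#' @export
kaks <- function(aln, code = "4") {
  stopifnot(inherits(aln, "CodonAlignment"))
  if (aln$n_codons < 1L) stop("empty codon alignment", call. = FALSE)
  sites_a <- vapply(aln$codons_a, ng86_sites, numeric(2), code = code)
  sites_b <- vapply(aln$codons_b, ng86_sites, numeric(2), code = code)
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- mapply(function(x, y) ng86_differences(x, y, code = code),
                  aln$codons_a, aln$codons_b)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(NA_real_)
    -0.75 * log(arg)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  list(gene = aln$gene, id_a = aln$id_a, id_b = aln$id_b,
       n_codons = aln$n_codons,
       S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
       ks_raw = ps, ka_raw = pn, Ks = Ks, Ka = Ka,
       ratio = ratio,
       positive_selection = !is.na(ratio) && ratio > 1)
}

#' Ka/Ks table over genes and genome pairs
#'
#' @param genomes list of [MitoGenome]
#' @param genes gene symbols (default: the 15 core PCGs present)
#' @param code NCBI genetic-code id
#' @return long data.frame, one row per gene x unordered genome pair
#' @export
kaks_table <- function(genomes, genes = CORE_PCGS, code = "4") {
  ids <- vapply(genomes, `[[`, character(1), "id")
  rows <- list()
  for (g in genes) {
    have <- which(vapply(genomes, function(x) !is.null(find_feature(x, g)),
                         logical(1)))
    if (length(have) < 2L) next
    cds <- lapply(genomes[have], function(x)
      suppressWarnings(extract_cds(x, g, code = code)))
    for (i in seq_along(have)[-length(have)]) {
      for (j in seq.int(i + 1L, length(have))) {
        res <- kaks(codon_align(cds[[i]], cds[[j]], code = code), code = code)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, taxon_a = ids[have[i]], taxon_b = ids[have[j]],
          n_codons = res$n_codons, S_sites = res$S_sites,
          N_sites = res$N_sites, Sd = res$Sd, Nd = res$Nd,
          Ka = res$Ka, Ks = res$Ks, ka_raw = res$ka_raw, ks_raw = res$ks_raw,
          ratio = res$ratio, positive_selection = res$positive_selection,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no gene shared by at least two genomes", call. = FALSE)
  do.call(rbind, rows)
}
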