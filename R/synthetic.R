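# Deterministic synthetic mitogenome generator with a ground-truth
# manifest.  The default spec states the world the package is tested in:
# a circular ~44 kb genome, GC ~0.23, slightly negative AT skew and
# positive GC skew, the 17-gene panel plus placeholder tRNAs, group-I
# introns planted in cox1/cob, and optional duplication/tandem plants.
#
# Randomness is split into named substreams (background, codons, introns,
# repeats, mutations, ...) derived from the master seed, so adding draws
# to one feature never shifts another's.

GENE_LENGTHS <- c(atp6 = 768L, atp8 = 147L, atp9 = 222L, cob = 1164L,
                  cox1 = 1596L, cox2 = 750L, cox3 = 810L, nad1 = 1062L,
                  nad2 = 1677L, nad3 = 414L, nad4 = 1461L, nad4L = 267L,
                  nad5 = 1983L, nad6 = 600L, rps3 = 1350L,
                  rnl = 3768L, rns = 1973L)
TRNA_LENGTH <- 72L

#' Specification for one synthetic mitogenome
#'
#' Defaults emulate the world the package targets: a 44 kb circular
#' fungal mitogenome at GC 0.23 with negative AT skew and positive GC
#' skew, the 17-gene panel, 26 tRNAs, and four group-I introns (three in
#' cox1, one in cob) at fixed reference-CDS offsets.
#'
#' @param id genome label
#' @param length target genome length in nt
#' @param gc target GC fraction
#' @param at_skew,gc_skew target strand skews
#' @param gene_order data.frame(symbol, strand) over the 17-gene panel
#' @param n_trna number of placeholder tRNA genes
#' @param introns data.frame(host, ref_offset, length) of planted introns;
#'   offsets are 1-based nt positions in the host's spliced CDS
#' @param intronic_orfs data.frame(host, intron, length): ORFs embedded in
#'   planted introns
#' @param duplications data.frame(length) of planted duplication pairs
#' @param tandems data.frame(period, copies) of planted tandem arrays
#' @return a `synth_spec` list
#' @export
synth_genome_spec <- function(id = "synth1", length = 44000L, gc = 0.23,
                              at_skew = -0.03, gc_skew = 0.05,
                              gene_order = default_gene_order(),
                              n_trna = 26L,
                              introns = default_intron_table(),
                              intronic_orfs = data.frame(
                                host = "cox1", intron = 1L, length = 300L),
                              duplications = data.frame(length = integer(),
                                                        inverted = logical()),
                              tandems = data.frame(period = integer(),
                                                   copies = integer())) {
  structure(list(id = id, length = as.integer(length), gc = gc,
                 at_skew = at_skew, gc_skew = gc_skew,
                 gene_order = gene_order, n_trna = as.integer(n_trna),
                 introns = introns, intronic_orfs = intronic_orfs,
                 duplications = duplications, tandems = tandems),
            class = "synth_spec")
}

#' Default panel arrangement used by the generator
#' @export
default_gene_order <- function() {
  data.frame(
    symbol = c("cox1", "atp6", "rps3", "nad4L", "nad5", "nad2", "rnl",
               "atp9", "nad6", "cox2", "rns", "cox3", "nad3", "atp8",
               "nad4", "cob", "nad1"),
    strand = c("+", "+", "+", "+", "+", "+", "+",
               "+", "-", "+", "+", "+", "+", "+",
               "+", "+", "+"),
    stringsAsFactors = FALSE)
}

#' Default planted-intron table (three cox1 introns, one cob intron)
#' @export
default_intron_table <- function() {
  data.frame(host = c("cox1", "cox1", "cox1", "cob"),
             ref_offset = c(383L, 717L, 1107L, 393L),
             length = c(1200L, 900L, 800L, 700L),
             stringsAsFactors = FALSE)
}

base_probs <- function(gc, at_skew, gc_skew) {
  p <- c(A = (1 - gc) * (1 + at_skew) / 2,
         C = gc * (1 - gc_skew) / 2,
         G = gc * (1 + gc_skew) / 2,
         T = (1 - gc) * (1 - at_skew) / 2)
  if (any(p < 0)) stop("infeasible composition targets", call. = FALSE)
  p
}

# Sense-codon sampling distribution under independent target base draws
# with stop codons excluded, plus the implied per-base composition of
# coding sequence (used to compensate the background so the whole genome
# meets the target in expectation).
codon_distribution <- function(p, code = "4") {
  gc <- genetic_code(code)
  codons <- names(gc)
  pr <- vapply(codons, function(cd) {
    b <- seq_chars(cd); p[b[1]] * p[b[2]] * p[b[3]]
  }, numeric(1))
  pr[gc == "*"] <- 0
  pr <- pr / sum(pr)
  base_freq <- c(A = 0, C = 0, G = 0, T = 0)
  for (k in seq_along(codons)) {
    for (b in seq_chars(codons[k])) {
      base_freq[b] <- base_freq[b] + pr[k] / 3
    }
  }
  list(pr = pr, codons = codons, base_freq = base_freq)
}

random_bases <- function(n, p) {
  if (n <= 0L) return("")
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_cds <- function(len, cdist) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_cod <- len %/% 3L - 2L  # minus start and stop
  body <- sample(cdist$codons, n_cod, replace = TRUE, prob = cdist$pr)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# ---------------------------------------------------------------- parts

# Draw every sequence part of a genome once; cohort members share these.
build_parts <- function(spec, seed, code = "4") {
  p_target <- base_probs(spec$gc, spec$at_skew, spec$gc_skew)
  cdist <- codon_distribution(p_target, code)

  syms <- spec$gene_order$symbol
  cds_len <- GENE_LENGTHS[syms]
  if (any(is.na(cds_len))) {
    stop("no default length for gene(s): ",
         paste(syms[is.na(cds_len)], collapse = ","), call. = FALSE)
  }
  coding <- !syms %in% c("rnl", "rns")
  L_coding <- sum(cds_len[coding]) +
    sum(spec$intronic_orfs$length)
  L_fixed <- sum(cds_len) + spec$n_trna * TRNA_LENGTH +
    sum(spec$introns$length) +
    2L * sum(spec$duplications$length) +
    sum(spec$tandems$period * spec$tandems$copies)
  L_spacer <- spec$length - L_fixed
  n_slots <- length(syms) + spec$n_trna + 1L
  if (L_spacer < 20L * n_slots) {
    stop("spec error: planted features (", L_fixed,
         " nt) leave too little intergenic room in ", spec$length, " nt",
         call. = FALSE)
  }
  # compensate the background so the genome-wide expectation hits targets
  L_nc <- spec$length - L_coding
  p_bg <- (spec$length * p_target - L_coding * cdist$base_freq) / L_nc
  p_bg <- pmax(p_bg, 1e-4)
  p_bg <- p_bg / sum(p_bg)

  genes <- with_seed(derive_seed(seed, "genes"), {
    out <- list()
    for (i in seq_along(syms)) {
      out[[syms[i]]] <- if (coding[i]) random_cds(cds_len[[i]], cdist)
                        else random_bases(cds_len[[i]], p_bg)
    }
    out
  })
  trnas <- with_seed(derive_seed(seed, "trna"),
    replicate(spec$n_trna, random_bases(TRNA_LENGTH, p_bg)))
  intron_seqs <- with_seed(derive_seed(seed, "introns"), {
    if (!nrow(spec$introns)) list() else
      lapply(seq_len(nrow(spec$introns)), function(k)
        random_bases(spec$introns$length[k], p_bg))
  })
  orf_seqs <- with_seed(derive_seed(seed, "iorfs"), {
    if (!nrow(spec$intronic_orfs)) list() else
      lapply(spec$intronic_orfs$length, random_cds, cdist = cdist)
  })
  dup_seqs <- with_seed(derive_seed(seed, "dups"), {
    if (!nrow(spec$duplications)) list() else
      lapply(spec$duplications$length, random_bases, p = p_bg)
  })
  tandem_seqs <- with_seed(derive_seed(seed, "tandems"), {
    if (!nrow(spec$tandems)) list() else
      lapply(seq_len(nrow(spec$tandems)), function(k) {
        motif <- random_bases(spec$tandems$period[k], p_bg)
        paste(rep(motif, spec$tandems$copies[k]), collapse = "")
      })
  })
  spacer_budget <- L_spacer
  list(spec = spec, p_bg = p_bg, cdist = cdist, genes = genes,
       trnas = trnas, intron_seqs = intron_seqs, orf_seqs = orf_seqs,
       dup_seqs = dup_seqs, tandem_seqs = tandem_seqs,
       spacer_budget = spacer_budget, code = code)
}

# ------------------------------------------------------------- assembly

# Assemble a MitoGenome from parts under a (possibly edited) gene order
# and a set of planted introns (rows of spec$introns to realize).
assemble_genome <- function(parts, id, gene_order = parts$spec$gene_order,
                            intron_rows = seq_len(nrow(parts$spec$introns)),
                            seed = 1L) {
  spec <- parts$spec
  syms <- gene_order$symbol
  strands <- gene_order$strand
  introns <- spec$introns[intron_rows, , drop = FALSE]
  intron_seqs <- parts$intron_seqs[intron_rows]

  n_genes <- length(syms)
  # distribute tRNAs round-robin after panel genes
  trna_after <- sort(rep(seq_len(n_genes), length.out = spec$n_trna))
  slots <- n_genes + spec$n_trna + 1L
  L_intron <- sum(introns$length)
  budget <- parts$spacer_budget +
    (sum(spec$introns$length) - L_intron)  # unused introns return space
  base_sp <- budget %/% slots
  extra <- budget - base_sp * slots
  spacer_len <- rep(base_sp, slots)
  if (extra > 0L) spacer_len[seq_len(extra)] <- spacer_len[seq_len(extra)] + 1L

  spacers <- with_seed(derive_seed(seed, paste0("spacer_", id)),
    lapply(spacer_len, random_bases, p = parts$p_bg))

  pieces <- character(0)
  pos <- 0L
  features <- list()
  intron_feats <- list()
  spacer_ivs <- list()
  add_piece <- function(s) {
    pieces[length(pieces) + 1L] <<- s
    st <- pos + 1L
    pos <<- pos + nchar(s)
    c(st, pos)
  }
  sp_i <- 1L
  add_spacer <- function() {
    iv <- add_piece(spacers[[sp_i]])
    spacer_ivs[[length(spacer_ivs) + 1L]] <<- iv
    sp_i <<- sp_i + 1L
  }
  trna_i <- 1L
  manifest_introns <- list()

  add_spacer()
  for (g in seq_len(n_genes)) {
    sym <- syms[g]; strand <- strands[g]
    seq_g <- parts$genes[[sym]]
    these <- which(introns$host == sym)
    if (length(these) && strand == "-") {
      stop("planted introns on '-'-strand host not supported in specs",
           call. = FALSE)
    }
    if (length(these)) {
      offs <- sort(introns$ref_offset[these])
      ord <- these[order(introns$ref_offset[these])]
      cuts <- c(0L, offs, nchar(seq_g))
      exon_ivs <- matrix(0L, nrow = length(offs) + 1L, ncol = 2L)
      gst <- pos + 1L
      for (e in seq_along(cuts)[-length(cuts)]) {
        ex <- substr(seq_g, cuts[e] + 1L, cuts[e + 1L])
        exon_ivs[e, ] <- add_piece(ex)
        if (e <= length(offs)) {
          k <- ord[e]
          iv <- add_piece(intron_seqs[[k]])
          # embed intronic ORFs assigned to this intron
          io <- spec$intronic_orfs
          hit <- which(io$host == sym & io$intron == e)
          for (h in hit) {
            orf <- parts$orf_seqs[[h]]
            orf_at <- iv[1L] + 30L
            features[[length(features) + 1L]] <- new_gene_feature(
              paste0("orf", nchar(orf) %/% 3L), "intronic_ORF", "+",
              matrix(c(orf_at, orf_at + nchar(orf) - 1L), ncol = 2L),
              "hypothetical intronic protein")
          }
          intron_feats[[length(intron_feats) + 1L]] <-
            new_intron_feature(sym, e, iv[1L], iv[2L], group = "I")
          manifest_introns[[length(manifest_introns) + 1L]] <-
            list(host = sym, index = e, ref_offset = offs[e],
                 start = iv[1L], end = iv[2L],
                 length = iv[2L] - iv[1L] + 1L)
        }
      }
      features[[length(features) + 1L]] <- new_gene_feature(
        sym, "PCG", "+", exon_ivs, paste0(sym, " protein"))
    } else {
      s_out <- if (strand == "-") revcomp(seq_g) else seq_g
      iv <- add_piece(s_out)
      kind <- if (sym %in% c("rnl", "rns")) "rRNA" else "PCG"
      features[[length(features) + 1L]] <- new_gene_feature(
        sym, kind, strand, matrix(iv, ncol = 2L),
        if (kind == "rRNA") paste0(sym, " ribosomal RNA") else paste0(sym, " protein"))
    }
    # tRNAs scheduled after this gene
    while (trna_i <= spec$n_trna && trna_after[trna_i] == g) {
      add_spacer()
      iv <- add_piece(parts$trnas[[trna_i]])
      features[[length(features) + 1L]] <- new_gene_feature(
        paste0("trn", LETTERS[(trna_i - 1L) %% 26L + 1L],
               if (trna_i > 26L) trna_i else ""),
        "tRNA", "+", matrix(iv, ncol = 2L), "tRNA")
      trna_i <- trna_i + 1L
    }
    add_spacer()
  }
  sequence <- paste(pieces, collapse = "")

  # plant duplication pairs and tandem arrays inside the largest spacers
  chars <- NULL
  man_dups <- list(); man_tandems <- list()
  plant_targets <- c(parts$dup_seqs, parts$dup_seqs, parts$tandem_seqs)
  if (length(parts$dup_seqs) || length(parts$tandem_seqs)) {
    chars <- seq_chars(sequence)
    widths <- vapply(spacer_ivs, function(iv) iv[2L] - iv[1L] + 1L, numeric(1))
    avail <- spacer_ivs[order(widths, decreasing = TRUE)]
    slot <- 1L
    place <- function(frag) {
      iv <- avail[[slot]]; slot <<- slot + 1L
      if (nchar(frag) + 10L > iv[2L] - iv[1L] + 1L) {
        stop("spec error: planted repeat longer than available spacer",
             call. = FALSE)
      }
      st <- iv[1L] + 5L
      chars[st:(st + nchar(frag) - 1L)] <<- seq_chars(frag)
      c(st, st + nchar(frag) - 1L)
    }
    for (k in seq_along(parts$dup_seqs)) {
      inv <- isTRUE(spec$duplications$inverted[k])
      iv1 <- place(parts$dup_seqs[[k]])
      iv2 <- place(if (inv) revcomp(parts$dup_seqs[[k]]) else
                     parts$dup_seqs[[k]])
      man_dups[[k]] <- list(length = nchar(parts$dup_seqs[[k]]),
                            inverted = inv, first = iv1, second = iv2)
    }
    for (k in seq_along(parts$tandem_seqs)) {
      iv <- place(parts$tandem_seqs[[k]])
      man_tandems[[k]] <- list(period = spec$tandems$period[k],
                               copies = spec$tandems$copies[k],
                               interval = iv)
    }
    sequence <- paste(chars, collapse = "")
  }

  genome <- MitoGenome(id = id, sequence = sequence, circular = TRUE,
                       features = features, introns = intron_feats,
                       source = "synthetic")
  manifest <- list(id = id, length = nchar(sequence),
                   gc_target = spec$gc, at_skew_target = spec$at_skew,
                   gc_skew_target = spec$gc_skew,
                   order = data.frame(symbol = syms, strand = strands,
                                      stringsAsFactors = FALSE),
                   introns = manifest_introns,
                   duplications = man_dups, tandems = man_tandems,
                   cds = parts$genes)
  list(genome = genome, manifest = manifest)
}

#' Generate one synthetic mitogenome
#'
#' Fully deterministic under `seed`.  The manifest records the planted
#' gene order, intron sites (host, reference offset, genome interval),
#' repeat intervals, composition targets and the unspliced per-gene CDS.
#'
#' @param spec a [synth_genome_spec()]
#' @param seed integer master seed
#' @return list(genome = [MitoGenome], manifest = list)
#' @export
generate_genome <- function(spec = synth_genome_spec(), seed = 1L) {
  parts <- build_parts(spec, seed)
  assemble_genome(parts, id = spec$id, seed = seed)
}

# ------------------------------------------------------------- mutation

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

pick_substitution <- function(base, kappa) {
  alts <- setdiff(DNA_BASES, base)
  w <- ifelse(alts == transition_of[[base]], kappa, 1)
  sample(alts, 1L, prob = w)
}

# Apply syn/nonsyn substitutions to a CDS string; returns the new string
# and realized counts.  Expected counts are rate * site-count (NG86 sites).
mutate_cds <- function(nt, ks, ka, kappa, code = "4") {
  cods <- split_codons(nt)
  gc <- genetic_code(code)
  n_cod <- length(cods)
  body <- 2:(n_cod - 1L)  # keep start and stop codons intact
  sites <- vapply(cods[body], function(cd) {
    if (is.na(gc[cd]) || gc[cd] == "*") c(s = 0, n = 0) else ng86_sites(cd, code)
  }, numeric(2))
  S <- sum(sites["s", ]); N <- sum(sites["n", ])
  n_syn <- stats::rpois(1L, ks * S)
  n_non <- stats::rpois(1L, ka * N)
  apply_changes <- function(target_syn, n_changes) {
    done <- 0L; tries <- 0L
    while (done < n_changes && tries < 50L * n_changes + 200L) {
      tries <- tries + 1L
      ci <- sample(body, 1L)
      cd <- seq_chars(cods[ci])
      pos <- sample(3L, 1L)
      aa0 <- gc[paste(cd, collapse = "")]
      if (is.na(aa0) || aa0 == "*") next
      alt <- pick_substitution(cd[pos], kappa)
      cd2 <- cd; cd2[pos] <- alt
      aa1 <- gc[paste(cd2, collapse = "")]
      if (is.na(aa1) || aa1 == "*") next
      syn <- unname(aa1) == unname(aa0)
      if (syn != target_syn) next
      cods[ci] <<- paste(cd2, collapse = "")
      done <- done + 1L
    }
    done
  }
  r_syn <- apply_changes(TRUE, n_syn)
  r_non <- apply_changes(FALSE, n_non)
  list(nt = paste(cods, collapse = ""), n_syn = r_syn, n_nonsyn = r_non,
       S = S, N = N)
}

cds_to_genome_positions <- function(feature) {
  idx <- integer(0)
  for (e in seq_len(nrow(feature$exons))) {
    span <- feature$exons[e, 1L]:feature$exons[e, 2L]
    if (feature$strand == "-") span <- rev(span)
    idx <- c(idx, span)
  }
  idx
}

#' Mutate a genome under per-gene synonymous/nonsynonymous rates
#'
#' Substitutions are applied codon-aware inside protein-coding genes
#' (hitting the synonymous and nonsynonymous targets in expectation, NG86
#' site counting) and uniformly elsewhere.  No indels.  Realized counts
#' are returned alongside the descendant.
#'
#' @param genome ancestor [MitoGenome]
#' @param rates list with `genes` (data.frame gene, ks, ka), `noncoding`
#'   (per-site substitution probability) and `kappa`
#'   (transition:transversion weight, default 2)
#' @param seed integer seed
#' @param code NCBI genetic-code id
#' @return list(genome = descendant, realized = data.frame)
#' @export
mutate_genome <- function(genome, rates, seed = 1L, code = "4") {
  kappa <- if (is.null(rates$kappa)) 2 else rates$kappa
  noncoding <- if (is.null(rates$noncoding)) 0 else rates$noncoding
  gene_rates <- rates$genes
  if (!is.null(gene_rates) &&
      any(gene_rates$ks > 0.75 | gene_rates$ka > 0.75)) {
    warning("per-site rates above 0.75 imply saturation", call. = FALSE)
  }
  chars <- seq_chars(genome$sequence)
  coding_mask <- logical(length(chars))
  realized <- list()

  with_seed(derive_seed(seed, "mutations"), {
    if (!is.null(gene_rates)) {
      for (k in seq_len(nrow(gene_rates))) {
        gname <- gene_rates$gene[k]
        f <- find_feature(genome, gname)
        if (is.null(f)) next
        cds <- suppressWarnings(extract_cds(genome, gname, code = code))
        res <- mutate_cds(cds$nt, gene_rates$ks[k], gene_rates$ka[k],
                          kappa, code)
        gpos <- cds_to_genome_positions(f)
        old <- seq_chars(cds$nt); new <- seq_chars(res$nt)
        changed <- which(old != new)
        for (i in changed) {
          b <- new[i]
          if (f$strand == "-") b <- chartr("ACGT", "TGCA", b)
          chars[gpos[i]] <- b
        }
        coding_mask[gpos] <- TRUE
        realized[[length(realized) + 1L]] <- data.frame(
          gene = gname, n_syn = res$n_syn, n_nonsyn = res$n_nonsyn,
          S_sites = res$S, N_sites = res$N, stringsAsFactors = FALSE)
      }
    }
    # every CDS position is protected from the uniform noncoding process
    for (f in genome$features) {
      if (f$kind %in% c("PCG", "plasmid_derived", "unknown_ORF",
                        "intronic_ORF")) {
        coding_mask[cds_to_genome_positions(f)] <- TRUE
      }
    }
    if (noncoding > 0) {
      nc <- which(!coding_mask)
      hit <- nc[stats::runif(length(nc)) < noncoding]
      for (i in hit) chars[i] <- pick_substitution(chars[i], kappa)
    }
  })
  descendant <- MitoGenome(id = paste0(genome$id, "_mut"),
                           sequence = paste(chars, collapse = ""),
                           circular = genome$circular,
                           features = genome$features,
                           introns = genome$introns,
                           source = "synthetic")
  list(genome = descendant,
       realized = if (length(realized)) do.call(rbind, realized) else
         data.frame(gene = character(), n_syn = integer(),
                    n_nonsyn = integer(), S_sites = numeric(),
                    N_sites = numeric(), stringsAsFactors = FALSE))
}

# ----------------------------------------------------------- gene order

apply_order_edit <- function(order_df, edit) {
  n <- nrow(order_df)
  switch(edit$type,
    swap_adjacent = {
      i <- edit$pos; j <- if (i == n) 1L else i + 1L
      order_df[c(i, j), ] <- order_df[c(j, i), ]
      order_df
    },
    invert = {
      idx <- edit$pos:(edit$pos + edit$len - 1L)
      stopifnot(max(idx) <= n)
      block <- order_df[rev(idx), , drop = FALSE]
      block$strand <- ifelse(block$strand == "+", "-", "+")
      order_df[idx, ] <- block
      order_df
    },
    move = {
      row <- order_df[edit$from, , drop = FALSE]
      rest <- order_df[-edit$from, , drop = FALSE]
      to <- edit$to
      if (to > nrow(rest) + 1L) to <- nrow(rest) + 1L
      out <- rbind(rest[seq_len(to - 1L), , drop = FALSE], row,
                   rest[seq.int(to, length.out = nrow(rest) - to + 1L), ,
                        drop = FALSE])
      rownames(out) <- NULL
      out
    },
    stop("unknown order edit type: ", edit$type, call. = FALSE))
}

#' Generate a synthetic cohort sharing one ancestor
#'
#' Builds ancestor parts once, then assembles each member under optional
#' per-genome gene-order edits and planted intron sets, and finally
#' applies per-branch substitution rates.  Everything planted is recorded
#' in the manifest.
#'
#' @param n number of genomes
#' @param template a [synth_genome_spec()] shared by the cohort
#' @param seed master seed
#' @param order_edits named list: per genome id, a list of edits, each
#'   `list(type = "swap_adjacent"|"invert"|"move", ...)`
#' @param rates named list: per genome id, a rates list as in
#'   [mutate_genome()]; NULL members stay identical to the ancestor
#' @param pcl_table optional binary matrix (genomes x planted intron rows
#'   of `template$introns`): which introns each genome carries
#' @param ids genome ids (default g1..gn)
#' @return list(genomes, manifest); `manifest$genomes` holds per-genome
#'   ground truth
#' @export
generate_cohort <- function(n, template = synth_genome_spec(), seed = 1L,
                            order_edits = list(), rates = list(),
                            pcl_table = NULL,
                            ids = paste0("g", seq_len(n))) {
  stopifnot(n >= 2L, length(ids) == n)
  parts <- build_parts(template, seed)
  genomes <- vector("list", n); names(genomes) <- ids
  man <- list(seed = seed, template_id = template$id, genomes = list())
  for (i in seq_len(n)) {
    id <- ids[i]
    od <- template$gene_order
    for (e in if (is.null(order_edits[[id]])) list() else order_edits[[id]]) {
      od <- apply_order_edit(od, e)
    }
    intron_rows <- if (is.null(pcl_table)) seq_len(nrow(template$introns))
                   else which(pcl_table[i, ] == 1L)
    asm <- assemble_genome(parts, id = id, gene_order = od,
                           intron_rows = intron_rows,
                           seed = derive_seed(seed, paste0("asm_", id)))
    g <- asm$genome
    realized <- NULL
    if (!is.null(rates[[id]])) {
      mg <- mutate_genome(g, rates[[id]],
                          seed = derive_seed(seed, paste0("mut_", id)))
      g <- mg$genome; g$id <- id
      realized <- mg$realized
    }
    genomes[[i]] <- g
    man$genomes[[id]] <- c(asm$manifest[c("order", "introns", "duplications",
                                          "tandems")],
                           list(rates = rates[[id]], realized = realized))
  }
  man$ancestor_cds <- parts$genes
  list(genomes = genomes, manifest = man)
}

#' Simulate genome sizes and intron counts with a known correlation
#'
#' Statistical stand-in for a species panel in which mitogenome size and
#' intron number are correlated: a bivariate normal draw at the given
#' generating correlation, with sizes and counts rounded to integers and
#' counts floored at zero.  Defaults echo a basidiomycete panel: sizes
#' around 35 kb (sd 9 kb), 14 introns on average (sd 5, so the
#' zero-floor truncates a negligible mass).
#'
#' @param n number of species
#' @param r generating Pearson correlation
#' @param mean_size,sd_size genome size distribution in nt
#' @param mean_introns,sd_introns intron count distribution
#' @param seed integer seed
#' @return data.frame(size, n_intron)
#' @export
simulate_size_intron_cohort <- function(n = 79L, r = 0.8,
                                        mean_size = 35000, sd_size = 9000,
                                        mean_introns = 14, sd_introns = 5,
                                        seed = 1L) {
  with_seed(derive_seed(seed, "size_intron"), {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    data.frame(size = round(mean_size + sd_size * z1),
               n_intron = pmax(0, round(mean_introns + sd_introns * z2)))
  })
}

#' Draw a random intron position-class table
#'
#' Ground truth for Pcl parameter-recovery tests: `n_pcls` reference
#' positions inside the cox1 CDS and a presence matrix in which class j is
#' carried by `prevalences[j]` species chosen at random.  For panels of 20
#' or more species the default prevalences include the just-below /
#' just-above one-fifth boundary pair (15 and 16 species when n is 79).
#'
#' @param n_species number of species
#' @param n_pcls number of position classes
#' @param seed integer seed
#' @param cds_length host CDS length the positions must fit in
#' @param prevalences per-class species counts (default: includes 15 and
#'   16 when n_species allows, the rest uniform on 1..n/2)
#' @return list(positions, prevalences, presence) with a binary
#'   species x class matrix
#' @export
random_pcl_table <- function(n_species = 79L, n_pcls = 12L, seed = 17L,
                             cds_length = GENE_LENGTHS[["cox1"]] - 60L,
                             prevalences = NULL) {
  with_seed(derive_seed(seed, "pcl_table"), {
    # codon-boundary-free positions away from the termini
    positions <- sort(sample(seq(30L, cds_length - 30L), n_pcls))
    if (is.null(prevalences)) {
      prevalences <- sample(seq_len(max(2L, n_species %/% 2L)), n_pcls,
                            replace = TRUE)
      if (n_species >= 20L && n_pcls >= 2L) {
        prevalences[1:2] <- c(
          max(1L, round(n_species * 0.19)),  # just below 1/5
          floor(n_species / 5) + 1L)         # just above 1/5
      }
    }
    prevalences <- as.integer(prevalences)
    presence <- matrix(0L, n_species, n_pcls,
                       dimnames = list(paste0("g", seq_len(n_species)),
                                       paste0("P", positions)))
    for (j in seq_len(n_pcls)) {
      presence[sample(n_species, prevalences[j]), j] <- 1L
    }
    list(positions = positions, prevalences = prevalences,
         presence = presence)
  })
}
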