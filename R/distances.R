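# Pairwise Kimura 2-parameter distances and a neighbor-joining utility.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns in which either sequence carries a gap ('-') or an N are removed
#' first (pairwise deletion).  With P the transition and Q the transversion
#' fraction over retained columns, the distance is
#' `-1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`.  A non-positive log argument
#' (saturation) yields NA rather than a sentinel.
#'
#' @param a,b aligned DNA strings of equal length (gaps as '-')
#' @return substitutions per site, or NA on saturation / zero retained
#'   columns
#' @export
pairwise_k2p <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences differ in length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  x <- seq_chars(toupper(a)); y <- seq_chars(toupper(b))
  keep <- x %in% DNA_BASES & y %in% DNA_BASES
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) {
    warning("no retained columns after pairwise deletion", call. = FALSE)
    return(NA_real_)
  }
  diff <- x != y
  ts <- diff & ((x %in% PURINES & y %in% PURINES) |
                (x %in% PYRIMIDINES & y %in% PYRIMIDINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

# Proportion of differing retained columns (used in tests and reports).
p_distance <- function(a, b) {
  x <- seq_chars(toupper(a)); y <- seq_chars(toupper(b))
  keep <- x %in% DNA_BASES & y %in% DNA_BASES
  if (!sum(keep)) return(NA_real_)
  mean(x[keep] != y[keep])
}

#' Per-gene K2P distance matrix across genomes
#'
#' Each genome pair sharing the gene is codon-aligned (protein-guided; see
#' [codon_align()]) and K2P is computed on the aligned nucleotides.  Pairs
#' where the gene is missing are NA, not 0.
#'
#' @param genomes list of [MitoGenome]
#' @param gene gene symbol, or "concatenated" to splice all shared core
#'   genes in alphabetical order
#' @param code NCBI genetic-code id
#' @return a `DistanceMatrix`: list(taxa, values, gene) with a symmetric
#'   matrix, zero diagonal
#' @export
gene_k2p_matrix <- function(genomes, gene, code = "4") {
  ids <- vapply(genomes, `[[`, character(1), "id")
  n <- length(genomes)
  genes <- if (identical(gene, "concatenated")) {
    shared <- Reduce(intersect, lapply(genomes, function(g)
      vapply(g$features, `[[`, character(1), "name")))
    sort(intersect(shared, CORE_PCGS))
  } else gene
  have <- vapply(genomes, function(g)
    all(vapply(genes, function(s) !is.null(find_feature(g, s)), logical(1))),
    logical(1))
  if (sum(have) < 2L) {
    stop("gene ", paste(genes, collapse = "+"),
         " present in fewer than two genomes", call. = FALSE)
  }
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  cds <- vector("list", n)
  for (i in which(have)) {
    cds[[i]] <- lapply(genes, function(s)
      suppressWarnings(extract_cds(genomes[[i]], s, code = code)))
  }
  idx <- which(have)
  for (ii in seq_along(idx)[-length(idx)]) {
    for (jj in seq.int(ii + 1L, length(idx))) {
      i <- idx[ii]; j <- idx[jj]
      nts <- vapply(seq_along(genes), function(k) {
        aln <- codon_align(cds[[i]][[k]], cds[[j]][[k]], code = code)
        c(paste(aln$codons_a, collapse = ""), paste(aln$codons_b, collapse = ""))
      }, character(2))
      d <- pairwise_k2p(paste(nts[1L, ], collapse = ""),
                        paste(nts[2L, ], collapse = ""))
      m[i, j] <- m[j, i] <- d
    }
  }
  structure(list(taxa = ids, values = m,
                 gene = if (length(genes) > 1L) "concatenated" else genes),
            class = "DistanceMatrix")
}

#' Long-format K2P distance table over several genes
#'
#' @param genomes list of [MitoGenome]
#' @param genes gene symbols
#' @param code NCBI genetic-code id
#' @return data.frame (gene, taxon_a, taxon_b, k2p)
#' @export
k2p_table <- function(genomes, genes = CORE_PCGS, code = "4") {
  rows <- list()
  for (g in genes) {
    dm <- tryCatch(gene_k2p_matrix(genomes, g, code = code),
                   error = function(e) NULL)
    if (is.null(dm)) next
    n <- length(dm$taxa)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, taxon_a = dm$taxa[i], taxon_b = dm$taxa[j],
        k2p = dm$values[i, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with deterministic tie-breaking (the
#' pair with the lowest taxon indices wins).  Negative branch lengths are
#' clamped to 0 with the deficit moved to the sister branch.
#'
#' @param dm a `DistanceMatrix` (no missing entries) or a plain symmetric
#'   matrix with dimnames
#' @return a Newick string (unrooted; trifurcating root)
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "DistanceMatrix")) dm$values else dm
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(is.na(m))) {
    stop("distance matrix contains missing entries; impute or drop taxa first",
         call. = FALSE)
  }
  labels <- rownames(m)
  node <- as.list(labels)  # newick fragment per active node

  while (length(labels) > 3L) {
    n <- nrow(m)
    r <- rowSums(m)
    q <- (n - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    di <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    dj <- m[i, j] - di
    # clamp negatives, moving the deficit to the sister branch
    if (di < 0) { dj <- dj + di; di <- 0 }
    if (dj < 0) { di <- di + dj; dj <- 0 }
    if (di < 0) di <- 0  # both negative (degenerate all-zero case)
    if (dj < 0) dj <- 0
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", node[[i]], di, node[[j]], dj)
    d_new <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    m2 <- m[keep, keep, drop = FALSE]
    m2 <- rbind(cbind(m2, d_new[keep]), c(d_new[keep], 0))
    lab_new <- paste0("(", labels[i], ",", labels[j], ")")
    labels <- c(labels[keep], lab_new)
    rownames(m2) <- colnames(m2) <- labels
    node <- c(node[keep], new_frag)
    m <- m2
  }

  # resolve the final three nodes around an internal trifurcation
  d12 <- m[1, 2]; d13 <- m[1, 3]; d23 <- m[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  b <- pmax(c(b1, b2, b3), 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          node[[1L]], b[1L], node[[2L]], b[2L], node[[3L]], b[3L])
}
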