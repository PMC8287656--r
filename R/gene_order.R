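# Circular gene-order extraction, canonicalization and rearrangement
# statistics over the 17-gene panel (15 core PCGs + rns + rnl).

#' The default 17-gene arrangement panel: 15 core PCGs plus rns and rnl
#' @export
DEFAULT_PANEL <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                   "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                   "rps3", "rns", "rnl")

new_gene_order <- function(genome_id, symbols, strands, panel = DEFAULT_PANEL) {
  stopifnot(length(symbols) == length(strands), all(strands %in% c("+", "-")))
  if (anyDuplicated(symbols)) {
    stop("duplicated panel gene in order: ",
         symbols[duplicated(symbols)][1L], call. = FALSE)
  }
  structure(list(genome_id = genome_id, panel = panel,
                 symbols = symbols, strands = strands,
                 missing = setdiff(panel, symbols)),
            class = "GeneOrder")
}

#' @export
print.GeneOrder <- function(x, ...) {
  cat(sprintf("GeneOrder %s: %s\n", x$genome_id,
              paste0(x$symbols, x$strands, collapse = " ")))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ","), "\n")
  invisible(x)
}

#' Extract the circular gene order of a genome
#'
#' Panel genes are taken in order of start coordinate; all other features
#' are ignored.  A panel symbol annotated more than once is an annotation
#' error.
#'
#' @param genome a [MitoGenome]
#' @param panel gene symbols to include (default [DEFAULT_PANEL])
#' @return a canonicalized `GeneOrder`
#' @export
extract_order <- function(genome, panel = DEFAULT_PANEL) {
  keep <- vapply(genome$features, function(f) f$name %in% panel, logical(1))
  fs <- genome$features[keep]
  syms <- vapply(fs, `[[`, character(1), "name")
  if (anyDuplicated(syms)) {
    stop("annotation error in ", genome$id, ": duplicated panel gene ",
         syms[duplicated(syms)][1L], call. = FALSE)
  }
  ord <- order(vapply(fs, feature_start, integer(1)))
  canonicalize_circular(
    new_gene_order(genome$id, syms[ord],
                   vapply(fs[ord], `[[`, character(1), "strand"), panel))
}

#' Canonicalize a circular gene order
#'
#' Rotates so that cox1 comes first; if cox1 lies on the minus strand the
#' order is reflected and all strands flipped so cox1 reads '+'.  When cox1
#' is absent the lexicographically smallest present symbol anchors instead.
#' Idempotent, and invariant under rotation and reflection of the input.
#'
#' @param order a `GeneOrder`
#' @return the canonical `GeneOrder`
#' @export
canonicalize_circular <- function(order) {
  stopifnot(inherits(order, "GeneOrder"))
  n <- length(order$symbols)
  if (n == 0L) return(order)
  anchor <- if ("cox1" %in% order$symbols) "cox1" else sort(order$symbols)[1L]
  k <- match(anchor, order$symbols)
  idx <- c(seq.int(k, n), if (k > 1L) seq.int(1L, k - 1L))
  syms <- order$symbols[idx]; strs <- order$strands[idx]
  if (strs[1L] == "-") {
    # reflect: anchor stays first, the rest reverses; all strands flip
    if (n > 1L) {
      syms <- c(syms[1L], rev(syms[-1L]))
      strs <- c(strs[1L], rev(strs[-1L]))
    }
    strs <- ifelse(strs == "+", "-", "+")
  }
  new_gene_order(order$genome_id, syms, strs, order$panel)
}

# Orientation-aware circular adjacency set.  Each consecutive pair (u, v)
# is encoded canonically so that reading the chromosome in either direction
# yields the same code: min("u_su>v_sv", "v_-sv>u_-su").
adjacency_set <- function(order) {
  n <- length(order$symbols)
  if (n < 2L) return(character())
  flip <- function(s) ifelse(s == "+", "-", "+")
  codes <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fwd <- paste0(order$symbols[i], order$strands[i], ">",
                  order$symbols[j], order$strands[j])
    rev_ <- paste0(order$symbols[j], flip(order$strands[j]), ">",
                   order$symbols[i], flip(order$strands[i]))
    codes[i] <- min(fwd, rev_)
  }
  codes
}

restrict_order <- function(order, genes) {
  keep <- order$symbols %in% genes
  new_gene_order(order$genome_id, order$symbols[keep], order$strands[keep],
                 order$panel)
}

common_restriction <- function(a, b) {
  shared <- intersect(a$symbols, b$symbols)
  if (!length(shared)) {
    stop("gene orders share no genes: ", a$genome_id, " vs ", b$genome_id,
         call. = FALSE)
  }
  if (length(shared) < length(a$symbols) || length(shared) < length(b$symbols)) {
    message("comparing ", a$genome_id, " and ", b$genome_id,
            " on the ", length(shared), "-gene intersection")
  }
  list(a = canonicalize_circular(restrict_order(a, shared)),
       b = canonicalize_circular(restrict_order(b, shared)))
}

#' Are two circular gene orders identical?
#'
#' Orders are compared after canonicalization (so rotation and reflection
#' do not matter) on the intersection of their present genes.
#'
#' @param a,b `GeneOrder` objects over the same panel
#' @return TRUE/FALSE
#' @export
orders_identical <- function(a, b) {
  r <- common_restriction(a, b)
  identical(r$a$symbols, r$b$symbols) && identical(r$a$strands, r$b$strands)
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of orientation-aware circular adjacencies present in `a` but
#' not in `b`, after restriction to the shared gene set.  Zero iff the
#' orders are identical.
#'
#' @param a,b `GeneOrder` objects
#' @return non-negative integer
#' @export
breakpoint_distance <- function(a, b) {
  r <- common_restriction(a, b)
  sum(!adjacency_set(r$a) %in% adjacency_set(r$b))
}

#' Genes whose neighborhood differs from an ancestral order
#'
#' A gene is rearranged iff its unordered pair of circular neighbours
#' (symbols with strands, in the canonical orientation of each order)
#' differs from the ancestor's.  An inverted block therefore flags its
#' interior (neighbour strands flip) as well as its flanks.
#'
#' @param orders list of `GeneOrder`
#' @param ancestor the reference `GeneOrder`
#' @return named list: per genome, the character vector of rearranged genes
#' @export
classify_rearranged <- function(orders, ancestor) {
  anc <- canonicalize_circular(ancestor)
  neighbor_map <- function(o) {
    n <- length(o$symbols)
    nb <- vector("list", n); names(nb) <- o$symbols
    for (i in seq_len(n)) {
      l <- if (i == 1L) n else i - 1L
      r <- if (i == n) 1L else i + 1L
      nb[[i]] <- sort(c(paste0(o$symbols[l], o$strands[l]),
                        paste0(o$symbols[r], o$strands[r])))
    }
    nb
  }
  out <- lapply(orders, function(o) {
    oc <- canonicalize_circular(o)
    shared <- intersect(oc$symbols, anc$symbols)
    nb_o <- neighbor_map(canonicalize_circular(restrict_order(oc, shared)))
    nb_a <- neighbor_map(canonicalize_circular(restrict_order(anc, shared)))
    moved <- vapply(shared, function(g)
      !identical(nb_o[[g]], nb_a[[g]]), logical(1))
    shared[moved]
  })
  names(out) <- vapply(orders, `[[`, character(1), "genome_id")
  out
}

#' Plurality (majority) gene arrangement of a cohort
#'
#' @param orders list of at least 3 `GeneOrder`
#' @return the most frequent canonical `GeneOrder`; ties and all-unique
#'   cohorts raise errors
#' @export
majority_ancestor <- function(orders) {
  if (length(orders) < 3L) stop("need at least 3 gene orders", call. = FALSE)
  canon <- lapply(orders, canonicalize_circular)
  keys <- vapply(canon, function(o)
    paste0(o$symbols, o$strands, collapse = "|"), character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  if (length(tab) == length(keys) && tab[1L] == 1L) {
    stop("no majority arrangement: all ", length(keys),
         " arrangements are unique", call. = FALSE)
  }
  top <- tab[tab == tab[1L]]
  if (length(top) > 1L) {
    stop("tied plurality arrangements: ",
         paste(names(top), collapse = "  vs  "), call. = FALSE)
  }
  winner <- canon[[match(names(tab)[1L], keys)]]
  winner$genome_id <- "majority_ancestor"
  winner
}

#' Gene-order table for reporting
#'
#' @param orders list of `GeneOrder`
#' @return data.frame (genome_id, position, gene, strand)
#' @export
gene_order_table <- function(orders) {
  rows <- lapply(orders, function(o) {
    data.frame(genome_id = o$genome_id, position = seq_along(o$symbols),
               gene = o$symbols, strand = o$strands, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
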