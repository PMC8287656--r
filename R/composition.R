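# Base composition, GC content and strand-asymmetry skews.
#
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C).  N bases are
# excluded from every denominator; a skew with zero denominator is NA.

#' Base composition and strand skews of a DNA sequence
#'
#' @param seq DNA string over ACGTN (or a [MitoGenome])
#' @return list with counts `A`,`C`,`G`,`T`, `n_excluded` (N count),
#'   `gc_content` (fraction of the four canonical bases), `at_skew`,
#'   `gc_skew`
#' @export
base_composition <- function(seq) {
  if (inherits(seq, "MitoGenome")) seq <- seq$sequence
  seq <- validate_dna(seq)
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  a <- counts[["A"]]; c_ <- counts[["C"]]; g <- counts[["G"]]; t <- counts[["T"]]
  denom <- a + c_ + g + t
  list(
    A = a, C = c_, G = g, T = t,
    n_excluded = nchar(seq) - denom,
    gc_content = if (denom > 0) (g + c_) / denom else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_
  )
}

#' Sliding-window skew profile
#'
#' Windows start every `step` nt; on a circular sequence the final windows
#' wrap around the origin, so every base is covered by the same number of
#' windows.  Windows whose denominator is zero emit NA.
#'
#' @param seq DNA string or [MitoGenome]
#' @param window window size in nt
#' @param step step size in nt
#' @param circular wrap windows around the origin (defaults to the
#'   genome's topology when a MitoGenome is given, else FALSE)
#' @return data.frame with midpoint, at_skew, gc_skew, gc_content
#' @export
skew_profile <- function(seq, window, step = window, circular = NULL) {
  if (inherits(seq, "MitoGenome")) {
    if (is.null(circular)) circular <- seq$circular
    seq <- seq$sequence
  }
  if (is.null(circular)) circular <- FALSE
  seq <- validate_dna(seq)
  if (window < 1L || step < 1L) stop("window and step must be >= 1", call. = FALSE)
  n <- nchar(seq)
  if (!circular && window > n) {
    stop("window (", window, ") exceeds linear sequence length (", n, ")",
         call. = FALSE)
  }
  starts <- seq.int(1L, n, by = step)
  if (!circular) starts <- starts[starts + window - 1L <= n]
  rows <- lapply(starts, function(s) {
    e <- s + window - 1L
    w <- if (e <= n) substr(seq, s, e)
         else paste0(substr(seq, s, n), substr(seq, 1L, e - n))
    bc <- base_composition(w)
    data.frame(start = s, midpoint = s + (window - 1L) / 2,
               at_skew = bc$at_skew, gc_skew = bc$gc_skew,
               gc_content = bc$gc_content)
  })
  do.call(rbind, rows)
}

#' Composition report for a set of genomes
#'
#' GC content is reported as a percentage with full internal precision;
#' round only for display.
#'
#' @param genomes list of [MitoGenome]
#' @return data.frame (genome_id, length, A, T, G, C, GC_pct, AT_skew,
#'   GC_skew)
#' @export
composition_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    bc <- base_composition(g)
    data.frame(genome_id = g$id, length = genome_length(g),
               A = bc$A, T = bc$T, G = bc$G, C = bc$C,
               GC_pct = 100 * bc$gc_content,
               AT_skew = bc$at_skew, GC_skew = bc$gc_skew,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
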