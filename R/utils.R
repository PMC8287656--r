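# Internal sequence and RNG helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Accepts the alphabet ACGTN (case-insensitive); N is self-complementary.
#'
#' @param seq a single DNA string
#' @return the reverse-complemented string, uppercase
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Vector-of-characters variant used in hot loops.
revcomp_chars <- function(chars) {
  rev(chartr("ACGTN", "TGCAN", chars))
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(seq) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- gsub("[ACGTN]", "", toupper(seq))
  if (nchar(bad) > 0L) {
    stop(
      what, " contains characters outside ACGTN: ",
      paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(toupper(seq))
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All generator randomness goes through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named purpose so that adding draws to
# one substream never shifts another's.  Kept below 2^31.
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 48271 + h * 1103) %% 2147483587) + 1L
}

# Translation-table cache: Biostrings genetic codes keyed by NCBI id string.
genetic_code <- function(code = "4") {
  Biostrings::getGeneticCode(as.character(code))
}

# Translate a spliced CDS string.  Returns the amino-acid string; a single
# terminal stop is dropped.  Internal stops are reported via warning unless
# quiet = TRUE (they translate to '*').
translate_cds <- function(nt, code = "4", quiet = FALSE) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code(code)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (!quiet && any(aa == "*")) {
    warning("internal stop codon(s) at codon ",
            paste(which(aa == "*"), collapse = ","), call. = FALSE)
  }
  paste(aa, collapse = "")
}

split_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

is_stop_codon <- function(codon, code = "4") {
  gc <- genetic_code(code)
  !is.na(gc[codon]) && unname(gc[codon]) == "*"
}

# Format a numeric for TSV reports: 6 significant digits, NA -> "NA".
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
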