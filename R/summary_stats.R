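# Cohort-level comparative table and the size-vs-intron-number correlation.

# Region partition of one genome.  Priority when intervals overlap:
# intron > coding > RNA > intergenic; every base is counted exactly once.
# Intronic-ORF bases therefore count as intronic; pct_coding_incl_iorf
# reports the alternative convention where they count as coding.
region_partition <- function(genome) {
  len <- genome_length(genome)
  cls <- integer(len)  # 0 intergenic, 1 RNA, 2 coding, 3 intron
  paint <- function(ivs, value) {
    for (k in seq_len(nrow(ivs))) {
      idx <- ivs[k, 1L]:ivs[k, 2L]
      cls[idx] <<- pmax(cls[idx], value)
    }
  }
  for (f in genome$features) {
    v <- switch(f$kind, tRNA = 1L, rRNA = 1L,
                PCG = 2L, plasmid_derived = 2L, unknown_ORF = 2L,
                intronic_ORF = 0L, 0L)
    if (v > 0L) paint(f$exons[, , drop = FALSE], v)
  }
  if (length(genome$introns)) {
    iv <- cbind(vapply(genome$introns, `[[`, integer(1), "start"),
                vapply(genome$introns, `[[`, integer(1), "end"))
    paint(iv, 3L)
  }
  iorf <- 0L
  for (f in genome$features) {
    if (f$kind == "intronic_ORF") iorf <- iorf + feature_span(f)
  }
  c(intergenic = sum(cls == 0L), rna = sum(cls == 1L),
    coding = sum(cls == 2L), intron = sum(cls == 3L), intronic_orf = iorf)
}

#' Cohort comparative table
#'
#' One row per genome: size, composition, skews, feature counts and the
#' percentage of the genome in each region class.  The four region classes
#' partition the genome (intron > coding > RNA > intergenic priority), so
#' their percentages sum to 100.
#'
#' @param genomes list of [MitoGenome]
#' @return data.frame keyed by genome_id
#' @export
comparative_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    s <- summarize_annotation(g)
    bc <- base_composition(g)
    reg <- region_partition(g)
    len <- s$length
    data.frame(
      genome_id = s$genome_id, length = len,
      GC_pct = 100 * bc$gc_content, AT_skew = bc$at_skew, GC_skew = bc$gc_skew,
      n_pcg = s$n_pcg, n_pcg_all = s$n_pcg_all, n_trna = s$n_trna,
      n_rrna = s$n_rrna, n_intron = s$n_intron,
      n_intronic_orf = s$n_intronic_orf,
      pct_coding = 100 * reg[["coding"]] / len,
      pct_rna = 100 * reg[["rna"]] / len,
      pct_intron = 100 * reg[["intron"]] / len,
      pct_intergenic = 100 * reg[["intergenic"]] / len,
      pct_coding_incl_iorf = 100 * (reg[["coding"]] + reg[["intronic_orf"]]) / len,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between mitogenome size and intron number
#'
#' Pearson product-moment r with a two-sided t-test p-value, and Spearman
#' rank rho (average ranks for ties) with the t approximation.  Exact
#' closed forms, no resampling.
#'
#' @param sizes genome sizes in nt
#' @param intron_counts intron counts, same length
#' @return list(pearson_r, pearson_p, spearman_rho, spearman_p, n)
#' @export
correlate_size_intron <- function(sizes, intron_counts) {
  if (length(sizes) != length(intron_counts)) {
    stop("sizes and intron_counts differ in length", call. = FALSE)
  }
  n <- length(sizes)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(sizes) == 0 || stats::sd(intron_counts) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_, n = n))
  }
  t_pval <- function(r) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  r <- stats::cor(sizes, intron_counts)
  rho <- stats::cor(rank(sizes), rank(intron_counts))
  list(pearson_r = r, pearson_p = t_pval(r),
       spearman_rho = rho,
       spearman_p = if (abs(rho) >= 1) 0 else t_pval(rho),
       n = n)
}
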