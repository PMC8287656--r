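# Shared fixtures, built in code.

# A tiny hand-built genome: two PCGs (one on '-', one with two exons),
# one rRNA, one tRNA.  Coordinates chosen so everything is easy to check
# by eye.
tiny_genome <- function() {
  set.seed(42)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c(.38, .12, .12, .38)),
                          collapse = "")
  cds1 <- paste0("ATG", "GTTACCGAT", "TAA")               # 15 nt, '+'
  cds2 <- paste0("ATG", "TTTGGTCATACA", "TAA")            # 18 nt, '-'
  # split cds1 into exons of 6 + 9 nt with a 20 nt intron between
  ex1a <- substr(cds1, 1, 6); ex1b <- substr(cds1, 7, 15)
  intron <- bg(20)
  s <- paste0(bg(10), ex1a, intron, ex1b,                 # gene1: 11..16, 37..45
              bg(8), revcomp(cds2),                       # gene2: 54..71 '-'
              bg(5), bg(30),                              # rRNA: 77..106
              bg(4), bg(12),                              # tRNA: 111..122
              bg(10))
  f1 <- mitocomp:::new_gene_feature("cox1", "PCG", "+",
                                    rbind(c(11L, 16L), c(37L, 45L)), "cox1")
  f2 <- mitocomp:::new_gene_feature("nad3", "PCG", "-",
                                    matrix(c(54L, 71L), ncol = 2), "nad3")
  f3 <- mitocomp:::new_gene_feature("rns", "rRNA", "+",
                                    matrix(c(77L, 106L), ncol = 2), "rns")
  f4 <- mitocomp:::new_gene_feature("trnM", "tRNA", "+",
                                    matrix(c(111L, 122L), ncol = 2), "tRNA-Met")
  it <- mitocomp:::new_intron_feature("cox1", 1L, 17L, 36L, group = "I")
  list(genome = MitoGenome("tiny", s, TRUE, list(f1, f2, f3, f4), list(it)),
       cds1 = cds1, cds2 = cds2)
}

# Random sense-codon CDS under table 4 (start + body + stop).
random_cds_nt <- function(n_codons) {
  gc <- Biostrings::getGeneticCode("4")
  sense <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

# A small cached generator genome shared by several test files.
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(synth_genome_spec(), seed = 7)
    cache
  }
})

make_order <- function(symbols, strands = rep("+", length(symbols)),
                       id = "o", panel = symbols) {
  mitocomp:::new_gene_order(id, symbols, strands, panel)
}
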