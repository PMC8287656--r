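# GenBank/FASTA parsing, CDS extraction, annotation summaries.

gbk_record <- function(loc_lines, length = 400L, seq = NULL) {
  if (is.null(seq)) {
    set.seed(1)
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
  }
  n <- nchar(seq)
  origin <- vapply(seq(1L, n, 60L), function(p) {
    ends <- pmin(p + seq(0L, 50L, 10L) + 9L, n)
    starts <- p + seq(0L, 50L, 10L)
    keep <- starts <= n
    sprintf("%9d %s", p,
            tolower(paste(substring(seq, starts[keep], ends[keep]),
                          collapse = " ")))
  }, character(1))
  c(sprintf("LOCUS       test%20d bp    DNA     circular   UNA 01-JAN-2000", n),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    loc_lines, "ORIGIN", origin, "//")
}

test_that("minimal single-CDS record parses to one feature", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk_record(c("     CDS             1..300",
                          "                     /gene=\"cox1\"")), path)
  g <- read_genbank(path)
  expect_s3_class(g, "MitoGenome")
  expect_true(g$circular)
  expect_length(g$features, 1L)
  expect_identical(g$features[[1]]$name, "cox1")
  expect_identical(g$features[[1]]$exons, matrix(c(1L, 300L), ncol = 2,
                   dimnames = list(NULL, c("start", "end"))))
})

test_that("join() CDS splices to a 200 nt CDS with exon boundary 100", {
  # CDS built so that it translates cleanly under table 4
  set.seed(3)
  cds <- random_cds_nt(64L)  # 198 nt; use first 200 of a padded seq below
  exon1 <- substr(cds, 1, 100); exon2 <- substr(cds, 101, 198)
  seq <- paste0(exon1, paste(rep("T", 100), collapse = ""), exon2,
                paste(rep("A", 50), collapse = ""))
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk_record(c("     CDS             join(1..100,201..298)",
                          "                     /gene=\"cox2\""),
                        seq = seq), path)
  g <- read_genbank(path)
  cs <- extract_cds(g, "cox2")
  expect_identical(nchar(cs$nt), 198L)
  expect_identical(cs$exon_boundaries, 100L)
  expect_identical(cs$nt, cds)
  # the gap between the exons is inferred as an intron
  expect_length(g$introns, 1L)
  expect_identical(g$introns[[1]]$host_gene, "cox2")
  expect_identical(c(g$introns[[1]]$start, g$introns[[1]]$end), c(101L, 200L))
})

test_that("complement(join()) yields reverse-complemented spliced CDS", {
  set.seed(4)
  cds <- random_cds_nt(40L)  # 126 nt
  exon1 <- substr(cds, 1, 60); exon2 <- substr(cds, 61, 126)
  # on the genome, coding-order exon1 sits 3' because the gene is on '-'
  seq <- paste0(paste(rep("G", 20), collapse = ""), revcomp(exon2),
                paste(rep("T", 30), collapse = ""), revcomp(exon1),
                paste(rep("A", 20), collapse = ""))
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk_record(c("     CDS             complement(join(21..86,117..176))",
                          "                     /gene=\"nad5\""), seq = seq), path)
  g <- read_genbank(path)
  cs <- extract_cds(g, "nad5")
  expect_identical(cs$nt, cds)
})

test_that("garbage input and out-of-bounds features raise format errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("this is", "not genbank"), path)
  expect_error(read_genbank(path), "LOCUS")
  path2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk_record(c("     CDS             1..9999",
                          "                     /gene=\"cox1\"")), path2)
  expect_error(read_genbank(path2), "coordinate")
})

test_that("GenBank round trip preserves every feature and intron", {
  res <- synth_fixture()
  g <- res$genome
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$circular, g$circular)
  expect_identical(length(g2$features), length(g$features))
  key <- function(x) paste(vapply(x$features, function(f)
    paste(f$name, f$kind, f$strand,
          paste(t(f$exons), collapse = ","), sep = "|"), character(1)),
    collapse = ";")
  expect_identical(key(g2), key(g))
  expect_identical(length(g2$introns), length(g$introns))
  expect_identical(
    vapply(g2$introns, function(i) c(i$start, i$end), integer(2)),
    vapply(g$introns, function(i) c(i$start, i$end), integer(2)))
  # extracted CDS are byte-identical after the round trip
  for (gene in c("cox1", "nad6", "rps3")) {
    expect_identical(extract_cds(g2, gene)$nt, extract_cds(g, gene)$nt)
  }
})

test_that("read_fasta normalizes case and maps U to T", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgu", ">y", "TTGC"), path)
  fa <- read_fasta(path)
  expect_identical(fa, list(x = "ACGT", y = "TTGC"))
  expect_error(read_fasta(withr::local_tempfile(fileext = ".fa")), "no such")
})

test_that("FASTA write/read round trip is the identity", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(1:4, 1)
    seqs <- stats::setNames(
      as.list(vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), sample(10:200, 1),
                     replace = TRUE), collapse = ""), character(1))),
      paste0("rec", seq_len(n)))
    path <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seqs, path)
    expect_identical(read_fasta(path), seqs)
  }
})

test_that("extract_cds handles strands and reports exon structure", {
  fx <- tiny_genome()
  cs1 <- extract_cds(fx$genome, "cox1")
  expect_identical(cs1$nt, fx$cds1)
  expect_identical(cs1$exon_boundaries, 6L)
  expect_identical(cs1$aa, "MVTD")
  cs2 <- extract_cds(fx$genome, "nad3")
  expect_identical(cs2$nt, fx$cds2)  # reverse complement applied
  expect_identical(nchar(cs2$nt), sum(cs2$exon_boundaries, nchar(cs2$nt)))
  expect_error(extract_cds(fx$genome, "nope"), "not found")
  expect_error(extract_cds(fx$genome, "rns"), "not protein-coding")
})

test_that("summarize_annotation partitions counts by kind", {
  fx <- tiny_genome()
  s <- summarize_annotation(fx$genome)
  expect_identical(s$n_pcg, 2L)
  expect_identical(s$n_trna, 1L)
  expect_identical(s$n_rrna, 1L)
  expect_identical(s$n_intron, 1L)
  expect_identical(s$len_rns, 30L)
  empty <- MitoGenome("e", "ACGTACGT", TRUE)
  s0 <- summarize_annotation(empty)
  expect_identical(s0$n_pcg + s0$n_trna + s0$n_rrna + s0$n_intron, 0L)
  # synthetic default world: 15 core PCGs, 26 tRNAs, 2 rRNAs, 4 introns
  s1 <- summarize_annotation(synth_fixture()$genome)
  expect_identical(c(s1$n_pcg, s1$n_trna, s1$n_rrna, s1$n_intron,
                     s1$n_intronic_orf), c(15L, 26L, 2L, 4L, 1L))
  expect_identical(c(s1$len_rns, s1$len_rnl), c(1973L, 3768L))
})

test_that("internal stop codons warn but do not abort", {
  s <- paste0("ATG", "TAG", "GGT", "TAA")  # internal stop at codon 2
  g <- MitoGenome("w", paste0("AAAA", s, "TTTT"), FALSE,
                  list(mitocomp:::new_gene_feature(
                    "orfX", "unknown_ORF", "+",
                    matrix(c(5L, 16L), ncol = 2), "")))
  expect_warning(extract_cds(g, "orfX"), "internal stop")
})
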