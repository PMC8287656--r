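# Intron position-class mapping and common/rare classification.

# Build a single-gene genome whose cox1 carries introns at the given CDS
# offsets; cds may differ from the reference used for mapping.
intron_genome <- function(cds, offsets, id = "q") {
  set.seed(77)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  cuts <- c(0L, sort(offsets), nchar(cds))
  pieces <- list(bg(50))
  pos <- 50L
  exons <- matrix(0L, nrow = length(offsets) + 1L, ncol = 2L)
  introns <- list()
  for (e in seq_len(length(cuts) - 1L)) {
    ex <- substr(cds, cuts[e] + 1L, cuts[e + 1L])
    pieces <- c(pieces, ex)
    exons[e, ] <- c(pos + 1L, pos + nchar(ex))
    pos <- pos + nchar(ex)
    if (e <= length(offsets)) {
      it <- bg(120L)
      pieces <- c(pieces, it)
      introns[[e]] <- mitocomp:::new_intron_feature("cox1", e, pos + 1L,
                                                    pos + 120L, "I")
      pos <- pos + 120L
    }
  }
  pieces <- c(pieces, bg(50))
  MitoGenome(id, paste(unlist(pieces), collapse = ""), TRUE,
             list(mitocomp:::new_gene_feature("cox1", "PCG", "+", exons,
                                              "cox1")),
             introns)
}

test_that("intron offsets map to reference positions and Pcl names", {
  set.seed(51)
  ref <- random_cds_nt(200)  # 609 nt
  g <- intron_genome(ref, c(383L), id = "s1")
  asn <- map_intron_positions(g, "cox1", ref)
  expect_identical(asn$pcl_name, "P383")
  expect_identical(asn$ref_position, 383L)
  expect_equal(asn$alignment_support, 1)
  # zero introns -> empty assignment table
  g0 <- intron_genome(ref, integer(), id = "s0")
  expect_identical(nrow(map_intron_positions(g0, "cox1", ref)), 0L)
  expect_error(map_intron_positions(g0, "cox9", ref), "not found")
})

test_that("a 9-nt insertion upstream leaves the reference position fixed", {
  set.seed(52)
  ref <- random_cds_nt(200)
  # query CDS: insert three codons at codon boundary 120 (CDS offset 360)
  ins <- "GCTGCAGCT"
  qcds <- paste0(substr(ref, 1, 360), ins, substr(ref, 361, nchar(ref)))
  # intron after what is now offset 383 + 9 in the query
  g_ins <- intron_genome(qcds, c(392L), id = "ins")
  g_ctl <- intron_genome(ref, c(383L), id = "ctl")
  a_ins <- map_intron_positions(g_ins, "cox1", ref)
  a_ctl <- map_intron_positions(g_ctl, "cox1", ref)
  expect_identical(a_ins$ref_position, a_ctl$ref_position)
  expect_identical(a_ins$pcl_name, "P383")
})

test_that("Pcl assignment survives 5% silent third-position mutation", {
  set.seed(53)
  gc4 <- Biostrings::getGeneticCode("4")
  sense <- names(gc4)[gc4 != "*"]
  ref <- random_cds_nt(250)
  cods <- substring(ref, seq(1, nchar(ref), 3), seq(3, nchar(ref), 3))
  for (i in 2:(length(cods) - 1)) {
    if (runif(1) < 0.05) {
      syn <- sense[gc4[sense] == gc4[[cods[i]]]]
      cods[i] <- sample(syn, 1)
    }
  }
  qcds <- paste(cods, collapse = "")
  g <- intron_genome(qcds, c(383L, 600L), id = "silent")
  asn <- map_intron_positions(g, "cox1", ref)
  expect_identical(asn$ref_position, c(383L, 600L))
})

test_that("alignments below the identity floor carry a warning", {
  set.seed(54)
  ref <- random_cds_nt(150)
  other <- random_cds_nt(150)  # unrelated: background identity ~0.3
  g <- intron_genome(other, c(100L), id = "far")
  expect_warning(map_intron_positions(g, "cox1", ref, min_identity = 0.5),
                 "low-confidence")
})

test_that("assign_pcls builds exact-position classes", {
  asn <- data.frame(
    genome_id = c("a", "b", "c", "c"), host_gene = "cox1",
    intron_index = 1L, ref_position = c(383L, 383L, 384L, 500L),
    pcl_name = c("P383", "P383", "P384", "P500"),
    alignment_support = 1, stringsAsFactors = FALSE)
  m <- assign_pcls(asn)
  expect_identical(m$pcls, c("P383", "P384", "P500"))
  expect_identical(unname(m$prevalence), c(2L, 1L, 1L))
  # merge window 1 collapses 383/384
  m2 <- assign_pcls(asn, merge_window = 1L)
  expect_identical(m2$pcls, c("P383", "P500"))
  expect_identical(unname(m2$prevalence[1]), 3L)
  # species with no introns still occupy rows
  m3 <- assign_pcls(asn, species = c("a", "b", "c", "d"))
  expect_identical(nrow(m3$presence), 4L)
  expect_true(all(m3$presence["d", ] == 0L))
})

test_that("common/rare threshold is strict at one fifth", {
  mk <- function(n_species, prevalence) {
    pres <- matrix(0L, n_species, 1,
                   dimnames = list(paste0("s", 1:n_species), "P10"))
    pres[seq_len(prevalence), 1] <- 1L
    structure(list(species = rownames(pres), pcls = "P10", positions = 10L,
                   presence = pres, prevalence = c(P10 = prevalence),
                   label = NA_character_), class = "PclMatrix")
  }
  expect_identical(classify_common_rare(mk(79, 16))$label[[1]], "common")
  expect_identical(classify_common_rare(mk(79, 15))$label[[1]], "rare")
  expect_identical(classify_common_rare(mk(80, 16))$label[[1]], "rare")
  expect_identical(classify_common_rare(mk(80, 17))$label[[1]], "common")
})

test_that("disjunct Pcls are flagged only with a cross-clade witness", {
  species <- c(paste0("bol", 1:8), paste0("out", 1:4))
  pres <- matrix(0L, 12, 3,
                 dimnames = list(species, c("P717", "P383", "P999")))
  pres["bol3", "P717"] <- 1L
  pres[c("out1", "out2", "out4"), "P717"] <- 1L   # flagged
  pres[, "P383"] <- 1L                            # uniform: not flagged
  pres["bol5", "P999"] <- 1L                      # private: not flagged
  m <- structure(list(species = species, pcls = colnames(pres),
                      positions = c(717L, 383L, 999L), presence = pres,
                      prevalence = colSums(pres),
                      label = NA_character_), class = "PclMatrix")
  groups <- stats::setNames(rep(c("Boletales", "other"), c(8, 4)), species)
  fl <- flag_disjunct_pcls(m, groups, focal = "Boletales")
  expect_identical(fl$pcl, "P717")
  expect_identical(fl$focal_species, "bol3")
  expect_identical(fl$n_other, 3L)
  expect_error(flag_disjunct_pcls(m, groups[-1], focal = "Boletales"),
               "without a clade")
})
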