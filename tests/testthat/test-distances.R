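# K2P distances and neighbor joining.

# Build an aligned pair with exactly n_ts transitions and n_tv
# transversions over n columns of 'A'.
pq_pair <- function(n, n_ts, n_tv) {
  a <- rep("A", n)
  b <- a
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("pairwise_k2p reproduces the closed form", {
  p <- pq_pair(100, 10, 5)
  P <- 0.1; Q <- 0.05
  expect_equal(pairwise_k2p(p$a, p$b),
               -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
               tolerance = 1e-12)
  expect_equal(round(pairwise_k2p(p$a, p$b), 4), 0.1702)
  expect_identical(pairwise_k2p("ACGT", "ACGT"), 0)
  # saturation: P = 0.5, Q = 0 makes the log argument 0
  sat <- pq_pair(100, 50, 0)
  expect_true(is.na(pairwise_k2p(sat$a, sat$b)))
  expect_error(pairwise_k2p("ACG", "ACGT"), "length")
  expect_warning(d <- pairwise_k2p("NNN", "---"), "no retained")
  expect_true(is.na(d))
})

test_that("gap and N columns are dropped pairwise", {
  # columns 2 (gap) and 6 (N) are removed; the rest count
  expect_equal(pairwise_k2p("A-CGTN", "AACATA"),
               pairwise_k2p("ACGT", "ACAT"))
})

test_that("K2P >= p-distance, symmetric, reverse-complement invariant", {
  set.seed(21)
  for (i in 1:25) {
    n <- 300
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    bch <- strsplit(a, "")[[1]]
    mut <- runif(n) < 0.12
    bch[mut] <- vapply(bch[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b <- paste(bch, collapse = "")
    d <- pairwise_k2p(a, b)
    expect_gte(d + 1e-15, mitocomp:::p_distance(a, b))
    expect_identical(d, pairwise_k2p(b, a))
    expect_equal(pairwise_k2p(revcomp(a), revcomp(b)), d, tolerance = 1e-12)
  }
})

test_that("pairwise_k2p agrees with ape::dist.dna on random pairs", {
  set.seed(22)
  for (i in 1:10) {
    n <- 600
    a <- sample(c("a", "c", "g", "t"), n, TRUE)
    b <- a
    mut <- runif(n) < 0.1
    b[mut] <- vapply(b[mut], function(x)
      sample(setdiff(c("a", "c", "g", "t"), x), 1), character(1))
    m <- ape::as.DNAbin(rbind(x = a, y = b))
    expect_equal(pairwise_k2p(paste(a, collapse = ""), paste(b, collapse = "")),
                 as.numeric(ape::dist.dna(m, model = "K80")),
                 tolerance = 1e-9)
  }
})

test_that("gene_k2p_matrix is zero for identical genomes and NA-safe", {
  g <- synth_fixture()$genome
  g2 <- g; g2$id <- "copy"
  dm <- gene_k2p_matrix(list(g, g2), "cox1")
  expect_equal(unname(dm$values), matrix(0, 2, 2))
  expect_error(gene_k2p_matrix(list(g), "cox1"), "fewer than two")
})

test_that("mean K2P rank-orders genes by planted mutation rate", {
  tmpl <- synth_genome_spec(id = "anc", length = 26000,
    gene_order = default_gene_order()[c(1, 3, 8), ], n_trna = 4,
    introns = data.frame(host = character(), ref_offset = integer(),
                         length = integer()),
    intronic_orfs = data.frame(host = character(), intron = integer(),
                               length = integer()))
  # planted per-gene divergence: rps3 >> cox1 > atp9
  rt <- list(genes = data.frame(gene = c("cox1", "rps3", "atp9"),
                                ks = c(0.06, 0.25, 0.01),
                                ka = c(0.02, 0.12, 0.003)))
  coh <- generate_cohort(4, tmpl, seed = 31,
                         rates = list(g2 = rt, g3 = rt, g4 = rt))
  means <- vapply(c("atp9", "cox1", "rps3"), function(gene) {
    dm <- gene_k2p_matrix(coh$genomes, gene)
    mean(dm$values[upper.tri(dm$values)], na.rm = TRUE)
  }, numeric(1))
  expect_true(means[["rps3"]] > means[["cox1"]])
  expect_true(means[["cox1"]] > means[["atp9"]])
})

test_that("neighbor_joining solves the 3-taxon case exactly", {
  m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nw <- neighbor_joining(m)
  tr <- ape::read.tree(text = nw)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.05)
  expect_equal(bl[["B"]], 0.15)
  expect_equal(bl[["C"]], 0.25)
})

test_that("neighbor_joining recovers an additive 4-taxon tree", {
  # tree: ((A:1,B:2):3,(C:4,D:5))  -> additive distances
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 8
  m["A", "D"] <- m["D", "A"] <- 9
  m["B", "C"] <- m["C", "B"] <- 9
  m["B", "D"] <- m["D", "B"] <- 10
  m["C", "D"] <- m["D", "C"] <- 9
  tr <- ape::read.tree(text = neighbor_joining(m))
  # path-length equality to an additive matrix pins topology and lengths
  d <- as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(d), unname(m), tolerance = 1e-9)
})

test_that("degenerate and invalid NJ inputs behave as specified", {
  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- ape::read.tree(text = neighbor_joining(z))
  expect_true(all(tr$edge.length == 0))
  z[1, 2] <- z[2, 1] <- NA
  expect_error(neighbor_joining(z), "missing")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})
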