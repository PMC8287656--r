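# Circular gene-order canonicalization, identity, breakpoints,
# rearrangement classification.

rand_order <- function(n = 17, id = "r") {
  syms <- sample(DEFAULT_PANEL, n)
  make_order(syms, sample(c("+", "-"), n, TRUE), id = id,
             panel = DEFAULT_PANEL)
}

rotate_order <- function(o, k) {
  n <- length(o$symbols)
  idx <- c(seq.int(k, n), if (k > 1) seq.int(1, k - 1))
  make_order(o$symbols[idx], o$strands[idx], id = paste0(o$genome_id, "_rot"),
             panel = o$panel)
}

reflect_order <- function(o) {
  make_order(rev(o$symbols), ifelse(rev(o$strands) == "+", "-", "+"),
             id = paste0(o$genome_id, "_ref"), panel = o$panel)
}

test_that("canonicalize is idempotent and rotation/reflection invariant", {
  set.seed(61)
  for (i in 1:25) {
    o <- rand_order()
    canon <- canonicalize_circular(o)
    expect_identical(canonicalize_circular(canon), canon)
    expect_identical(canon$symbols[1], "cox1")
    expect_identical(canon$strands[1], "+")
    k <- sample(length(o$symbols), 1)
    expect_identical(canonicalize_circular(rotate_order(o, k))$symbols,
                     canon$symbols)
    refl <- canonicalize_circular(reflect_order(o))
    expect_identical(refl$symbols, canon$symbols)
    expect_identical(refl$strands, canon$strands)
  }
  # fallback anchor when cox1 is absent
  o2 <- make_order(c("nad2", "atp6", "cob"), c("+", "-", "+"))
  expect_identical(canonicalize_circular(o2)$symbols[1], "atp6")
})

test_that("orders_identical detects rotations and rejects swaps", {
  o <- make_order(c("cox1", "nad2", "rnl", "atp6"))
  expect_true(orders_identical(o, rotate_order(o, 3)))
  expect_true(orders_identical(o, reflect_order(o)))
  swapped <- make_order(c("cox1", "rnl", "nad2", "atp6"))
  expect_false(orders_identical(o, swapped))
  expect_error(orders_identical(o, make_order(c("rps3", "nad5"))), "no genes")
})

test_that("breakpoint distance on hand-enumerable cases", {
  a <- make_order(c("cox1", "nad1", "nad2", "nad3"))
  expect_identical(breakpoint_distance(a, a), 0L)
  b <- make_order(c("cox1", "nad2", "nad1", "nad3"))
  # adjacency sets share none of the four adjacencies except... enumerate:
  expect_identical(breakpoint_distance(a, b), bf_breakpoints(a, b))
  # reversal of a 2-gene block breaks exactly the two flanking adjacencies
  c_ <- make_order(c("cox1", "nad2", "nad1", "nad3"),
                   c("+", "-", "-", "+"))
  expect_identical(breakpoint_distance(a, c_), 2L)
})

test_that("breakpoint distance equals brute force and is a metric", {
  set.seed(62)
  orders <- replicate(30, {
    syms <- sample(DEFAULT_PANEL)
    make_order(syms, sample(c("+", "-"), 17, TRUE))
  }, simplify = FALSE)
  for (i in 1:25) {
    a <- orders[[sample(30, 1)]]; b <- orders[[sample(30, 1)]]
    d <- breakpoint_distance(a, b)
    expect_identical(d, bf_breakpoints(canonicalize_circular(a),
                                       canonicalize_circular(b)))
    expect_identical(d, breakpoint_distance(b, a))
    expect_identical(d == 0L, orders_identical(a, b))
    cc <- orders[[sample(30, 1)]]
    expect_lte(breakpoint_distance(a, b),
               breakpoint_distance(a, cc) + breakpoint_distance(cc, b))
  }
})

test_that("classify_rearranged applies the neighbour rule", {
  anc <- make_order(DEFAULT_PANEL)
  expect_identical(classify_rearranged(list(anc), anc)[[1]], character(0))
  # move nad2 (position 9 in the panel) between nad5 and nad6
  syms <- DEFAULT_PANEL[-9]
  at <- match("nad5", syms)
  moved <- make_order(append(syms, "nad2", after = at), id = "m")
  got <- sort(classify_rearranged(list(moved), anc)[[1]])
  # moved gene, its two old flanks (now adjacent), and its two new flanks
  expect_identical(got, sort(c("nad2", "nad1", "nad3", "nad5", "nad6")))
})

test_that("majority_ancestor takes the plurality and rejects ties", {
  base <- make_order(DEFAULT_PANEL)
  other <- make_order(rev(DEFAULT_PANEL))
  third <- make_order(DEFAULT_PANEL[c(2:17, 1)][c(17, 1:16)])  # same as base
  swapped <- make_order(DEFAULT_PANEL[c(1, 3, 2, 4:17)])
  expect_identical(
    majority_ancestor(list(base, rotate_order(base, 5), swapped))$symbols,
    canonicalize_circular(base)$symbols)
  expect_error(majority_ancestor(list(base, base, swapped, swapped)),
               "tied")
  uniq <- list(base, swapped, make_order(DEFAULT_PANEL[c(1, 4, 3, 2, 5:17)]))
  expect_error(majority_ancestor(uniq), "unique")
  expect_error(majority_ancestor(list(base, base)), "at least 3")
})

test_that("extract_order round-trips the generator manifest", {
  res <- synth_fixture()
  o <- extract_order(res$genome)
  planted <- canonicalize_circular(
    make_order(res$manifest$order$symbol, res$manifest$order$strand,
               id = "planted"))
  expect_identical(o$symbols, planted$symbols)
  expect_identical(o$strands, planted$strands)
  expect_identical(o$missing, character(0))
})

test_that("duplicated panel genes raise an annotation error", {
  f1 <- mitocomp:::new_gene_feature("cox1", "PCG", "+",
                                    matrix(c(1L, 30L), ncol = 2), "")
  f2 <- mitocomp:::new_gene_feature("cox1", "PCG", "+",
                                    matrix(c(41L, 70L), ncol = 2), "")
  g <- MitoGenome("dup", paste(rep("ACGT", 25), collapse = ""), TRUE,
                  list(f1, f2))
  expect_error(extract_order(g), "duplicated")
})
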