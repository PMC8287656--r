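# Independent brute-force oracles used by module tests and the
# acceptance suite.  These share no code with the package: sites are
# enumerated neighbour by neighbour, pathway averages by explicit
# permutation, breakpoints by direct scanning.

bf_code <- Biostrings::getGeneticCode("4")
bf_bases <- c("A", "C", "G", "T")
sense_codons <- names(bf_code)[bf_code != "*"]

bf_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    nsyn <- 0; nvalid <- 0
    for (b in setdiff(bf_bases, ch[pos])) {
      mu <- ch; mu[pos] <- b
      aa <- bf_code[[paste(mu, collapse = "")]]
      if (aa == "*") next
      nvalid <- nvalid + 1
      if (aa == bf_code[[codon]]) nsyn <- nsyn + 1
    }
    if (nvalid) s <- s + nsyn / nvalid
  }
  s
}

bf_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(0, 0))
  perms <- list()
  gen <- function(prefix, left) {
    if (!length(left)) { perms[[length(perms) + 1]] <<- prefix; return() }
    for (k in seq_along(left)) gen(c(prefix, left[k]), left[-k])
  }
  gen(integer(), dp)
  res <- list()
  for (p in perms) {
    cur <- a; sd <- 0; nd <- 0; hit_stop <- FALSE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- b[pos]
      if (bf_code[[paste(nxt, collapse = "")]] == "*") hit_stop <- TRUE
      if (bf_code[[paste(cur, collapse = "")]] ==
          bf_code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(sd, nd, hit_stop)
  }
  mat <- do.call(rbind, res)
  ok <- mat[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(mat))
  c(mean(mat[ok, 1]), mean(mat[ok, 2]))
}

bf_kaks <- function(codons_a, codons_b) {
  Sa <- sum(vapply(codons_a, bf_sites, numeric(1)))
  Sb <- sum(vapply(codons_b, bf_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(bf_diffs, codons_a, codons_b)
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# mutate codon vector a at ~rate, never through stops; returns codons
bf_mutate_codons <- function(a, rate) {
  b <- a
  for (j in which(runif(length(a)) < rate)) {
    repeat {
      cd <- strsplit(b[j], "")[[1]]
      pos <- sample(3, 1)
      cd[pos] <- sample(setdiff(bf_bases, cd[pos]), 1)
      cand <- paste(cd, collapse = "")
      if (bf_code[[cand]] != "*") { b[j] <- cand; break }
    }
  }
  b
}

# orientation-aware circular breakpoint count by direct scanning
bf_breakpoints <- function(a, b) {
  pairs_of <- function(o) {
    n <- length(o$symbols)
    lapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      list(s1 = o$symbols[i], d1 = o$strands[i],
           s2 = o$symbols[j], d2 = o$strands[j])
    })
  }
  flip <- function(x) if (x == "+") "-" else "+"
  pa <- pairs_of(a); pb <- pairs_of(b)
  present <- function(p) {
    for (q in pb) {
      if (q$s1 == p$s1 && q$d1 == p$d1 && q$s2 == p$s2 && q$d2 == p$d2) {
        return(TRUE)
      }
      if (q$s1 == p$s2 && q$d1 == flip(p$d2) &&
          q$s2 == p$s1 && q$d2 == flip(p$d1)) {
        return(TRUE)
      }
    }
    FALSE
  }
  sum(!vapply(pa, present, logical(1)))
}

# exact coverage oracle: mark covered bases in a logical vector
bf_coverage_pct <- function(len, ivs) {
  hit <- logical(len)
  for (k in seq_len(nrow(ivs))) hit[ivs[k, 1]:ivs[k, 2]] <- TRUE
  100 * sum(hit) / len
}
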