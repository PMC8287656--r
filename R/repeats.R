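# Repeat accounting: interspersed duplications by seed-and-extend
# self-alignment, tandem repeats by a deterministic period scan, and
# cross-genome shared fragments.
#
# E-values use fixed blastn-like Karlin-Altschul parameters for the
# +2/-3 scoring scheme (lambda = 0.625, K = 0.41).  Parity with any
# particular BLASTN build is not claimed; the E < threshold semantics are.

KA_LAMBDA <- 0.625
KA_K <- 0.41
MATCH_SCORE <- 2
MISMATCH_SCORE <- -3

# Positions of every word-mer of s, as a named list kmer -> integer vector.
kmer_index <- function(s, word) {
  n <- nchar(s)
  if (n < word) return(list())
  starts <- seq_len(n - word + 1L)
  kmers <- substring(s, starts, starts + word - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  split(starts[ok], kmers[ok])
}

# Ungapped x-drop extension of a seed match between character vectors q and
# s starting at (qi, si) with length word.  Returns the maximal-scoring
# ungapped local alignment containing the seed.
extend_seed <- function(q, s, qi, si, word, xdrop = 20) {
  score <- word * MATCH_SCORE
  # right
  best <- 0; cur <- 0; best_ext <- 0L
  i <- qi + word; j <- si + word; ext <- 0L
  while (i <= length(q) && j <= length(s)) {
    cur <- cur + if (q[i] == s[j]) MATCH_SCORE else MISMATCH_SCORE
    ext <- ext + 1L
    if (cur > best) { best <- cur; best_ext <- ext }
    if (best - cur > xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  r_ext <- best_ext; score <- score + best
  # left
  best <- 0; cur <- 0; best_ext <- 0L
  i <- qi - 1L; j <- si - 1L; ext <- 0L
  while (i >= 1L && j >= 1L) {
    cur <- cur + if (q[i] == s[j]) MATCH_SCORE else MISMATCH_SCORE
    ext <- ext + 1L
    if (cur > best) { best <- cur; best_ext <- ext }
    if (best - cur > xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  l_ext <- best_ext; score <- score + best
  qs <- qi - l_ext; qe <- qi + word - 1L + r_ext
  len <- qe - qs + 1L
  matches <- sum(q[qs:qe] == s[(si - l_ext):(si + word - 1L + r_ext)])
  list(q_start = qs, q_end = qe, s_start = si - l_ext,
       s_end = si + word - 1L + r_ext, score = score,
       identity = 100 * matches / len, length = len)
}

karlin_evalue <- function(score, m, n) {
  KA_K * as.numeric(m) * as.numeric(n) * exp(-KA_LAMBDA * score)
}

overlap_len <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

# Merge hits sharing >= `frac` of the shorter query interval (same strand
# relation), keeping the lower E-value representative.
merge_hits <- function(hits, frac = 0.5) {
  if (!length(hits)) return(hits)
  ord <- order(vapply(hits, `[[`, numeric(1), "e_value"))
  hits <- hits[ord]
  kept <- list()
  for (h in hits) {
    dup <- FALSE
    for (k in kept) {
      if (!identical(h$relation, k$relation)) next
      ov_q <- overlap_len(h$q_start, h$q_end, k$q_start, k$q_end)
      ov_s <- overlap_len(h$s_start, h$s_end, k$s_start, k$s_end)
      shorter <- min(h$q_end - h$q_start, k$q_end - k$q_start) + 1L
      if (ov_q >= frac * shorter && ov_s >= frac * shorter) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- h
  }
  kept
}

hits_to_df <- function(hits) {
  if (!length(hits)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      relation = character(), identity = numeric(),
                      aligned_length = integer(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    data.frame(q_start = h$q_start, q_end = h$q_end,
               s_start = h$s_start, s_end = h$s_end,
               relation = h$relation, identity = h$identity,
               aligned_length = h$length, e_value = h$e_value,
               stringsAsFactors = FALSE)
  }))
  df[order(df$e_value, df$q_start), , drop = FALSE]
}

# Shared engine: all significant ungapped local matches between q and s
# (direct) and between q and revcomp(s) (inverted), mapped back to s's
# forward coordinates.  self = TRUE drops diagonal and mirror pairs and
# overlapping self-matches.
seed_and_extend <- function(qseq, sseq, self, word, e_max, xdrop = 20) {
  q <- seq_chars(qseq); s <- seq_chars(sseq)
  m <- length(q); n <- length(s)
  iq <- kmer_index(qseq, word)
  hits <- list()
  covered <- function(qi, si, relation) {
    for (h in hits) {
      if (h$relation != relation) next
      if (qi >= h$q_start && qi + word - 1L <= h$q_end &&
          si >= h$raw_s_start && si + word - 1L <= h$raw_s_end) return(TRUE)
    }
    FALSE
  }
  scan <- function(starget, target_chars, relation) {
    it <- kmer_index(starget, word)
    for (kmer in intersect(names(iq), names(it))) {
      for (qi in iq[[kmer]]) for (si in it[[kmer]]) {
        if (self && relation == "direct" && qi >= si) next
        if (covered(qi, si, relation)) next
        e <- extend_seed(q, target_chars, qi, si, word, xdrop)
        ev <- karlin_evalue(e$score, m, n)
        if (ev >= e_max) next
        if (self && relation == "direct" &&
            overlap_len(e$q_start, e$q_end, e$s_start, e$s_end) > 0L) next
        # map subject interval back to forward coordinates when inverted
        if (relation == "inverted") {
          ss <- n - e$s_end + 1L; se <- n - e$s_start + 1L
        } else {
          ss <- e$s_start; se <- e$s_end
        }
        if (self && relation == "inverted") {
          if (overlap_len(e$q_start, e$q_end, ss, se) > 0L) next
          if (ss < e$q_start) next  # mirror duplicate of a pair seen forward
        }
        hits[[length(hits) + 1L]] <<- list(
          q_start = e$q_start, q_end = e$q_end, s_start = ss, s_end = se,
          raw_s_start = e$s_start, raw_s_end = e$s_end,
          relation = relation, identity = e$identity, length = e$length,
          e_value = ev)
      }
    }
  }
  scan(sseq, s, "direct")
  rc <- revcomp(sseq)
  scan(rc, seq_chars(rc), "inverted")
  merge_hits(hits)
}

#' Find intra-genomic duplications
#'
#' Seed-and-extend (word seeds, ungapped x-drop extension, +2/-3 scoring)
#' alignment of the genome against itself and its reverse complement.
#' Trivial self-hits, mirror duplicates and overlapping self-matches are
#' removed; overlapping hits are merged keeping the lowest E-value.
#'
#' @param genome a [MitoGenome] or DNA string
#' @param e_max E-value threshold (default 1e-10)
#' @param word seed length (default 11)
#' @return data.frame of hits (q_start, q_end, s_start, s_end, relation,
#'   identity, aligned_length, e_value)
#' @export
find_duplications <- function(genome, e_max = 1e-10, word = 11L) {
  s <- if (inherits(genome, "MitoGenome")) genome$sequence else validate_dna(genome)
  if (nchar(s) < word) stop("sequence shorter than the seed word", call. = FALSE)
  hits_to_df(seed_and_extend(s, s, self = TRUE, word = word, e_max = e_max))
}

#' Find shared fragments between a mitogenome and another sequence set
#'
#' Same engine as [find_duplications()], run across genomes; subject
#' coordinates refer to the other sequence.
#'
#' @param mito a [MitoGenome] or DNA string (query)
#' @param other named list of subject sequences (e.g. from [read_fasta()])
#'   or a single DNA string
#' @param e_max E-value threshold
#' @param word seed length
#' @return data.frame of hits with a `subject` column
#' @export
cross_genome_fragments <- function(mito, other, e_max = 1e-10, word = 11L) {
  q <- if (inherits(mito, "MitoGenome")) mito$sequence else validate_dna(mito)
  if (is.character(other) && is.null(names(other)) && length(other) == 1L) {
    other <- list(subject = other)
  }
  out <- list()
  for (nm in names(other)) {
    df <- hits_to_df(seed_and_extend(q, other[[nm]], self = FALSE,
                                     word = word, e_max = e_max))
    if (nrow(df)) { df$subject <- nm; out[[length(out) + 1L]] <- df }
  }
  if (!length(out)) {
    df <- hits_to_df(list()); df$subject <- character(0); return(df)
  }
  res <- do.call(rbind, out)
  res[order(res$e_value), , drop = FALSE]
}

#' Find tandem repeats by deterministic period scan
#'
#' For each period p (1..max_period) the sequence is scanned for maximal
#' runs where `s[i] == s[i+p]` holds with at least `min_identity` density;
#' a run of match length L spans L + p bases with (L + p)/p copies.  Runs
#' are reported once, at their smallest qualifying period; runs contained
#' in a smaller-period report are suppressed.
#'
#' @param genome a [MitoGenome] or DNA string
#' @param min_total minimum total repeat length in nt (default 11,
#'   i.e. repeats longer than 10 bp)
#' @param min_copies minimum copy number (default 2)
#' @param max_period largest period scanned (default 500)
#' @param min_identity per-run match density floor (default 0.8)
#' @return data.frame (start, end, period, copy_number, total_length,
#'   consensus)
#' @export
find_tandem_repeats <- function(genome, min_total = 11L, min_copies = 2,
                                max_period = 500L, min_identity = 0.8) {
  s <- if (inherits(genome, "MitoGenome")) genome$sequence else validate_dna(genome)
  chars <- seq_chars(s)
  n <- length(chars)
  out <- list()
  contained <- function(st, en) {
    for (r in out) if (st >= r$start && en <= r$end) return(TRUE)
    FALSE
  }
  for (p in seq_len(min(max_period, n %/% 2L))) {
    m <- chars[seq_len(n - p)] == chars[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    true_i <- which(r$values)
    # seeds: TRUE runs spanning at least one full period (two exact copies)
    seeds <- true_i[r$lengths[true_i] >= p]
    if (!length(seeds)) next
    for (si in seeds) {
      seg_s <- starts[si]; seg_e <- ends[si]
      if (contained(seg_s, seg_e + p)) next
      matches <- r$lengths[si]
      # absorb neighbouring TRUE runs while density stays acceptable and
      # gaps do not exceed one period
      k <- si + 2L
      while (k <= length(r$lengths) && r$values[k]) {
        gap <- starts[k] - seg_e - 1L
        new_m <- matches + r$lengths[k]
        if (gap <= p && new_m / (ends[k] - seg_s + 1L) >= min_identity) {
          seg_e <- ends[k]; matches <- new_m; k <- k + 2L
        } else break
      }
      k <- si - 2L
      while (k >= 1L && r$values[k]) {
        gap <- seg_s - ends[k] - 1L
        new_m <- matches + r$lengths[k]
        if (gap <= p && new_m / (seg_e - starts[k] + 1L) >= min_identity) {
          seg_s <- starts[k]; matches <- new_m; k <- k - 2L
        } else break
      }
      total <- seg_e - seg_s + 1L + p
      copies <- total / p
      if (total >= min_total && copies >= min_copies &&
          !contained(seg_s, seg_e + p)) {
        cons <- paste(chars[seg_s:min(seg_s + p - 1L, n)], collapse = "")
        out[[length(out) + 1L]] <- list(start = seg_s, end = seg_e + p,
                                        period = p, copy_number = copies,
                                        total_length = total,
                                        consensus = cons)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), total_length = integer(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  df[order(df$start, df$period), , drop = FALSE]
}

#' Fraction of a genome covered by repeat hits
#'
#' The union of all hit intervals (query and subject intervals of
#' duplication hits; spans of tandem repeats), with no double counting,
#' divided by genome length.
#'
#' @param genome a [MitoGenome] or DNA string
#' @param hits data.frame from [find_duplications()] /
#'   [find_tandem_repeats()], or any data.frame with start/end or
#'   q_start/q_end (+ s_start/s_end) columns
#' @return percent of the genome covered
#' @export
repeat_fraction <- function(genome, hits) {
  len <- if (inherits(genome, "MitoGenome")) genome_length(genome) else nchar(genome)
  ivs <- matrix(integer(), ncol = 2L)
  if (nrow(hits)) {
    if (all(c("q_start", "q_end") %in% names(hits))) {
      ivs <- rbind(ivs, cbind(hits$q_start, hits$q_end))
      if (all(c("s_start", "s_end") %in% names(hits)) &&
          !"subject" %in% names(hits)) {
        ivs <- rbind(ivs, cbind(hits$s_start, hits$s_end))
      }
    } else if (all(c("start", "end") %in% names(hits))) {
      ivs <- rbind(ivs, cbind(hits$start, hits$end))
    } else {
      stop("hits must have start/end or q_start/q_end columns", call. = FALSE)
    }
  }
  if (!nrow(ivs)) return(0)
  if (any(ivs[, 1L] < 1L) || any(ivs[, 2L] > len)) {
    stop("hit interval outside genome bounds 1..", len, call. = FALSE)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = ivs[, 1L], end = ivs[, 2L]))
  100 * sum(IRanges::width(ir)) / len
}
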