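# Intron position classes (Pcls): map insertion sites onto a reference CDS
# and classify classes as common or rare across a species panel.
#
# Convention (fixed and test-pinned): the insertion coordinate is the
# 1-based reference-CDS position of the last aligned nucleotide 5' of the
# exon junction, on the spliced reference CDS; the class is named
# "P" + position.

#' Map intron insertion sites of a host gene onto a reference CDS
#'
#' The genome's spliced host CDS is globally aligned to the reference
#' (protein-guided, see [codon_align()]); each exon-junction CDS offset is
#' mapped through the alignment to a reference coordinate.  Offsets landing
#' in reference gaps map to the nearest 5' non-gap reference position.
#'
#' @param genome a [MitoGenome]
#' @param host_gene intron-bearing gene symbol (commonly cox1)
#' @param reference_cds reference CDS: a `CodingSequence`, a plain DNA
#'   string, or a single-record FASTA path
#' @param code NCBI genetic-code id
#' @param min_identity amino-acid identity floor below which every
#'   assignment carries a low-confidence warning (default 0.3)
#' @return data.frame with genome_id, host_gene, intron_index, ref_position,
#'   pcl_name, alignment_support; zero rows when the gene has no introns
#' @export
map_intron_positions <- function(genome, host_gene, reference_cds,
                                 code = "4", min_identity = 0.3) {
  f <- find_feature(genome, host_gene)
  if (is.null(f)) stop("host gene not found in ", genome$id, ": ", host_gene,
                       call. = FALSE)
  ref_nt <- if (inherits(reference_cds, "CodingSequence")) reference_cds$nt
            else if (file.exists(as.character(reference_cds)[1]) &&
                     !grepl("^[ACGTNacgtn]+$", reference_cds)) {
              read_fasta(reference_cds)[[1L]]
            } else validate_dna(reference_cds, "reference CDS")

  cds <- suppressWarnings(extract_cds(genome, host_gene, code = code))
  empty <- data.frame(genome_id = character(), host_gene = character(),
                      intron_index = integer(), ref_position = integer(),
                      pcl_name = character(), alignment_support = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(cds$exon_boundaries)) return(empty)

  aln <- codon_align(cds, ref_nt, code = code)
  # amino-acid identity over aligned columns
  cols <- aln$aligned_aa_a != "-" & aln$aligned_aa_b != "-"
  identity <- if (any(cols)) {
    mean(aln$aligned_aa_a[cols] == aln$aligned_aa_b[cols])
  } else 0
  low_conf <- identity < min_identity
  if (low_conf) {
    warning("alignment identity ", round(identity, 3), " below ",
            min_identity, " for ", genome$id, "/", host_gene,
            "; Pcl assignments are low-confidence", call. = FALSE)
  }

  # nucleotide identity support in a +/-15 nt window around a query offset
  qchars <- seq_chars(cds$nt)
  rchars <- seq_chars(ref_nt)
  support_at <- function(q, r) {
    w <- 15L
    qs <- max(1L, q - w); qe <- min(length(qchars), q + w)
    rs <- r - (q - qs); re <- r + (qe - q)
    if (rs < 1L || re > length(rchars) || r < 1L) return(NA_real_)
    mean(qchars[qs:qe] == rchars[rs:re])
  }

  rows <- lapply(seq_along(cds$exon_boundaries), function(i) {
    q <- cds$exon_boundaries[i]
    r <- map_position_through(aln, q)
    data.frame(genome_id = genome$id, host_gene = host_gene,
               intron_index = i, ref_position = r,
               pcl_name = paste0("P", r),
               alignment_support = support_at(q, r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$ref_position >= 1L, , drop = FALSE]
}

#' Build a species x Pcl presence/absence matrix
#'
#' @param assignments pooled rows from [map_intron_positions()] across
#'   genomes (data.frame)
#' @param species optional full species list (genomes with zero introns
#'   still occupy a row)
#' @param merge_window merge Pcls whose ref positions differ by at most
#'   this many nt (default 0: exact-position identity)
#' @return a `PclMatrix`: list(species, pcls, positions, presence,
#'   prevalence, label); labels are filled by [classify_common_rare()]
#' @export
assign_pcls <- function(assignments, species = NULL, merge_window = 0L) {
  stopifnot(is.data.frame(assignments))
  if (is.null(species)) species <- unique(assignments$genome_id)
  pos <- sort(unique(assignments$ref_position))
  if (merge_window > 0L && length(pos) > 1L) {
    grp <- cumsum(c(TRUE, diff(pos) > merge_window))
    canon <- tapply(pos, grp, min)
    remap <- stats::setNames(canon[as.character(grp)], pos)
    assignments$ref_position <- as.integer(remap[as.character(assignments$ref_position)])
    pos <- sort(unique(assignments$ref_position))
  }
  pcls <- paste0("P", pos)
  presence <- matrix(0L, nrow = length(species), ncol = length(pos),
                     dimnames = list(species, pcls))
  for (k in seq_len(nrow(assignments))) {
    sp <- assignments$genome_id[k]
    if (!sp %in% species) next
    presence[sp, paste0("P", assignments$ref_position[k])] <- 1L
  }
  structure(list(species = species, pcls = pcls, positions = pos,
                 presence = presence,
                 prevalence = stats::setNames(as.integer(colSums(presence)),
                                              pcls),
                 label = rep(NA_character_, length(pcls))),
            class = "PclMatrix")
}

#' Label Pcls as common or rare
#'
#' A Pcl present in strictly more than `fraction` of the species panel is
#' common, otherwise rare (prevalence == n/5 exactly is rare).
#'
#' @param matrix a `PclMatrix`
#' @param fraction prevalence threshold as a fraction of species (default
#'   1/5)
#' @return the `PclMatrix` with `label` filled in
#' @export
classify_common_rare <- function(matrix, fraction = 0.2) {
  stopifnot(inherits(matrix, "PclMatrix"))
  n <- length(matrix$species)
  matrix$label <- ifelse(matrix$prevalence > n * fraction, "common", "rare")
  matrix
}

#' Flag Pcls with a disjunct phylogenetic distribution
#'
#' Returns Pcls present in exactly one member of the focal clade and in at
#' least one species of a different clade -- the signature of a candidate
#' horizontal intron transfer.
#'
#' @param matrix a `PclMatrix`
#' @param groups named character vector mapping species to clade labels
#' @param focal the clade of interest
#' @return data.frame (pcl, focal_species, n_focal, n_other, witnesses)
#' @export
flag_disjunct_pcls <- function(matrix, groups, focal) {
  stopifnot(inherits(matrix, "PclMatrix"))
  missing_sp <- setdiff(matrix$species, names(groups))
  if (length(missing_sp)) {
    stop("species without a clade label: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(groups), matrix$species)
  if (length(unknown)) {
    stop("unknown species in groups: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cl <- groups[matrix$species]
  rows <- list()
  for (j in seq_along(matrix$pcls)) {
    present <- matrix$presence[, j] == 1L
    in_focal <- present & cl == focal
    in_other <- present & cl != focal
    if (sum(in_focal) == 1L && sum(in_other) >= 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        pcl = matrix$pcls[j],
        focal_species = matrix$species[in_focal],
        n_focal = sum(in_focal), n_other = sum(in_other),
        witnesses = paste(matrix$species[in_other], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pcl = character(), focal_species = character(),
                      n_focal = integer(), n_other = integer(),
                      witnesses = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a Pcl presence/absence matrix as TSV
#'
#' The matrix block is followed by prevalence and label footer rows.
#'
#' @param matrix a `PclMatrix` (labelled)
#' @param path output path
#' @return the path, invisibly
#' @export
write_pcl_matrix <- function(matrix, path) {
  df <- as.data.frame(matrix$presence)
  df <- cbind(species = rownames(df), df)
  foot1 <- c("prevalence", as.character(matrix$prevalence))
  foot2 <- c("label", matrix$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste(foot1, collapse = "\t"), con)
  writeLines(paste(foot2, collapse = "\t"), con)
  invisible(path)
}
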