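# Planted-structure synthetic data: protein families whose subfamilies
# share disjoint hexapeptide vocabularies at a controlled conservation
# level, and genome contigs embedding reverse-translated members of those
# subfamilies between stretches of random intergenic DNA.  Ground truth is
# returned alongside every fixture so recovery can be scored exactly.

.random_aa <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Planted-family specification
#'
#' Describes a synthetic protein family: `n_subfamilies` planted
#' subfamilies whose members share a private vocabulary of
#' `vocabulary_size` hexapeptides, each peptide carried by a
#' `conservation` fraction of the members, plus `decoy_count` proteins of
#' pure random background.  Background residues are uniform over the 20
#' amino acids, so an accidental hexapeptide match has probability 20^-6
#' per position.
#'
#' @param n_subfamilies Number of planted subfamilies.
#' @param members_per_subfamily Proteins per subfamily.
#' @param vocabulary_size Planted peptides per subfamily.
#' @param conservation Fraction of members carrying each planted peptide.
#' @param protein_length Member length in residues; must accommodate the
#'   planted peptides.
#' @param decoy_count Number of background-only proteins.
#' @param peptide_length Planted peptide length in residues.
#' @param ec_labels Optional character vector, one EC (or `NA`) per
#'   subfamily, attached to a random 25% (at least one) of its members.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(n_subfamilies = 3L, members_per_subfamily = 20L,
                       vocabulary_size = 70L, conservation = 1.0,
                       protein_length = 500L, decoy_count = 10L,
                       peptide_length = 6L, ec_labels = NULL) {
  stopifnot(conservation > 0, conservation <= 1,
            n_subfamilies >= 1L, members_per_subfamily >= 1L)
  if (vocabulary_size * peptide_length > protein_length) {
    stop("planted peptides (", vocabulary_size * peptide_length,
         " residues) exceed protein_length (", protein_length, ")")
  }
  if (!is.null(ec_labels)) stopifnot(length(ec_labels) == n_subfamilies)
  structure(list(n_subfamilies = as.integer(n_subfamilies),
                 members_per_subfamily = as.integer(members_per_subfamily),
                 vocabulary_size = as.integer(vocabulary_size),
                 conservation = conservation,
                 protein_length = as.integer(protein_length),
                 decoy_count = as.integer(decoy_count),
                 peptide_length = as.integer(peptide_length),
                 ec_labels = ec_labels),
            class = "plant_spec")
}

# Assemble one member: its peptides in random order, separated by random
# background linkers that pad the sequence to protein_length.  Linker
# lengths are a random composition of the spare residues.  When length
# permits, consecutive peptides are kept at least one background residue
# apart, so the junction between two planted peptides never forms a
# deterministic hexapeptide shared across members.
.plant_member <- function(peptides, protein_length, peptide_length) {
  npep <- length(peptides)
  if (npep == 0L) return(.random_aa(protein_length))
  spare <- protein_length - npep * peptide_length
  inner_min <- if (spare >= npep - 1L) 1L else 0L
  loose <- spare - inner_min * (npep - 1L)
  gaps <- if (loose > 0L) {
    tabulate(sample.int(npep + 1L, loose, replace = TRUE), npep + 1L)
  } else rep(0L, npep + 1L)
  if (inner_min > 0L && npep > 1L) {
    gaps[2:npep] <- gaps[2:npep] + inner_min
  }
  order <- sample.int(npep)
  parts <- character(2L * npep + 1L)
  parts[seq(1L, 2L * npep + 1L, by = 2L)] <-
    vapply(gaps, .random_aa, character(1))
  parts[seq(2L, 2L * npep, by = 2L)] <- peptides[order]
  paste(parts, collapse = "")
}

#' Generate a planted protein family
#'
#' Draws pairwise-disjoint hexapeptide vocabularies, builds each member as
#' random background with its planted peptides inserted at random
#' non-overlapping positions (each peptide present in exactly
#' `ceiling(conservation * members)` members), and appends background-only
#' decoys.  Reproducible under `set.seed()`.
#'
#' @param spec A [plant_spec()] object.
#' @return List with `proteins` (named character vector), `truth`
#'   (data.frame `id`, `subfamily`; decoys have subfamily 0),
#'   `vocabularies` (list of peptide character vectors per subfamily) and
#'   `ec_labels` (named list id -> ECs, possibly empty).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  k <- spec$peptide_length
  n_vocab <- spec$n_subfamilies * spec$vocabulary_size
  vocab <- character(0)
  while (length(vocab) < n_vocab) {
    vocab <- unique(c(vocab, vapply(seq_len(n_vocab - length(vocab) + 8L),
                                    function(i) .random_aa(k),
                                    character(1))))
  }
  vocab <- vocab[seq_len(n_vocab)]
  vocabularies <- split(vocab, rep(seq_len(spec$n_subfamilies),
                                   each = spec$vocabulary_size))
  m <- spec$members_per_subfamily
  n_carry <- as.integer(ceiling(spec$conservation * m))
  proteins <- character(0)
  truth_id <- character(0)
  truth_sub <- integer(0)
  ec_labels <- list()
  for (s in seq_len(spec$n_subfamilies)) {
    # per-peptide carrier draw: each planted peptide goes into exactly
    # n_carry of the m members
    carriers <- lapply(seq_len(spec$vocabulary_size),
                       function(i) sample.int(m, n_carry))
    member_peps <- lapply(seq_len(m), function(j) {
      vocabularies[[s]][vapply(carriers, function(cc) j %in% cc, logical(1))]
    })
    ids <- sprintf("sub%d_mem%d", s, seq_len(m))
    seqs <- vapply(member_peps, .plant_member, character(1),
                   protein_length = spec$protein_length,
                   peptide_length = k)
    proteins <- c(proteins, setNames(seqs, ids))
    truth_id <- c(truth_id, ids)
    truth_sub <- c(truth_sub, rep(s, m))
    if (!is.null(spec$ec_labels) && !is.na(spec$ec_labels[s])) {
      labeled <- sample(ids, max(1L, m %/% 4L))
      for (id in labeled) ec_labels[[id]] <- spec$ec_labels[s]
    }
  }
  if (spec$decoy_count > 0L) {
    ids <- sprintf("decoy%d", seq_len(spec$decoy_count))
    seqs <- vapply(seq_len(spec$decoy_count),
                   function(i) .random_aa(spec$protein_length), character(1))
    proteins <- c(proteins, setNames(seqs, ids))
    truth_id <- c(truth_id, ids)
    truth_sub <- c(truth_sub, rep(0L, spec$decoy_count))
  }
  list(proteins = proteins,
       truth = data.frame(id = truth_id, subfamily = truth_sub,
                          stringsAsFactors = FALSE),
       vocabularies = vocabularies,
       ec_labels = ec_labels)
}

# codon table inverted once: amino acid -> candidate codons
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

#' Reverse-translate a protein with random synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' codons under the standard genetic code; `*` becomes a random stop codon.
#'
#' @param aa Amino-acid sequence (character scalar).
#' @return DNA coding sequence (character scalar).
#' @export
reverse_translate <- function(aa) {
  tab <- .codons_by_aa()
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(tab))
  if (length(bad) > 0L) stop("cannot reverse-translate letter: ", bad[1L])
  paste(vapply(tab[res], function(cc) cc[sample.int(length(cc), 1L)],
               character(1)), collapse = "")
}

#' Genome specification for planted genes
#'
#' @param genes data.frame with columns `protein_id`, `family`,
#'   `subfamily`, `seq` (amino-acid sequence) — one row per gene to plant.
#' @param intergenic_mean Mean length of intergenic segments in bases;
#'   `NULL` uses the mean planted coding-sequence length, which makes the
#'   genome roughly half intergenic DNA.
#' @param gc_content GC fraction of intergenic DNA.
#' @param genes_per_contig Genes placed on each contig.
#' @param placement `"interleaved"` cycles through the planted subfamilies
#'   so consecutive genes come from different families (the dispersed
#'   arrangement typical of CAZyme genes in fungal genomes, and the layout
#'   under which one planted gene corresponds to one merged gene call);
#'   `"as_given"` keeps the input row order.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(genes, intergenic_mean = NULL, gc_content = 0.5,
                        genes_per_contig = 5L,
                        placement = c("interleaved", "as_given")) {
  stopifnot(is.data.frame(genes),
            all(c("protein_id", "family", "subfamily", "seq") %in%
                  names(genes)))
  structure(list(genes = genes, intergenic_mean = intergenic_mean,
                 gc_content = gc_content,
                 genes_per_contig = as.integer(genes_per_contig),
                 placement = match.arg(placement)),
            class = "genome_spec")
}

#' Generate a synthetic genome with planted genes
#'
#' Builds contigs as alternating random intergenic DNA and
#' reverse-translated planted genes (random synonymous codons, a start
#' codon prefix and a stop codon suffix, strand drawn at random), and
#' records the true coordinates of every gene.  Intergenic segment lengths
#' are uniform in `[0.5, 1.5] * intergenic_mean`.  Reproducible under
#' `set.seed()`.
#'
#' @param spec A [genome_spec()] object.
#' @return List with `contigs` (named character vector of DNA) and `truth`
#'   (data.frame `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `family`, `subfamily`, `protein_id`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  genes <- spec$genes
  if (spec$placement == "interleaved") {
    ord <- order(stats::ave(seq_len(nrow(genes)),
                            paste(genes$family, genes$subfamily),
                            FUN = seq_along))
    genes <- genes[ord, , drop = FALSE]
  }
  cds <- vapply(genes$seq, function(aa) {
    paste0("ATG", reverse_translate(aa),
           sample(c("TAA", "TAG", "TGA"), 1L))
  }, character(1), USE.NAMES = FALSE)
  mean_len <- if (is.null(spec$intergenic_mean)) mean(nchar(cds))
              else spec$intergenic_mean
  n_contig <- ceiling(nrow(genes) / spec$genes_per_contig)
  contig_of <- rep(seq_len(n_contig), each = spec$genes_per_contig,
                   length.out = nrow(genes))
  contigs <- character(n_contig)
  names(contigs) <- sprintf("contig%d", seq_len(n_contig))
  truth <- list()
  for (ci in seq_len(n_contig)) {
    idx <- which(contig_of == ci)
    parts <- character(0)
    pos <- 0L
    for (gi in idx) {
      ig <- .random_dna(as.integer(round(stats::runif(1, 0.5, 1.5) *
                                           mean_len)), spec$gc_content)
      parts <- c(parts, ig)
      pos <- pos + nchar(ig)
      strand <- sample(c("+", "-"), 1L)
      gseq <- if (strand == "+") cds[gi] else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds[gi])))
      parts <- c(parts, gseq)
      truth[[length(truth) + 1L]] <-
        data.frame(contig = names(contigs)[ci], start = pos,
                   end = pos + nchar(gseq), strand = strand,
                   family = genes$family[gi],
                   subfamily = genes$subfamily[gi],
                   protein_id = genes$protein_id[gi],
                   stringsAsFactors = FALSE)
      pos <- pos + nchar(gseq)
    }
    tail_ig <- .random_dna(as.integer(round(stats::runif(1, 0.5, 1.5) *
                                              mean_len)), spec$gc_content)
    contigs[ci] <- paste(c(parts, tail_ig), collapse = "")
  }
  list(contigs = contigs, truth = do.call(rbind, truth))
}
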