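# Sequence input/output, contig filtering, genome fragmentation and
# six-frame translation.  Sequences are carried as named character vectors
# (names = record ids, values = uppercase sequence strings); Biostrings does
# the heavy lifting for FASTA parsing and codon translation.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fragmentation parameters
#'
#' Window parameters for splitting genome contigs before six-frame
#' translation, and the minimum contig length retained for analysis.
#' Defaults: 2000-base fragments overlapping by 100 bases, contigs shorter
#' than 500 bases discarded.
#'
#' @param fragment_length Fragment window size in bases.
#' @param overlap_length Overlap between consecutive fragments in bases;
#'   must be smaller than `fragment_length`.
#' @param min_contig_length Contigs shorter than this are discarded.
#' @return An object of class `fragmentation_params`.
#' @export
fragmentation_params <- function(fragment_length = 2000L,
                                 overlap_length = 100L,
                                 min_contig_length = 500L) {
  fragment_length <- as.integer(fragment_length)
  overlap_length <- as.integer(overlap_length)
  min_contig_length <- as.integer(min_contig_length)
  stopifnot(overlap_length >= 0L, overlap_length < fragment_length,
            min_contig_length > 0L)
  structure(list(fragment_length = fragment_length,
                 overlap_length = overlap_length,
                 min_contig_length = min_contig_length),
            class = "fragmentation_params")
}

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a named
#' character vector.  Sequences are uppercased; the id is the header token
#' before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    if (all(!nzchar(trimws(lines)))) {
      warning("empty FASTA file: ", path)
      return(setNames(character(0), character(0)))
    }
    stop("not a FASTA file (no '>' header): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("malformed FASTA: entry with no sequence: ", ids[which(empty)[1L]])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Discard short contigs
#'
#' Keeps exactly the records whose length is at least
#' `params$min_contig_length`, preserving order.  A 500-base contig is
#' retained under the default; a 499-base contig is discarded.
#'
#' @param seqs Named character vector of contig sequences.
#' @param params A [fragmentation_params()] object.
#' @return Named character vector of retained contigs.
#' @export
filter_contigs <- function(seqs, params = fragmentation_params()) {
  seqs[nchar(seqs) >= params$min_contig_length]
}

#' Split a contig into overlapping fragments
#'
#' Fragments start at multiples of `fragment_length - overlap_length`
#' (the step), each spanning up to `fragment_length` bases; together they
#' cover every base of the contig.  A trailing window fully contained in the
#' previous fragment is not emitted, so the last fragment may be short but
#' always extends past its predecessor.  Coordinates are 0-based, half-open.
#'
#' @param seq A single contig sequence (character scalar).
#' @param contig_id Identifier carried into the fragment table.
#' @param params A [fragmentation_params()] object.
#' @return A data.frame with columns `contig_id`, `start`, `end`, `seq`.
#' @export
fragment_genome <- function(seq, contig_id = "contig",
                            params = fragmentation_params()) {
  stopifnot(length(seq) == 1L)
  L <- nchar(seq)
  if (L < params$min_contig_length) {
    stop("contig '", contig_id, "' shorter than min_contig_length (",
         L, " < ", params$min_contig_length, ")")
  }
  step <- params$fragment_length - params$overlap_length
  if (L <= params$fragment_length) {
    starts <- 0L
  } else {
    n <- ceiling((L - params$overlap_length) / step)
    starts <- as.integer(step * (seq_len(n) - 1L))
  }
  ends <- pmin(starts + params$fragment_length, L)
  data.frame(contig_id = contig_id, start = starts, end = ends,
             seq = substring(seq, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Fragment every contig of a genome
#'
#' Applies [filter_contigs()] then [fragment_genome()] to each contig.
#'
#' @param seqs Named character vector of contigs.
#' @param params A [fragmentation_params()] object.
#' @return One data.frame of fragments across all retained contigs.
#' @export
fragment_contigs <- function(seqs, params = fragmentation_params()) {
  kept <- filter_contigs(seqs, params)
  if (length(kept) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(kept), function(i) {
    fragment_genome(kept[[i]], names(kept)[i], params)
  }))
}

# Translate one DNA string in a single forward frame offset (1, 2 or 3).
# Stop codons become "*"; codons with unresolvable ambiguity codes become
# "X".  Neither letter occurs in a peptide list, so peptide matching can
# never cross either sentinel.
.translate_frame <- function(dna, offset) {
  n <- nchar(dna)
  naa <- (n - offset + 1L) %/% 3L
  if (naa <= 0L) return("")
  sub <- Biostrings::subseq(Biostrings::DNAString(dna), start = offset,
                            width = naa * 3L)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}

#' Translate a fragment in all six reading frames
#'
#' Frames +1..+3 read the given strand at offsets 0..2; frames -1..-3 read
#' the reverse complement the same way.  Translation uses the standard
#' genetic code; stop codons are rendered as `*` and codons containing
#' ambiguity letters that do not resolve to a unique amino acid as `X`, so
#' no hexapeptide of amino-acid letters can match across either.
#'
#' @param seq DNA sequence (character scalar, IUPAC letters).
#' @return Named list of six amino-acid strings, names `"+1"` .. `"-3"`.
#' @export
translate_six_frames <- function(seq) {
  stopifnot(length(seq) == 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- c(lapply(1:3, function(o) .translate_frame(seq, o)),
           lapply(1:3, function(o) .translate_frame(rc, o)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Map an amino-acid interval back to genomic coordinates
#'
#' Given a fragment's genomic span and a frame label, converts a 1-based
#' amino-acid interval of the frame translation to the 0-based half-open
#' genomic base span it was translated from.  Reverse frames count from the
#' fragment's 3' end of the given strand.
#'
#' @param frame Frame label, one of `"+1"`,`"+2"`,`"+3"`,`"-1"`,`"-2"`,`"-3"`.
#' @param aa_start,aa_end 1-based inclusive amino-acid positions.
#' @param frag_start,frag_end 0-based half-open genomic span of the fragment.
#' @return Integer vector `c(start, end)`, 0-based half-open genomic span.
#' @export
aa_to_genomic <- function(frame, aa_start, aa_end, frag_start, frag_end) {
  offset <- as.integer(substring(frame, 2L)) - 1L
  len <- 3L * (aa_end - aa_start + 1L)
  if (startsWith(frame, "+")) {
    g0 <- frag_start + offset + 3L * (aa_start - 1L)
    c(g0, g0 + len)
  } else {
    g1 <- frag_end - offset - 3L * (aa_start - 1L)
    c(g1 - len, g1)
  }
}

#' Reverse-complement a DNA string
#'
#' @param seq DNA sequence (character scalar).
#' @return The reverse complement as a character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
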