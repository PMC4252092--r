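# Hotpep: score translated genome fragments (or full-length proteins)
# against subfamily peptide profiles, call hits under three threshold
# conditions, merge nearby same-family hits into gene calls, and transfer
# the subfamily's function to each call.

#' Hotpep threshold and merge parameters
#'
#' A reading frame is a hit when it contains at least `min_peptide_hits`
#' conserved peptides of one subfamily, the sum of their subfamily
#' frequencies is strictly greater than `min_freq_sum`, and the peptides
#' cover at least `min_residues_covered` amino acids.  Same-family hits
#' closer than `merge_distance` bases on one contig are counted as one
#' gene.
#'
#' @param min_peptide_hits Minimum distinct conserved peptides.
#' @param min_freq_sum Frequency-score bound (strict inequality).
#' @param min_residues_covered Minimum residues covered by the peptides.
#' @param merge_distance Maximum genomic gap (bases, exclusive) merged.
#' @return An object of class `hotpep_params`.
#' @export
hotpep_params <- function(min_peptide_hits = 3L, min_freq_sum = 1.0,
                          min_residues_covered = 10L,
                          merge_distance = 5800L) {
  stopifnot(min_peptide_hits > 0L, min_freq_sum > 0, min_residues_covered > 0L,
            merge_distance > 0L)
  structure(list(min_peptide_hits = as.integer(min_peptide_hits),
                 min_freq_sum = min_freq_sum,
                 min_residues_covered = as.integer(min_residues_covered),
                 merge_distance = as.integer(merge_distance)),
            class = "hotpep_params")
}

#' Score one translated frame against a subfamily peptide profile
#'
#' Finds every profile peptide present in the sequence.  Each distinct
#' peptide counts once towards `n_peptides` and contributes its subfamily
#' frequency once to `freq_sum` regardless of how often it occurs, but all
#' of its occurrence spans contribute to `residues_covered`, the size of
#' the union of covered positions.  Peptides never match across the stop
#' (`*`) or ambiguity (`X`) sentinels because profile peptides contain only
#' amino-acid letters.  Three peptides with frequencies 0.30, 0.34 and 0.62
#' give `freq_sum` 1.26; peptides at residues 110-115, 111-116 and 64-69
#' cover 7 + 6 = 13 residues.
#'
#' @param aa_seq Amino-acid sequence of the frame (character scalar).
#' @param profile Named numeric vector: peptide -> subfamily frequency.
#' @return List with `n_peptides`, `freq_sum`, `residues_covered` and
#'   `matched` (named integer list of 1-based start positions per peptide).
#' @export
score_frame <- function(aa_seq, profile) {
  stopifnot(length(profile) > 0L)
  .score_windows(.peptide_windows(aa_seq, nchar(names(profile)[1L])),
                 profile)
}

# all length-k windows of a sequence, in position order (empty if short)
.peptide_windows <- function(aa_seq, k) {
  n <- nchar(aa_seq)
  if (n < k) return(character(0))
  substring(aa_seq, 1:(n - k + 1L), k:n)
}

# score precomputed windows against a profile (see score_frame)
.score_windows <- function(w, profile) {
  k <- nchar(names(profile)[1L])
  hit_pos <- which(w %in% names(profile))
  if (length(hit_pos) == 0L) {
    return(list(n_peptides = 0L, freq_sum = 0, residues_covered = 0L,
                matched = list()))
  }
  matched <- split(hit_pos, w[hit_pos])
  covered <- unique(unlist(lapply(hit_pos, function(p) p:(p + k - 1L)),
                           use.names = FALSE))
  list(n_peptides = length(matched),
       freq_sum = sum(profile[names(matched)]),
       residues_covered = length(covered),
       matched = matched)
}

#' Test the three hit conditions
#'
#' All three must hold: peptide count at least `min_peptide_hits`,
#' frequency sum strictly greater than `min_freq_sum`, and residue
#' coverage at least `min_residues_covered`.  A score of exactly 1.0 fails
#' under the defaults.
#'
#' @param score A score list from [score_frame()] (or any list with
#'   `n_peptides`, `freq_sum`, `residues_covered`).
#' @param params A [hotpep_params()] object.
#' @return Logical scalar.
#' @export
passes_thresholds <- function(score, params = hotpep_params()) {
  score$n_peptides >= params$min_peptide_hits &&
    score$freq_sum > params$min_freq_sum &&
    score$residues_covered >= params$min_residues_covered
}

#' Pick the best subfamily among threshold-passing scores
#'
#' Returns the index (into `scores`) of the passing score with the highest
#' frequency sum; ties go to the earliest (lowest subfamily index by the
#' caller's ordering).  `NULL` when no score passes.
#'
#' @param scores List of score lists for subfamilies of one family.
#' @param params A [hotpep_params()] object.
#' @return Integer index into `scores`, or `NULL`.
#' @export
best_subfamily <- function(scores, params = hotpep_params()) {
  pass <- which(vapply(scores, passes_thresholds, logical(1), params = params))
  if (length(pass) == 0L) return(NULL)
  sums <- vapply(scores[pass], `[[`, numeric(1), "freq_sum")
  pass[which.max(sums)]
}

# Translate many fragments in six frames in one vectorized pass.
# Returns a list of six character vectors (frames "+1".."-3"), each of
# length(seqs).
.translate_frames_batch <- function(seqs) {
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  out <- vector("list", 6L)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (o in 1:3) {
    for (set_i in 1:2) {
      set <- if (set_i == 1L) dna else rc
      w <- pmax((Biostrings::width(set) - o + 1L) %/% 3L, 0L) * 3L
      sub <- Biostrings::subseq(set, start = pmin(o, Biostrings::width(set) + 1L),
                                width = w)
      out[[o + 3L * (set_i - 1L)]] <-
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
    }
  }
  out
}

# Score every subfamily profile against every frame of one fragment and
# return at most one hit row per family: best frame (max freq_sum, then
# max residues_covered, then lowest frame index), then best subfamily on
# that frame.  `frame_windows` is a named list of precomputed peptide
# window vectors, one per frame.
.fragment_hits <- function(frame_windows, profiles, params) {
  fams <- unique(vapply(profiles, `[[`, character(1), "family"))
  rows <- list()
  for (fam in fams) {
    fam_profiles <- profiles[vapply(profiles, function(p) p$family == fam,
                                    logical(1))]
    best <- NULL
    for (fi in seq_along(frame_windows)) {
      scores <- lapply(fam_profiles,
                       function(p) .score_windows(frame_windows[[fi]],
                                                  p$profile))
      bi <- best_subfamily(scores, params)
      if (is.null(bi)) next
      sc <- scores[[bi]]
      if (is.null(best) ||
          sc$freq_sum > best$score$freq_sum + 1e-12 ||
          (abs(sc$freq_sum - best$score$freq_sum) <= 1e-12 &&
           sc$residues_covered > best$score$residues_covered)) {
        best <- list(frame = names(frame_windows)[fi],
                     sub = fam_profiles[[bi]], score = sc)
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, subfamily = best$sub$index,
                   frame = best$frame,
                   n_peptides = best$score$n_peptides,
                   freq_sum = best$score$freq_sum,
                   residues_covered = best$score$residues_covered,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Annotate a genome with subfamily peptide profiles
#'
#' Contigs are filtered and split into overlapping fragments, each fragment
#' is translated in six frames, and every frame is scored against every
#' subfamily profile.  Per fragment and family at most one hit is kept (the
#' best frame and, within it, the best subfamily by frequency sum); one
#' fragment can hit several families, and scores are never compared across
#' families.  Hit spans are the fragment's genomic span.
#'
#' @param genome Named character vector of contig DNA sequences.
#' @param profiles List of subfamily profile objects (see [read_profiles()]).
#' @param params A [hotpep_params()] object.
#' @param frag_params A [fragmentation_params()] object.
#' @return data.frame of hits: `contig`, `start`, `end` (0-based half-open),
#'   `frame`, `family`, `subfamily`, `n_peptides`, `freq_sum`,
#'   `residues_covered`.
#' @export
annotate_genome <- function(genome, profiles,
                            params = hotpep_params(),
                            frag_params = fragmentation_params()) {
  stopifnot(length(profiles) > 0L)
  frags <- fragment_contigs(genome, frag_params)
  if (nrow(frags) == 0L) return(.empty_hits())
  k <- nchar(names(profiles[[1L]]$profile)[1L])
  frames6 <- .translate_frames_batch(frags$seq)
  rows <- list()
  for (i in seq_len(nrow(frags))) {
    frame_windows <- lapply(frames6, function(fr) .peptide_windows(fr[i], k))
    hits <- .fragment_hits(frame_windows, profiles, params)
    if (is.null(hits)) next
    hits <- cbind(data.frame(contig = frags$contig_id[i],
                             start = frags$start[i], end = frags$end[i],
                             stringsAsFactors = FALSE),
                  hits)
    rows[[length(rows) + 1L]] <- hits
  }
  if (length(rows) == 0L) return(.empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("contig", "start", "end", "frame", "family", "subfamily",
          "n_peptides", "freq_sum", "residues_covered")]
}

.empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             frame = character(0), family = character(0),
             subfamily = integer(0), n_peptides = integer(0),
             freq_sum = numeric(0), residues_covered = integer(0),
             stringsAsFactors = FALSE)
}

#' Annotate full-length protein sequences
#'
#' Applies the same scoring and threshold conditions as genome mode
#' directly to each amino-acid sequence, with no fragmentation and no
#' merging.  Useful for genes that fragment translation misses, e.g. genes
#' broken across assembly gaps.
#'
#' @param proteins Named character vector of protein sequences.
#' @param profiles List of subfamily profile objects.
#' @param params A [hotpep_params()] object.
#' @return data.frame of hits: `protein`, `family`, `subfamily`,
#'   `n_peptides`, `freq_sum`, `residues_covered`.
#' @export
annotate_proteins <- function(proteins, profiles,
                              params = hotpep_params()) {
  stopifnot(length(profiles) > 0L)
  rows <- list()
  k <- nchar(names(profiles[[1L]]$profile)[1L])
  fams <- unique(vapply(profiles, `[[`, character(1), "family"))
  for (pid in names(proteins)) {
    w <- .peptide_windows(proteins[[pid]], k)
    for (fam in fams) {
      fam_profiles <- profiles[vapply(profiles, function(p) p$family == fam,
                                      logical(1))]
      scores <- lapply(fam_profiles,
                       function(p) .score_windows(w, p$profile))
      bi <- best_subfamily(scores, params)
      if (is.null(bi)) next
      sc <- scores[[bi]]
      rows[[length(rows) + 1L]] <-
        data.frame(protein = pid, family = fam,
                   subfamily = fam_profiles[[bi]]$index,
                   n_peptides = sc$n_peptides, freq_sum = sc$freq_sum,
                   residues_covered = sc$residues_covered,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein = character(0), family = character(0),
                      subfamily = integer(0), n_peptides = integer(0),
                      freq_sum = numeric(0), residues_covered = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge nearby same-family hits into gene calls
#'
#' Within one contig and family, hits are chained transitively whenever the
#' gap between their genomic spans is smaller than `merge_distance`; each
#' chain becomes one gene call.  Overlapping fragments (gap <= 0) always
#' merge.  Hits in different families or on different contigs never merge.
#' The call's subfamily and scores come from the constituent hit with the
#' highest frequency sum; a chain mixing forward and reverse frames is
#' flagged `mixed_strand`.
#'
#' @param hits Hit data.frame from [annotate_genome()].
#' @param params A [hotpep_params()] object.
#' @return data.frame of gene calls: `contig`, `family`, `start`, `end`,
#'   `n_hits`, `subfamily`, `strand`, `mixed_strand`, `n_peptides`,
#'   `freq_sum`, `residues_covered`.
#' @export
merge_hits <- function(hits, params = hotpep_params()) {
  if (nrow(hits) == 0L) return(.empty_calls())
  key <- paste(hits$contig, hits$family, sep = "\r")
  rows <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    # sweep: a sorted interval starts a new chain iff its gap to the
    # running max end is >= merge_distance; equivalent to transitive
    # closure of the pairwise gap predicate on intervals
    chain <- integer(nrow(h))
    chain[1L] <- 1L
    max_end <- h$end[1L]
    for (j in seq_len(nrow(h))[-1L]) {
      gap <- h$start[j] - max_end
      chain[j] <- if (gap < params$merge_distance) chain[j - 1L]
                  else chain[j - 1L] + 1L
      max_end <- max(max_end, h$end[j])
    }
    do.call(rbind, lapply(split(seq_len(nrow(h)), chain), function(ci) {
      g <- h[ci, , drop = FALSE]
      best <- which.max(g$freq_sum)
      strands <- unique(substr(g$frame, 1L, 1L))
      data.frame(contig = g$contig[1L], family = g$family[1L],
                 start = min(g$start), end = max(g$end),
                 n_hits = nrow(g), subfamily = g$subfamily[best],
                 strand = if (length(strands) == 1L) strands else ".",
                 mixed_strand = length(strands) > 1L,
                 n_peptides = g$n_peptides[best],
                 freq_sum = g$freq_sum[best],
                 residues_covered = g$residues_covered[best],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_calls <- function() {
  data.frame(contig = character(0), family = character(0),
             start = integer(0), end = integer(0), n_hits = integer(0),
             subfamily = integer(0), strand = character(0),
             mixed_strand = logical(0), n_peptides = integer(0),
             freq_sum = numeric(0), residues_covered = integer(0),
             stringsAsFactors = FALSE)
}

#' Transfer subfamily functions to gene calls
#'
#' Each call inherits the function assigned to its subfamily (empty when
#' the subfamily is unlabeled); calls in the LPMO families AA9, AA10 and
#' AA11 are always labeled "LPMO".
#'
#' @param calls Gene-call data.frame from [merge_hits()].
#' @param profiles List of subfamily profile objects carrying `ec` fields
#'   (from [read_profiles()] or built from assigned subfamilies).
#' @return `calls` with a `fun` character column ("" when unassigned).
#' @export
transfer_function <- function(calls, profiles) {
  tab <- setNames(
    lapply(profiles, `[[`, "ec"),
    vapply(profiles, function(p) paste(p$family, p$index, sep = "\r"),
           character(1)))
  key <- paste(calls$family, calls$subfamily, sep = "\r")
  missing <- setdiff(unique(key), names(tab))
  if (length(missing) > 0L) {
    stop("unknown subfamily: ", gsub("\r", " subfamily ", missing[1L]))
  }
  fun <- vapply(key, function(k) {
    ec <- tab[[k]]
    if (length(ec) == 0L) "" else paste(ec, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  lpmo <- calls$family %in% c("AA9", "AA10", "AA11")
  fun[lpmo] <- "LPMO"
  calls$fun <- fun
  calls
}

#' Write the annotation table
#'
#' Tab-separated, one row per gene call: contig, start (1-based inclusive),
#' end, strand of the best hit, family, subfamily, n_peptides, freq_sum
#' (4 decimals), residues_covered, function.
#'
#' @param calls Gene-call data.frame with a `fun` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(calls, path) {
  out <- data.frame(contig = calls$contig, start = calls$start + 1L,
                    end = calls$end, strand = calls$strand,
                    family = calls$family, subfamily = calls$subfamily,
                    n_peptides = calls$n_peptides,
                    freq_sum = sprintf("%.4f", calls$freq_sum),
                    residues_covered = calls$residues_covered,
                    fun = ifelse(calls$fun == "", "-", calls$fun),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write gene calls as GFF3
#'
#' One `gene_call` feature per call with `Family`, `Subfamily` and `EC`
#' attributes.
#'
#' @param calls Gene-call data.frame with a `fun` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(calls) > 0L) {
    attrs <- sprintf("ID=call%d;Family=%s;Subfamily=%d;EC=%s",
                     seq_len(nrow(calls)), calls$family, calls$subfamily,
                     ifelse(calls$fun == "", "-", calls$fun))
    writeLines(paste(calls$contig, "hotpepr", "gene_call",
                     calls$start + 1L, calls$end, ".",
                     ifelse(calls$strand == ".", ".", calls$strand),
                     ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
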