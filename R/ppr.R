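# Peptide Pattern Recognition (PPR): partition a protein family into
# subfamilies defined by shared lists of conserved hexapeptides, and label
# subfamilies with EC functions from characterized members.
#
# A conserved peptide is one present in at least `conservation_threshold`
# (default 20%) of a group's members; a group keeps at most `list_size`
# (default 70) such peptides, and a protein belongs to a group when it
# carries at least `min_peptides_per_protein` (default 10) of them.

#' PPR parameters
#'
#' Defaults are the empirically optimal settings for function prediction in
#' glycoside hydrolase families: hexapeptides, 70 peptides per list, 10
#' peptides per protein, a 20% conservation threshold, and groups of at
#' least five proteins.
#'
#' @param peptide_length Peptide window length in residues.
#' @param list_size Maximum number of conserved peptides kept per subfamily.
#' @param min_peptides_per_protein Minimum profile peptides a protein must
#'   carry to be a subfamily member.
#' @param conservation_threshold Minimum fraction of group members a peptide
#'   must occur in to be conserved.
#' @param min_group_size Smallest group reported as a subfamily.
#' @param max_iterations Bound on the profile/membership alternation.
#' @param n_seeds Number of top shared peptides used to seed candidate
#'   groups.
#' @return An object of class `ppr_params`.
#' @export
ppr_params <- function(peptide_length = 6L, list_size = 70L,
                       min_peptides_per_protein = 10L,
                       conservation_threshold = 0.20,
                       min_group_size = 5L, max_iterations = 100L,
                       n_seeds = 50L) {
  stopifnot(conservation_threshold > 0, conservation_threshold <= 1,
            min_peptides_per_protein <= list_size, min_group_size >= 2L)
  structure(list(peptide_length = as.integer(peptide_length),
                 list_size = as.integer(list_size),
                 min_peptides_per_protein = as.integer(min_peptides_per_protein),
                 conservation_threshold = conservation_threshold,
                 min_group_size = as.integer(min_group_size),
                 max_iterations = as.integer(max_iterations),
                 n_seeds = as.integer(n_seeds)),
            class = "ppr_params")
}

#' Extract the distinct k-mer peptides of a protein
#'
#' Returns the presence set of all length-`k` windows of the sequence.
#' Windows containing a letter outside the 20 standard amino acids (stops,
#' ambiguity codes) are excluded.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param k Peptide length in residues.
#' @return Character vector of distinct peptides (empty if the sequence is
#'   shorter than `k`).
#' @export
extract_peptides <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1L), k:n)
  w <- unique(w)
  w[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", w)]
}

# Presence sets for a vector of sequences, computed once per family.
.peptide_sets <- function(seqs, k) {
  lapply(seqs, extract_peptides, k = k)
}

.profile_from_sets <- function(sets, params) {
  n <- length(sets)
  counts <- table(unlist(sets, use.names = FALSE))
  freq <- as.numeric(counts) / n
  peps <- names(counts)
  keep <- freq >= params$conservation_threshold
  peps <- peps[keep]
  freq <- freq[keep]
  ord <- order(-freq, peps)
  ord <- ord[seq_len(min(length(ord), params$list_size))]
  setNames(freq[ord], peps[ord])
}

#' Build a conserved-peptide profile for a group of proteins
#'
#' Computes the presence frequency of every peptide across the group
#' (fraction of members containing it at least once), drops peptides below
#' the conservation threshold, and keeps the `list_size` most frequent of
#' the rest.  Ties are broken by frequency descending, then lexicographic
#' peptide order.  A candidate list of 70 peptides in which one occurs in
#' only 15% of members therefore yields a 69-peptide profile at the default
#' 20% threshold.
#'
#' @param seqs Character vector of member amino-acid sequences.
#' @param params A [ppr_params()] object.
#' @return Named numeric vector: peptide -> frequency in (0, 1], sorted by
#'   frequency descending then peptide.
#' @export
build_profile <- function(seqs, params = ppr_params()) {
  stopifnot(length(seqs) > 0L)
  .profile_from_sets(.peptide_sets(seqs, params$peptide_length), params)
}

# Count, for every protein index in `sets`, how many of `peps` it carries.
.profile_hits <- function(sets, index, peps) {
  vapply(index, function(i) sum(sets[[i]] %in% peps), integer(1))
}

# Alternate profile building and membership testing from one seed member
# set until a fixed point (or oscillation cutoff).  `pool` are the indices
# of proteins still unassigned.  Returns integer member indices or NULL.
.fixed_point_group <- function(sets, pool, seed_members, params) {
  members <- sort(seed_members)
  prev <- integer(0)
  for (it in seq_len(params$max_iterations)) {
    if (length(members) == 0L) return(NULL)
    profile <- .profile_from_sets(sets[members], params)
    hits <- .profile_hits(sets, pool, names(profile))
    nxt <- sort(pool[hits >= params$min_peptides_per_protein])
    if (identical(nxt, members)) {
      return(list(members = members, profile = profile))
    }
    prev <- members
    members <- nxt
  }
  # did not converge: take the smaller of the last two member sets
  members <- if (length(prev) > 0L && length(prev) < length(members)) prev else members
  if (length(members) == 0L) return(NULL)
  list(members = members, profile = .profile_from_sets(sets[members], params))
}

#' Find the largest peptide-coherent group in a family
#'
#' Seeds one candidate group from each of the most widely shared peptides
#' (all proteins containing that peptide), then alternates profile
#' construction and membership testing to a fixed point; the largest fixed
#' point wins.  Ties go to the candidate with the higher total profile
#' frequency, then to the lexicographically smallest member-id tuple.
#' Returns `NULL` when no candidate reaches `min_group_size` members.
#'
#' @param seqs Named character vector of unassigned family proteins.
#' @param params A [ppr_params()] object.
#' @return `NULL`, or a list with `members` (ids), `profile` (named numeric
#'   vector) and `sizes` bookkeeping.
#' @export
find_largest_group <- function(seqs, params = ppr_params()) {
  if (length(seqs) < params$min_group_size) return(NULL)
  sets <- .peptide_sets(seqs, params$peptide_length)
  grp <- .find_largest_group_sets(sets, seq_along(seqs), params)
  if (is.null(grp)) return(NULL)
  list(members = names(seqs)[grp$members], profile = grp$profile)
}

.find_largest_group_sets <- function(sets, pool, params) {
  counts <- table(unlist(sets[pool], use.names = FALSE))
  ord <- order(-as.numeric(counts), names(counts))
  seed_peps <- names(counts)[ord[seq_len(min(params$n_seeds, length(ord)))]]
  best <- NULL
  for (pep in seed_peps) {
    carriers <- pool[vapply(pool, function(i) pep %in% sets[[i]], logical(1))]
    cand <- .fixed_point_group(sets, pool, carriers, params)
    if (is.null(cand) || length(cand$members) < params$min_group_size) next
    if (is.null(best)) { best <- cand; next }
    nb <- length(best$members); nc <- length(cand$members)
    if (nc > nb) { best <- cand; next }
    if (nc == nb) {
      sb <- sum(best$profile); sc <- sum(cand$profile)
      if (sc > sb + 1e-12) { best <- cand; next }
      if (abs(sc - sb) <= 1e-12 &&
          paste(cand$members, collapse = "\r") <
          paste(best$members, collapse = "\r")) best <- cand
    }
  }
  best
}

#' Partition a protein family into peptide-defined subfamilies
#'
#' Repeatedly extracts the largest remaining group with
#' [find_largest_group()]: the first group is subfamily 1, the largest
#' group among proteins not in subfamily 1 is subfamily 2, and so on until
#' fewer than `min_group_size` proteins can be grouped.  Member sets are
#' pairwise disjoint; proteins never grouped are reported as ungrouped.
#'
#' @param seqs Named character vector of family protein sequences.
#' @param params A [ppr_params()] object.
#' @param family_name Family label stamped on each subfamily (e.g. "GH5").
#' @return List with `subfamilies` (list of objects with `family`, `index`,
#'   `members`, `profile`) and `ungrouped` (character vector of ids).
#' @export
partition_family <- function(seqs, params = ppr_params(),
                             family_name = "FAM") {
  stopifnot(!is.null(names(seqs)) || length(seqs) == 0L)
  if (anyDuplicated(names(seqs))) stop("duplicate protein ids in family")
  sets <- .peptide_sets(seqs, params$peptide_length)
  pool <- seq_along(seqs)
  subfamilies <- list()
  idx <- 0L
  while (length(pool) >= params$min_group_size) {
    grp <- .find_largest_group_sets(sets, pool, params)
    if (is.null(grp)) break
    idx <- idx + 1L
    subfamilies[[idx]] <- list(family = family_name, index = idx,
                               members = names(seqs)[grp$members],
                               profile = grp$profile,
                               ec = character(0), majority_ec = NA_character_,
                               ambiguous = FALSE)
    pool <- setdiff(pool, grp$members)
  }
  list(subfamilies = subfamilies, ungrouped = names(seqs)[pool])
}

#' Assign an enzymatic function to a subfamily
#'
#' The subfamily inherits the union of its members' EC labels; the majority
#' label is the most frequent EC among labeled members (all tied ECs are
#' reported and the subfamily flagged ambiguous on a tie).  Subfamilies with
#' no labeled member keep an empty function set.  Subfamilies of the LPMO
#' families AA9, AA10 and AA11 are always labeled "LPMO".
#'
#' @param subfamily A subfamily object from [partition_family()].
#' @param ec_labels Named list: protein id -> character vector of EC
#'   numbers (may omit unlabeled proteins).
#' @return The subfamily with `ec`, `majority_ec` and `ambiguous` filled in.
#' @export
assign_function <- function(subfamily, ec_labels = list()) {
  labs <- ec_labels[intersect(subfamily$members, names(ec_labels))]
  labs <- labs[vapply(labs, length, integer(1)) > 0L]
  if (subfamily$family %in% c("AA9", "AA10", "AA11")) {
    subfamily$ec <- unique(c("LPMO", unlist(labs, use.names = FALSE)))
    subfamily$majority_ec <- "LPMO"
    return(subfamily)
  }
  if (length(labs) == 0L) {
    subfamily$ec <- character(0)
    subfamily$majority_ec <- NA_character_
    return(subfamily)
  }
  all_ecs <- unlist(labs, use.names = FALSE)
  bad <- !grepl("^\\d+\\.\\d+\\.\\d+\\.(\\d+|-)$", all_ecs)
  if (any(bad)) stop("malformed EC label: ", all_ecs[bad][1L])
  counts <- sort(table(all_ecs), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  subfamily$ec <- sort(unique(all_ecs))
  subfamily$majority_ec <- paste(sort(top), collapse = ";")
  subfamily$ambiguous <- length(top) > 1L
  subfamily
}

#' Read a sidecar EC annotation table
#'
#' Tab-separated file with two columns: protein id and a semicolon-separated
#' list of EC numbers.  Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return Named list: protein id -> character vector of ECs.
#' @export
read_ec_annotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("id", "ec"),
                           colClasses = "character")
  setNames(strsplit(tab$ec, ";", fixed = TRUE), tab$id)
}

# ---- Subfamily peptide-profile files -------------------------------------
# One file per subfamily.  Line 1 holds four tab-separated fields:
# family, subfamily index, number of members, function (semicolon-joined
# ECs, "LPMO", or "-").  Every following line is "peptide<TAB>frequency"
# with the frequency printed to 4 decimals.  These files are the contract
# consumed by the Hotpep annotator.

#' Write subfamily peptide profiles to a directory
#'
#' @param subfamilies List of subfamily objects (see [partition_family()],
#'   optionally after [assign_function()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_profiles <- function(subfamilies, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(subfamilies, function(sf) {
    fun <- if (length(sf$ec) == 0L) "-" else paste(sf$ec, collapse = ";")
    path <- file.path(dir, sprintf("%s_subfam%d.txt", sf$family, sf$index))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(sf$family, sf$index, length(sf$members), fun,
                     sep = "\t"), con)
    writeLines(sprintf("%s\t%.4f", names(sf$profile), sf$profile), con)
    path
  }, character(1))
  invisible(paths)
}

#' Read subfamily peptide profiles
#'
#' Reads all `*_subfam*.txt` profile files in a directory (or an explicit
#' vector of file paths) into the structure used by the annotator.
#'
#' @param dir Directory containing profile files, or a character vector of
#'   file paths.
#' @return List of profile objects, each with `family`, `index`,
#'   `n_members`, `ec` (character vector, empty if unassigned) and
#'   `profile` (named numeric vector).
#' @export
read_profiles <- function(dir) {
  paths <- if (length(dir) == 1L && dir.exists(dir)) {
    sort(list.files(dir, pattern = "_subfam[0-9]+\\.txt$", full.names = TRUE))
  } else dir
  out <- lapply(paths, function(path) {
    if (!file.exists(path)) stop("profile file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 2L) stop("malformed profile file: ", path)
    head <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(head) != 4L) stop("malformed profile header in ", path)
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    if (any(lengths(body) != 2L)) stop("malformed peptide line in ", path)
    peps <- vapply(body, `[`, character(1), 1L)
    freqs <- as.numeric(vapply(body, `[`, character(1), 2L))
    if (anyNA(freqs)) stop("non-numeric frequency in ", path)
    list(family = head[1L], index = as.integer(head[2L]),
         n_members = as.integer(head[3L]),
         ec = if (head[4L] == "-") character(0)
              else strsplit(head[4L], ";", fixed = TRUE)[[1L]],
         profile = setNames(freqs, peps))
  })
  # subfamily-index order within family, so score ties resolve to the
  # lower (earlier-discovered, larger) subfamily
  out[order(vapply(out, `[[`, character(1), "family"),
            vapply(out, `[[`, integer(1), "index"))]
}
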