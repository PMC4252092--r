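# Independent oracles and small generators shared across the test files.
# Every oracle here is written from first principles so it never shares a
# code path (or a library call) with the implementation it checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent codon-table translation oracle ---------------------------
# Hand-written standard genetic code; the implementation translates through
# Biostrings, so agreement is a genuine cross-check.
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  codons <- c()
  for (b1 in bases) for (b2 in bases) for (b3 in bases)
    codons <- c(codons, paste0(b1, b2, b3))
  setNames(aa, codons)
})

oracle_translate <- function(dna, offset = 1L) {
  n <- nchar(dna)
  naa <- (n - offset + 1L) %/% 3L
  if (naa <= 0L) return("")
  starts <- offset + 3L * (seq_len(naa) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- ifelse(codons %in% names(CODON_TABLE), CODON_TABLE[codons], "X")
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(dna, "", fixed = TRUE)[[1]])
  paste(comp[chars], collapse = "")
}

# --- brute-force window enumeration ---------------------------------------
oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in 1:(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("[^ACDEFGHIKLMNPQRSTVWY]", w) && !(w %in% out))
      out <- c(out, w)
  }
  out
}

# --- brute-force conserved-profile oracle ---------------------------------
oracle_profile <- function(seqs, threshold = 0.20, list_size = 70L, k = 6L) {
  all_peps <- unique(unlist(lapply(seqs, oracle_kmers, k = k)))
  freq <- vapply(all_peps, function(p) {
    mean(vapply(seqs, function(s) grepl(p, s, fixed = TRUE), logical(1)))
  }, numeric(1))
  keep <- freq >= threshold
  freq <- freq[keep]
  ord <- order(-freq, names(freq))
  freq[ord][seq_len(min(list_size, sum(keep)))]
}

# --- O(n^2) transitive-closure merge oracle -------------------------------
# Chains hits whose spans are closer than `d`, by repeated expansion of an
# explicit adjacency matrix within each (contig, family).
oracle_merge_components <- function(hits, d) {
  key <- paste(hits$contig, hits$family)
  comp <- integer(nrow(hits))
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    n <- length(idx)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(hits$start[idx[i]], hits$start[idx[j]]) -
        min(hits$end[idx[i]], hits$end[idx[j]])
      adj[i, j] <- gap < d
    }
    reach <- adj
    for (step in seq_len(n)) reach <- reach | (reach %*% adj > 0)
    assigned <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (is.na(assigned[i])) {
        next_id <- next_id + 1L
        assigned[which(reach[i, ])] <- next_id
      }
    }
    comp[idx] <- assigned
  }
  comp
}

# --- textbook Ward agglomeration oracle -----------------------------------
# Greedy merging that recomputes the within-cluster variance increase from
# raw coordinates at every step; heights follow sqrt(2 * deltaESS), the
# scale of Ward linkage on Euclidean distances.
oracle_ward <- function(x) {
  cl <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  clades <- list()
  while (length(cl) > 1) {
    best <- NULL
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      ci <- colMeans(x[cl[[i]], , drop = FALSE])
      cj <- colMeans(x[cl[[j]], , drop = FALSE])
      ni <- length(cl[[i]]); nj <- length(cl[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
    }
    heights <- c(heights, sqrt(2 * best$d))
    merged <- sort(c(cl[[best$i]], cl[[best$j]]))
    clades <- c(clades, list(merged))
    cl <- c(cl[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, clades = clades)
}

hclust_clades <- function(hc) {
  members <- list()
  clades <- list()
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    merged <- sort(c(get(hc$merge[m, 1]), get(hc$merge[m, 2])))
    members[[m]] <- merged
    clades[[m]] <- merged
  }
  clades
}

# --- misc -----------------------------------------------------------------
# one protein sequence containing the given peptides at given 1-based
# positions over a fixed background (positions must not collide)
place_peptides <- function(length, placements, background_alphabet = AA20) {
  s <- paste(sample(background_alphabet, length, replace = TRUE),
             collapse = "")
  for (i in seq_along(placements$pep)) {
    substr(s, placements$pos[i],
           placements$pos[i] + nchar(placements$pep[i]) - 1L) <-
      placements$pep[i]
  }
  s
}

match_calls_to_truth <- function(calls, truth) {
  ok <- logical(nrow(truth))
  used <- integer(0)
  for (i in seq_len(nrow(truth))) {
    m <- which(calls$contig == truth$contig[i] &
                 calls$family == truth$family[i] &
                 calls$start < truth$end[i] & calls$end > truth$start[i])
    ok[i] <- length(m) == 1L
    used <- c(used, m)
  }
  list(recovered = ok, n_false = nrow(calls) - length(unique(used)))
}
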