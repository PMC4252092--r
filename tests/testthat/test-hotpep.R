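# Hotpep scoring, thresholds, hit calling, merging and function transfer.

worked_profile <- c(FGTFHL = 0.30, GTFHLY = 0.34, YIKSLD = 0.62)

# background alphabet without F/G/T/H/L/Y/I/K/S/D cannot spawn accidental
# copies of the worked-example peptides
SAFE_BG <- setdiff(AA20, c("F", "G", "T", "H", "L", "Y", "I", "K", "S", "D"))

worked_sequence <- function() {
  s <- paste(rep("A", 150), collapse = "")
  substr(s, 64, 69) <- "YIKSLD"
  substr(s, 110, 116) <- "FGTFHLY"  # FGTFHL at 110, GTFHLY at 111
  s
}

test_that("frequency scores and residue coverage follow the worked examples", {
  sc <- score_frame(worked_sequence(), worked_profile)
  expect_equal(sc$n_peptides, 3)
  expect_equal(sc$freq_sum, 0.30 + 0.34 + 0.62)  # 1.26
  expect_equal(sc$residues_covered, 13)          # 7 overlapping + 6

  # the two overlapping peptides alone cover 7 residues
  sc2 <- score_frame(worked_sequence(), worked_profile[c("FGTFHL", "GTFHLY")])
  expect_equal(sc2$residues_covered, 7)
  expect_equal(sc2$freq_sum, 0.64)

  # no shared peptide: all-zero score
  sc0 <- score_frame(paste(rep("W", 50), collapse = ""), worked_profile)
  expect_equal(unlist(sc0[c("n_peptides", "freq_sum", "residues_covered")]),
               c(n_peptides = 0, freq_sum = 0, residues_covered = 0))
})

test_that("repeated peptide occurrences count once in the score but add coverage", {
  s <- paste0(paste(rep("A", 10), collapse = ""), "FGTFHL",
              paste(rep("A", 10), collapse = ""), "FGTFHL",
              paste(rep("A", 10), collapse = ""))
  sc <- score_frame(s, worked_profile)
  expect_equal(sc$n_peptides, 1)
  expect_equal(sc$freq_sum, 0.30)
  expect_equal(sc$residues_covered, 12)

  # score additivity: dropping a matched peptide removes exactly its weight
  sc_full <- score_frame(worked_sequence(), worked_profile)
  sc_less <- score_frame(worked_sequence(), worked_profile[-3])
  expect_equal(sc_full$freq_sum - sc_less$freq_sum,
               unname(worked_profile[3]))
})

test_that("peptides never match across the stop sentinel", {
  s <- paste0("AAAFGT", "*", "FHLAAA")
  sc <- score_frame(s, worked_profile)
  expect_equal(sc$n_peptides, 0)
})

test_that("coverage of three distinct single-occurrence hexapeptides stays in [8, 18]", {
  set.seed(101)
  covs <- integer(0)
  for (rep in 1:400) {
    starts <- sort(sample(1:40, 3))
    s <- paste(sample(SAFE_BG, 60, replace = TRUE), collapse = "")
    peps <- c("FGTFHL", "GTFHLY", "YIKSLD")
    ok <- TRUE
    for (i in 3:1) substr(s, starts[i], starts[i] + 5) <- peps[i]
    # overwriting may erase an earlier peptide; require all three intact
    # exactly once each
    counts <- vapply(peps, function(p) {
      length(gregexpr(p, s, fixed = TRUE)[[1]][gregexpr(p, s, fixed = TRUE)[[1]] > 0])
    }, integer(1))
    if (!all(counts == 1)) next
    sc <- score_frame(s, worked_profile)
    expect_equal(sc$n_peptides, 3)
    expect_gte(sc$residues_covered, 8)
    expect_lte(sc$residues_covered, 18)
    covs <- c(covs, sc$residues_covered)
  }
  # the analytic extremes are attained by maximal overlap and disjoint
  # placement
  tight <- paste0("FGTFHLYIKSLD")  # not 3 distinct here; build explicitly
  s_min <- paste(sample(SAFE_BG, 30, replace = TRUE), collapse = "")
  prof3 <- c(AAAAAA = 0.4, AAAAAC = 0.4, AAAACC = 0.4)
  substr(s_min, 10, 17) <- "AAAAAACC"  # windows at 10, 11, 12
  expect_equal(score_frame(s_min, prof3)$residues_covered, 8)
  s_max <- paste(sample(SAFE_BG, 40, replace = TRUE), collapse = "")
  substr(s_max, 1, 6) <- "FGTFHL"
  substr(s_max, 10, 15) <- "GTFHLY"
  substr(s_max, 20, 25) <- "YIKSLD"
  expect_equal(score_frame(s_max, worked_profile)$residues_covered, 18)
})

test_that("a hit requires all three threshold conditions, score strictly above 1", {
  params <- hotpep_params()
  mk <- function(n, s, c) list(n_peptides = n, freq_sum = s,
                               residues_covered = c)
  for (n in c(2, 3)) for (s in c(1.0, 1.26)) for (cv in c(9, 13)) {
    expect_identical(passes_thresholds(mk(n, s, cv), params),
                     n >= 3 && s > 1.0 && cv >= 10)
  }
})

test_that("the best subfamily maximizes the frequency score among passers", {
  params <- hotpep_params()
  s1 <- list(n_peptides = 3, freq_sum = 1.26, residues_covered = 13)
  s2 <- list(n_peptides = 5, freq_sum = 2.10, residues_covered = 25)
  expect_equal(best_subfamily(list(s1, s2), params), 2)
  fail <- list(n_peptides = 2, freq_sum = 3.0, residues_covered = 30)
  expect_null(best_subfamily(list(fail), params))
  # argmax equals an exhaustive scan over random passing scores
  set.seed(111)
  for (rep in 1:20) {
    scores <- lapply(1:10, function(i) {
      list(n_peptides = sample(3:8, 1),
           freq_sum = round(runif(1, 1.01, 4), 6),
           residues_covered = sample(10:40, 1))
    })
    sums <- vapply(scores, `[[`, numeric(1), "freq_sum")
    expect_equal(best_subfamily(scores, params), which.max(sums))
  }
})

test_that("hit merging chains same-family neighbors and matches the closure oracle", {
  params <- hotpep_params()
  base <- data.frame(contig = "c1", family = "GH5", subfamily = 1L,
                     frame = "+1", n_peptides = 10L, freq_sum = 3,
                     residues_covered = 60, stringsAsFactors = FALSE)
  two <- rbind(cbind(base, start = 0L, end = 2000L),
               cbind(base, start = 1900L, end = 3900L))
  expect_equal(nrow(merge_hits(two, params)), 1)

  far <- two
  far$start[2] <- 8000L; far$end[2] <- 10000L
  expect_equal(nrow(merge_hits(far, params)), 2)

  # different families never merge
  mixed <- two
  mixed$family[2] <- "GH7"
  expect_equal(nrow(merge_hits(mixed, params)), 2)

  # random hit sets versus O(n^2) transitive-closure oracle
  set.seed(121)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    starts <- sample(0:40000, n) %/% 100 * 100
    hits <- data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
                       family = sample(c("GH5", "GH7"), n, replace = TRUE),
                       subfamily = 1L, frame = "+1",
                       start = starts, end = starts + 2000L,
                       n_peptides = sample(3:20, n, replace = TRUE),
                       freq_sum = runif(n, 1.1, 5),
                       residues_covered = sample(10:60, n, replace = TRUE),
                       stringsAsFactors = FALSE)
    comp <- oracle_merge_components(hits, params$merge_distance)
    calls <- merge_hits(hits, params)
    expect_equal(nrow(calls), length(unique(comp)))
    # every oracle component corresponds to one call spanning its hits
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      m <- calls$contig == hits$contig[idx[1]] &
        calls$family == hits$family[idx[1]] &
        calls$start == min(hits$start[idx]) &
        calls$end == max(hits$end[idx])
      expect_equal(sum(m), 1)
      expect_equal(calls$n_hits[which(m)], length(idx))
    }
  }
})

test_that("gene calls inherit the best constituent hit and its subfamily", {
  params <- hotpep_params()
  hits <- data.frame(contig = "c1", family = "GH5",
                     subfamily = c(1L, 2L), frame = c("+1", "-2"),
                     start = c(0L, 1900L), end = c(2000L, 3900L),
                     n_peptides = c(5L, 9L), freq_sum = c(1.5, 3.2),
                     residues_covered = c(20L, 50L),
                     stringsAsFactors = FALSE)
  call <- merge_hits(hits, params)
  expect_equal(nrow(call), 1)
  expect_equal(call$subfamily, 2L)
  expect_equal(call$freq_sum, 3.2)
  expect_true(call$mixed_strand)
  expect_identical(call$strand, ".")
})

test_that("functions transfer from the subfamily table, LPMO families forced", {
  profiles <- list(
    list(family = "GH3", index = 1L, n_members = 10L, ec = "3.2.1.21",
         profile = c(AAAAAA = 1)),
    list(family = "GH3", index = 2L, n_members = 8L, ec = character(0),
         profile = c(CCCCCC = 1)),
    list(family = "AA9", index = 4L, n_members = 6L, ec = character(0),
         profile = c(DDDDDD = 1)))
  calls <- data.frame(contig = "c1", family = c("GH3", "GH3", "AA9"),
                      start = c(0L, 9000L, 20000L),
                      end = c(2000L, 11000L, 22000L),
                      n_hits = 1L, subfamily = c(1L, 2L, 4L),
                      strand = "+", mixed_strand = FALSE, n_peptides = 5L,
                      freq_sum = 2, residues_covered = 30L,
                      stringsAsFactors = FALSE)
  got <- transfer_function(calls, profiles)
  expect_identical(got$fun, c("3.2.1.21", "", "LPMO"))
  bad <- calls
  bad$subfamily[1] <- 9L
  expect_error(transfer_function(bad, profiles), "unknown subfamily")
})

test_that("genome annotation finds planted genes and ignores intergenic DNA", {
  set.seed(131)
  fam <- generate_family(plant_spec(1, 15, 70, 1.0, 500, 0))
  part <- partition_family(fam$proteins, family_name = "GH5")
  profiles <- part$subfamilies
  genes <- data.frame(protein_id = "g1", family = "GH5", subfamily = 1L,
                      seq = unname(fam$proteins[1]),
                      stringsAsFactors = FALSE)
  gn <- generate_genome(genome_spec(genes))
  hits <- annotate_genome(gn$contigs, profiles)
  expect_gte(nrow(hits), 1)
  expect_true(all(hits$family == "GH5" & hits$subfamily == 1))
  calls <- merge_hits(hits)
  expect_equal(nrow(calls), 1)
  expect_lt(calls$start, gn$truth$end)
  expect_gt(calls$end, gn$truth$start)

  # pure intergenic DNA yields nothing at the default thresholds
  noise <- setNames(random_dna(20000), "noise1")
  expect_equal(nrow(annotate_genome(noise, profiles)), 0)
})

test_that("a two-domain fragment is reported once per family, never compared across", {
  set.seed(141)
  # two families whose members share no vocabulary; one gene carries a
  # domain of each
  famA <- generate_family(plant_spec(1, 10, 40, 1.0, 280, 0))
  famB <- generate_family(plant_spec(1, 10, 40, 1.0, 280, 0))
  profs <- c(partition_family(famA$proteins, family_name = "GH43")$subfamilies,
             partition_family(famB$proteins, family_name = "GH10")$subfamilies)
  fused <- paste0(famA$proteins[1], famB$proteins[1])
  cds <- paste0("ATG", reverse_translate(fused), "TAA")
  contig <- setNames(paste0(random_dna(300), cds, random_dna(300)), "c1")
  hits <- annotate_genome(contig, profs)
  expect_setequal(hits$family, c("GH43", "GH10"))
  frag_key <- paste(hits$contig, hits$start)
  # at most one hit per family on any fragment
  expect_false(any(duplicated(paste(frag_key, hits$family))))
})

test_that("protein mode applies the same thresholds without fragmentation", {
  set.seed(151)
  fam <- generate_family(plant_spec(1, 12, 70, 1.0, 500, 0))
  part <- partition_family(fam$proteins, family_name = "GH7")
  profiles <- part$subfamilies
  hits <- annotate_proteins(fam$proteins[1], profiles)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$family, "GH7")

  # a 6-residue protein equal to one profile peptide fails (one peptide)
  pep <- names(profiles[[1]]$profile)[1]
  expect_equal(nrow(annotate_proteins(setNames(pep, "tiny"), profiles)), 0)

  # residue-composition-preserving shuffles almost never pass
  s <- strsplit(unname(fam$proteins[1]), "")[[1]]
  n_pass <- 0
  for (i in 1:50) {
    shuf <- setNames(paste(sample(s), collapse = ""), "shuf")
    n_pass <- n_pass + nrow(annotate_proteins(shuf, profiles))
  }
  expect_lte(n_pass, 2)
})

test_that("genome-mode detections are confirmed in protein mode", {
  set.seed(161)
  fam <- generate_family(plant_spec(1, 10, 70, 1.0, 500, 0))
  part <- partition_family(fam$proteins, family_name = "GH5")
  genes <- data.frame(protein_id = "g1", family = "GH5", subfamily = 1L,
                      seq = unname(fam$proteins[3]),
                      stringsAsFactors = FALSE)
  gn <- generate_genome(genome_spec(genes))
  gcalls <- merge_hits(annotate_genome(gn$contigs, part$subfamilies))
  pcalls <- annotate_proteins(fam$proteins[3], part$subfamilies)
  expect_equal(nrow(gcalls), 1)
  expect_equal(nrow(pcalls), 1)
  expect_identical(gcalls$family, pcalls$family)
  expect_identical(gcalls$subfamily, pcalls$subfamily)
})

test_that("shifting a planted gene across the fragment grid keeps the call", {
  set.seed(171)
  fam <- generate_family(plant_spec(1, 10, 70, 1.0, 500, 0))
  part <- partition_family(fam$proteins, family_name = "GH5")
  cds <- paste0("ATG", reverse_translate(unname(fam$proteins[1])), "TAA")
  for (shift in c(0, 500, 950, 1400, 1880)) {
    contig <- setNames(paste0(random_dna(1000 + shift), cds,
                              random_dna(1500)), "c1")
    calls <- merge_hits(annotate_genome(contig, part$subfamilies))
    expect_equal(nrow(calls), 1)
    expect_identical(calls$family, "GH5")
    expect_identical(calls$subfamily, 1L)
  }
})

test_that("annotation tables and GFF3 use 1-based coordinates", {
  calls <- data.frame(contig = "c1", family = "GH5", start = 1900L,
                      end = 3900L, n_hits = 2L, subfamily = 1L,
                      strand = "+", mixed_strand = FALSE, n_peptides = 12L,
                      freq_sum = 3.25, residues_covered = 70L,
                      fun = "3.2.1.4", stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(calls, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$start, 1901)
  expect_equal(tab$end, 3900)
  expect_identical(tab$freq_sum, 3.25)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(calls, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[3], "gene_call")
  expect_identical(fields[4], "1901")
  expect_match(fields[9], "Family=GH5")
  expect_match(fields[9], "EC=3.2.1.4")
})
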