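Package: hotpepr
Title: Peptide-Pattern Subfamily Discovery and CAZyme Gene Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers peptide-defined subfamilies within carbohydrate-active
    enzyme (CAZyme) protein families by Peptide Pattern Recognition (PPR):
    greedy extraction of the largest group of proteins sharing at least 10 of
    up to 70 conserved hexapeptides, repeated until fewer than five proteins
    can be grouped.  Annotates glycoside hydrolase (GH) and lytic
    polysaccharide monooxygenase (LPMO) genes in genome assemblies by the
    Hotpep procedure: contigs are split into overlapping fragments, translated
    in six reading frames, scored against subfamily peptide lists by peptide
    count, frequency-sum and residue coverage, and nearby same-family hits are
    merged into gene calls with functions (EC numbers) transferred from
    characterized subfamily members.  Includes per-genome enzyme-profile
    construction with Ward hierarchical clustering, and generators for
    planted-structure synthetic protein families and genomes used to
    benchmark recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
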