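# Genome-level enzyme profiles: per-family and per-function gene counts,
# count matrices across genomes, Ward hierarchical clustering, and
# activity-class summaries (cellulose / hemicellulose / other).

#' Summarize one genome's gene calls into an enzyme profile
#'
#' Counts gene calls per family and per predicted function.  Calls with an
#' empty function contribute to `n_total` only.  A multi-family fragment
#' yields one call per family and is therefore counted once in each.
#'
#' @param calls Gene-call data.frame (with a `fun` column from
#'   [transfer_function()]).
#' @param genome_id Identifier for the genome.
#' @return An object of class `genome_profile`: list with `genome_id`,
#'   `family_counts`, `function_counts` (named integer vectors), `n_total`
#'   and `n_assigned_function`.
#' @export
genome_profile <- function(calls, genome_id) {
  fam <- table(calls$family)
  fun_labels <- calls$fun[!is.na(calls$fun) & calls$fun != ""]
  fun <- table(fun_labels)
  structure(list(genome_id = genome_id,
                 family_counts = setNames(as.integer(fam), names(fam)),
                 function_counts = setNames(as.integer(fun), names(fun)),
                 n_total = nrow(calls),
                 n_assigned_function = length(fun_labels)),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("Genome profile:", x$genome_id, "\n")
  cat("  gene calls:", x$n_total, "(", x$n_assigned_function,
      "with predicted function )\n")
  cat("  families:", paste0(names(x$family_counts), ":",
                            x$family_counts, collapse = " "), "\n")
  invisible(x)
}

#' Build a genomes-by-features count matrix
#'
#' Columns are the union of features (families or functions) observed in
#' any profile, missing counts are zero, and row order follows the input.
#'
#' @param profiles List of [genome_profile()] objects.
#' @param mode `"families"` or `"functions"`.
#' @return Integer matrix with genome ids as row names.
#' @export
profile_matrix <- function(profiles, mode = c("families", "functions")) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= 2L)
  field <- if (mode == "families") "family_counts" else "function_counts"
  feats <- sort(unique(unlist(lapply(profiles,
                                     function(p) names(p[[field]])))))
  m <- matrix(0L, nrow = length(profiles), ncol = length(feats),
              dimnames = list(vapply(profiles, `[[`, character(1),
                                     "genome_id"),
                              feats))
  for (i in seq_along(profiles)) {
    cnt <- profiles[[i]][[field]]
    m[i, names(cnt)] <- cnt
  }
  m
}

#' Ward hierarchical clustering of genome profiles
#'
#' Agglomerative Ward minimum-variance clustering on Euclidean distances
#' between count rows (optionally normalized to row proportions).
#' Deterministic for fixed input.
#'
#' @param m Genomes-by-features count matrix from [profile_matrix()].
#' @param normalize Divide each row by its sum before clustering.
#' @return An [stats::hclust] tree with genome ids as labels.
#' @export
cluster_genomes <- function(m, normalize = FALSE) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  x <- if (normalize) m / pmax(rowSums(m), 1) else m
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

#' Write a dendrogram as Newick
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Default EC-to-activity-class map
#'
#' Routes cellulose-degrading activities (endoglucanase EC 3.2.1.4,
#' beta-glucosidase EC 3.2.1.21, the cellobiohydrolases EC 3.2.1.91 and
#' EC 3.2.1.176) plus the cellulose-active LPMOs (family AA9) to class
#' `cellulose`; common hemicellulases (xylanase, xylosidase,
#' arabinofuranosidase, mannanase, mannosidase, galactosidase) to
#' `hemicellulose`; everything else, including the chitin-active AA11
#' LPMOs, to `other`.
#'
#' @return Named character vector: EC -> class.
#' @export
activity_class_map <- function() {
  c("3.2.1.4" = "cellulose", "3.2.1.21" = "cellulose",
    "3.2.1.91" = "cellulose", "3.2.1.176" = "cellulose",
    "3.2.1.8" = "hemicellulose", "3.2.1.37" = "hemicellulose",
    "3.2.1.55" = "hemicellulose", "3.2.1.78" = "hemicellulose",
    "3.2.1.25" = "hemicellulose", "3.2.1.22" = "hemicellulose",
    "3.2.1.23" = "hemicellulose")
}

#' Summarize activity classes per genome
#'
#' Sums each genome's function counts into the classes cellulose,
#' hemicellulose and other.  "LPMO" counts are split by family: AA9 calls
#' count as cellulose, AA10/AA11 as other; ECs absent from the map count
#' as other.  With a `groups` labeling, per-group mean counts are appended.
#'
#' @param profiles List of [genome_profile()] objects.
#' @param class_map Named character vector EC -> class (see
#'   [activity_class_map()]).
#' @param groups Optional named character vector genome_id -> group label.
#' @return data.frame with one row per genome (columns `genome_id`,
#'   `cellulose`, `hemicellulose`, `other`, optionally `group`); group
#'   means are attached as attribute `"group_means"`.
#' @export
summarize_activity_classes <- function(profiles,
                                       class_map = activity_class_map(),
                                       groups = NULL) {
  rows <- lapply(profiles, function(p) {
    sums <- c(cellulose = 0L, hemicellulose = 0L, other = 0L)
    fc <- p$function_counts
    for (lab in names(fc)) {
      if (lab == "LPMO") {
        aa9 <- if ("AA9" %in% names(p$family_counts))
          p$family_counts[["AA9"]] else 0L
        aa9 <- min(aa9, fc[[lab]])
        sums["cellulose"] <- sums["cellulose"] + aa9
        sums["other"] <- sums["other"] + fc[[lab]] - aa9
      } else {
        cls <- if (lab %in% names(class_map)) class_map[[lab]] else "other"
        sums[cls] <- sums[cls] + fc[[lab]]
      }
    }
    data.frame(genome_id = p$genome_id, cellulose = sums[["cellulose"]],
               hemicellulose = sums[["hemicellulose"]],
               other = sums[["other"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) {
    out$group <- unname(groups[out$genome_id])
    gm <- stats::aggregate(out[, c("cellulose", "hemicellulose", "other")],
                    by = list(group = out$group), FUN = mean)
    attr(out, "group_means") <- gm
  }
  out
}

#' Read a genome-group labels file
#'
#' Tab-separated: genome_id TAB group label (e.g. degrader/non-degrader).
#'
#' @param path Path to the TSV file.
#' @return Named character vector genome_id -> group.
#' @export
read_group_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("genome_id", "group"),
                           colClasses = "character")
  setNames(tab$group, tab$genome_id)
}
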