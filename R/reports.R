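# Summary arithmetic over regulog collections: box-arrangement
# distributions, per-taxon TF counts, and ortholog-group size statistics.
# Bundled fixtures carry the summary tables of a published large-scale
# reconstruction of MocR-subfamily regulons (390 bacterial genomes) so the
# reporting arithmetic can be exercised without running the pipeline.

#' Percentage distribution of box-arrangement categories
#'
#' `percent(cat) = round(100 * regulon_count(cat) / total_regulons)`,
#' rounded half-up to integers. Composite queries pool category subsets
#' before dividing.
#'
#' @param counts `data.frame` with columns `category` and `regulons`
#'   (optionally `regulogs`), e.g. from [mocr_structure_counts()].
#' @param groups Optional named list of character vectors; each entry is
#'   reported as the pooled percentage of its categories.
#' @return Named integer vector of percentages.
#' @export
structure_distribution <- function(counts, groups = NULL) {
  total <- sum(counts$regulons)
  if (total <= 0) stop("total regulon count must be positive")
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(counts$category), counts$category)
  }
  vapply(groups, function(cats) {
    n <- sum(counts$regulons[counts$category %in% cats])
    as.integer(round_half_up(100 * n / total))
  }, 0L)
}

#' Per-taxon summary of TF counts
#'
#' Adds the mean number of TFs per genome (TFs divided by genomes that
#' contain them, rounded half-up to 2 decimals) per row, and a `Total` row
#' aggregating all taxa.
#'
#' @param rows `data.frame` with columns `taxon`, `lineages`,
#'   `genomes_with_tf`, `genomes_total`, `regulogs`, `regulons`, `tfs`
#'   (e.g. from [mocr_taxon_counts()]).
#' @return `data.frame` of class `taxon_summary` with an added
#'   `mean_tfs_per_genome` column and a final `Total` row.
#' @export
taxon_summary <- function(rows) {
  req <- c("taxon", "lineages", "genomes_with_tf", "genomes_total",
           "regulogs", "regulons", "tfs")
  stopifnot(all(req %in% names(rows)))
  if (any(rows$genomes_with_tf <= 0)) {
    stop("genomes_with_tf must be positive in every row")
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  total <- data.frame(taxon = "Total",
                      lineages = sum(rows$lineages),
                      genomes_with_tf = sum(rows$genomes_with_tf),
                      genomes_total = sum(rows$genomes_total),
                      regulogs = sum(rows$regulogs),
                      regulons = sum(rows$regulons),
                      tfs = sum(rows$tfs), stringsAsFactors = FALSE)
  if (!is.null(rows$phylum)) total$phylum <- ""
  out <- rbind(rows[, names(total)], total)
  out$mean_tfs_per_genome <- round_half_up(out$tfs / out$genomes_with_tf, 2)
  class(out) <- c("taxon_summary", "data.frame")
  out
}

#' Ortholog-group size statistics
#'
#' @param sizes Non-empty integer vector of TFs per ortholog group.
#' @return List with `min`, `max` and `mean` (rounded half-up to 1
#'   decimal).
#' @export
group_size_stats <- function(sizes) {
  stopifnot(length(sizes) >= 1L)
  list(min = min(sizes), max = max(sizes),
       mean = round_half_up(mean(sizes), 1))
}

#' Bundled summary tables of the MocR-subfamily reconstruction
#'
#' `mocr_structure_counts()` returns regulog/regulon counts per
#' box-arrangement category; `mocr_taxon_counts()` the per-taxon counts of
#' lineages, genomes, regulogs, regulons and TFs; `mocr_group_summary()`
#' headline counts of the ortholog grouping (86 groups over 825 TFs).
#'
#' @return A `data.frame` (or named list for `mocr_group_summary`).
#' @export
mocr_structure_counts <- function() {
  utils::read.delim(system.file("extdata", "mocr_motif_structures.tsv",
                                package = "regulogR"),
                    stringsAsFactors = FALSE)
}

#' @rdname mocr_structure_counts
#' @export
mocr_taxon_counts <- function() {
  utils::read.delim(system.file("extdata", "mocr_taxon_counts.tsv",
                                package = "regulogR"),
                    stringsAsFactors = FALSE)
}

#' @rdname mocr_structure_counts
#' @export
mocr_group_summary <- function() {
  as.list(utils::read.delim(system.file("extdata", "mocr_group_summary.tsv",
                                        package = "regulogR"),
                            stringsAsFactors = FALSE))
}

#' Classify the arrangement of each regulog in a collection and tabulate
#'
#' @param regulogs List of `regulog` objects whose `motif` field is set.
#' @return `data.frame` with columns `category`, `regulogs`, `regulons`.
#' @export
structure_counts <- function(regulogs) {
  cats <- vapply(regulogs, function(rg)
    classify_structure(rg$motif)$category_string, "")
  nreg <- vapply(regulogs, function(rg) regulog_stats(rg)$n_regulons, 0L)
  agg <- stats::aggregate(list(regulogs = rep(1L, length(cats)),
                               regulons = nreg), by = list(category = cats),
                          FUN = sum)
  agg[order(-agg$regulons), , drop = FALSE]
}
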