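# Cross-genome regulon reconstruction: candidate collection, the
# positional weak-site rescue rule, the consistency check over a regulog,
# and summary statistics.

#' Configuration for regulon reconstruction
#'
#' @param K_rule Function of the regulog size `N` returning the minimum
#'   number of genomes in which an orthologous gene family must carry an
#'   accepted site; default `max(2, ceiling(N / 3))`.
#' @param position_tolerance Positional tolerance (nt) for the weak-site
#'   rule; default 20, about two DNA helical turns.
#' @param max_gap Operon intergenic-distance cutoff (nt).
#' @return An object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(K_rule = function(N) max(2L, ceiling(N / 3)),
                                  position_tolerance = 20L, max_gap = 200L) {
  stopifnot(is.function(K_rule), position_tolerance >= 0L)
  structure(list(K_rule = K_rule,
                 position_tolerance = as.integer(position_tolerance),
                 max_gap = as.integer(max_gap)),
            class = "reconstruction_config")
}

#' Collect candidate operons from scan hits
#'
#' An operon is a candidate when its lead gene's upstream region carries at
#' least one hit (strong or weak). A hit recorded on a non-lead gene is
#' reassigned to its operon's lead gene and logged.
#'
#' @param hits `data.frame` of hits (see [scan_region()]) for one genome.
#' @param operons Operon list from [predict_operons()] for the same genome.
#' @return `data.frame` of candidate hits with added columns `operon_id`
#'   and `lead_gene_id`; one row per retained hit.
#' @export
collect_candidates <- function(hits, operons) {
  empty <- data.frame(gene_id = character(0), genome_id = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), weak = logical(0),
                      operon_id = character(0), lead_gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(empty)
  op_of <- list()
  for (op in operons) for (g in op$gene_ids) op_of[[g]] <- op
  keep <- list()
  for (i in seq_len(nrow(hits))) {
    op <- op_of[[hits$gene_id[i]]]
    if (is.null(op)) next
    h <- hits[i, , drop = FALSE]
    if (h$gene_id != op$lead_gene_id) {
      message("hit on non-lead gene ", h$gene_id,
              " reassigned to operon lead ", op$lead_gene_id)
    }
    h$operon_id <- op$operon_id
    h$lead_gene_id <- op$lead_gene_id
    keep[[length(keep) + 1L]] <- h
  }
  if (!length(keep)) return(empty)
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Positional rescue rule for weak sites
#'
#' A weak site (score between the weak floor and the threshold) is accepted
#' when its position is within `cfg$position_tolerance` of the median
#' position of strong sites upstream of orthologous genes, and no strong
#' site with a higher score exists elsewhere in the same region.
#'
#' @param candidate_hit One hit row with `weak = TRUE`.
#' @param ortholog_strong_hits Hits (`weak = FALSE`) upstream of orthologs
#'   in other genomes; their `position` column is the anchor.
#' @param cfg A [reconstruction_config()].
#' @param region_hits Optional: all hits in the candidate's region, used
#'   for the competing-site clause.
#' @return `TRUE` or `FALSE`.
#' @export
weak_site_rule <- function(candidate_hit, ortholog_strong_hits, cfg,
                           region_hits = NULL) {
  stopifnot(isTRUE(candidate_hit$weak))
  if (is.null(ortholog_strong_hits) || !nrow(ortholog_strong_hits)) {
    return(FALSE)  # no positional anchor
  }
  anchor <- stats::median(ortholog_strong_hits$position)
  if (abs(candidate_hit$position - anchor) > cfg$position_tolerance) {
    return(FALSE)
  }
  if (!is.null(region_hits) && nrow(region_hits)) {
    competing <- !region_hits$weak &
      region_hits$position != candidate_hit$position &
      region_hits$score > candidate_hit$score
    if (any(competing)) return(FALSE)
  }
  TRUE
}

#' Consistency check: assemble a regulog from per-genome candidates
#'
#' An orthologous family of lead genes enters the regulog when its members
#' carry accepted sites (strong, or weak passing [weak_site_rule()]) in at
#' least `K(N)` genomes, `N` being the regulog size. Accepted members are
#' expanded to their whole operons. For `N = 1` only strong sites are
#' accepted and the `K` rule is vacuous.
#'
#' @param candidates_by_genome Named list (genome id) of candidate
#'   `data.frame`s from [collect_candidates()].
#' @param operons_by_genome Named list of operon lists matching the
#'   candidates.
#' @param groups An `ortholog_groups` object covering the lead genes.
#' @param cfg A [reconstruction_config()].
#' @param group_id Identifier of the TF ortholog group owning the regulog.
#' @param taxon_group Taxon-group label.
#' @param motif Optional `motif_model` to attach.
#' @return An object of class `regulog`: per-genome regulons, each member a
#'   list with `operon`, `hits` and the ortholog `family`.
#' @export
consistency_check <- function(candidates_by_genome, operons_by_genome,
                              groups, cfg = reconstruction_config(),
                              group_id = "regulog", taxon_group = "unspecified",
                              motif = NULL) {
  genomes <- names(candidates_by_genome)
  N <- length(genomes)
  stopifnot(N >= 1L)
  K <- if (N == 1L) 1L else cfg$K_rule(N)
  # family of each candidate's lead gene; leads without an ortholog group
  # become private singleton families
  fam_rows <- list()
  for (g in genomes) {
    cand <- candidates_by_genome[[g]]
    if (!nrow(cand)) next
    fam <- groups$index[cand$lead_gene_id]
    fam[is.na(fam)] <- paste0("solo_", cand$lead_gene_id[is.na(fam)])
    cand$family <- unname(fam)
    cand$genome <- g
    fam_rows[[g]] <- cand
  }
  all_cand <- if (length(fam_rows))
    do.call(rbind, c(fam_rows, list(make.row.names = FALSE))) else NULL
  regulons <- stats::setNames(
    lapply(genomes, function(g) list(genome_id = g, members = list())),
    genomes)
  accepted_families <- character(0)
  if (!is.null(all_cand) && nrow(all_cand)) {
    for (fam in unique(all_cand$family)) {
      fc <- all_cand[all_cand$family == fam, , drop = FALSE]
      strong <- fc[!fc$weak, , drop = FALSE]
      acc_genomes <- unique(strong$genome)
      if (N > 1L) {
        for (g in setdiff(unique(fc$genome), acc_genomes)) {
          gw <- fc[fc$genome == g & fc$weak, , drop = FALSE]
          anchors <- strong[strong$genome != g, , drop = FALSE]
          region_hits <- fc[fc$genome == g, , drop = FALSE]
          ok <- vapply(seq_len(nrow(gw)), function(i)
            weak_site_rule(gw[i, ], anchors, cfg, region_hits), TRUE)
          if (any(ok)) acc_genomes <- c(acc_genomes, g)
        }
      }
      if (length(acc_genomes) >= K) {
        accepted_families <- c(accepted_families, fam)
        for (g in acc_genomes) {
          gc <- fc[fc$genome == g, , drop = FALSE]
          for (opid in unique(gc$operon_id)) {
            op <- Find(function(o) o$operon_id == opid,
                       operons_by_genome[[g]])
            regulons[[g]]$members[[length(regulons[[g]]$members) + 1L]] <-
              list(operon = op, family = fam,
                   hits = gc[gc$operon_id == opid, , drop = FALSE])
          }
        }
      }
    }
  }
  structure(list(group_id = group_id, taxon_group = taxon_group,
                 K = K, config = cfg, regulons = regulons,
                 families = sort(unique(accepted_families)), motif = motif),
            class = "regulog")
}

#' @export
print.regulog <- function(x, ...) {
  st <- regulog_stats(x)
  cat("<regulog> ", x$group_id, " (", x$taxon_group, "): ",
      st$n_regulons, " regulons in ", st$n_genomes, " genomes, ",
      st$n_sites, " sites, ", st$n_target_genes, " target genes (K = ",
      x$K, ")\n", sep = "")
  invisible(x)
}

#' Summary counts for a regulog
#'
#' @param regulog A `regulog` object.
#' @return List with `n_genomes`, `n_regulons` (genomes with at least one
#'   member), `n_operons`, `n_sites` and `n_target_genes`.
#' @export
regulog_stats <- function(regulog) {
  n_sites <- 0L; n_genes <- 0L; n_ops <- 0L; n_reg <- 0L
  for (r in regulog$regulons) {
    if (length(r$members)) n_reg <- n_reg + 1L
    for (m in r$members) {
      n_ops <- n_ops + 1L
      n_genes <- n_genes + length(m$operon$gene_ids)
      n_sites <- n_sites + nrow(m$hits)
    }
  }
  list(n_genomes = length(regulog$regulons), n_regulons = n_reg,
       n_operons = n_ops, n_sites = n_sites, n_target_genes = n_genes)
}

#' Export a regulog as TSV
#'
#' One row per member gene: `group_id`, `genome_id`, `operon_id`,
#' `gene_id`, `site_position`, `score`, `weak`.
#'
#' @param regulog A `regulog`.
#' @param path Output path; a JSON summary is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_regulog <- function(regulog, path) {
  rows <- list()
  for (r in regulog$regulons) {
    for (m in r$members) {
      best <- m$hits[which.max(m$hits$score), , drop = FALSE]
      for (g in m$operon$gene_ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = regulog$group_id, genome_id = r$genome_id,
          operon_id = m$operon$operon_id, gene_id = g,
          site_position = best$position, score = round(best$score, 4),
          weak = best$weak, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), genome_id = character(0),
               operon_id = character(0), gene_id = character(0),
               site_position = integer(0), score = numeric(0),
               weak = logical(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- regulog_stats(regulog)
  st$group_id <- regulog$group_id
  st$K <- regulog$K
  st$position_tolerance <- regulog$config$position_tolerance
  jsonlite::write_json(st, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
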