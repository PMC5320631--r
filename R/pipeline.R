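# End-to-end orchestration: footprint a training set of upstream regions,
# build a full-site PWM from the discovered sites, scan every operon lead
# across the genomes, and assemble the regulog by consistency check.

#' Full-site training alignment from a motif model
#'
#' Site strings of the model's site set, restricted to the modal inter-box
#' gap so all strings align column-wise.
#'
#' @param model A `motif_model`.
#' @return Character vector of equal-length site strings.
#' @export
full_site_alignment <- function(model) {
  if (is_empty_motif(model)) stop("empty motif model")
  sites <- model$site_set
  g <- modal_gap(sites$gap)
  aln <- sites$site_seq[sites$gap == g]
  aln[!grepl("N", aln, fixed = TRUE)]
}

#' Reconstruct a regulog from genomes and a training region set
#'
#' Discovers a repeat-structured motif over the training regions, builds a
#' full-site PWM from the discovered site alignment with the 10%-below-
#' minimum threshold rule, scans the upstream region of every operon lead
#' gene in every genome on both strands, collects candidate operons, and
#' assembles the regulog with the cross-genome consistency check. Ortholog
#' groups are taken from `groups` or computed by reciprocal best hits over
#' the genome proteins.
#'
#' @param genomes Named list of [genome()] objects (one taxon group).
#' @param training_regions List of `upstream_region` objects (upstream of
#'   genes presumed to belong to the regulon, e.g. the TF's divergon
#'   partners across genomes).
#' @param groups Optional `ortholog_groups`; computed by RBH when `NULL`.
#' @param window Scan window relative to the start codon.
#' @param rcfg A [reconstruction_config()].
#' @param group_id Regulog identifier.
#' @param ... Passed on to [discover_motif()].
#' @return List with `model` (`motif_model`), `pwm` (full-site PWM),
#'   `scan_config`, `operons`, `hits`, `candidates` and `regulog`; or
#'   `NULL` when no motif was found.
#' @export
reconstruct_regulog <- function(genomes, training_regions, groups = NULL,
                                window = c(-350L, 50L),
                                rcfg = reconstruction_config(),
                                group_id = "regulog", ...) {
  model <- discover_motif(training_regions, ...)
  if (is_empty_motif(model)) return(NULL)
  aln <- full_site_alignment(model)
  pwm_full <- build_pwm(aln)
  scores <- vapply(aln, score_site, 0, pwm = pwm_full)
  cfg <- compute_threshold(scores, window = window)
  if (is.null(groups)) {
    proteomes <- lapply(genomes, function(g)
      data.frame(protein_id = names(g$proteins), genome_id = g$genome_id,
                 sequence = unname(g$proteins), stringsAsFactors = FALSE))
    groups <- build_groups(reciprocal_best_hits(proteomes),
                           genes = do.call(rbind, lapply(genomes, function(g)
                             data.frame(genome_id = g$genome_id,
                                        gene_id = g$genes$gene_id))))
  }
  operons <- lapply(genomes, predict_operons, max_gap = rcfg$max_gap)
  hits <- list(); candidates <- list()
  for (gid in names(genomes)) {
    leads <- vapply(operons[[gid]], `[[`, "", "lead_gene_id")
    regions <- upstream_regions(genomes[[gid]], leads, window = window)
    h <- scan_regions(pwm_full, regions, cfg)
    hits[[gid]] <- h
    candidates[[gid]] <- collect_candidates(h, operons[[gid]])
  }
  regulog <- consistency_check(candidates, operons, groups, rcfg,
                               group_id = group_id,
                               taxon_group = genomes[[1L]]$taxon_group,
                               motif = model)
  list(model = model, pwm = pwm_full, scan_config = cfg, operons = operons,
       hits = hits, candidates = candidates, regulog = regulog)
}

# (genome, gene) pairs of all regulog member operon genes
regulog_member_pairs <- function(regulog) {
  out <- character(0)
  for (r in regulog$regulons) {
    for (m in r$members) {
      out <- c(out, paste(r$genome_id, m$operon$gene_ids, sep = "/"))
    }
  }
  unique(out)
}

#' Membership precision/recall/F1 against a ground truth
#'
#' @param regulog A `regulog`.
#' @param truth `data.frame` with columns `genome_id`, `gene_id` (the
#'   planted member genes, e.g. `ground_truth$membership`).
#' @return List with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
membership_scores <- function(regulog, truth) {
  pred <- regulog_member_pairs(regulog)
  want <- unique(paste(truth$genome_id, truth$gene_id, sep = "/"))
  tp <- length(intersect(pred, want))
  fp <- length(setdiff(pred, want))
  fn <- length(setdiff(want, pred))
  precision <- if (tp + fp) tp / (tp + fp) else 1
  recall <- if (tp + fn) tp / (tp + fn) else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Fraction of decoy families pulled into a regulog
#'
#' @param regulog A `regulog`.
#' @param ground_truth Ground truth of the generating dataset.
#' @return Decoy families with any predicted member divided by the number
#'   of decoy families.
#' @export
decoy_fpr <- function(regulog, ground_truth) {
  om <- ground_truth$ortholog_map
  decoy_fams <- unique(om$family[startsWith(om$family, "dec")])
  if (!length(decoy_fams)) return(0)
  pred <- regulog_member_pairs(regulog)
  pred_genes <- sub("^[^/]*/", "", pred)
  hit <- vapply(unique(sub("_g[0-9]+$", "", decoy_fams)), function(fam)
    any(grepl(paste0("_", fam, "_g"), pred_genes)), TRUE)
  mean(hit)
}

#' Planted-site recovery of a discovered motif
#'
#' A planted site counts as recovered when a discovered site in the same
#' region overlaps it by at least one base.
#'
#' @param model A `motif_model` discovered over regions extracted with
#'   [upstream_regions()] from the dataset's genomes.
#' @param ground_truth Ground truth of the generating dataset.
#' @return Fraction of planted sites overlapped by discovered sites.
#' @export
site_recovery <- function(model, ground_truth) {
  if (is_empty_motif(model)) return(0)
  sites <- model$site_set
  gt <- ground_truth$sites
  span_gt <- ground_truth$span
  hitp <- paste(sites$genome_id, sites$gene_id)
  rec <- vapply(seq_len(nrow(gt)), function(i) {
    j <- which(hitp == paste(gt$genome_id[i], gt$gene_id[i]))
    if (!length(j)) return(FALSE)
    any(vapply(j, function(jj) {
      # discovered start is in region coordinates; convert the planted
      # position (relative to start codon) likewise via the model regions
      ds <- sites$start[jj]
      de <- ds + 2L * model$width + sites$gap[jj] - 1L
      ps <- gt$position[i] + sites$region_offset[jj]
      pe <- ps + span_gt - 1L
      ds <= pe && de >= ps
    }, TRUE))
  }, TRUE)
  mean(rec)
}
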