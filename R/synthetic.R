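# Synthetic genome sets with planted regulogs. Each genome carries a TF
# gene in divergon arrangement with its first target operon, further
# member operons whose lead genes get one operator site sampled from the
# true box profile, decoy operons with no sites, and ortholog families
# realised as per-genome mutated copies of ancestral proteins. A
# GroundTruth manifest records everything for recovery testing.

#' Generator configuration
#'
#' Defaults describe the canonical planted scene: 10 genomes, 5 regulon
#' member families, 3 decoy families, a two-box direct repeat of width 8
#' with a 13 nt gap (start-to-start 21 nt, two DNA helical turns) whose
#' consensus starts with the conserved TGT group, per-column consensus
#' probability `1 - site_mut = 0.93` (about 1.5 bits per column), and
#' within-operon gaps well below the 200 nt operon cutoff while
#' between-unit spacing is far above it.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_genomes Number of genomes in the taxon group.
#' @param replicon_length Length (nt) of the single replicon per genome.
#' @param n_member_families Number of regulon member families (each an
#'   operon whose lead gene carries one planted site).
#' @param n_decoy_families Decoy families that receive no sites.
#' @param box_width Width of one motif box (nt).
#' @param arrows Box orientations over `c(">", "<")`, length 2-4.
#' @param gaps Edge-to-edge inter-box gaps (nt), length `length(arrows)-1`.
#' @param box_consensus Optional consensus string for the shared box;
#'   sampled (starting `TGT`) when `NULL`.
#' @param site_mut Per-base probability that a planted site base deviates
#'   from the consensus (uniform over the other three bases).
#' @param gc Background GC content.
#' @param bg_order Background Markov order (0 keeps bases independent).
#' @param divergon Place the TF gene divergently transcribed from the first
#'   member operon, sharing one intergenic region.
#' @param operon_gap_range Within-operon intergenic gaps (nt).
#' @param unit_spacing_range Spacing between transcription units (nt); kept
#'   above the upstream window so no window captures a neighbour's site.
#' @param gene_length_range Gene lengths (nt).
#' @param genes_per_operon_range Genes per member/decoy operon.
#' @param protein_length Ancestral protein length (aa).
#' @param protein_mut Per-residue substitution probability per genome.
#' @param site_pos_range Window (nt relative to the start codon) in which
#'   the site's left edge is planted; inside the -350..+50 scan window with
#'   margins so box extension never leaves it.
#' @param taxon_group Taxon-group label stamped on the genomes.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_genomes = 10L,
                             replicon_length = 40000L,
                             n_member_families = 5L, n_decoy_families = 3L,
                             box_width = 8L, arrows = c(">", ">"),
                             gaps = 13L, box_consensus = NULL,
                             site_mut = 0.07, gc = 0.5, bg_order = 0L,
                             divergon = TRUE,
                             operon_gap_range = c(25L, 150L),
                             unit_spacing_range = c(620L, 900L),
                             gene_length_range = c(600L, 1200L),
                             genes_per_operon_range = c(1L, 3L),
                             protein_length = 180L, protein_mut = 0.05,
                             site_pos_range = c(-250L, -30L),
                             taxon_group = "SyntheticTaxon") {
  stopifnot(n_genomes >= 1L, length(arrows) >= 2L, length(arrows) <= 4L,
            length(gaps) == length(arrows) - 1L, all(gaps >= 0L),
            site_mut >= 0, site_mut <= 1, protein_mut >= 0, protein_mut <= 1,
            gc >= 0, gc <= 1)
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              replicon_length = as.integer(replicon_length),
              n_member_families = as.integer(n_member_families),
              n_decoy_families = as.integer(n_decoy_families),
              box_width = as.integer(box_width), arrows = arrows,
              gaps = as.integer(gaps), box_consensus = box_consensus,
              site_mut = site_mut, gc = gc, bg_order = as.integer(bg_order),
              divergon = isTRUE(divergon),
              operon_gap_range = as.integer(operon_gap_range),
              unit_spacing_range = as.integer(unit_spacing_range),
              gene_length_range = as.integer(gene_length_range),
              genes_per_operon_range = as.integer(genes_per_operon_range),
              protein_length = as.integer(protein_length),
              protein_mut = protein_mut,
              site_pos_range = as.integer(site_pos_range),
              taxon_group = taxon_group)
  structure(cfg, class = "generator_config")
}

base_probs_for_gc <- function(gc) {
  stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

#' Sample a background replicon
#'
#' Order-0 sampling at the configured GC; for `order > 0` a custom 4^order
#' x 4 `transition` matrix (rows named by context) may be supplied,
#' otherwise bases stay independent at the configured GC. Uses the current
#' RNG state, so results are deterministic under `set.seed()`.
#'
#' @param length Replicon length (nt).
#' @param gc GC content in `[0, 1]`.
#' @param order Markov order.
#' @param transition Optional conditional matrix for `order > 0`.
#' @param replicon_id Identifier.
#' @return A [replicon()].
#' @export
sample_background_genome <- function(length, gc = 0.5, order = 0L,
                                     transition = NULL,
                                     replicon_id = "chr") {
  p <- base_probs_for_gc(gc)
  if (order > 0L && !is.null(transition)) {
    ctx_w <- as.integer(order)
    bases <- character(length)
    bases[seq_len(ctx_w)] <- sample(DNA_BASES, ctx_w, TRUE, prob = p)
    for (i in (ctx_w + 1L):length) {
      ctx <- paste(bases[(i - ctx_w):(i - 1L)], collapse = "")
      bases[i] <- sample(DNA_BASES, 1L, prob = transition[ctx, ])
    }
  } else {
    bases <- sample(DNA_BASES, length, TRUE, prob = p)
  }
  replicon(replicon_id, paste(bases, collapse = ""))
}

# sample a box realisation from the profile (consensus orientation)
sample_box <- function(consensus, site_mut) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mut <- stats::runif(length(b)) < site_mut
  if (any(mut)) {
    b[mut] <- vapply(b[mut], function(x)
      sample(setdiff(DNA_BASES, x), 1L), "")
  }
  paste(b, collapse = "")
}

# overwrite `str` (given in coding orientation at coding-relative position
# `rel`, where 0 is the start codon's first base) into a character vector
# of replicon bases
write_coding <- function(chars, gene_start, gene_end, strand, rel, str) {
  n <- nchar(str)
  if (strand == "+") {
    idx <- gene_start + rel + 0:(n - 1L)
    chars[idx] <- strsplit(str, "", fixed = TRUE)[[1]]
  } else {
    # coding position p maps to replicon position end - p; each coding base
    # is stored as its complement (no reversal: idx already descends)
    idx <- gene_end - rel - (0:(n - 1L))
    chars[idx] <- strsplit(chartr("ACGTN", "TGCAN", str), "", fixed = TRUE)[[1]]
    idx <- rev(idx)
  }
  list(chars = chars, left = idx[1L], right = idx[length(idx)])
}

mutate_protein <- function(seq, rate) {
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  mut <- stats::runif(length(a)) < rate
  if (any(mut)) {
    a[mut] <- vapply(a[mut], function(x) sample(setdiff(AA_BASES, x), 1L), "")
  }
  paste(a, collapse = "")
}

#' Plant a regulog across synthetic genomes
#'
#' Lays out, for each genome, a TF gene (divergently transcribed from the
#' first member operon when `divergon = TRUE`), member operons whose lead
#' genes receive one operator site sampled from the true profile, and decoy
#' operons with no sites; derives per-genome proteins from family
#' ancestors; and records everything in a ground-truth manifest.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `synthetic_dataset`: `genomes` (list of
#'   [genome()] objects with proteins), `ground_truth` (profile,
#'   arrangement, planted sites, membership, operons, ortholog map, config
#'   echo) and `config`.
#' @export
plant_regulog <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  w <- cfg$box_width
  nb <- length(cfg$arrows)
  span <- nb * w + sum(cfg$gaps)
  box_offsets <- cumsum(c(0L, rep(w, nb - 1L) + cfg$gaps))  # 0-based in site
  consensus <- cfg$box_consensus %||%
    paste0("TGT", paste(sample(DNA_BASES, w - 3L, TRUE), collapse = ""))
  stopifnot(nchar(consensus) == w)
  prob_matrix <- matrix(cfg$site_mut / 3, 4L, w, dimnames = list(DNA_BASES, NULL))
  cons_b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  prob_matrix[cbind(match(cons_b, DNA_BASES), seq_len(w))] <- 1 - cfg$site_mut

  # family plan, shared across genomes (conserved gene content and synteny)
  fam_ids <- c("tf",
               sprintf("mem%d", seq_len(cfg$n_member_families)),
               sprintf("dec%d", seq_len(cfg$n_decoy_families)))
  fam_sizes <- stats::setNames(c(1L, sample(
    cfg$genes_per_operon_range[1]:cfg$genes_per_operon_range[2],
    cfg$n_member_families + cfg$n_decoy_families, TRUE)), fam_ids)
  slot_ids <- unlist(lapply(fam_ids, function(f)
    if (f == "tf") "tf" else sprintf("%s_g%d", f, seq_len(fam_sizes[[f]]))))
  ancestors <- stats::setNames(vapply(slot_ids, function(s)
    paste(sample(AA_BASES, cfg$protein_length, TRUE), collapse = ""), ""),
    slot_ids)

  genomes <- list()
  sites <- list(); membership <- list(); operons_truth <- list()
  ortho <- list()
  for (gi in seq_len(cfg$n_genomes)) {
    gid <- sprintf("g%02d", gi)
    rep0 <- sample_background_genome(cfg$replicon_length, cfg$gc,
                                     cfg$bg_order, replicon_id = "chr")
    chars <- strsplit(rep0$sequence, "", fixed = TRUE)[[1]]
    genes <- list()
    cursor <- sample(400:700, 1L)
    lay_gene <- function(slot, start, len, strand) {
      list(gene_id = paste0(gid, "_", slot), slot = slot,
           start = start, end = start + len - 1L, strand = strand)
    }
    # TF gene on the minus strand, then the shared divergon region
    tf_len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
    tf_strand <- if (cfg$divergon) "-" else sample(c("+", "-"), 1L)
    genes[["tf"]] <- lay_gene("tf", cursor, tf_len, tf_strand)
    cursor <- cursor + tf_len - 1L
    lead_info <- list()
    op_units <- fam_ids[fam_ids != "tf"]
    operons_truth[[gid]] <- list(tf = genes[["tf"]]$gene_id)
    for (ui in seq_along(op_units)) {
      fam <- op_units[ui]
      spacing <- sample(cfg$unit_spacing_range[1]:cfg$unit_spacing_range[2], 1L)
      strand <- if (cfg$divergon && ui == 1L) "+" else sample(c("+", "-"), 1L)
      start <- cursor + spacing
      n_genes <- fam_sizes[[fam]]
      # transcription order g1..gN is conserved across genomes, so on the
      # minus strand g1 (the lead) takes the rightmost coordinates
      slot_order <- if (strand == "+") seq_len(n_genes) else rev(seq_len(n_genes))
      unit_genes <- vector("list", n_genes)
      for (k in slot_order) {
        len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
        unit_genes[[k]] <- lay_gene(sprintf("%s_g%d", fam, k), start, len, strand)
        gap <- sample(cfg$operon_gap_range[1]:cfg$operon_gap_range[2], 1L)
        start <- start + len + gap
      }
      cursor <- max(vapply(unit_genes, `[[`, 0L, "end"))
      for (g in unit_genes) genes[[g$slot]] <- g
      operons_truth[[gid]][[fam]] <-
        vapply(unit_genes, `[[`, "", "gene_id")
      lead_info[[fam]] <- unit_genes[[1L]]
    }
    if (cursor > cfg$replicon_length - 200L) {
      stop("infeasible layout: genes exceed replicon_length ",
           cfg$replicon_length)
    }
    # plant one operator site per member lead gene
    mem_fams <- sprintf("mem%d", seq_len(cfg$n_member_families))
    for (fam in mem_fams) {
      lead <- lead_info[[fam]]
      pos <- sample(cfg$site_pos_range[1]:(cfg$site_pos_range[2] - span + 1L), 1L)
      left_abs <- NULL; right_abs <- NULL
      for (b in seq_len(nb)) {
        bx <- sample_box(consensus, cfg$site_mut)
        if (cfg$arrows[b] == "<") bx <- revcomp(bx)
        res <- write_coding(chars, lead$start, lead$end, lead$strand,
                            pos + box_offsets[b], bx)
        chars <- res$chars
        left_abs <- min(left_abs %||% res$left, res$left)
        right_abs <- max(right_abs %||% res$right, res$right)
      }
      site_str <- paste(chars[left_abs:right_abs], collapse = "")
      if (lead$strand == "-") site_str <- revcomp(site_str)
      sites[[length(sites) + 1L]] <- data.frame(
        genome_id = gid, gene_id = lead$gene_id, family = fam,
        position = pos, abs_left = left_abs, abs_right = right_abs,
        strand = lead$strand, site_seq = site_str, stringsAsFactors = FALSE)
      for (slot_gene in operons_truth[[gid]][[fam]]) {
        membership[[length(membership) + 1L]] <- data.frame(
          genome_id = gid, family = fam, gene_id = slot_gene,
          stringsAsFactors = FALSE)
      }
    }
    gene_df <- do.call(rbind, lapply(genes, function(g)
      data.frame(gene_id = g$gene_id, replicon_id = "chr", start = g$start,
                 end = g$end, strand = g$strand,
                 product = paste0("synthetic ", g$slot, " protein"),
                 stringsAsFactors = FALSE)))
    gene_df <- gene_df[order(gene_df$start), , drop = FALSE]
    rownames(gene_df) <- NULL
    proteins <- stats::setNames(vapply(names(genes), function(slot)
      mutate_protein(ancestors[[slot]], cfg$protein_mut), ""),
      vapply(genes, `[[`, "", "gene_id"))
    rep_final <- replicon("chr", paste(chars, collapse = ""))
    genomes[[gid]] <- genome(gid, list(rep_final), gene_df,
                             taxon_group = cfg$taxon_group,
                             proteins = proteins)
    for (slot in names(genes)) {
      ortho[[length(ortho) + 1L]] <- data.frame(
        family = slot, genome_id = gid, gene_id = genes[[slot]]$gene_id,
        stringsAsFactors = FALSE)
    }
  }
  gt <- list(
    profile = list(consensus = consensus, prob_matrix = prob_matrix,
                   box_width = w),
    arrows = cfg$arrows, gaps = cfg$gaps, span = span,
    sites = do.call(rbind, sites),
    membership = do.call(rbind, membership),
    operons = operons_truth,
    ortholog_map = do.call(rbind, ortho),
    config = unclass(cfg))
  structure(list(genomes = genomes, ground_truth = gt, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$genomes), " genomes, ",
      nrow(x$ground_truth$sites), " planted sites (",
      paste(x$ground_truth$arrows, collapse = " "), ", gap ",
      paste(x$ground_truth$gaps, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Per genome: `<id>.fna` (FASTA), `<id>_genes.tsv` (gene table),
#' `<id>.faa` (protein FASTA); plus `ground_truth.json` and
#' `manifest.json` (seed, config, config MD5 hash, file listing).
#'
#' @param ds A [plant_regulog()] dataset.
#' @param directory Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(ds, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (g in ds$genomes) {
    fna <- file.path(directory, paste0(g$genome_id, ".fna"))
    seqs <- Biostrings::DNAStringSet(
      vapply(g$replicons, `[[`, "", "sequence"))
    names(seqs) <- names(g$replicons)
    Biostrings::writeXStringSet(seqs, fna)
    tsv <- file.path(directory, paste0(g$genome_id, "_genes.tsv"))
    write_gene_table(g, tsv)
    faa <- file.path(directory, paste0(g$genome_id, ".faa"))
    aa <- Biostrings::AAStringSet(g$proteins)
    Biostrings::writeXStringSet(aa, faa)
    files[[g$genome_id]] <- list(fasta = basename(fna),
                                 genes = basename(tsv),
                                 proteins = basename(faa))
  }
  gt_path <- file.path(directory, "ground_truth.json")
  gt <- ds$ground_truth
  gt$profile$prob_matrix <- as.data.frame(gt$profile$prob_matrix)
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  cfg_json <- jsonlite::toJSON(unclass(ds$config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(seed = ds$config$seed, config = unclass(ds$config),
                   config_md5 = md5, taxon_group = ds$config$taxon_group,
                   genomes = files)
  man_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(man_path)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory Dataset directory.
#' @return List with `genomes`, `ground_truth` and `manifest`.
#' @export
read_dataset <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  genomes <- lapply(names(manifest$genomes), function(gid) {
    f <- manifest$genomes[[gid]]
    read_genome(file.path(directory, f$fasta), file.path(directory, f$genes),
                genome_id = gid, taxon_group = manifest$taxon_group,
                protein_fasta = file.path(directory, f$proteins))
  })
  names(genomes) <- names(manifest$genomes)
  gt <- jsonlite::read_json(file.path(directory, "ground_truth.json"),
                            simplifyVector = TRUE)
  list(genomes = genomes, ground_truth = gt, manifest = manifest)
}
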