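# Genome data model: replicons, gene tables, upstream windows, operons.
#
# Coordinates are 1-based inclusive (GFF3 convention) throughout. Upstream
# windows default to -350..+50 nt relative to the first base of the start
# codon, the standard search window for bacterial operator sites.

#' Construct a replicon
#'
#' @param replicon_id Identifier matching the FASTA record id.
#' @param sequence DNA string over `{A,C,G,T,N}` (lower case is accepted and
#'   upper-cased).
#' @param circular Whether upstream windows may wrap around the origin.
#' @return An object of class `replicon`.
#' @export
replicon <- function(replicon_id, sequence, circular = FALSE) {
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("replicon '", replicon_id, "': empty sequence")
  if (!is_dna(sequence)) {
    stop("replicon '", replicon_id, "': sequence contains characters outside {A,C,G,T,N}")
  }
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "replicon")
}

#' Construct a genome from replicons and a gene table
#'
#' Validates that every gene lies on a known replicon, within its bounds,
#' and that gene identifiers are unique.
#'
#' @param genome_id Genome identifier.
#' @param replicons List of [replicon()] objects.
#' @param genes `data.frame` with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`) and optionally `product`.
#' @param taxon_group Taxonomic group label used when pooling genomes into a
#'   regulog.
#' @param proteins Optional named character vector of protein sequences,
#'   names matching `gene_id`.
#' @return An object of class `genome`.
#' @export
genome <- function(genome_id, replicons, genes, taxon_group = "unspecified",
                   proteins = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  names(replicons) <- vapply(replicons, `[[`, "", "replicon_id")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "replicon_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(genes$product)) genes$product <- ""
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rep <- replicons[[g$replicon_id]]
    if (is.null(rep)) {
      stop("gene '", g$gene_id, "': unknown replicon '", g$replicon_id, "'")
    }
    L <- nchar(rep$sequence)
    if (g$start < 1L || g$end > L || g$start > g$end) {
      stop("gene '", g$gene_id, "': coordinates ", g$start, "..", g$end,
           " outside replicon '", g$replicon_id, "' (length ", L, ")")
    }
  }
  structure(list(genome_id = genome_id, taxon_group = taxon_group,
                 replicons = replicons, genes = genes, proteins = proteins),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, " (", x$taxon_group, "): ",
      length(x$replicons), " replicon(s), ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a genome from FASTA plus a gene table
#'
#' The gene table is either GFF3 (`.gff`/`.gff3`; features of type `gene` or
#' `CDS`, `ID` and `product` attributes) or a tab-separated table with
#' columns `gene_id`, `replicon_id`, `start`, `end`, `strand`, `product`.
#'
#' @param fasta_path Path to a (multi-record) nucleotide FASTA file.
#' @param gene_table_path Path to the gene table (GFF3 or TSV).
#' @param genome_id Genome identifier; defaults to the FASTA file stem.
#' @param taxon_group Taxon-group label.
#' @param protein_fasta Optional path to a protein FASTA whose record ids are
#'   gene ids.
#' @param circular Logical, recycled over replicons.
#' @return A validated [genome()] object.
#' @export
read_genome <- function(fasta_path, gene_table_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path)),
                        taxon_group = "unspecified", protein_fasta = NULL,
                        circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  reps <- mapply(function(id, s, circ) replicon(id, s, circ),
                 ids, as.character(seqs), rep_len(circular, length(seqs)),
                 SIMPLIFY = FALSE)
  if (grepl("\\.gff3?$", gene_table_path, ignore.case = TRUE)) {
    genes <- read_gff_genes(gene_table_path)
  } else {
    genes <- utils::read.delim(gene_table_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }
  proteins <- NULL
  if (!is.null(protein_fasta)) {
    aa <- Biostrings::readAAStringSet(protein_fasta)
    proteins <- as.character(aa)
    names(proteins) <- sub("\\s.*$", "", names(aa))
  }
  genome(genome_id, reps, genes, taxon_group, proteins)
}

read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  keep <- tolower(as.character(gr$type)) %in% c("gene", "cds")
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  prod <- gr$product
  if (is.null(prod)) prod <- rep("", length(gr))
  data.frame(gene_id = as.character(ids),
             replicon_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             product = ifelse(is.na(prod), "", as.character(prod)),
             stringsAsFactors = FALSE)
}

#' Write a genome's gene table as TSV
#'
#' @param genome A [genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genome, path) {
  utils::write.table(genome$genes[, c("gene_id", "replicon_id", "start",
                                      "end", "strand", "product")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strand-aware slice of a replicon, possibly wrapping on circular replicons.
replicon_slice <- function(rep, left, right) {
  L <- nchar(rep$sequence)
  if (left >= 1L && right <= L) return(substr(rep$sequence, left, right))
  if (!rep$circular) stop("slice outside a linear replicon")
  idx <- ((seq.int(left, right) - 1L) %% L) + 1L
  paste(strsplit(rep$sequence, "", fixed = TRUE)[[1]][idx], collapse = "")
}

#' Extract the upstream region of a gene
#'
#' Returns the window `window[1]..window[2]` relative to the first base of
#' the start codon, in coding-strand orientation (reverse-complemented for
#' `-` strand genes). On linear replicons the window is clipped to the
#' replicon; on circular replicons it wraps around the origin.
#'
#' @param genome A [genome()] object.
#' @param gene_id Gene identifier.
#' @param window Integer pair `(upstream, downstream)` with
#'   `window[1] < 0 < window[2]`; default `c(-350, 50)`.
#' @param clip_to_intergenic If `TRUE`, additionally truncate the upstream
#'   side at the nearest boundary of another annotated gene.
#' @return An object of class `upstream_region` with fields `gene_id`,
#'   `replicon_id`, `left`, `right` (replicon interval), `sequence` (coding
#'   orientation) and `offset_of_start_codon` (1-based index of the start
#'   codon's first base within `sequence`), or `NULL` when clipping leaves
#'   an empty window.
#' @export
extract_upstream <- function(genome, gene_id, window = c(-350L, 50L),
                             clip_to_intergenic = FALSE) {
  stopifnot(window[1] < 0, window[2] > 0)
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id '", gene_id, "'")
  g <- genome$genes[i, ]
  rep <- genome$replicons[[g$replicon_id]]
  L <- nchar(rep$sequence)
  up <- -window[1]; down <- window[2]
  if (g$strand == "+") {
    s <- g$start
    left <- s - up; right <- s + down
  } else {
    e <- g$end
    left <- e - down; right <- e + up
  }
  if (!rep$circular) {
    left <- max(1L, left); right <- min(L, right)
  }
  if (clip_to_intergenic) {
    others <- genome$genes[genome$genes$replicon_id == g$replicon_id &
                             genome$genes$gene_id != gene_id, , drop = FALSE]
    if (g$strand == "+") {
      ups <- others$end[others$start < g$start]
      if (length(ups)) left <- max(left, max(ups) + 1L)
    } else {
      dns <- others$start[others$end > g$end]
      if (length(dns)) right <- min(right, min(dns) - 1L)
    }
  }
  if (left > right) {
    warning("empty upstream window for gene '", gene_id, "'")
    return(NULL)
  }
  raw <- replicon_slice(rep, left, right)
  if (g$strand == "+") {
    seq <- raw
    offset <- g$start - left + 1L
  } else {
    seq <- revcomp(raw)
    offset <- right - g$end + 1L
  }
  structure(list(gene_id = gene_id, genome_id = genome$genome_id,
                 replicon_id = g$replicon_id, strand = g$strand,
                 left = as.integer(left), right = as.integer(right),
                 sequence = seq, offset_of_start_codon = as.integer(offset)),
            class = "upstream_region")
}

#' Extract upstream regions for several genes
#'
#' @inheritParams extract_upstream
#' @param gene_ids Character vector of gene ids; defaults to all genes.
#' @return Named list of `upstream_region` objects (empty windows dropped).
#' @export
upstream_regions <- function(genome, gene_ids = genome$genes$gene_id,
                             window = c(-350L, 50L),
                             clip_to_intergenic = FALSE) {
  out <- lapply(gene_ids, function(g)
    extract_upstream(genome, g, window, clip_to_intergenic))
  names(out) <- gene_ids
  out[!vapply(out, is.null, TRUE)]
}

#' Write upstream regions as FASTA
#'
#' Headers follow `genome|gene|left..right|strand`.
#'
#' @param regions List of `upstream_region` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_upstream_fasta <- function(regions, path) {
  seqs <- Biostrings::DNAStringSet(vapply(regions, `[[`, "", "sequence"))
  names(seqs) <- vapply(regions, function(r)
    paste0(r$genome_id %||% "NA", "|", r$gene_id, "|", r$left, "..", r$right,
           "|", r$strand), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Predict operons from intergenic distances
#'
#' Consecutive genes on the same replicon and strand are joined into one
#' operon when the intergenic gap (`start2 - end1 - 1`) does not exceed
#' `max_gap`; a strand change or a larger gap starts a new operon.
#' Overlapping same-strand genes (negative gap) are treated as gap 0.
#'
#' @param genome A [genome()] object.
#' @param max_gap Maximum intergenic distance in nt (default 200).
#' @return List of operons; each has `operon_id`, `gene_ids` (5'->3'),
#'   `strand`, `replicon_id` and `lead_gene_id` (the first gene, whose
#'   upstream region carries candidate sites).
#' @export
predict_operons <- function(genome, max_gap = 200L) {
  out <- list()
  n_op <- 0L
  for (rid in names(genome$replicons)) {
    gs <- genome$genes[genome$genes$replicon_id == rid, , drop = FALSE]
    if (!nrow(gs)) next
    gs <- gs[order(gs$start, gs$end), , drop = FALSE]
    run_start <- 1L
    flush <- function(a, b) {
      grp <- gs[a:b, , drop = FALSE]
      n_op <<- n_op + 1L
      ids <- grp$gene_id
      if (grp$strand[1] == "-") ids <- rev(ids)  # 5'->3' on the minus strand
      out[[n_op]] <<- list(
        operon_id = sprintf("%s_opn%03d", rid, n_op),
        gene_ids = ids, strand = grp$strand[1], replicon_id = rid,
        lead_gene_id = ids[1])
    }
    if (nrow(gs) > 1L) {
      for (i in 2:nrow(gs)) {
        gap <- gs$start[i] - gs$end[i - 1L] - 1L
        if (gap < 0L) {
          message("overlapping genes ", gs$gene_id[i - 1L], "/", gs$gene_id[i],
                  ": gap treated as 0")
          gap <- 0L
        }
        if (gs$strand[i] != gs$strand[i - 1L] || gap > max_gap) {
          flush(run_start, i - 1L)
          run_start <- i
        }
      }
    }
    flush(run_start, nrow(gs))
  }
  out
}

# operon adjacencies as ordered (5'->3') gene pairs
operon_adjacencies <- function(operons) {
  do.call(rbind, lapply(operons, function(op) {
    if (length(op$gene_ids) < 2L) return(NULL)
    data.frame(g1 = op$gene_ids[-length(op$gene_ids)],
               g2 = op$gene_ids[-1L], stringsAsFactors = FALSE)
  }))
}

#' Filter operons by cross-genome persistence
#'
#' A junction between two consecutive operon genes is kept only when the
#' orthologous junction (same ordered pair of ortholog groups) occurs in at
#' least `min_genomes` genomes; operons are re-split at discarded junctions.
#' With fewer than `min_genomes` genomes the filter is skipped.
#'
#' @param operon_sets Named list (by genome id) of operon lists from
#'   [predict_operons()].
#' @param groups An [ortholog_groups()] object covering the genes.
#' @param min_genomes Minimum number of genomes supporting a junction.
#' @return Named list of filtered operon lists, same shape as `operon_sets`.
#' @export
operon_persistence <- function(operon_sets, groups, min_genomes = 2L) {
  if (length(operon_sets) < min_genomes) return(operon_sets)
  adj_keys <- lapply(operon_sets, function(ops) {
    ad <- operon_adjacencies(ops)
    if (is.null(ad)) return(character(0))
    k1 <- groups$index[ad$g1]; k2 <- groups$index[ad$g2]
    ok <- !is.na(k1) & !is.na(k2)
    unique(paste(k1[ok], k2[ok], sep = "~"))
  })
  support <- table(unlist(adj_keys))
  kept <- names(support)[support >= min_genomes]
  lapply(operon_sets, function(ops) {
    res <- list()
    for (op in ops) {
      ids <- op$gene_ids
      if (length(ids) < 2L) { res[[length(res) + 1L]] <- op; next }
      cut_after <- logical(length(ids) - 1L)
      for (j in seq_len(length(ids) - 1L)) {
        k1 <- groups$index[ids[j]]; k2 <- groups$index[ids[j + 1L]]
        key <- if (is.na(k1) || is.na(k2)) NA_character_ else paste(k1, k2, sep = "~")
        cut_after[j] <- is.na(key) || !(key %in% kept)
      }
      piece_start <- 1L
      piece_n <- 0L
      for (j in seq_along(cut_after)) {
        if (cut_after[j]) {
          piece_n <- piece_n + 1L
          res[[length(res) + 1L]] <- split_operon(op, ids[piece_start:j], piece_n)
          piece_start <- j + 1L
        }
      }
      if (piece_start == 1L) {
        res[[length(res) + 1L]] <- op
      } else {
        piece_n <- piece_n + 1L
        res[[length(res) + 1L]] <-
          split_operon(op, ids[piece_start:length(ids)], piece_n)
      }
    }
    res
  })
}

split_operon <- function(op, ids, piece) {
  list(operon_id = paste0(op$operon_id, letters[piece]),
       gene_ids = ids, strand = op$strand, replicon_id = op$replicon_id,
       lead_gene_id = ids[1])
}
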