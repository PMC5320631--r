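# Ortholog grouping by k-mer reciprocal best hits + connected components.
#
# A desk-scale surrogate for profile-search + tree-based orthology: protein
# similarity is the cosine of k-mer count vectors, best hits must be
# reciprocal between genomes, and groups are connected components of the
# resulting graph. A precomputed ortholog table (TSV) can be supplied
# instead, which is the recommended path for real annotated genomes.

kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(NULL)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  table(kmers)
}

#' Cosine k-mer similarity of two protein sequences
#'
#' @param a,b Amino-acid strings (or lists with a `sequence` field).
#' @param k k-mer length (default 4).
#' @return Similarity in `[0, 1]`; `NA` with a warning when a sequence is
#'   shorter than `k`.
#' @export
kmer_similarity <- function(a, b, k = 4L) {
  if (is.list(a)) a <- a$sequence
  if (is.list(b)) b <- b$sequence
  ca <- kmer_counts(a, k); cb <- kmer_counts(b, k)
  if (is.null(ca) || is.null(cb)) {
    warning("sequence shorter than k = ", k, "; similarity undefined")
    return(NA_real_)
  }
  cosine_from_counts(ca, cb)
}

cosine_from_counts <- function(ca, cb) {
  shared <- intersect(names(ca), names(cb))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
  num / sqrt(sum(as.numeric(ca)^2)) / sqrt(sum(as.numeric(cb)^2))
}

#' Reciprocal best hits between proteomes
#'
#' @param proteomes List of `data.frame`s, one per genome, with columns
#'   `protein_id`, `genome_id`, `sequence`.
#' @param min_sim Minimum similarity for an edge (default 0.3).
#' @param k k-mer length for [kmer_similarity()].
#' @return `data.frame` of edges with columns `a`, `b` (protein ids) and
#'   `sim`; `(x, y)` is an edge iff each is the other's best-scoring partner
#'   in the other's genome (ties broken by lexicographic protein id) and the
#'   similarity is at least `min_sim`.
#' @export
reciprocal_best_hits <- function(proteomes, min_sim = 0.3, k = 4L) {
  stopifnot(length(proteomes) >= 2L)
  proteomes <- lapply(proteomes, as.data.frame, stringsAsFactors = FALSE)
  counts <- lapply(proteomes, function(p)
    lapply(p$sequence, kmer_counts, k = k))
  edges <- list()
  ng <- length(proteomes)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    pa <- proteomes[[i]]; pb <- proteomes[[j]]
    sim <- matrix(0, nrow(pa), nrow(pb))
    for (x in seq_len(nrow(pa))) for (y in seq_len(nrow(pb))) {
      if (is.null(counts[[i]][[x]]) || is.null(counts[[j]][[y]])) next
      sim[x, y] <- cosine_from_counts(counts[[i]][[x]], counts[[j]][[y]])
    }
    # best partner with lexicographic tie-break on the partner's id
    best_in_b <- apply(sim, 1L, function(r)
      order(-r, pb$protein_id)[1L])
    best_in_a <- apply(sim, 2L, function(c)
      order(-c, pa$protein_id)[1L])
    for (x in seq_len(nrow(pa))) {
      y <- best_in_b[x]
      if (best_in_a[y] == x && sim[x, y] >= min_sim) {
        edges[[length(edges) + 1L]] <-
          data.frame(a = pa$protein_id[x], b = pb$protein_id[y],
                     sim = sim[x, y], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(a = character(0), b = character(0), sim = numeric(0)))
  }
  do.call(rbind, edges)
}

#' Build ortholog groups from RBH edges
#'
#' Groups are connected components of the reciprocal-best-hit graph, so
#' same-genome paralogs linked through a common partner land in one group.
#'
#' @param edges `data.frame` with columns `a`, `b` from
#'   [reciprocal_best_hits()].
#' @param genes Optional `data.frame` with columns `genome_id`, `gene_id`
#'   giving the full gene universe; genes absent from `edges` become
#'   singleton groups.
#' @param gene_genomes Optional named character vector mapping gene id to
#'   genome id (used when `genes` is not given).
#' @return An object of class `ortholog_groups`: `groups` (named list,
#'   group id -> data.frame(genome_id, gene_id)) and `index` (named vector
#'   gene id -> group id). Group ids are `grp_<smallest member gene id>`.
#' @export
build_groups <- function(edges, genes = NULL, gene_genomes = NULL) {
  if (is.null(gene_genomes) && !is.null(genes)) {
    gene_genomes <- stats::setNames(as.character(genes$genome_id),
                                    as.character(genes$gene_id))
  }
  verts <- unique(c(edges$a, edges$b))
  comp_of <- character(0)
  if (length(verts)) {
    g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                       vertices = verts)
    comp <- igraph::components(g)$membership
    comp_of <- stats::setNames(as.character(comp), names(comp))
  }
  all_genes <- union(verts, names(gene_genomes))
  memb <- comp_of[all_genes]
  names(memb) <- all_genes
  singles <- is.na(memb)
  memb[singles] <- paste0("s", seq_len(sum(singles)))
  split_genes <- split(all_genes, memb)
  group_ids <- vapply(split_genes, function(m) paste0("grp_", min(m)), "")
  ord <- order(group_ids)
  split_genes <- split_genes[ord]; group_ids <- group_ids[ord]
  groups <- stats::setNames(lapply(split_genes, function(m) {
    m <- sort(m)
    gm <- if (is.null(gene_genomes)) rep(NA_character_, length(m)) else
      unname(gene_genomes[m])
    data.frame(genome_id = gm, gene_id = m, stringsAsFactors = FALSE)
  }), group_ids)
  index <- stats::setNames(rep(group_ids, lengths(split_genes)),
                           unlist(split_genes, use.names = FALSE))
  structure(list(groups = groups, index = index), class = "ortholog_groups")
}

#' @export
print.ortholog_groups <- function(x, ...) {
  cat("<ortholog_groups> ", length(x$groups), " groups over ",
      length(x$index), " genes\n", sep = "")
  invisible(x)
}

#' Construct ortholog groups from a known gene -> group mapping
#'
#' @param mapping `data.frame` with columns `group_id`, `genome_id`,
#'   `gene_id` (the on-disk TSV dialect).
#' @return An `ortholog_groups` object.
#' @export
ortholog_groups <- function(mapping) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  sp <- split(mapping, mapping$group_id)
  groups <- lapply(sp, function(d)
    data.frame(genome_id = as.character(d$genome_id),
               gene_id = as.character(d$gene_id), stringsAsFactors = FALSE))
  index <- stats::setNames(rep(names(sp), vapply(sp, nrow, 0L)),
                           unlist(lapply(sp, `[[`, "gene_id"), use.names = FALSE))
  structure(list(groups = groups, index = index), class = "ortholog_groups")
}

#' Read/write ortholog groups as TSV
#'
#' Three columns: `group_id`, `genome_id`, `gene_id`.
#'
#' @param path File path.
#' @return For `read_ortholog_groups`, an `ortholog_groups` object.
#' @export
read_ortholog_groups <- function(path) {
  ortholog_groups(utils::read.delim(path, colClasses = "character"))
}

#' @rdname read_ortholog_groups
#' @param groups An `ortholog_groups` object.
#' @export
write_ortholog_groups <- function(groups, path) {
  rows <- do.call(rbind, lapply(names(groups$groups), function(gid)
    cbind(group_id = gid, groups$groups[[gid]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
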