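# Genome model: I/O round trips, upstream windows, operon prediction.

test_that("read_genome round-trips a FASTA + TSV fixture and validates input", {
  dir <- withr::local_tempdir()
  seq <- random_dna(5000, seed = 101)
  writeLines(c(">chr", seq), file.path(dir, "g.fna"))
  genes <- data.frame(gene_id = c("a", "b", "c"), replicon_id = "chr",
                      start = c(100, 900, 2000), end = c(700, 1500, 2900),
                      strand = c("+", "+", "-"), product = "p")
  utils::write.table(genes, file.path(dir, "g.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- read_genome(file.path(dir, "g.fna"), file.path(dir, "g.tsv"))
  expect_s3_class(g, "genome")
  expect_equal(nrow(g$genes), 3L)
  expect_equal(g$replicons[["chr"]]$sequence, seq)

  bad <- genes
  bad$end[2] <- 6000
  utils::write.table(bad, file.path(dir, "bad.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_genome(file.path(dir, "g.fna"), file.path(dir, "bad.tsv")),
               "b")
  dup <- rbind(genes, genes[1, ])
  utils::write.table(dup, file.path(dir, "dup.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_genome(file.path(dir, "g.fna"), file.path(dir, "dup.tsv")),
               "duplicate")
  expect_error(genome("x", replicon("chr", seq),
                      transform(genes[1, ], replicon_id = "nope")),
               "unknown replicon")
})

test_that("generator-written datasets reload with the ground-truth gene count", {
  ds <- plant_regulog(generator_config(seed = 3, n_genomes = 2))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  for (gid in names(ds$genomes)) {
    expect_equal(nrow(back$genomes[[gid]]$genes), nrow(ds$genomes[[gid]]$genes))
    expect_equal(sort(back$genomes[[gid]]$genes$gene_id),
                 sort(ds$genomes[[gid]]$genes$gene_id))
  }
})

test_that("upstream windows follow the -350..+50 rule with boundary clipping", {
  seq <- random_dna(5000, seed = 7)
  g <- toy_genome(seq, data.frame(
    gene_id = c("plus", "edge", "minus"), replicon_id = "chr",
    start = c(1000, 100, 2000), end = c(1600, 700, 2500),
    strand = c("+", "+", "-")))
  r <- extract_upstream(g, "plus")
  expect_equal(c(r$left, r$right), c(650, 1050))
  expect_equal(nchar(r$sequence), 401L)
  expect_equal(r$offset_of_start_codon, 351L)
  expect_equal(r$sequence, substr(seq, 650, 1050))

  r2 <- extract_upstream(g, "edge")
  expect_equal(c(r2$left, r2$right), c(1, 150))
  expect_equal(nchar(r2$sequence), 150L)

  # minus strand: start codon at the gene end, sequence reverse-complemented
  r3 <- extract_upstream(g, "minus")
  expect_equal(c(r3$left, r3$right), c(2450, 2850))
  expect_equal(r3$sequence, oracle_revcomp(substr(seq, 2450, 2850)))
  expect_equal(r3$offset_of_start_codon, 351L)

  expect_error(extract_upstream(g, "nope"), "unknown gene_id")
})

test_that("upstream windows respect clipping options and degenerate cases", {
  seq <- random_dna(3000, seed = 8)
  g <- toy_genome(seq, data.frame(
    gene_id = c("up", "target"), replicon_id = "chr",
    start = c(100, 1000), end = c(950, 1900), strand = "+"))
  r <- extract_upstream(g, "target", clip_to_intergenic = TRUE)
  expect_equal(r$left, 951)
  full <- extract_upstream(g, "target")
  expect_equal(full$left, 650)
  # an upstream gene running past the start codon leaves no intergenic
  # window at all: empty-region signal, not an error
  g2 <- toy_genome(seq, data.frame(
    gene_id = c("up", "target"), replicon_id = "chr",
    start = c(100, 1000), end = c(1100, 1900), strand = "+"))
  expect_warning(r2 <- extract_upstream(g2, "target", window = c(-350, 50),
                                        clip_to_intergenic = TRUE),
                 "empty")
  expect_null(r2)
  g3 <- toy_genome(seq, data.frame(
    gene_id = c("up", "target"), replicon_id = "chr",
    start = c(100, 1000), end = c(2100, 1900), strand = "+"))
  expect_warning(r3 <- extract_upstream(g3, "target", window = c(-350, 50),
                                        clip_to_intergenic = TRUE),
                 "empty")
  expect_null(r3)
})

test_that("circular replicons wrap the upstream window across the origin", {
  seq <- random_dna(1000, seed = 9)
  g <- genome("circ", replicon("chr", seq, circular = TRUE),
              data.frame(gene_id = "a", replicon_id = "chr",
                         start = 100, end = 600, strand = "+"))
  r <- extract_upstream(g, "a")
  expect_equal(nchar(r$sequence), 401L)
  # window -250..150 wraps: positions -250..0 map to 750..1000
  expect_equal(substr(r$sequence, 1, 251), substr(seq, 750, 1000))
  expect_equal(substr(r$sequence, 252, 401), substr(seq, 1, 150))
})

test_that("strand symmetry: the mirrored locus yields the identical region", {
  seq <- random_dna(4000, seed = 10)
  L <- nchar(seq)
  g_fwd <- toy_genome(seq, data.frame(gene_id = "x", replicon_id = "chr",
                                      start = 1500, end = 2200, strand = "+"))
  g_rev <- toy_genome(oracle_revcomp(seq),
                      data.frame(gene_id = "x", replicon_id = "chr",
                                 start = L - 2200 + 1, end = L - 1500 + 1,
                                 strand = "-"))
  expect_equal(extract_upstream(g_fwd, "x")$sequence,
               extract_upstream(g_rev, "x")$sequence)
})

test_that("planted markers are recovered at the predicted offset", {
  ds <- plant_regulog(generator_config(seed = 21, n_genomes = 2))
  gt <- ds$ground_truth
  for (i in seq_len(nrow(gt$sites))) {
    s <- gt$sites[i, ]
    r <- extract_upstream(ds$genomes[[s$genome_id]], s$gene_id)
    idx <- s$position + r$offset_of_start_codon
    expect_equal(substr(r$sequence, idx, idx + gt$span - 1L), s$site_seq)
  }
})

test_that("operons split at gaps above the cutoff and strand changes", {
  seq <- random_dna(3000, seed = 11)
  g <- toy_genome(seq, data.frame(
    gene_id = c("A", "B", "C"), replicon_id = "chr",
    start = c(100, 450, 1150), end = c(400, 900, 1500), strand = "+"))
  ops <- predict_operons(g)
  expect_equal(lapply(ops, `[[`, "gene_ids"), list(c("A", "B"), "C"))
  expect_equal(ops[[1]]$lead_gene_id, "A")

  # boundary: gap of exactly 200 joins, 201 splits
  g200 <- toy_genome(seq, data.frame(
    gene_id = c("A", "B"), replicon_id = "chr",
    start = c(100, 601), end = c(400, 900), strand = "+"))
  expect_length(predict_operons(g200), 1L)
  g201 <- toy_genome(seq, data.frame(
    gene_id = c("A", "B"), replicon_id = "chr",
    start = c(100, 602), end = c(400, 900), strand = "+"))
  expect_length(predict_operons(g201), 2L)

  # strand change splits even at distance 0; single gene forms its own operon
  gs <- toy_genome(seq, data.frame(
    gene_id = c("A", "B"), replicon_id = "chr",
    start = c(100, 450), end = c(400, 900), strand = c("+", "-")))
  expect_length(predict_operons(gs), 2L)
  g1 <- toy_genome(seq, data.frame(gene_id = "A", replicon_id = "chr",
                                   start = 100, end = 400, strand = "+"))
  expect_equal(predict_operons(g1)[[1]]$gene_ids, "A")

  # overlapping genes are treated as gap 0 and joined, with a message
  gov <- toy_genome(seq, data.frame(
    gene_id = c("A", "B"), replicon_id = "chr",
    start = c(100, 380), end = c(400, 900), strand = "+"))
  expect_message(ov <- predict_operons(gov), "overlapping")
  expect_length(ov, 1L)
})

test_that("minus-strand operons are ordered 5' to 3' with the right lead", {
  seq <- random_dna(3000, seed = 12)
  g <- toy_genome(seq, data.frame(
    gene_id = c("A", "B"), replicon_id = "chr",
    start = c(100, 500), end = c(450, 900), strand = "-"))
  ops <- predict_operons(g)
  expect_equal(ops[[1]]$gene_ids, c("B", "A"))
  expect_equal(ops[[1]]$lead_gene_id, "B")
})

test_that("predicted operons partition the genes and match planted operons", {
  ds <- plant_regulog(generator_config(seed = 13, n_genomes = 3))
  for (gid in names(ds$genomes)) {
    g <- ds$genomes[[gid]]
    ops <- predict_operons(g)
    got <- unlist(lapply(ops, `[[`, "gene_ids"))
    expect_setequal(got, g$genes$gene_id)
    expect_equal(anyDuplicated(got), 0L)
    planted <- ds$ground_truth$operons[[gid]]
    planted_sets <- lapply(planted, sort)
    pred_sets <- lapply(ops, function(o) sort(o$gene_ids))
    for (p in planted_sets) {
      expect_true(any(vapply(pred_sets, identical, TRUE, p)))
    }
    # leads agree with the planted transcription order
    for (fam in names(planted)) {
      lead <- planted[[fam]][1]
      expect_true(any(vapply(ops, function(o)
        identical(o$gene_ids, planted[[fam]]) && o$lead_gene_id == lead,
        TRUE)))
    }
  }
})

test_that("operon persistence keeps supported junctions and splits the rest", {
  seq <- random_dna(4000, seed = 14)
  mk <- function(starts, ends, ids) toy_genome(seq, data.frame(
    gene_id = ids, replicon_id = "chr", start = starts, end = ends,
    strand = "+"))
  # three genomes share the a-b junction; genome 3 fuses b-c spuriously
  g1 <- mk(c(100, 450), c(400, 900), c("a1", "b1"))
  g2 <- mk(c(100, 450), c(400, 900), c("a2", "b2"))
  g3 <- mk(c(100, 450, 1000), c(400, 900, 1500), c("a3", "b3", "c3"))
  ops <- list(g1 = predict_operons(g1), g2 = predict_operons(g2),
              g3 = predict_operons(g3))
  groups <- ortholog_groups(data.frame(
    group_id = rep(c("A", "B", "C"), times = c(3, 3, 1)),
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g3", "g3"),
    gene_id = c("a1", "a2", "a3", "b1", "b2", "b3", "c3")))
  filt <- operon_persistence(ops, groups, min_genomes = 2)
  expect_equal(lapply(filt$g1, `[[`, "gene_ids"), list(c("a1", "b1")))
  sets3 <- lapply(filt$g3, `[[`, "gene_ids")
  expect_true(list(c("a3", "b3")) %in% sets3 || any(vapply(sets3, identical, TRUE, c("a3", "b3"))))
  expect_true(any(vapply(sets3, identical, TRUE, "c3")))
  # with fewer genomes than min_genomes the filter is skipped
  expect_identical(operon_persistence(ops["g1"], groups, min_genomes = 2),
                   ops["g1"])
})

test_that("upstream FASTA export uses the documented header dialect", {
  ds <- plant_regulog(generator_config(seed = 15, n_genomes = 1))
  g <- ds$genomes[[1]]
  rs <- upstream_regions(g, g$genes$gene_id[1:2])
  path <- withr::local_tempfile(fileext = ".fna")
  write_upstream_fasta(rs, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), 2L)
  expect_match(names(back)[1], "^g01\\|.+\\|\\d+\\.\\.\\d+\\|[+-]$")
  expect_equal(as.character(back[[1]]), rs[[1]]$sequence)
})
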