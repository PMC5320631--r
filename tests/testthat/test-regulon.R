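# Candidate collection, the weak-site rule, consistency check, stats.

mk_hit <- function(gene, pos, score, weak, genome = "g1") {
  data.frame(gene_id = gene, genome_id = genome, region_pos = NA_integer_,
             position = pos, strand = "+", score = score, weak = weak,
             site_seq = "", stringsAsFactors = FALSE)
}

toy_operons <- function(...) {
  ops <- list(...)
  lapply(seq_along(ops), function(i)
    list(operon_id = paste0("op", i), gene_ids = ops[[i]], strand = "+",
         replicon_id = "chr", lead_gene_id = ops[[i]][1]))
}

test_that("candidates are operons whose lead carries a hit", {
  ops <- toy_operons(c("a", "b"), "c")
  hits <- rbind(mk_hit("a", -80, 10, FALSE), mk_hit("c", -120, 4, TRUE))
  cand <- collect_candidates(hits, ops)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$operon_id, c("op1", "op2"))
  expect_equal(cand$lead_gene_id[cand$operon_id == "op1"], "a")

  # a hit on a non-lead gene is reassigned to the operon lead, with a note
  expect_message(c2 <- collect_candidates(mk_hit("b", -50, 8, FALSE), ops),
                 "reassigned")
  expect_equal(c2$operon_id, "op1")
  expect_equal(c2$lead_gene_id, "a")

  expect_equal(nrow(collect_candidates(hits[0, ], ops)), 0L)
})

test_that("the weak-site rule follows the positional truth table", {
  cfg <- reconstruction_config()
  anchors <- rbind(mk_hit("o1", -75, 12, FALSE, "g2"),
                   mk_hit("o2", -77, 11, FALSE, "g3"))
  # within tolerance of the anchor median (-76), no competitor: accepted
  expect_true(weak_site_rule(mk_hit("x", -74, 6, TRUE), anchors, cfg))
  # outside the tolerance: rejected
  expect_false(weak_site_rule(mk_hit("x", -150, 6, TRUE), anchors, cfg))
  # a stronger strong site elsewhere in the same region: rejected
  region <- rbind(mk_hit("x", -74, 6, TRUE), mk_hit("x", -200, 13, FALSE))
  expect_false(weak_site_rule(mk_hit("x", -74, 6, TRUE), anchors, cfg,
                              region_hits = region))
  # no anchors at all: rejected
  expect_false(weak_site_rule(mk_hit("x", -74, 6, TRUE), anchors[0, ], cfg))
  # positional tolerance is configurable
  wide <- reconstruction_config(position_tolerance = 100)
  expect_true(weak_site_rule(mk_hit("x", -150, 6, TRUE), anchors, wide))
})

test_that("consistency check needs K genomes and expands to whole operons", {
  ops <- list()
  cands <- list()
  for (g in paste0("g", 1:6)) {
    ops[[g]] <- toy_operons(c(paste0(g, "_fam1_a"), paste0(g, "_fam1_b")),
                            paste0(g, "_fam2_a"))
  }
  groups <- ortholog_groups(data.frame(
    group_id = rep(c("F1", "F2"), each = 6),
    genome_id = rep(paste0("g", 1:6), 2),
    gene_id = c(paste0("g", 1:6, "_fam1_a"), paste0("g", 1:6, "_fam2_a"))))
  # fam1: strong hits in 3 genomes; fam2: hit in 1 genome only
  for (g in paste0("g", 1:6)) {
    h <- mk_hit(paste0(g, "_fam1_a"), -70, 10, FALSE, g)[0, ]
    if (g %in% c("g1", "g2", "g3")) {
      h <- mk_hit(paste0(g, "_fam1_a"), -70, 10, FALSE, g)
    }
    if (g == "g4") {
      h <- rbind(h, mk_hit(paste0(g, "_fam2_a"), -90, 10, FALSE, g))
    }
    cands[[g]] <- collect_candidates(h, ops[[g]])
  }
  cfg <- reconstruction_config()  # K(6) = max(2, 2) = 2
  rg <- consistency_check(cands, ops, groups, cfg)
  expect_s3_class(rg, "regulog")
  expect_equal(rg$families, "F1")
  # included exactly where a hit exists, expanded to both operon genes
  expect_equal(length(rg$regulons$g1$members), 1L)
  expect_equal(rg$regulons$g1$members[[1]]$operon$gene_ids,
               c("g1_fam1_a", "g1_fam1_b"))
  expect_length(rg$regulons$g4$members, 0L)
  expect_length(rg$regulons$g5$members, 0L)
  st <- regulog_stats(rg)
  expect_equal(st$n_regulons, 3L)
  expect_equal(st$n_target_genes, 6L)
})

test_that("weak sites join only through orthologous strong anchors", {
  ops <- list(); cands <- list()
  for (g in paste0("g", 1:3)) {
    ops[[g]] <- toy_operons(paste0(g, "_fam1_a"))
  }
  groups <- ortholog_groups(data.frame(
    group_id = "F1", genome_id = paste0("g", 1:3),
    gene_id = paste0("g", 1:3, "_fam1_a")))
  h1 <- mk_hit("g1_fam1_a", -75, 10, FALSE, "g1")
  h2 <- mk_hit("g2_fam1_a", -77, 11, FALSE, "g2")
  h3w <- mk_hit("g3_fam1_a", -74, 6, TRUE, "g3")  # near the anchors
  cands$g1 <- collect_candidates(h1, ops$g1)
  cands$g2 <- collect_candidates(h2, ops$g2)
  cands$g3 <- collect_candidates(h3w, ops$g3)
  rg <- consistency_check(cands, ops, groups, reconstruction_config())
  expect_length(rg$regulons$g3$members, 1L)

  # the same weak hit far from the anchors does not join
  cands$g3 <- collect_candidates(mk_hit("g3_fam1_a", -200, 6, TRUE, "g3"),
                                 ops$g3)
  rg2 <- consistency_check(cands, ops, groups, reconstruction_config())
  expect_length(rg2$regulons$g3$members, 0L)
})

test_that("a single-genome regulog accepts only strong sites", {
  ops <- list(g1 = toy_operons("g1_a", "g1_b"))
  groups <- ortholog_groups(data.frame(group_id = c("A", "B"),
                                       genome_id = "g1",
                                       gene_id = c("g1_a", "g1_b")))
  cands <- list(g1 = collect_candidates(
    rbind(mk_hit("g1_a", -70, 10, FALSE), mk_hit("g1_b", -80, 5, TRUE)),
    ops$g1))
  rg <- consistency_check(cands, ops, groups, reconstruction_config())
  expect_length(rg$regulons$g1$members, 1L)
  expect_equal(rg$regulons$g1$members[[1]]$operon$gene_ids, "g1_a")
})

test_that("membership is antitone in the score threshold", {
  ds <- plant_regulog(generator_config(seed = 81, n_genomes = 6))
  gt <- ds$ground_truth
  res <- reconstruct_regulog(ds$genomes, member_regions(ds))
  n_base <- length(regulogR:::regulog_member_pairs(res$regulog))
  # raise the threshold well above every site score and re-run the
  # downstream steps: membership can only shrink
  cfg_hi <- res$scan_config
  cfg_hi$threshold <- cfg_hi$threshold + 100
  cfg_hi$weak_floor <- cfg_hi$weak_floor + 100
  cands <- list()
  for (gid in names(ds$genomes)) {
    leads <- vapply(res$operons[[gid]], `[[`, "", "lead_gene_id")
    regions <- upstream_regions(ds$genomes[[gid]], leads)
    cands[[gid]] <- collect_candidates(
      scan_regions(res$pwm, regions, cfg_hi), res$operons[[gid]])
  }
  groups <- ortholog_groups(data.frame(
    group_id = gt$ortholog_map$family, genome_id = gt$ortholog_map$genome_id,
    gene_id = gt$ortholog_map$gene_id))
  rg_hi <- consistency_check(cands, res$operons, groups)
  expect_lte(length(regulogR:::regulog_member_pairs(rg_hi)), n_base)
  expect_equal(length(regulogR:::regulog_member_pairs(rg_hi)), 0L)
})

test_that("every member operon traces back to at least one stored hit", {
  ds <- plant_regulog(generator_config(seed = 82, n_genomes = 6))
  res <- reconstruct_regulog(ds$genomes, member_regions(ds))
  for (r in res$regulog$regulons) {
    for (m in r$members) {
      expect_gte(nrow(m$hits), 1L)
      expect_true(m$operon$lead_gene_id %in% m$hits$lead_gene_id)
    }
  }
  st <- regulog_stats(res$regulog)
  expect_gte(st$n_sites, st$n_operons)
})

test_that("empty regulogs report zero counts and export cleanly", {
  ops <- list(g1 = toy_operons("g1_a"))
  groups <- ortholog_groups(data.frame(group_id = "A", genome_id = "g1",
                                       gene_id = "g1_a"))
  cands <- list(g1 = collect_candidates(mk_hit("x", -1, 1, FALSE)[0, ],
                                        ops$g1))
  rg <- consistency_check(cands, ops, groups)
  st <- regulog_stats(rg)
  expect_equal(st$n_regulons, 0L)
  expect_equal(st$n_sites, 0L)
  expect_equal(st$n_target_genes, 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regulog(rg, path)
  expect_equal(nrow(utils::read.delim(path)), 0L)
})

test_that("regulog TSV export carries one row per member gene", {
  ds <- plant_regulog(generator_config(seed = 83, n_genomes = 4))
  res <- reconstruct_regulog(ds$genomes, member_regions(ds), group_id = "tfX")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regulog(res$regulog, path)
  tab <- utils::read.delim(path)
  st <- regulog_stats(res$regulog)
  expect_equal(nrow(tab), st$n_target_genes)
  expect_true(all(tab$group_id == "tfX"))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_target_genes, st$n_target_genes)
})
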