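# PWM construction, scoring, thresholds, scanning.

test_that("PWM weights follow the centred log-count formula", {
  # uniform column: all four weights zero
  p <- build_pwm(c("A", "C", "G", "T"))
  expect_equal(unname(p$weights[, 1]), rep(0, 4), tolerance = 1e-12)

  # single-base column, frozen values from direct evaluation of
  # ln(N + 0.5) - mean_b ln(N_b + 0.5) with counts (4, 0, 0, 0)
  p4 <- build_pwm(c("A", "A", "A", "A"))
  expect_equal(unname(p4$weights["A", 1]), 1.6479, tolerance = 1e-4)
  expect_equal(unname(p4$weights["C", 1]), -0.5493, tolerance = 1e-4)
  expect_equal(unname(p4$weights["G", 1]), -0.5493, tolerance = 1e-4)

  # column weight sums vanish for arbitrary alignments (algebraic identity)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    W <- sample(4:10, 1)
    sites <- vapply(seq_len(n), function(j) random_dna(W), "")
    pw <- build_pwm(sites)
    expect_equal(max(abs(colSums(pw$weights))), 0, tolerance = 1e-9)
    expect_equal(max(abs(colSums(pw$probs) - 1)), 0, tolerance = 1e-12)
  }

  expect_error(build_pwm("ACGT"), "at least 2")
  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
})

test_that("site scoring is additive and strand-symmetric", {
  aln <- c("ATG", "ATG", "ATG", "ACG")
  p <- build_pwm(aln)
  # frozen value from per-column hand evaluation of the weight formula
  expect_equal(score_site(p, "ATG"), 4.4806, tolerance = 1e-4)
  # consensus maximizes the additive score
  cons <- p$consensus
  set.seed(52)
  for (i in 1:20) {
    expect_lte(score_site(p, random_dna(3)), score_site(p, cons))
  }
  # strand symmetry through the reverse-complement PWM
  s <- "ATG"
  expect_equal(score_site(pwm_revcomp(p), oracle_revcomp(s)),
               score_site(p, s), tolerance = 1e-12)
  expect_true(is.na(score_site(p, "ANG")))
  expect_error(score_site(p, "ATGA"), "width")
})

test_that("adding a consensus site never decreases consensus weights", {
  set.seed(53)
  sites <- vapply(1:8, function(i) random_dna(6), "")
  p <- build_pwm(sites)
  cons <- p$consensus
  p2 <- build_pwm(c(sites, cons))
  cb <- strsplit(cons, "")[[1]]
  for (k in seq_len(6)) {
    expect_gte(p2$weights[cb[k], k], p$weights[cb[k], k])
  }
})

test_that("thresholds sit 10% below the training minimum, sign-safely", {
  cfg <- compute_threshold(c(4.4806, 4.0, 3.5))
  expect_equal(cfg$threshold, 3.15, tolerance = 1e-12)
  expect_equal(cfg$weak_floor, 2.835, tolerance = 1e-12)
  cfg_neg <- compute_threshold(c(-2.0, 1.0))
  expect_equal(cfg_neg$threshold, -2.2, tolerance = 1e-12)
  expect_equal(cfg_neg$weak_floor, -2.42, tolerance = 1e-12)
  cfg0 <- compute_threshold(c(0, 2))
  expect_equal(cfg0$threshold, 0)
  expect_equal(cfg0$weak_floor, 0)
  # monotone in the training minimum
  set.seed(54)
  ms <- sort(runif(10, -5, 5))
  ts <- vapply(ms, function(m) compute_threshold(m)$threshold, 0)
  expect_true(all(diff(ts) > 0))
})

test_that("scanning finds a planted consensus exactly once", {
  set.seed(55)
  sites <- c("TGTAAAGC", "TGTAAAGC", "TGTCAAGC", "TGTAATGC")
  p <- build_pwm(sites)
  cfg <- compute_threshold(vapply(sites, score_site, 0, pwm = p))
  reg <- paste0(random_dna(40), "TGTAAAGC", random_dna(40))
  hits <- scan_region(p, reg, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$region_pos, 41L)
  expect_false(hits$weak)
  expect_equal(hits$site_seq, "TGTAAAGC")

  # palindromic consensus: the forward/reverse tie breaks to forward
  pal_sites <- c("TGTACA", "TGTACA", "TGTACA", "TGGACA")
  pp <- build_pwm(pal_sites)
  pcfg <- compute_threshold(vapply(pal_sites, score_site, 0, pwm = pp))
  preg <- paste0(random_dna(30), "TGTACA", random_dna(30))
  ph <- scan_region(pp, preg, pcfg)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$strand, "+")

  # windows containing N are skipped; short regions give empty results
  regn <- paste0("TGTANAGC")
  expect_equal(nrow(scan_region(p, regn, cfg)), 0L)
  expect_equal(nrow(scan_region(p, "TGTA", cfg)), 0L)
})

test_that("hit positions are reported relative to the start codon", {
  ds <- plant_regulog(generator_config(seed = 56, n_genomes = 3))
  gt <- ds$ground_truth
  aln <- gt$sites$site_seq
  p <- build_pwm(aln)
  cfg <- compute_threshold(vapply(aln, score_site, 0, pwm = p))
  for (i in c(1, 5, 9)) {
    s <- gt$sites[i, ]
    r <- extract_upstream(ds$genomes[[s$genome_id]], s$gene_id)
    hits <- scan_region(p, r, cfg)
    strong <- hits[!hits$weak, ]
    expect_true(s$position %in% strong$position)
  }
})

test_that("scan_region agrees with brute-force enumeration on short sequences", {
  set.seed(57)
  sites <- vapply(1:6, function(i) random_dna(5), "")
  p <- build_pwm(sites)
  cfg <- compute_threshold(vapply(sites, score_site, 0, pwm = p))
  cfg$weak_floor <- -5  # force plenty of candidate windows
  for (case in 1:40) {
    seq <- random_dna(sample(5:60, 1))
    got <- scan_region(p, seq, cfg)
    want <- oracle_scan(p, seq, cfg)
    expect_equal(got$region_pos, want$region_pos)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("PWMs serialize to MEME format with a weights sidecar", {
  p <- build_pwm(c("ACGTAC", "ACGTAC", "ACGTTC"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_pwm_meme(p, path, name = "op1")
  txt <- readLines(path)
  expect_true(any(grepl("MEME version 4", txt)))
  expect_true(any(grepl("MOTIF op1", txt)))
  mat_start <- grep("letter-probability matrix", txt)
  probs <- do.call(rbind, lapply(strsplit(trimws(
    txt[(mat_start + 1):(mat_start + 6)]), "\\s+"), as.numeric))
  expect_equal(unname(t(probs)), unname(p$probs), tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".weights.tsv")))
})
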