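# Independent oracles and small fixture builders used across tests.

# reverse complement through Biostrings, independent of the package's
# base-R implementation
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# brute-force scan: score every window on both strands with score_site,
# keep scores >= weak floor, then resolve overlaps with an explicit
# quadratic greedy pass (descending score; ties smaller position, then
# forward strand)
oracle_scan <- function(pwm, seq, cfg) {
  W <- pwm$width
  n <- nchar(seq)
  if (n < W) return(data.frame(region_pos = integer(0), strand = character(0),
                               score = numeric(0)))
  cand <- list()
  for (p in seq_len(n - W + 1L)) {
    win <- substr(seq, p, p + W - 1L)
    sf <- score_site(pwm, win)
    if (!is.na(sf) && sf >= cfg$weak_floor) {
      cand[[length(cand) + 1L]] <- data.frame(region_pos = p, strand = "+",
                                              score = sf)
    }
    if (isTRUE(cfg$both_strands)) {
      sr <- score_site(pwm, oracle_revcomp(win))
      if (!is.na(sr) && sr >= cfg$weak_floor) {
        cand[[length(cand) + 1L]] <- data.frame(region_pos = p, strand = "-",
                                                score = sr)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(region_pos = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  ord <- order(-cand$score, cand$region_pos, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (nrow(kept)) {
      for (j in seq_len(nrow(kept))) {
        if (cand$region_pos[i] <= kept$region_pos[j] + W - 1L &&
            kept$region_pos[j] <= cand$region_pos[i] + W - 1L) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) kept <- rbind(kept, cand[i, ])
  }
  kept <- kept[order(kept$region_pos), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# canonicalization oracle: enumerate the arrangement and its strand flip
# as strings and take the minimum under ">" < "<"
oracle_canonicalize <- function(arrows) {
  flip <- rev(ifelse(arrows == ">", "<", ">"))
  key <- function(a) paste(match(a, c(">", "<")), collapse = "")
  if (key(flip) < key(arrows)) flip else arrows
}

all_arrow_strings <- function(lengths = 2:4) {
  out <- list()
  for (n in lengths) {
    grid <- expand.grid(rep(list(c(">", "<")), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) out[[length(out) + 1L]] <-
      unname(unlist(grid[i, ]))
  }
  out
}

# deterministic random DNA string
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# one-replicon test genome from a gene table sketch
toy_genome <- function(seq, genes, genome_id = "toy", circular = FALSE) {
  genome(genome_id, replicon("chr", seq, circular), genes)
}

# upstream regions of all planted member lead genes of a dataset
member_regions <- function(ds, window = c(-350L, 50L)) {
  gt <- ds$ground_truth
  regions <- vector("list", nrow(gt$sites))
  for (i in seq_len(nrow(gt$sites))) {
    regions[[i]] <- extract_upstream(ds$genomes[[gt$sites$genome_id[i]]],
                                     gt$sites$gene_id[i], window = window)
  }
  regions
}

# motif model assembled directly from a planted profile (bypasses
# discovery; used to test classification in isolation)
planted_motif_model <- function(consensus, arrows, gaps, n_sites = 30,
                                site_mut = 0.07, seed = 1) {
  set.seed(seed)
  w <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1]]
  sample_inst <- function() {
    b <- cons
    mut <- runif(w) < site_mut
    if (any(mut)) b[mut] <- vapply(b[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  shared <- build_pwm(vapply(seq_len(n_sites), function(i) sample_inst(), ""))
  boxes <- lapply(arrows, function(a)
    if (a == ">") shared else pwm_revcomp(shared))
  structure(list(boxes = boxes, orientations = arrows, gaps = gaps,
                 width = w, shared = shared),
            class = "motif_model")
}
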