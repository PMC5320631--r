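# Position weight matrices: construction from a training alignment of
# sites, additive log-odds scoring, the "10% below the lowest training
# score" threshold rule, and both-strand scanning of upstream regions.

#' Build a position weight matrix from aligned sites
#'
#' Weights follow the log-count construction with a 0.5 pseudocount,
#' centred per column:
#' `w(b,k) = ln(N(b,k) + 0.5) - (1/4) * sum_b' ln(N(b',k) + 0.5)`.
#' Probabilities are `p(b,k) = (N(b,k) + 0.5) / (n + 2)` for `n` sites, and
#' per-column information content is `IC(k) = 2 + sum_b p * log2(p)` bits.
#'
#' @param sites Character vector of equal-length DNA strings over
#'   `{A,C,G,T}` (at least 2).
#' @param gene_ids Optional character vector recording the source genes of
#'   the training sites.
#' @return An object of class `pwm` with fields `width`, `nsites`,
#'   `counts`, `weights`, `probs` (4 x width matrices, rows A,C,G,T), `ic`
#'   (bits per column) and `consensus`.
#' @export
build_pwm <- function(sites, gene_ids = NULL) {
  sites <- toupper(sites)
  if (length(sites) < 2L) stop("need at least 2 training sites")
  W <- nchar(sites[1L])
  if (any(nchar(sites) != W)) stop("training sites must have equal length")
  if (any(!grepl("^[ACGT]+$", sites))) {
    stop("training sites must be over {A,C,G,T}")
  }
  mat <- do.call(rbind, lapply(sites, base_ints))
  counts <- vapply(seq_len(W), function(k)
    tabulate(mat[, k], nbins = 4L), integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  pwm_from_counts(counts, length(sites), gene_ids)
}

pwm_from_counts <- function(counts, nsites, gene_ids = NULL) {
  lw <- log(counts + 0.5)
  weights <- sweep(lw, 2L, colMeans(lw))
  probs <- (counts + 0.5) / (nsites + 2)
  ic <- 2 + colSums(probs * log2(probs))
  consensus <- paste(DNA_BASES[apply(counts, 2L, which.max)], collapse = "")
  structure(list(width = ncol(counts), nsites = nsites, counts = counts,
                 weights = weights, probs = probs, ic = ic,
                 consensus = consensus, gene_ids = gene_ids),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width ", x$width, ", ", x$nsites, " sites, consensus ",
      x$consensus, "\n  IC/column: ",
      paste(sprintf("%.2f", x$ic), collapse = " "), " bits\n", sep = "")
  invisible(x)
}

#' @export
plot.pwm <- function(x, ...) {
  graphics::barplot(x$ic, names.arg = strsplit(x$consensus, "")[[1]],
                    ylab = "information content (bits)",
                    xlab = "position (consensus base)", ylim = c(0, 2), ...)
  invisible(x)
}

#' Reverse complement of a PWM
#'
#' @param pwm A [build_pwm()] object.
#' @return The `pwm` describing sites read on the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  flip <- function(m) m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE][
    , , drop = FALSE]
  counts <- flip(pwm$counts)
  rownames(counts) <- DNA_BASES
  out <- pwm_from_counts(counts, pwm$nsites, pwm$gene_ids)
  out
}

#' Score one site against a PWM
#'
#' Additive log-odds score, `sum_k w(s[k], k)`.
#'
#' @param pwm A `pwm` object.
#' @param s DNA string of length `pwm$width`.
#' @return Numeric score; `NA` when `s` contains an ambiguous base.
#' @export
score_site <- function(pwm, s) {
  s <- toupper(s)
  if (nchar(s) != pwm$width) {
    stop("site length ", nchar(s), " != PWM width ", pwm$width)
  }
  ints <- base_ints(s)
  if (anyNA(ints)) return(NA_real_)
  sum(pwm$weights[cbind(ints, seq_len(pwm$width))])
}

# Scores of all windows of a sequence against a PWM (forward orientation of
# the sequence). NA where the window is incomplete or contains N.
score_windows <- function(pwm, seq) {
  n <- nchar(seq)
  W <- pwm$width
  if (n < W) return(numeric(0))
  ints <- base_ints(seq)
  npos <- n - W + 1L
  idx <- outer(seq_len(npos), 0:(W - 1L), `+`)
  b <- matrix(ints[idx], nrow = npos)
  sc <- matrix(NA_real_, npos, W)
  ok <- !is.na(b)
  cols <- col(b)
  sc[ok] <- pwm$weights[cbind(b[ok], cols[ok])]
  rowSums(sc)
}

#' Score threshold from a training set
#'
#' With `m` the lowest training-set score, the search threshold is set 10%
#' below it, `T = m - 0.1 * |m|` (sign-safe), and weaker sites down to
#' another 10% below the threshold (`weak_floor = T - 0.1 * |T|`) are kept
#' as rescue candidates for the positional weak-site rule.
#'
#' @param training_scores Non-empty numeric vector of site scores.
#' @param both_strands Scan both strands (default `TRUE`).
#' @param window Scan window relative to the start codon.
#' @return An object of class `scan_config` with `threshold`, `weak_floor`,
#'   `both_strands` and `window`.
#' @export
compute_threshold <- function(training_scores, both_strands = TRUE,
                              window = c(-350L, 50L)) {
  stopifnot(length(training_scores) >= 1L)
  m <- min(training_scores)
  thr <- m - 0.1 * abs(m)
  structure(list(threshold = thr, weak_floor = thr - 0.1 * abs(thr),
                 both_strands = both_strands, window = window),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config> threshold ", sprintf("%.4f", x$threshold),
      ", weak floor ", sprintf("%.4f", x$weak_floor),
      if (x$both_strands) ", both strands" else ", forward strand only",
      "\n", sep = "")
  invisible(x)
}

#' Scan an upstream region for PWM hits
#'
#' Slides the PWM over the region (and, by default, its reverse
#' complement), keeps windows scoring at least `cfg$weak_floor`, and
#' resolves overlaps greedily by descending score (ties: smaller position,
#' then forward strand). Windows containing `N` are skipped. Hits with
#' score below `cfg$threshold` are flagged `weak`.
#'
#' @param pwm A `pwm` object.
#' @param region An `upstream_region` from [extract_upstream()], or a plain
#'   DNA string (positions are then reported relative to the sequence end,
#'   as if the whole string were upstream of the start codon).
#' @param cfg A `scan_config` from [compute_threshold()].
#' @return `data.frame` with columns `gene_id`, `genome_id`, `region_pos`
#'   (1-based offset of the site's leftmost base in the region), `position`
#'   (leftmost base relative to the start codon; negative = upstream),
#'   `strand` (relative to the coding strand), `score`, `weak`,
#'   `site_seq` (in hit orientation).
#' @export
scan_region <- function(pwm, region, cfg) {
  if (is.character(region)) {
    region <- list(gene_id = NA_character_, genome_id = NA_character_,
                   sequence = toupper(region),
                   offset_of_start_codon = nchar(region) + 1L)
  }
  seq <- region$sequence
  W <- pwm$width
  n <- nchar(seq)
  empty <- data.frame(gene_id = character(0), genome_id = character(0),
                      region_pos = integer(0), position = integer(0),
                      strand = character(0), score = numeric(0),
                      weak = logical(0), site_seq = character(0),
                      stringsAsFactors = FALSE)
  if (n < W) return(empty)
  fwd <- score_windows(pwm, seq)
  cand <- data.frame(region_pos = seq_along(fwd), strand = "+", score = fwd,
                     stringsAsFactors = FALSE)
  if (isTRUE(cfg$both_strands)) {
    rev_sc <- score_windows(pwm_revcomp(pwm), seq)
    cand <- rbind(cand, data.frame(region_pos = seq_along(rev_sc),
                                   strand = "-", score = rev_sc,
                                   stringsAsFactors = FALSE))
  }
  cand <- cand[!is.na(cand$score) & cand$score >= cfg$weak_floor, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # greedy non-overlap: best score first; ties to smaller position, then "+"
  cand <- cand[order(-cand$score, cand$region_pos, cand$strand), , drop = FALSE]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$region_pos[i]:(cand$region_pos[i] + W - 1L)
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$region_pos), , drop = FALSE]
  site <- windows_at(seq, cand$region_pos, W)
  site[cand$strand == "-"] <- revcomp(site[cand$strand == "-"])
  data.frame(gene_id = region$gene_id %||% NA_character_,
             genome_id = region$genome_id %||% NA_character_,
             region_pos = cand$region_pos,
             position = cand$region_pos - region$offset_of_start_codon,
             strand = cand$strand, score = cand$score,
             weak = cand$score < cfg$threshold,
             site_seq = site, stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan many regions
#'
#' @param pwm A `pwm` object.
#' @param regions List of `upstream_region` objects.
#' @param cfg A `scan_config`.
#' @return A single `data.frame` of hits (see [scan_region()]).
#' @export
scan_regions <- function(pwm, regions, cfg) {
  do.call(rbind, c(lapply(regions, function(r) scan_region(pwm, r, cfg)),
                   list(make.row.names = FALSE)))
}

#' Write a PWM in MEME motif format
#'
#' Minimal MEME (version 4) text with the probability matrix; a sidecar TSV
#' of log-odds weights is written next to it (`<path>.weights.tsv`).
#'
#' @param pwm A `pwm` object.
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_pwm_meme <- function(pwm, path, name = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pwm$width, pwm$nsites)), con)
  writeLines(apply(pwm$probs, 2L, function(p)
    paste(sprintf("%.6f", p), collapse = " ")), con)
  w <- as.data.frame(t(pwm$weights))
  utils::write.table(cbind(pos = seq_len(pwm$width), round(w, 6)),
                     paste0(path, ".weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
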