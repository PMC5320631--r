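# Phylogenetic footprinting by spaced-dyad seeding and greedy PWM
# refinement. Operator motifs of this TF family are repeats of a short box
# in direct or inverted orientation, so seeds are word pairs (word, word),
# (word, revcomp word) or (revcomp word, word) at a fixed edge-to-edge gap;
# the top seeds by enrichment z-score are refined into a two-box model, and
# additional conserved boxes are then searched in the site flanks.

ARRANGEMENTS <- c("DD", "IR_out", "IR_in")
arr_arrows <- function(arr) switch(arr,
  DD = c(">", ">"), IR_in = c(">", "<"), IR_out = c("<", ">"))

as_region <- function(r, name = NA_character_) {
  if (is.character(r)) {
    r <- list(gene_id = name, genome_id = NA_character_, sequence = toupper(r),
              offset_of_start_codon = nchar(r) + 1L)
    class(r) <- "upstream_region"
  }
  r
}

as_region_list <- function(regions) {
  if (is.character(regions)) regions <- as.list(regions)
  nm <- names(regions) %||% as.character(seq_along(regions))
  mapply(as_region, regions, nm, SIMPLIFY = FALSE)
}

#' Estimate a strand-symmetric background model
#'
#' Maximum-likelihood (conditional) base frequencies of order 0-2 over the
#' regions plus their reverse complements. Falls back to a uniform model
#' with a warning when the data cannot support the requested order
#' (total length below `100 * 4^order`).
#'
#' @param regions List of `upstream_region` objects or character strings.
#' @param order Markov order, 0-2.
#' @return An object of class `background_model` with fields `order`,
#'   `marginal` (named base frequencies) and, for `order > 0`, `cond`
#'   (matrix of conditional probabilities, one row per context).
#' @export
estimate_background <- function(regions, order = 0L) {
  stopifnot(order %in% 0:2)
  regions <- as_region_list(regions)
  seqs <- vapply(regions, `[[`, "", "sequence")
  seqs <- c(seqs, revcomp(seqs))
  total <- sum(nchar(seqs))
  uniform <- structure(list(order = 0L,
                            marginal = stats::setNames(rep(0.25, 4), DNA_BASES)),
                       class = "background_model")
  if (total < 100 * 4^order) {
    warning("insufficient data for background of order ", order,
            "; using uniform frequencies")
    return(uniform)
  }
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  chars <- chars[chars %in% DNA_BASES]
  marg <- table(factor(chars, levels = DNA_BASES))
  marginal <- as.numeric(marg) / sum(marg)
  names(marginal) <- DNA_BASES
  out <- list(order = as.integer(order), marginal = marginal)
  if (order > 0L) {
    ctx_w <- order + 1L
    grams <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < ctx_w) return(character(0))
      substring(s, 1:(n - ctx_w + 1L), ctx_w:n)
    }), use.names = FALSE)
    grams <- grams[!grepl("N", grams, fixed = TRUE)]
    ctx <- substr(grams, 1L, order)
    nxt <- substr(grams, ctx_w, ctx_w)
    tab <- table(ctx, factor(nxt, levels = DNA_BASES))
    cond <- sweep(tab + 0.5, 1L, rowSums(tab + 0.5), `/`)
    out$cond <- unclass(cond)
  }
  structure(out, class = "background_model")
}

# Probability of a word under the background (first `order` bases from the
# marginal, the rest conditional).
word_prob <- function(bg, word) {
  b <- strsplit(word, "", fixed = TRUE)[[1]]
  if (bg$order == 0L || length(b) <= bg$order) {
    return(prod(bg$marginal[b]))
  }
  p <- prod(bg$marginal[b[seq_len(bg$order)]])
  for (i in (bg$order + 1L):length(b)) {
    ctx <- paste(b[(i - bg$order):(i - 1L)], collapse = "")
    p <- p * bg$cond[ctx, b[i]]
  }
  unname(p)
}

#' Enumerate spaced-dyad seeds
#'
#' Counts, for each (word, arrangement, gap), occurrences of the dyad
#' across all regions and ranks them by the enrichment z-score
#' `(obs - exp) / sqrt(exp)` under the background model. `DD` is
#' word...word, `IR_in` word...revcomp(word), `IR_out`
#' revcomp(word)...word; gaps are edge-to-edge. Occurrences are counted on
#' the forward strand of each region; a dyad on the opposite strand is the
#' forward occurrence of the strand-mirrored (word, arrangement) pair, so
#' enumeration over all words covers both strands without double counting.
#'
#' @param regions List of `upstream_region` objects or character strings.
#' @param k Word length (default 5).
#' @param gap_range Integer pair of edge-to-edge gaps to consider.
#' @param arrangements Subset of `c("DD", "IR_out", "IR_in")`.
#' @param bg Background model; estimated from `regions` at order 0 when
#'   omitted.
#' @param top_n Number of top-ranked seeds to return (default 50).
#' @return `data.frame` (class `dyad_seeds`) with columns `word`,
#'   `arrangement`, `gap`, `count`, `expected`, `z`, sorted by decreasing
#'   `z`.
#' @export
enumerate_dyad_seeds <- function(regions, k = 5L, gap_range = c(5L, 40L),
                                 arrangements = ARRANGEMENTS, bg = NULL,
                                 top_n = 50L) {
  regions <- as_region_list(regions)
  seqs <- vapply(regions, `[[`, "", "sequence")
  if (any(nchar(seqs) < 2L * k + gap_range[1]))
    stop("regions shorter than 2k + min gap; decrease k")
  if (is.null(bg)) bg <- estimate_background(regions, 0L)
  gaps <- gap_range[1]:gap_range[2]
  words <- character(0); arrs <- character(0); gps <- integer(0)
  opp <- stats::setNames(integer(length(gaps)), gaps)
  for (s in seqs) {
    n <- nchar(s)
    npos <- n - k + 1L
    km <- substring(s, 1:npos, k:n)
    km[grepl("N", km, fixed = TRUE)] <- NA
    rkm <- km
    ok <- !is.na(km)
    rkm[ok] <- revcomp(km[ok])
    for (g in gaps) {
      ni <- npos - k - g
      if (ni < 1L) next
      opp[as.character(g)] <- opp[as.character(g)] + ni
      i <- seq_len(ni); j <- i + k + g
      for (arr in arrangements) {
        m <- switch(arr,
          DD = km[i] == km[j],
          IR_in = km[i] == rkm[j],
          IR_out = rkm[i] == km[j])
        m[is.na(m)] <- FALSE
        if (!any(m)) next
        w <- if (arr == "IR_out") km[j][m] else km[i][m]
        words <- c(words, w)
        arrs <- c(arrs, rep(arr, sum(m)))
        gps <- c(gps, rep(g, sum(m)))
      }
    }
  }
  if (!length(words)) {
    return(structure(data.frame(word = character(0), arrangement = character(0),
                                gap = integer(0), count = integer(0),
                                expected = numeric(0), z = numeric(0)),
                     class = c("dyad_seeds", "data.frame")))
  }
  key <- paste(words, arrs, gps, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(word = vapply(parts, `[[`, "", 1L),
                    arrangement = vapply(parts, `[[`, "", 2L),
                    gap = as.integer(vapply(parts, `[[`, "", 3L)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  pw <- vapply(out$word, word_prob, 0, bg = bg)
  prc <- vapply(revcomp(out$word), word_prob, 0, bg = bg)
  p2 <- ifelse(out$arrangement == "DD", pw * pw, pw * prc)
  out$expected <- opp[as.character(out$gap)] * p2
  out$z <- (out$count - out$expected) / sqrt(out$expected)
  out <- out[order(-out$z, out$word, out$arrangement, out$gap), , drop = FALSE]
  rownames(out) <- NULL
  structure(utils::head(out, top_n), class = c("dyad_seeds", "data.frame"))
}

# exact dyad occurrences of a seed on the forward strand of each region:
# data.frame(region, start)
seed_occurrences <- function(seed, seqs, k) {
  res <- list()
  for (ri in seq_along(seqs)) {
    s <- seqs[ri]
    n <- nchar(s)
    npos <- n - k + 1L
    if (npos - k - seed$gap < 1L) next
    km <- substring(s, 1:npos, k:n)
    i <- seq_len(npos - k - seed$gap)
    j <- i + k + seed$gap
    m <- switch(seed$arrangement,
      DD = km[i] == seed$word & km[j] == seed$word,
      IR_in = km[i] == seed$word & km[j] == revcomp(seed$word),
      IR_out = km[i] == revcomp(seed$word) & km[j] == seed$word)
    m[is.na(m)] <- FALSE
    if (any(m)) res[[length(res) + 1L]] <-
      data.frame(region = ri, start = i[m])
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# site-local sequence of a full site at (start, strand) with span `span`
site_local_seq <- function(seq, start, span, strand) {
  s <- substr(seq, start, start + span - 1L)
  if (strand == "-") s <- revcomp(s)
  s
}

# box instances (strings in the shared ">" frame) from a site table
box_instances <- function(seqs, sites, arrows, w, extra_left = 0L,
                          extra_right = 0L) {
  inst <- character(0)
  for (r in seq_len(nrow(sites))) {
    span <- 2L * w + sites$gap[r]
    loc <- site_local_seq(seqs[sites$region[r]], sites$start[r], span,
                          sites$strand[r])
    b1 <- substr(loc, 1L, w)
    b2 <- substr(loc, w + sites$gap[r] + 1L, span)
    if (arrows[1] == "<") b1 <- revcomp(b1)
    if (arrows[2] == "<") b2 <- revcomp(b2)
    inst <- c(inst, b1, b2)
  }
  inst[!grepl("N", inst, fixed = TRUE)]
}

# best full-site occurrence per region under the current 2-box model
collect_sites <- function(seqs, shared, arrows, gap, gap_slack,
                          rc_seqs = revcomp(seqs)) {
  w <- shared$width
  rc <- pwm_revcomp(shared)
  b1p <- if (arrows[1] == ">") shared else rc
  b2p <- if (arrows[2] == ">") shared else rc
  same_box <- identical(arrows[1], arrows[2])
  gaps_try <- max(0L, gap - gap_slack):(gap + gap_slack)
  rows <- list()
  for (ri in seq_along(seqs)) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[ri] else rc_seqs[ri]
      n <- nchar(s)
      sc1 <- score_windows(b1p, s)
      sc2 <- if (same_box) sc1 else score_windows(b2p, s)
      npos <- length(sc1)
      if (!npos) next
      for (g in gaps_try) {
        ni <- npos - w - g
        if (ni < 1L) next
        tot <- sc1[seq_len(ni)] + sc2[seq_len(ni) + w + g]
        if (all(is.na(tot))) next
        p <- which.max(tot)
        cand <- list(score = tot[p], start = p, gap = g, strand = strand)
        if (is.null(best) || cand$score > best$score) best <- cand
      }
    }
    if (is.null(best)) next
    span <- 2L * w + best$gap
    start_f <- if (best$strand == "+") best$start else
      nchar(seqs[ri]) - (best$start + span - 1L) + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(region = ri, start = start_f, strand = best$strand,
                 gap = best$gap, score = best$score)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# candidate one-column extension of the shared box on `side` ("L"/"R"):
# returns the flanking bases of every box instance, or NULL when any
# instance would leave its region or the inner gap would go negative.
extension_column <- function(seqs, sites, arrows, w, side) {
  if (side == "R" && any(sites$gap < 1L)) return(NULL)
  bases <- character(0)
  for (r in seq_len(nrow(sites))) {
    g <- sites$gap[r]
    span <- 2L * w + g
    n <- nchar(seqs[sites$region[r]])
    # local offsets (within the site, 1-based) of the new column per box
    off <- integer(2)
    for (b in 1:2) {
      o <- if (b == 1L) 1L else w + g + 1L  # local start of box b
      grow_left <- (arrows[b] == ">") == (side == "L")
      off[b] <- if (grow_left) o - 1L else o + w
    }
    # map local offsets to region coordinates
    for (b in 1:2) {
      if (sites$strand[r] == "+") pos <- sites$start[r] + off[b] - 1L
      else pos <- sites$start[r] + span - off[b]
      if (pos < 1L || pos > n) return(NULL)
      base <- substr(seqs[sites$region[r]], pos, pos)
      if (sites$strand[r] == "-") base <- chartr("ACGTN", "TGCAN", base)
      if (arrows[b] == "<") base <- chartr("ACGTN", "TGCAN", base)
      bases <- c(bases, base)
    }
  }
  if (any(bases == "N")) return(NULL)
  bases
}

column_ic <- function(bases) {
  counts <- matrix(tabulate(match(bases, DNA_BASES), 4L), ncol = 1,
                   dimnames = list(DNA_BASES, NULL))
  p <- (counts + 0.5) / (length(bases) + 2)
  2 + sum(p * log2(p))
}

# apply a one-column extension: shift site starts/gaps to the new frame
apply_extension <- function(sites, arrows, w, side) {
  for (r in seq_len(nrow(sites))) {
    g <- sites$gap[r]
    starts <- c(1L, w + g + 1L)
    ends <- starts + w - 1L
    for (b in 1:2) {
      grow_left <- (arrows[b] == ">") == (side == "L")
      if (grow_left) starts[b] <- starts[b] - 1L else ends[b] <- ends[b] + 1L
    }
    new_left_local <- min(starts)
    shift <- 1L - new_left_local      # 1 when the site grew on its local left
    span_new <- max(ends) - new_left_local + 1L
    gap_new <- (starts[2] + shift) - (ends[1] + shift) - 1L
    if (sites$strand[r] == "+") {
      sites$start[r] <- sites$start[r] - shift
    } else {
      span_old <- 2L * w + g
      right_old <- sites$start[r] + span_old - 1L
      right_new <- right_old + shift
      sites$start[r] <- right_new - span_new + 1L
    }
    sites$gap[r] <- gap_new
  }
  sites
}

motif_objective <- function(shared, n_boxes, sites, n_regions) {
  cov <- nrow(sites) / n_regions
  list(total = sum(shared$ic) * n_boxes * cov,
       mean = mean(shared$ic) * cov,
       coverage = cov)
}

#' Refine a dyad seed into a two-box motif model
#'
#' Greedy ascent: (1) collect the best full-site occurrence per region,
#' letting the inter-box gap vary by `gap_slack`; (2) extend the shared box
#' while the flanking column carries at least `ic_extend` bits and the box
#' width stays at most `max_width`; (3) rebuild the shared box PWM from all
#' box instances (direct-repeat boxes share one PWM; inverted boxes share
#' it through reverse complementation). Iterates until the site set is
#' fixed, `max_iter` is reached, or the objective (total information
#' content times coverage) would decrease.
#'
#' @param seed One row of [enumerate_dyad_seeds()] output (or a list with
#'   `word`, `arrangement`, `gap`).
#' @param regions List of `upstream_region` objects or character strings.
#' @param max_iter Maximum refinement iterations.
#' @param gap_slack Allowed per-site deviation from the model gap (nt).
#' @param max_width Maximum box width (nt).
#' @param ic_extend Minimum information content (bits) of a column added by
#'   box extension.
#' @return A `motif_model`, or `NULL` (discard-seed signal) when fewer than
#'   2 seed occurrences exist or refinement degenerates.
#' @export
refine_motif <- function(seed, regions, max_iter = 50L, gap_slack = 2L,
                         max_width = 12L, ic_extend = 0.3) {
  regions <- as_region_list(regions)
  seqs <- vapply(regions, `[[`, "", "sequence")
  seed <- as.list(seed)
  k <- nchar(seed$word)
  occ <- seed_occurrences(seed, seqs, k)
  if (is.null(occ) || nrow(occ) < 2L) return(NULL)
  arrows <- arr_arrows(seed$arrangement)
  sites0 <- data.frame(region = occ$region, start = occ$start, strand = "+",
                       gap = seed$gap, score = NA_real_)
  inst <- box_instances(seqs, sites0, arrows, k)
  if (length(inst) < 2L) return(NULL)
  shared <- build_pwm(inst)
  w <- k
  gap <- seed$gap
  sites <- sites0
  obj <- motif_objective(shared, 2L, sites, length(seqs))
  trace <- obj$total
  rc_seqs <- revcomp(seqs)
  for (iter in seq_len(max_iter)) {
    prev <- list(shared = shared, w = w, gap = gap, sites = sites, obj = obj)
    new_sites <- collect_sites(seqs, shared, arrows, gap, gap_slack, rc_seqs)
    if (is.null(new_sites) || nrow(new_sites) < 2L) break
    sites <- new_sites
    # box extension
    repeat {
      if (w >= max_width) break
      ext <- NULL
      for (side in c("L", "R")) {
        bases <- extension_column(seqs, sites, arrows, w, side)
        if (is.null(bases)) next
        ic <- column_ic(bases)
        if (ic >= ic_extend && (is.null(ext) || ic > ext$ic)) {
          ext <- list(side = side, ic = ic)
        }
      }
      if (is.null(ext)) break
      sites <- apply_extension(sites, arrows, w, ext$side)
      w <- w + 1L
    }
    inst <- box_instances(seqs, sites, arrows, w)
    if (length(inst) < 2L) { sites <- prev$sites; w <- prev$w; break }
    shared <- build_pwm(inst)
    gap <- modal_gap(sites$gap)
    obj <- motif_objective(shared, 2L, sites, length(seqs))
    if (obj$total < prev$obj$total - 1e-9) {
      shared <- prev$shared; w <- prev$w; gap <- prev$gap
      sites <- prev$sites; obj <- prev$obj
      break
    }
    trace <- c(trace, obj$total)
    same <- identical(prev$sites[c("region", "start", "strand", "gap")],
                      sites[c("region", "start", "strand", "gap")]) &&
      w == prev$w
    if (same) break
  }
  new_motif_model(shared, arrows, gap, sites, seqs, regions, trace, seed)
}

modal_gap <- function(g) {
  tab <- table(g)
  as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1L])
}

new_motif_model <- function(shared, arrows, gap, sites, seqs, regions,
                            trace, seed = NULL) {
  w <- shared$width
  nb <- length(arrows)
  gaps <- if (nb == 2L) gap else gap  # multi-box models set gaps directly
  sites$gene_id <- vapply(regions[sites$region], function(r)
    r$gene_id %||% NA_character_, "")
  sites$genome_id <- vapply(regions[sites$region], function(r)
    r$genome_id %||% NA_character_, "")
  sites$region_offset <- vapply(regions[sites$region], function(r)
    as.integer(r$offset_of_start_codon %||% NA_integer_), 0L)
  sites$site_seq <- vapply(seq_len(nrow(sites)), function(r)
    site_local_seq(seqs[sites$region[r]], sites$start[r],
                   2L * w + sites$gap[r], sites$strand[r]), "")
  boxes <- lapply(arrows, function(a)
    if (a == ">") shared else pwm_revcomp(shared))
  obj <- motif_objective(shared, nb, sites, length(seqs))
  structure(list(boxes = boxes, orientations = arrows,
                 gaps = rep(gap, nb - 1L), width = w, shared = shared,
                 site_set = sites, n_regions = length(seqs),
                 objective = obj$mean, objective_total = obj$total,
                 objective_trace = trace, seed = seed),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  if (is_empty_motif(x)) {
    cat("<motif_model> no motif found\n")
    return(invisible(x))
  }
  cat("<motif_model> ", length(x$boxes), " boxes (",
      paste(x$orientations, collapse = " "), "), box width ", x$width,
      ", gap(s) ", paste(x$gaps, collapse = ", "),
      "\n  shared box consensus: ", x$shared$consensus,
      "\n  sites in ", nrow(x$site_set), "/", x$n_regions,
      " regions; objective (mean IC x coverage) ",
      sprintf("%.3f", x$objective), "\n", sep = "")
  invisible(x)
}

#' @export
summary.motif_model <- function(object, ...) {
  print(object)
  if (!is_empty_motif(object)) {
    cat("  per-column IC (bits): ",
        paste(sprintf("%.2f", object$shared$ic), collapse = " "), "\n")
  }
  invisible(object)
}

empty_motif <- function(reason = "no seed above the enrichment cutoff") {
  structure(list(boxes = list(), orientations = character(0),
                 gaps = integer(0), site_set = NULL, reason = reason),
            class = "motif_model")
}

#' Test for the explicit no-motif outcome
#'
#' @param x A `motif_model`.
#' @return `TRUE` when discovery produced no motif.
#' @export
is_empty_motif <- function(x) length(x$boxes) == 0L

# span already claimed by previously appended boxes on one side
appended_extent <- function(model, side) {
  extent <- 0L
  for (a in model$appended %||% list()) {
    if (a$side == side) extent <- extent + a$d + model$width
  }
  extent
}

# search the flanks of accepted sites -- and, when the two core boxes are
# far enough apart, the interior of the gap -- for one more conserved box
# (the shared PWM or its reverse complement at a fixed offset); `site_set`
# keeps the original two-box core coordinates, so flank offsets are taken
# beyond any boxes appended earlier
find_flanking_box <- function(model, seqs, flank = 60L, ic_extra = 0.7,
                              cov_extra = 0.7, sim_min = 0.5) {
  w <- model$width
  sites <- model$site_set
  sides <- c("L", "R")
  if (is.null(model$middle) && min(sites$gap) >= w) sides <- c(sides, "M")
  best <- NULL
  for (side in sides) {
    offs <- if (side == "M") 0:(min(sites$gap) - w) else {
      base_off <- appended_extent(model, side)
      if (base_off > flank - w) next
      base_off:(flank - w)
    }
    for (d in offs) {
      strs <- character(0)
      for (r in seq_len(nrow(sites))) {
        n <- nchar(seqs[sites$region[r]])
        span <- 2L * w + sites$gap[r]
        # site-local coordinates of the candidate box, strand aware;
        # interior candidates are anchored on the left core box's end
        loc <- switch(side,
          L = (1L - d - w):(0L - d),
          R = (span + d + 1L):(span + d + w),
          M = (w + d + 1L):(w + d + w))
        if (sites$strand[r] == "+") {
          pos <- sites$start[r] + loc - 1L
        } else {
          pos <- rev(sites$start[r] + span - loc)
        }
        if (pos[1] < 1L || pos[length(pos)] > n) next
        s <- substr(seqs[sites$region[r]], pos[1], pos[length(pos)])
        if (sites$strand[r] == "-") s <- revcomp(s)
        if (grepl("N", s, fixed = TRUE)) next
        strs <- c(strs, s)
      }
      if (length(strs) < 2L || length(strs) / nrow(sites) < cov_extra) next
      cand <- build_pwm(strs)
      if (mean(cand$ic) < ic_extra) next
      sim <- box_similarity(cand, model$shared)
      if (max(sim) < sim_min) next
      score <- mean(cand$ic) * length(strs) / nrow(sites)
      if (is.null(best) || score > best$score) {
        d_rel <- if (side == "M") d else d - appended_extent(model, side)
        best <- list(side = side, d = d_rel, pwm = cand,
                     orientation = if (sim[1] >= sim[2]) ">" else "<",
                     score = score)
      }
    }
  }
  best
}

# mean per-column Pearson correlation of probability columns (forward and
# against the reverse complement)
box_similarity <- function(box, ref) {
  stopifnot(box$width == ref$width)
  col_cor <- function(a, b) {
    out <- vapply(seq_len(ncol(a)), function(k) {
      if (stats::sd(a[, k]) == 0 || stats::sd(b[, k]) == 0) return(0)
      stats::cor(a[, k], b[, k])
    }, 0)
    mean(out)
  }
  c(forward = col_cor(box$probs, ref$probs),
    reverse = col_cor(box$probs, pwm_revcomp(ref)$probs))
}

append_box <- function(model, found) {
  if (found$side == "L") {
    model$boxes <- c(list(found$pwm), model$boxes)
    model$orientations <- c(found$orientation, model$orientations)
    model$gaps <- c(found$d, model$gaps)
    model$appended <- c(model$appended %||% list(),
                        list(found[c("side", "d")]))
  } else if (found$side == "R") {
    model$boxes <- c(model$boxes, list(found$pwm))
    model$orientations <- c(model$orientations, found$orientation)
    model$gaps <- c(model$gaps, found$d)
    model$appended <- c(model$appended %||% list(),
                        list(found[c("side", "d")]))
  } else {
    # interior box: split the core gap (index = boxes appended on the left
    # plus one) into the parts before and after the new box
    idx <- 1L
    for (a in model$appended %||% list()) if (a$side == "L") idx <- idx + 1L
    core_gap <- model$gaps[idx]
    model$boxes <- append(model$boxes, list(found$pwm), after = idx)
    model$orientations <- append(model$orientations, found$orientation,
                                 after = idx)
    model$gaps <- append(model$gaps[-idx],
                         c(found$d, core_gap - model$width - found$d),
                         after = idx - 1L)
    model$middle <- found$d
  }
  model
}

#' Discover a repeat-structured motif across upstream regions
#'
#' Runs [enumerate_dyad_seeds()], refines the top seeds with
#' [refine_motif()], selects the model maximizing mean information content
#' per column times the fraction of regions with a site, and finally scans
#' the site flanks for up to two additional conserved boxes (the shared box
#' PWM or its reverse complement), producing 2- to 4-box models.
#'
#' @param regions List of at least 3 `upstream_region` objects (or DNA
#'   strings): footprinting needs several genomes.
#' @param k Seed word length.
#' @param gap_range Edge-to-edge gap range for seeds.
#' @param top_n Seeds kept from enumeration.
#' @param n_refine Top seeds refined.
#' @param z_min Minimum seed enrichment z-score; below it the result is the
#'   explicit no-motif outcome (see [is_empty_motif()]).
#' @param gap_slack,max_width,ic_extend Passed to [refine_motif()].
#' @param extra_box Search site flanks for additional boxes.
#' @param flank Flank width (nt) searched for an extra box.
#' @param ic_extra Minimum mean column IC (bits) of an extra box.
#' @param cov_extra Minimum fraction of regions carrying the extra box.
#' @param bg Optional background model.
#' @return A `motif_model`.
#' @export
discover_motif <- function(regions, k = 5L, gap_range = c(5L, 40L),
                           top_n = 50L, n_refine = 10L, z_min = 3,
                           gap_slack = 2L, max_width = 12L, ic_extend = 0.3,
                           extra_box = TRUE, flank = 60L, ic_extra = 0.7,
                           cov_extra = 0.7, bg = NULL) {
  regions <- as_region_list(regions)
  if (length(regions) < 3L) stop("need at least 3 regions for footprinting")
  seeds <- enumerate_dyad_seeds(regions, k = k, gap_range = gap_range,
                                bg = bg, top_n = top_n)
  seeds <- seeds[seeds$z > z_min & seeds$count >= 2L, , drop = FALSE]
  if (!nrow(seeds)) return(empty_motif())
  models <- list()
  for (i in seq_len(min(n_refine, nrow(seeds)))) {
    m <- refine_motif(seeds[i, ], regions, gap_slack = gap_slack,
                      max_width = max_width, ic_extend = ic_extend)
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  if (!length(models)) return(empty_motif("no seed survived refinement"))
  objs <- vapply(models, `[[`, 0, "objective")
  model <- models[[which.max(objs)]]
  if (extra_box) {
    seqs <- vapply(regions, `[[`, "", "sequence")
    while (length(model$boxes) < 4L) {
      found <- find_flanking_box(model, seqs, flank = flank,
                                 ic_extra = ic_extra, cov_extra = cov_extra)
      if (is.null(found)) break
      model <- append_box(model, found)
    }
  }
  model
}

#' Write a motif model as MEME boxes plus a JSON sidecar
#'
#' @param model A `motif_model`.
#' @param path Output path for the MEME file; the sidecar goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_motif_model <- function(model, path) {
  if (is_empty_motif(model)) stop("cannot write an empty motif model")
  con <- file(path, "w")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25"), con)
  for (b in seq_along(model$boxes)) {
    pw <- model$boxes[[b]]
    writeLines(c("", paste0("MOTIF box", b, "_", model$orientations[b]),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         pw$width, pw$nsites)), con)
    writeLines(apply(pw$probs, 2L, function(p)
      paste(sprintf("%.6f", p), collapse = " ")), con)
  }
  close(con)
  sidecar <- list(orientations = model$orientations, gaps = model$gaps,
                  box_width = model$width,
                  objective = model$objective,
                  sites = model$site_set)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
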