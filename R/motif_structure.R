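# Box-arrangement classification of discovered motifs. Arrangements are
# written as arrows, ">" for a box in the reference orientation and "<"
# for its reverse complement; e.g. "> >" is a direct repeat and "< >" a
# tail-to-tail inverted repeat.

#' Known box-arrangement categories
#'
#' The ten arrangements observed among MocR-subfamily operators, from two
#' direct/inverted boxes up to four-box combinations.
#'
#' @format Character vector of canonical arrow strings.
#' @export
ARRANGEMENT_CATEGORIES <- c(
  "> >", "< >",
  "> > <", "> < >", "> > >", "> < <",
  "< < > >", "> < > >", "> > > <", "> > < >")

#' Orientation of a box relative to a reference PWM
#'
#' Compares the mean per-column Pearson correlation of probability columns
#' against the reference and against its reverse complement; ties go to
#' forward.
#'
#' @param box,ref `pwm` objects of equal width.
#' @return `">"` (forward) or `"<"` (reverse).
#' @export
box_orientation <- function(box, ref) {
  if (box$width != ref$width) stop("box and reference widths differ")
  sim <- box_similarity(box, ref)
  if (sim["forward"] >= sim["reverse"]) ">" else "<"
}

#' Canonical form of an arrow string
#'
#' A motif reported on the opposite strand has reversed box order and
#' flipped arrows; the canonical form is the lexicographic minimum of the
#' arrangement and its strand flip, with `>` ordered before `<`.
#' Idempotent.
#'
#' @param arrows Character vector over `c(">", "<")`.
#' @return Canonical arrow vector of the same length.
#' @export
canonicalize <- function(arrows) {
  stopifnot(length(arrows) >= 1L, all(arrows %in% c(">", "<")))
  flip <- rev(ifelse(arrows == ">", "<", ">"))
  a <- as.integer(arrows == "<")  # ">" sorts first
  b <- as.integer(flip == "<")
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(arrows)
    if (a[i] > b[i]) return(flip)
  }
  arrows
}

#' Reference reading of a box PWM
#'
#' A box and its reverse complement describe the same physical repeat
#' unit; arrows only become comparable across motifs once one reading is
#' fixed as forward. The convention here follows the family's conserved
#' 5' TGT core: the reading whose consensus shows `TGT` closest to its
#' start is forward; when neither reading is decisive, the reading with
#' its information content loaded towards the 5' end is used, and as a
#' last resort the box is kept as given.
#'
#' @param pwm A `pwm`.
#' @return The `pwm`, possibly reverse-complemented.
#' @export
box_reference <- function(pwm) {
  f <- pwm
  r <- pwm_revcomp(pwm)
  pos <- function(p) {
    m <- regexpr("TGT", p$consensus, fixed = TRUE)
    if (m < 0) Inf else as.integer(m)
  }
  if (pos(f) < pos(r)) return(f)
  if (pos(r) < pos(f)) return(r)
  com <- function(p) sum(seq_len(p$width) * p$ic) / sum(p$ic)
  if (com(f) <= com(r)) f else r
}

#' Classify the box arrangement of a motif
#'
#' Assigns an arrow to every box by [box_orientation()] against the
#' reference reading of box 1 (see [box_reference()]), canonicalizes the
#' arrow string, and matches it against the known arrangement categories.
#'
#' @param motif A `motif_model` with 2-4 boxes.
#' @return An object of class `arrangement` with fields `arrows`, `gaps`
#'   (edge-to-edge nt) and `category_string` (one of
#'   [ARRANGEMENT_CATEGORIES] or `"other"`).
#' @export
classify_structure <- function(motif) {
  nb <- length(motif$boxes)
  if (nb < 2L || nb > 4L) stop("motif must have 2-4 boxes")
  ref <- box_reference(motif$boxes[[1L]])
  arrows <- vapply(motif$boxes, box_orientation, "", ref = ref)
  arrows <- canonicalize(arrows)
  cat_str <- paste(arrows, collapse = " ")
  structure(list(arrows = arrows, gaps = box_distances(motif),
                 category_string = if (cat_str %in% ARRANGEMENT_CATEGORIES)
                   cat_str else "other"),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement> ", paste(x$arrows, collapse = " "),
      " (category: ", x$category_string, "), gaps: ",
      paste(x$gaps, collapse = ", "), " nt\n", sep = "")
  invisible(x)
}

#' Edge-to-edge distances between consecutive boxes
#'
#' @param motif A `motif_model` with at least 2 boxes.
#' @return Integer vector of nt gaps in motif order; overlapping boxes give
#'   a negative gap, reported as-is with a warning.
#' @export
box_distances <- function(motif) {
  if (length(motif$boxes) < 2L) stop("motif must have at least 2 boxes")
  g <- as.integer(motif$gaps)
  if (any(g < 0L)) warning("overlapping boxes: negative gap reported as-is")
  g
}
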