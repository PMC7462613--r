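# Local secondary-structure calling from a residue-pair coupling-strength
# matrix, and hypergeometric overlap evaluation against a reference
# annotation.

#' Validate / construct a coupling matrix
#'
#' @param mat Square numeric matrix of nonnegative residue-pair coupling
#'   strengths; must be symmetric within `tol`. The diagonal is ignored.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return The matrix, symmetrized as `(mat + t(mat)) / 2`, with class
#'   `coupling_matrix`.
#' @export
coupling_matrix <- function(mat, tol = 1e-9) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("coupling matrix must be square")
  if (any(mat < 0, na.rm = TRUE)) stop("coupling strengths must be nonnegative")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > tol)
    stop("coupling matrix is not symmetric within tolerance ", tol)
  mat[is.na(mat)] <- 0
  structure((mat + t(mat)) / 2, class = c("coupling_matrix", "matrix"))
}

#' Read a coupling matrix from a sparse TSV (`i  j  strength`)
#'
#' Indices are 1-based; the upper triangle is sufficient.
#'
#' @param path TSV path.
#' @param length Matrix dimension (default: the largest index present).
#' @return A [coupling_matrix()].
#' @export
read_coupling_matrix <- function(path, length = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "strength") %in% names(tab)))
  if (is.null(length)) length <- max(tab$i, tab$j)
  m <- matrix(0, length, length)
  m[cbind(tab$i, tab$j)] <- tab$strength
  m[cbind(tab$j, tab$i)] <- tab$strength
  coupling_matrix(m)
}

#' Per-residue local secondary-structure scores
#'
#' Sums the coupling strengths at would-be local contacts of each class:
#' for residue i, the alpha score is the summed strength at helix-turn
#' offsets (default `C(i, i+3) + C(i, i+4)`) and the beta score the
#' strength at the strand offset (default `C(i, i+2)`). Out-of-range terms
#' contribute zero.
#'
#' @param mat A [coupling_matrix()].
#' @param helix_offsets Integer offsets defining helix contacts (default
#'   `c(3, 4)`).
#' @param strand_offsets Integer offsets defining strand contacts (default
#'   `2`).
#' @return Data.frame `position`, `alpha_score`, `beta_score` for every
#'   residue.
#' @export
local_ss_scores <- function(mat, helix_offsets = c(3L, 4L),
                            strand_offsets = 2L) {
  stopifnot(inherits(mat, "coupling_matrix"))
  L <- nrow(mat)
  sum_offsets <- function(offsets) {
    s <- numeric(L)
    for (k in offsets) {
      i <- seq_len(L - k)
      s[i] <- s[i] + mat[cbind(i, i + k)]
    }
    s
  }
  data.frame(position = seq_len(L),
             alpha_score = sum_offsets(helix_offsets),
             beta_score = sum_offsets(strand_offsets))
}

#' Call secondary-structure segments from local scores
#'
#' Maximal runs of at least `min_core` consecutive residues scoring above
#' the class cutoff become segment cores; each core is extended by
#' `extension` residues on each side (clipped to the sequence); extended
#' segments shorter than `min_len` are discarded. Helices and strands are
#' called independently; segments of one class that overlap after extension
#' are merged. When a residue falls in both a helix and a strand segment,
#' the per-residue call gives helices precedence.
#'
#' @param scores A [local_ss_scores()] result.
#' @param cutoff_alpha,cutoff_beta Class score cutoffs (defaults 1.5 and
#'   0.75).
#' @param min_core Minimum core run length (default 2).
#' @param extension Residues added on each side of a core (default 1).
#' @param min_len Minimum extended segment length (default 4).
#' @return A list of class `ss_annotation`: `segments` (data.frame `class`,
#'   `start`, `end`), `call` (per-residue `helix`/`strand`/`none`), and the
#'   input `scores`.
#' @export
call_ss_segments <- function(scores, cutoff_alpha = 1.5, cutoff_beta = 0.75,
                             min_core = 2L, extension = 1L, min_len = 4L) {
  stopifnot(all(c("position", "alpha_score", "beta_score") %in% names(scores)))
  ord <- order(scores$position)
  pos <- scores$position[ord]
  L <- max(pos)
  call_track <- function(values, cutoff) {
    above <- values > cutoff
    if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
    p <- pos[above]
    run_id <- cumsum(c(1L, diff(p) != 1L))
    cores <- do.call(rbind, lapply(split(p, run_id), function(x)
      c(min(x), max(x))))
    cores <- cores[cores[, 2] - cores[, 1] + 1L >= min_core, , drop = FALSE]
    if (nrow(cores) == 0L) return(data.frame(start = integer(0), end = integer(0)))
    segs <- cbind(pmax(cores[, 1] - extension, 1L),
                  pmin(cores[, 2] + extension, L))
    segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_len, , drop = FALSE]
    if (nrow(segs) == 0L) return(data.frame(start = integer(0), end = integer(0)))
    # merge overlapping / adjacent-after-extension segments
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    merged <- list(segs[1, ])
    for (i in seq_len(nrow(segs))[-1]) {
      last <- merged[[length(merged)]]
      if (segs[i, 1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], segs[i, 2]))
      } else merged[[length(merged) + 1L]] <- segs[i, ]
    }
    m <- do.call(rbind, merged)
    data.frame(start = m[, 1], end = m[, 2])
  }
  helices <- call_track(scores$alpha_score[ord], cutoff_alpha)
  strands <- call_track(scores$beta_score[ord], cutoff_beta)
  segments <- rbind(
    if (nrow(helices)) cbind(class = "helix", helices),
    if (nrow(strands)) cbind(class = "strand", strands))
  if (is.null(segments))
    segments <- data.frame(class = character(0), start = integer(0),
                           end = integer(0))
  per_res <- rep("none", L)
  if (nrow(strands))
    for (i in seq_len(nrow(strands)))
      per_res[strands$start[i]:strands$end[i]] <- "strand"
  if (nrow(helices))
    for (i in seq_len(nrow(helices)))
      per_res[helices$start[i]:helices$end[i]] <- "helix"
  structure(list(segments = segments, call = per_res, scores = scores),
            class = "ss_annotation")
}

#' Hypergeometric overlap of predicted and reference residue sets
#'
#' Tests whether `predicted` residues overlap `reference` residues more
#' than expected under random draws from a universe of `universe` residues:
#' the upper-tail probability `P(X >= overlap)` for X hypergeometric with
#' `|reference|` successes, `universe - |reference|` failures and
#' `|predicted|` draws.
#'
#' @param predicted,reference Integer residue sets within `1..universe`.
#' @param universe Total number of residues considered.
#' @return A list with `overlap`, `p_value`, `n_predicted`, `n_reference`,
#'   `universe`.
#' @export
overlap_enrichment <- function(predicted, reference, universe) {
  predicted <- unique(as.integer(predicted))
  reference <- unique(as.integer(reference))
  universe <- as.integer(universe)
  if (universe <= 0L) stop("universe must be positive")
  if (length(predicted) > 0 && (min(predicted) < 1L || max(predicted) > universe))
    stop("predicted residues outside [1, universe]")
  if (length(reference) > 0 && (min(reference) < 1L || max(reference) > universe))
    stop("reference residues outside [1, universe]")
  overlap <- length(intersect(predicted, reference))
  p <- stats::phyper(overlap - 1L, length(reference),
                     universe - length(reference), length(predicted),
                     lower.tail = FALSE)
  list(overlap = overlap, p_value = p, n_predicted = length(predicted),
       n_reference = length(reference), universe = universe)
}
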