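# Sliding-window substitution-class score profiles and per-domain score
# distributions, used to discriminate transmembrane topology models.

#' Built-in substitution classes
#'
#' Charged (R, K, H, D, E) and aliphatic (G, A, V, I, L) residue sets: the
#' contrast between their windowed effect profiles demarcates transmembrane
#' segments, where charge is poorly tolerated.
#'
#' @return Named list of character vectors.
#' @export
aa_classes <- function() {
  list(charged = CHARGED_AAS, aliphatic = ALIPHATIC_AAS)
}

#' Windowed mean score of a substitution class
#'
#' For each center position p, pools all variant scores whose substituted
#' residue belongs to `residues` and whose position lies in the width-`window`
#' centered interval `[p - window/2 + 1, p + window/2]` (for the default
#' width 10: `p-4 .. p+5`, the right-heavy convention of centered rolling
#' means over even windows), and reports their arithmetic mean. Centers
#' whose window leaves `[1, length]`, or with no qualifying score, are
#' omitted.
#'
#' @param scores Data.frame with `position`, `alt_aa` and a score column.
#' @param residues Character vector of substituted amino acids to pool
#'   (e.g. `aa_classes()$charged`).
#' @param window Window width in positions (default 10).
#' @param length Protein length bounding valid windows (default: the
#'   largest scored position).
#' @param value_col Name of the score column (default `"score"`).
#' @return Data.frame `position`, `windowed_mean`, `n_scores`, containing
#'   only defined centers.
#' @export
windowed_profile <- function(scores, residues, window = 10L, length = NULL,
                             value_col = "score") {
  if (length(residues) == 0L) stop("empty substitution class")
  stopifnot(all(c("position", "alt_aa", value_col) %in% names(scores)))
  if (is.null(length)) length <- max(scores$position, na.rm = TRUE)
  window <- as.integer(window)
  lo_off <- window %/% 2L - (1L - window %% 2L)   # width 10 -> 4
  hi_off <- window %/% 2L + window %% 2L          # width 10 -> 5
  sel <- scores$alt_aa %in% residues & !is.na(scores[[value_col]]) &
    !is.na(scores$position)
  # only true substitutions qualify: a synonymous variant whose (unchanged)
  # residue happens to lie in the class is not a substitution to that class
  if ("wt_aa" %in% names(scores))
    sel <- sel & (is.na(scores$wt_aa) | scores$alt_aa != scores$wt_aa)
  pos <- scores$position[sel]
  val <- scores[[value_col]][sel]
  centers <- seq.int(1L + lo_off, length - hi_off)
  if (length(centers) == 0L)
    return(data.frame(position = integer(0), windowed_mean = numeric(0),
                      n_scores = integer(0)))
  res <- lapply(centers, function(p) {
    inside <- pos >= p - lo_off & pos <= p + hi_off
    n <- sum(inside)
    if (n == 0L) return(NULL)
    data.frame(position = p, windowed_mean = mean(val[inside]), n_scores = n)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(position = integer(0), windowed_mean = numeric(0),
                      n_scores = integer(0))
  rownames(out) <- NULL
  out
}

#' Call contiguous low regions of a windowed profile
#'
#' Returns maximal runs of consecutive defined center positions whose
#' profile value is strictly below `cutoff`; gaps in the defined grid break
#' runs. The cutoff is a tool parameter: a natural default is the nonsense
#' median score (0 on the normalized scale) plus a small margin such as 0.2.
#'
#' @param profile A [windowed_profile()] result.
#' @param cutoff Numeric threshold.
#' @return Data.frame with `start`, `end`, `n_positions`, `min_value` per
#'   called region (zero rows if none).
#' @export
call_low_regions <- function(profile, cutoff = 0.2) {
  stopifnot(all(c("position", "windowed_mean") %in% names(profile)))
  ord <- order(profile$position)
  pos <- profile$position[ord]
  val <- profile$windowed_mean[ord]
  low <- val < cutoff
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_positions = integer(0), min_value = numeric(0))
  if (!any(low)) return(empty)
  pos_low <- pos[low]
  val_low <- val[low]
  run_id <- cumsum(c(1L, diff(pos_low) != 1L))
  out <- do.call(rbind, lapply(split(seq_along(pos_low), run_id), function(i) {
    data.frame(start = min(pos_low[i]), end = max(pos_low[i]),
               n_positions = length(i), min_value = min(val_low[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Build a per-residue topology model
#'
#' @param intervals Data.frame with `start`, `end`, `label` (labels from
#'   `cytoplasmic`, `TM`, `lumenal`); intervals must be disjoint and
#'   jointly cover `1..length`.
#' @param length Protein length.
#' @return Object of class `topology_model`: list with `labels`
#'   (per-residue character vector) and `intervals`.
#' @export
topology_model <- function(intervals, length = max(intervals$end)) {
  stopifnot(all(c("start", "end", "label") %in% names(intervals)))
  labels <- rep(NA_character_, length)
  for (i in seq_len(nrow(intervals))) {
    span <- intervals$start[i]:intervals$end[i]
    if (any(!is.na(labels[span]))) stop("topology intervals overlap")
    labels[span] <- intervals$label[i]
  }
  structure(list(labels = labels, intervals = intervals),
            class = "topology_model")
}

#' Read a topology model from TSV (`start  end  label`)
#'
#' @param path TSV path.
#' @param length Protein length (default: max `end`).
#' @return A [topology_model()].
#' @export
read_topology_model <- function(path, length = NULL) {
  iv <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(length)) length <- max(iv$end)
  topology_model(iv, length)
}

#' Per-domain missense score distributions
#'
#' Partitions missense scores by the residue label of their position and
#' summarizes each domain.
#'
#' @param scores A score table with `position`, `mut_class`, `score`.
#' @param topology A [topology_model()] covering all scored positions.
#' @param breaks Histogram break specification passed to [hist()]
#'   (default 20 bins over the pooled range).
#' @return A list with `scores` (named list of per-domain score vectors),
#'   `summary` (data.frame `domain`, `n`, `median`), and `histogram`
#'   (per-domain bin counts on shared breaks).
#' @export
domain_distributions <- function(scores, topology, breaks = 20) {
  stopifnot(inherits(topology, "topology_model"))
  mis <- scores[scores$mut_class == "missense" & !is.na(scores$score), ,
                drop = FALSE]
  if (any(mis$position > length(topology$labels)) ||
      any(is.na(topology$labels[mis$position])))
    stop("topology model does not label every scored position")
  dom <- topology$labels[mis$position]
  domains <- c("cytoplasmic", "TM", "lumenal")
  by_dom <- split(mis$score, factor(dom, levels = domains))
  h_breaks <- if (length(breaks) == 1L)
    seq(min(mis$score), max(mis$score), length.out = breaks + 1L)
  else breaks
  hists <- lapply(by_dom, function(x) {
    if (length(x) == 0L) return(integer(length(h_breaks) - 1L))
    tabulate(findInterval(x, h_breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(h_breaks) - 1L)
  })
  summary <- data.frame(domain = domains,
                        n = vapply(by_dom, length, 1L),
                        median = vapply(by_dom, function(x)
                          if (length(x)) stats::median(x) else NA_real_, 1),
                        row.names = NULL)
  list(scores = by_dom, summary = summary,
       histogram = list(breaks = h_breaks, counts = hists))
}
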