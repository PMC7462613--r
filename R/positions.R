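# Position-level analyses: hierarchical clustering of substitution-score
# vectors, dataset-wide score rescaling, per-variant specific activity, and
# calling of functionally constrained (active-site) positions.

#' Position x substitution score matrix
#'
#' @param scores A score table with `position`, `alt_aa`, `score`.
#' @param substitutions Column universe (default the 20 amino acids plus
#'   stop). Duplicate (position, substitution) scores are averaged.
#' @return Numeric matrix, rows named by position, columns by substituted
#'   residue; missing combinations are NA.
#' @export
position_score_matrix <- function(scores,
                                  substitutions = c(AA_ALPHABET, AA_STOP)) {
  ok <- !is.na(scores$score) & scores$alt_aa %in% substitutions
  s <- scores[ok, , drop = FALSE]
  positions <- sort(unique(s$position))
  m <- matrix(NA_real_, length(positions), length(substitutions),
              dimnames = list(position = positions,
                              substitution = substitutions))
  means <- tapply(s$score, list(factor(s$position, levels = positions),
                                factor(s$alt_aa, levels = substitutions)),
                  mean)
  m[] <- means
  m
}

#' Hierarchically cluster positions by their substitution-score vectors
#'
#' Agglomerative clustering (complete linkage by default) on pairwise
#' Euclidean distances. Missing entries are handled pairwise-complete: the
#' squared distance over shared scored substitutions is scaled by
#' `n_total / n_shared` (the convention of [stats::dist()]). The tree is cut
#' into `k` groups.
#'
#' @param mat A [position_score_matrix()] (or any numeric matrix with rows
#'   to cluster).
#' @param k Number of groups to cut (default 4).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param distance Distance method for [stats::dist()] (default
#'   `"euclidean"`).
#' @return A list with `groups` (named integer vector of group labels in
#'   row order), `order` (dendrogram leaf order), and `hclust` (the tree).
#' @export
cluster_positions <- function(mat, k = 4L, linkage = "complete",
                              distance = "euclidean") {
  mat <- as.matrix(mat)
  scored <- rowSums(!is.na(mat)) > 0L
  if (any(!scored))
    stop("positions with no scored substitutions: ",
         paste(utils::head(rownames(mat)[!scored], 5), collapse = ", "))
  if (nrow(mat) < k) stop("need at least k = ", k, " positions")
  d <- stats::dist(mat, method = distance)
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(ij)
      paste(rownames(dm)[ij[1]], rownames(dm)[ij[2]], sep = "/"))
    stop("position pairs sharing no scored substitution: ",
         paste(utils::head(pairs, 5), collapse = ", "))
  }
  hc <- stats::hclust(d, method = linkage)
  list(groups = stats::cutree(hc, k = k), order = hc$order, hclust = hc)
}

#' Min-max rescale a score vector to the unit interval
#'
#' Affine map sending the lowest score in the dataset to 0 and the highest
#' to 1; applied per dataset (abundance and activity separately).
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Rescaled vector (NAs preserved).
#' @export
rescale_scores <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2])
    stop("rescaling needs at least two distinct finite scores")
  (x - r[1]) / (r[2] - r[1])
}

#' Per-variant specific activity
#'
#' Joins abundance and activity score tables on variant token, min-max
#' rescales each dataset to `[0, 1]`, and forms the ratio rescaled activity /
#' rescaled abundance. The ratio is undefined (NA, with a reason) when the
#' rescaled abundance does not exceed `eps`.
#'
#' @param abundance,activity Score tables from [score_variants()].
#' @param eps Division guard on rescaled abundance (default 1e-6).
#' @return Data.frame with `variant`, `position`, `mut_class`,
#'   `rescaled_abundance`, `rescaled_activity`, `specific_activity`,
#'   `undefined_reason`; one row per variant scored in both datasets.
#' @export
specific_activity_table <- function(abundance, activity, eps = 1e-6) {
  ab <- abundance[!is.na(abundance$score), c("variant", "position",
                                             "mut_class", "score")]
  ac <- activity[!is.na(activity$score), c("variant", "score")]
  names(ab)[4] <- "abundance_score"
  names(ac)[2] <- "activity_score"
  joined <- merge(ab, ac, by = "variant", sort = FALSE)
  joined$rescaled_abundance <- rescale_scores(joined$abundance_score)
  joined$rescaled_activity <- rescale_scores(joined$activity_score)
  defined <- joined$rescaled_abundance > eps
  joined$specific_activity <- ifelse(defined,
                                     joined$rescaled_activity /
                                       joined$rescaled_abundance, NA_real_)
  joined$undefined_reason <- ifelse(defined, NA_character_,
                                    "rescaled_abundance_at_zero")
  joined
}

#' Positional median specific activity
#'
#' @param sa A [specific_activity_table()] result.
#' @return Data.frame per position: `position`, `median_specific_activity`
#'   (over defined ratios), `n_activity_variants` (variants scored for
#'   activity at the position), `n_defined`.
#' @export
position_specific_activity <- function(sa) {
  pos <- sort(unique(sa$position))
  out <- do.call(rbind, lapply(pos, function(p) {
    rows <- sa[sa$position == p, , drop = FALSE]
    ratios <- rows$specific_activity[!is.na(rows$specific_activity)]
    data.frame(position = p,
               median_specific_activity =
                 if (length(ratios)) stats::median(ratios) else NA_real_,
               n_activity_variants = nrow(rows),
               n_defined = length(ratios))
  }))
  rownames(out) <- NULL
  out
}

#' Call functionally constrained (active-site) positions
#'
#' The threshold is the `quantile` (default 12.5%) percentile of the defined
#' positional median specific activities; constrained positions are those at
#' or below the threshold that carry at least `min_variants` activity-scored
#' variants. By default the quantile is computed over all positions with a
#' defined median and the variant-count filter applied afterwards
#' (`filter_first = TRUE` reverses the order).
#'
#' @param positional A [position_specific_activity()] result.
#' @param quantile Quantile level (default 0.125).
#' @param min_variants Minimum activity variants per position (default 4).
#' @param filter_first Apply the variant-count filter before computing the
#'   quantile (default FALSE).
#' @return `positional` with added logical `constrained` column and the
#'   threshold as attribute `threshold`.
#' @export
constrained_positions <- function(positional, quantile = 0.125,
                                  min_variants = 4L, filter_first = FALSE) {
  med <- positional$median_specific_activity
  pool <- !is.na(med)
  if (filter_first) pool <- pool & positional$n_activity_variants >= min_variants
  if (!any(pool)) stop("no positions with defined median specific activity")
  threshold <- stats::quantile(med[pool], quantile, names = FALSE, type = 7)
  positional$constrained <- !is.na(med) & med <= threshold &
    positional$n_activity_variants >= min_variants
  attr(positional, "threshold") <- threshold
  positional
}

#' Positional summary profile
#'
#' One row per position with median abundance/activity scores, variant
#' counts, rescaled medians, median specific activity, and the constrained
#' call: the shape of a released positional source-data table.
#'
#' @inheritParams specific_activity_table
#' @inheritParams constrained_positions
#' @return Data.frame with columns `position`, `median_abundance`,
#'   `median_activity`, `rescaled_abundance`, `rescaled_activity`,
#'   `specific_activity`, `n_abundance_variants`, `n_activity_variants`,
#'   `constrained`.
#' @export
position_profiles <- function(abundance, activity, eps = 1e-6,
                              quantile = 0.125, min_variants = 4L) {
  sa <- specific_activity_table(abundance, activity, eps)
  pa <- constrained_positions(position_specific_activity(sa), quantile,
                              min_variants)
  med_by <- function(tab, positions) {
    vapply(positions, function(p) {
      x <- tab$score[tab$position == p & !is.na(tab$score)]
      if (length(x)) stats::median(x) else NA_real_
    }, 1)
  }
  n_by <- function(tab, positions) {
    vapply(positions, function(p)
      sum(tab$position == p & !is.na(tab$score)), 1L)
  }
  pos <- pa$position
  out <- data.frame(
    position = pos,
    median_abundance = med_by(abundance, pos),
    median_activity = med_by(activity, pos),
    n_abundance_variants = n_by(abundance, pos),
    n_activity_variants = pa$n_activity_variants,
    specific_activity = pa$median_specific_activity,
    constrained = pa$constrained)
  # rescaled positional medians, on the same dataset-wide affine maps
  ab_range <- range(abundance$score, na.rm = TRUE)
  ac_range <- range(activity$score, na.rm = TRUE)
  out$rescaled_abundance <- (out$median_abundance - ab_range[1]) /
    diff(ab_range)
  out$rescaled_activity <- (out$median_activity - ac_range[1]) /
    diff(ac_range)
  attr(out, "threshold") <- attr(pa, "threshold")
  out[, c("position", "median_abundance", "median_activity",
          "rescaled_abundance", "rescaled_activity", "specific_activity",
          "n_abundance_variants", "n_activity_variants", "constrained")]
}
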