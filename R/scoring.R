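# Sort-seq variant scoring: per-bin frequencies, frequency/replicate
# filters, bin-weighted averages, min-max normalization to the nonsense and
# synonymous anchor medians, and replicate aggregation with standard errors
# and normal-approximation confidence intervals.

#' Scoring parameters
#'
#' @param bin_weights Weights applied bin-wise to the four sort bins, lowest
#'   to highest fluorescence (default 0.25, 0.5, 0.75, 1).
#' @param f_expt_min Minimum number of replicates a variant must pass the
#'   frequency filter in to be scored (default 2).
#' @param f_freq_min Minimum total frequency (summed over the four bins)
#'   within a replicate (default 1e-4).
#' @param ci_z Normal quantile for the confidence interval (default 1.96,
#'   a 95% interval).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(bin_weights = c(0.25, 0.5, 0.75, 1),
                           f_expt_min = 2L, f_freq_min = 1e-4,
                           ci_z = 1.96) {
  if (length(bin_weights) != 4L || any(diff(bin_weights) <= 0))
    stop("bin_weights must be 4 strictly increasing values")
  if (f_freq_min <= 0 || f_freq_min >= 1)
    stop("f_freq_min must be in (0, 1)")
  if (f_expt_min < 1L) stop("f_expt_min must be at least 1")
  structure(list(bin_weights = as.numeric(bin_weights),
                 f_expt_min = as.integer(f_expt_min),
                 f_freq_min = f_freq_min, ci_z = ci_z),
            class = "scoring_params")
}

#' Per-bin variant frequencies
#'
#' Divides each count by the total count of its (replicate, bin), so that
#' every bin's variant frequencies sum to one.
#'
#' @param counts Integer array replicate x bin x variant (see
#'   [merge_counts()]).
#' @return A numeric array of the same shape.
#' @export
bin_frequencies <- function(counts) {
  stopifnot(length(dim(counts)) == 3L)
  totals <- apply(counts, c(1L, 2L), sum)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0, arr.ind = TRUE)
    stop("zero total counts in replicate ",
         dimnames(counts)[[1]][bad[1, 1]], ", bin ",
         dimnames(counts)[[2]][bad[1, 2]])
  }
  sweep(counts, c(1L, 2L), totals, "/")
}

#' Replicate-level frequency filter
#'
#' A variant is included in a replicate iff its total frequency across the
#' four bins reaches `f_freq_min`; it is eligible for a final score iff it
#' is included in at least `f_expt_min` replicates.
#'
#' @param freqs Frequency array from [bin_frequencies()].
#' @param params A [scoring_params()].
#' @return A list with `included` (replicate x variant logical matrix) and
#'   `eligible` (named logical vector over variants).
#' @export
replicate_inclusion <- function(freqs, params = scoring_params()) {
  total <- apply(freqs, c(1L, 3L), sum)
  included <- total >= params$f_freq_min
  eligible <- colSums(included) >= params$f_expt_min
  list(included = included, eligible = eligible)
}

#' Bin-weighted average of variant frequencies
#'
#' For frequencies f over the four bins, computes
#' `w = sum(weight * f) / sum(f)`: the variant's mean bin weight, a value
#' between the lowest and highest weight. Undefined (NA) when all four
#' frequencies are zero.
#'
#' @param freqs Either a numeric vector of 4 bin frequencies, a 4 x V
#'   matrix (bins in rows), or a replicate x bin x variant array.
#' @param weights The four bin weights (default 0.25, 0.5, 0.75, 1).
#' @return A scalar, a length-V vector, or a replicate x variant matrix of
#'   weighted averages.
#' @export
weighted_average <- function(freqs, weights = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(length(weights) == 4L)
  if (is.array(freqs) && length(dim(freqs)) == 3L) {
    num <- apply(sweep(freqs, 2L, weights, "*"), c(1L, 3L), sum)
    den <- apply(freqs, c(1L, 3L), sum)
    return(num / ifelse(den > 0, den, NA_real_))
  }
  f <- if (is.matrix(freqs)) freqs else matrix(freqs, nrow = 4L)
  stopifnot(nrow(f) == 4L)
  den <- colSums(f)
  w <- colSums(f * weights) / ifelse(den > 0, den, NA_real_)
  if (!is.matrix(freqs)) w[[1L]] else w
}

#' Min-max normalize weighted averages within one replicate
#'
#' Anchors the score scale on the two control distributions: the median
#' weighted average of the nonsense variants maps to 0 and the synonymous
#' median maps to 1.
#'
#' @param w Named numeric vector of weighted averages (one replicate).
#' @param mut_class Character vector parallel to `w` with values
#'   `missense` / `synonymous` / `nonsense`.
#' @param included Optional logical mask of variants included in this
#'   replicate; excluded entries yield NA and do not move the anchors.
#' @return Numeric vector of normalized scores, with attributes
#'   `median_nonsense` and `median_synonymous` (on the weighted-average
#'   scale).
#' @export
normalize_replicate <- function(w, mut_class, included = NULL) {
  stopifnot(length(w) == length(mut_class))
  if (is.null(included)) included <- !is.na(w)
  use <- included & !is.na(w)
  med_non <- stats::median(w[use & mut_class == "nonsense"])
  med_syn <- stats::median(w[use & mut_class == "synonymous"])
  if (!is.finite(med_non) || !is.finite(med_syn))
    stop("need at least one included nonsense and synonymous variant to anchor the scale")
  if (med_syn <= med_non)
    stop("synonymous median (", signif(med_syn, 4),
         ") is not above the nonsense median (", signif(med_non, 4),
         "); inverted or degenerate assay")
  out <- ifelse(use, (w - med_non) / (med_syn - med_non), NA_real_)
  attr(out, "median_nonsense") <- med_non
  attr(out, "median_synonymous") <- med_syn
  out
}

#' Compute final variant scores from a count tensor
#'
#' The full scoring pipeline: per-bin frequencies, the frequency /
#' replicate-count filters, bin-weighted averages, per-replicate min-max
#' normalization to the nonsense (0) and synonymous (1) anchor medians,
#' replicate averaging with SD, SE and a normal-approximation confidence
#' interval, and (by default) a final renormalization of the experiment-wide
#' means so the aggregate anchor medians are exactly 0 and 1.
#'
#' @param counts Integer array replicate x bin x variant, or a long
#'   data.frame accepted by [merge_counts()].
#' @param variants Data.frame keyed by `variant` with at least a
#'   `mut_class` column (plus `position`, `wt_aa`, `alt_aa` carried
#'   through); must cover the tensor's variants.
#' @param params A [scoring_params()].
#' @param final_normalize Re-anchor the aggregated means so the median
#'   synonymous score is exactly 1 and the median nonsense score exactly 0
#'   (default TRUE). SDs, SEs and CIs are rescaled accordingly.
#' @return A data.frame of class `variant_score_table` with one row per
#'   tensor variant: `variant`, `position`, `wt_aa`, `alt_aa`, `mut_class`,
#'   `score`, `sd`, `se`, `ci_lower`, `ci_upper`, `n_reps`, `excluded`,
#'   `exclusion_reason`. Variants failing the filters are retained with NA
#'   scores and an explicit reason.
#' @export
score_variants <- function(counts, variants, params = scoring_params(),
                           final_normalize = TRUE) {
  if (is.data.frame(counts)) counts <- merge_counts(counts)
  tokens <- dimnames(counts)[[3]]
  hit <- match(tokens, variants$variant)
  if (anyNA(hit))
    stop("variants table is missing ", sum(is.na(hit)), " tensor variants, e.g. ",
         tokens[which(is.na(hit))[1]])
  info <- variants[hit, , drop = FALSE]
  mut_class <- info$mut_class

  freqs <- bin_frequencies(counts)
  filt <- replicate_inclusion(freqs, params)
  w <- weighted_average(freqs, params$bin_weights)      # replicate x variant
  included <- filt$included & !is.na(w)

  norm <- w
  anchors <- matrix(NA_real_, nrow(w), 2L,
                    dimnames = list(rownames(w), c("nonsense", "synonymous")))
  for (r in seq_len(nrow(w))) {
    z <- normalize_replicate(w[r, ], mut_class, included[r, ])
    anchors[r, ] <- c(attr(z, "median_nonsense"), attr(z, "median_synonymous"))
    norm[r, ] <- z
  }

  n_reps <- colSums(included)
  eligible <- n_reps >= params$f_expt_min
  mean_score <- colMeans(ifelse(included, norm, NA), na.rm = TRUE)
  sds <- apply(ifelse(included, norm, NA), 2L, stats::sd, na.rm = TRUE)
  mean_score[!eligible] <- NA_real_
  sds[!eligible] <- NA_real_
  se <- sds / sqrt(n_reps)

  if (final_normalize) {
    med_non <- stats::median(mean_score[eligible & mut_class == "nonsense"])
    med_syn <- stats::median(mean_score[eligible & mut_class == "synonymous"])
    if (!is.finite(med_non) || !is.finite(med_syn) || med_syn <= med_non)
      stop("cannot re-anchor final scores: degenerate aggregate anchor medians")
    scale <- med_syn - med_non
    mean_score <- (mean_score - med_non) / scale
    sds <- sds / scale
    se <- se / scale
  }

  reason <- rep(NA_character_, length(tokens))
  reason[!eligible & colSums(filt$included) > 0] <- "insufficient_replicates"
  reason[colSums(filt$included) == 0] <- "below_frequency_filter"

  out <- data.frame(
    variant = tokens,
    position = if ("position" %in% names(info)) info$position else NA_integer_,
    wt_aa = if ("wt_aa" %in% names(info)) info$wt_aa else NA_character_,
    alt_aa = if ("alt_aa" %in% names(info)) info$alt_aa else NA_character_,
    mut_class = mut_class,
    score = unname(mean_score), sd = unname(sds), se = unname(se),
    ci_lower = unname(mean_score - params$ci_z * se),
    ci_upper = unname(mean_score + params$ci_z * se),
    n_reps = unname(n_reps),
    excluded = !eligible,
    exclusion_reason = reason,
    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  attr(out, "replicate_anchors") <- anchors
  class(out) <- c("variant_score_table", "data.frame")
  out
}

#' Write a variant score table as TSV
#'
#' Columns mirror a released score table: `variant position wt_aa alt_aa
#' mut_class score SD SE CI_lower CI_upper n_reps`.
#'
#' @param scores A [score_variants()] result.
#' @param path Output path.
#' @param drop_excluded Omit filtered variants (default FALSE: they are
#'   written with empty scores and their exclusion reason).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, drop_excluded = FALSE) {
  out <- as.data.frame(scores)
  if (drop_excluded) out <- out[!out$excluded, , drop = FALSE]
  names(out)[names(out) == "sd"] <- "SD"
  names(out)[names(out) == "se"] <- "SE"
  names(out)[names(out) == "ci_lower"] <- "CI_lower"
  names(out)[names(out) == "ci_upper"] <- "CI_upper"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
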