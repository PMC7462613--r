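# Five-way classification of scored variants against the synonymous score
# distribution, annotation of curated human variants, and two-sample
# distribution comparison.

CLASS_LABELS <- c("low", "possibly_low", "possibly_WT-like", "WT-like", "high")

#' Classification thresholds from the synonymous score distribution
#'
#' The lower threshold separates the 5% of synonymous variants with the
#' lowest scores from the rest; the upper threshold separates the top 5%.
#' Percentiles use linear interpolation.
#'
#' @param scores A [score_variants()] table (or any data.frame with `score`
#'   and `mut_class`).
#' @param probs Lower/upper percentile levels (default 0.05 and 0.95).
#' @return A list of class `class_thresholds` with `t_low` and `t_high`.
#' @export
synonymous_thresholds <- function(scores, probs = c(0.05, 0.95)) {
  syn <- scores$score[scores$mut_class == "synonymous" & !is.na(scores$score)]
  if (length(syn) == 0L) stop("no scored synonymous variants to set thresholds")
  if (length(syn) < 20L)
    warning("only ", length(syn), " synonymous scores; thresholds will be noisy")
  q <- stats::quantile(syn, probs, names = FALSE, type = 7)
  structure(list(t_low = q[1], t_high = q[2]), class = "class_thresholds")
}

#' Classify scored variants against the synonymous thresholds
#'
#' Decision order, with `t_low`/`t_high` the 5th/95th synonymous
#' percentiles: (1) score and CI upper bound both below `t_low`: `low`;
#' (2) score below `t_low`: `possibly_low`; (3) score above `t_high` with
#' CI lower bound at or above `t_low`: `high`; (4) CI lower bound at or
#' above `t_low`: `WT-like`; (5) otherwise `possibly_WT-like`. Note that
#' `high` requires the CI lower bound to clear the *lower* threshold only.
#' Boundary ties resolve toward the WT-like side.
#'
#' @param scores A [score_variants()] table.
#' @param thresholds A [synonymous_thresholds()] result; computed from
#'   `scores` when NULL.
#' @return `scores` with an added `class` column (NA, with
#'   `exclusion_reason`, for unscored variants).
#' @export
classify_variants <- function(scores, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- synonymous_thresholds(scores)
  stopifnot(inherits(thresholds, "class_thresholds"))
  scores$class <- vapply(seq_len(nrow(scores)), function(i) {
    classify_one(scores$score[i], scores$ci_lower[i], scores$ci_upper[i],
                 thresholds)
  }, "")
  scores$class[is.na(scores$score)] <- NA_character_
  attr(scores, "thresholds") <- thresholds
  scores
}

classify_one <- function(score, ci_lower, ci_upper, thresholds) {
  if (is.na(score)) return(NA_character_)
  if (is.na(ci_lower) || is.na(ci_upper)) {
    # no interval (single replicate with f_expt_min = 1): treat as zero-width
    ci_lower <- score
    ci_upper <- score
  }
  t_low <- thresholds$t_low
  t_high <- thresholds$t_high
  if (score < t_low && ci_upper < t_low) return("low")
  if (score < t_low) return("possibly_low")
  if (score > t_high && ci_lower >= t_low) return("high")
  if (ci_lower >= t_low) return("WT-like")
  "possibly_WT-like"
}

#' Read a curated human-variant table
#'
#' Expected TSV columns: `variant` plus any provenance/phenotype columns
#' (e.g. `source_gnomad`, `source_clinvar`, `source_color`,
#' `source_literature`, `phenotype_note`). Malformed variant tokens are
#' flagged, not fatal.
#'
#' @param path TSV path.
#' @return Data.frame with parsed `position`, `wt_aa`, `alt_aa`,
#'   `mut_class`, and a logical `valid_token` column.
#' @export
read_curated_variants <- function(path) {
  cur <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("variant" %in% names(cur))
  parsed <- parse_variant_token(cur$variant)
  cur$position <- parsed$position
  cur$wt_aa <- parsed$wt_aa
  cur$alt_aa <- parsed$alt_aa
  cur$mut_class <- parsed$mut_class
  cur$valid_token <- parsed$valid
  cur
}

#' Annotate curated human variants with scores and classes
#'
#' Joins a curated variant list to classified abundance (and optionally
#' activity) score tables by variant token and cross-tabulates classes by
#' mutation class.
#'
#' @param curated Data.frame with a `variant` column (see
#'   [read_curated_variants()]).
#' @param abundance A [classify_variants()] table for the abundance assay.
#' @param activity Optional classified activity table.
#' @return A list with `annotated` (the curated table plus
#'   `abundance_score`, `abundance_class`, and if supplied
#'   `activity_score`, `activity_class`), `histogram` (mutation class x
#'   abundance class contingency table over annotated variants),
#'   `n_annotated` and `n_missing`.
#' @export
annotate_human_variants <- function(curated, abundance, activity = NULL) {
  stopifnot("variant" %in% names(curated), "class" %in% names(abundance))
  if (!"valid_token" %in% names(curated)) {
    parsed <- parse_variant_token(curated$variant)
    curated$valid_token <- parsed$valid
    if (!"mut_class" %in% names(curated)) curated$mut_class <- parsed$mut_class
  }
  hit <- match(curated$variant, abundance$variant)
  curated$abundance_score <- abundance$score[hit]
  curated$abundance_class <- abundance$class[hit]
  if (!is.null(activity)) {
    hit_a <- match(curated$variant, activity$variant)
    curated$activity_score <- activity$score[hit_a]
    curated$activity_class <- activity$class[hit_a]
  }
  annotated <- !is.na(curated$abundance_class)
  histogram <- table(
    mut_class = factor(curated$mut_class[annotated], levels = MUT_CLASSES),
    class = factor(curated$abundance_class[annotated], levels = CLASS_LABELS))
  list(annotated = curated, histogram = histogram,
       n_annotated = sum(annotated), n_missing = sum(!annotated))
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided approximation.
#'
#' @param a,b Numeric score vectors (each of length >= 2; NAs dropped).
#' @return A list with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
compare_score_distributions <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n_a = length(a), n_b = length(b))
}
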