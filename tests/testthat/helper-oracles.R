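# Independent oracles and small fixture builders. Everything here is
# deliberately naive (loops, enumeration) and kept separate from the
# package's own code paths.

# 5-codon toy gene: M T R W K
toy_reference <- function() {
  protein_reference("toy", "ATGACCCGGTGGAAA")
}

# replace codon `pos` of a reference's coding sequence
edit_codon <- function(reference, pos, codon) {
  s <- reference$coding_sequence
  paste0(substr(s, 1, 3 * pos - 3), codon, substr(s, 3 * pos + 1, nchar(s)))
}

# per-column majority consensus; NA on any tie
oracle_consensus <- function(reads) {
  chars <- strsplit(reads, "")
  out <- character(nchar(reads[1]))
  for (j in seq_along(out)) {
    col <- vapply(chars, `[`, "", j)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return(NA_character_)
    out[j] <- names(tab)[1]
  }
  paste(out, collapse = "")
}

# windowed class mean by double loop
oracle_windowed <- function(scores, residues, window, L) {
  lo <- window %/% 2 - 1
  hi <- window %/% 2
  res <- NULL
  for (p in seq_len(L)) {
    if (p - lo < 1 || p + hi > L) next
    vals <- c()
    for (i in seq_len(nrow(scores))) {
      if (is.na(scores$score[i])) next
      if (!scores$alt_aa[i] %in% residues) next
      if (!is.na(scores$wt_aa[i]) && scores$alt_aa[i] == scores$wt_aa[i]) next
      if (scores$position[i] >= p - lo && scores$position[i] <= p + hi)
        vals <- c(vals, scores$score[i])
    }
    if (length(vals) == 0L) next
    res <- rbind(res, data.frame(position = p, windowed_mean = mean(vals),
                                 n_scores = length(vals)))
  }
  res
}

# naive O(n^3) agglomerative clustering with complete linkage on a
# distance matrix; returns merge heights and the partition at k groups
oracle_complete_linkage <- function(dm, k) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- max(dm[clusters[[a]], clusters[[b]]])
      if (d < best_d) {
        best_d <- d
        best <- c(a, b)
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    if (length(clusters) == k) at_k <- clusters
  }
  if (k == n) at_k <- as.list(seq_len(n))
  groups <- integer(n)
  for (g in seq_along(at_k)) groups[at_k[[g]]] <- g
  list(heights = heights, groups = groups)
}

# two partitions are equal up to label permutation
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# KS statistic by explicit ECDF sweep over all jump points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 1)))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hypergeom_p <- function(universe, reference, n_pred, overlap) {
  draws <- utils::combn(universe, n_pred)
  hits <- colSums(matrix(draws %in% reference, nrow = n_pred))
  mean(hits >= overlap)
}

# brute-force reimplementation of the whole scoring chain (no final
# renormalization), written with explicit loops
oracle_scores <- function(counts, mut_class, params) {
  reps <- dim(counts)[1]
  V <- dim(counts)[3]
  w <- matrix(NA_real_, reps, V)
  incl <- matrix(FALSE, reps, V)
  for (r in seq_len(reps)) {
    freq <- matrix(NA_real_, 4, V)
    for (b in 1:4) freq[b, ] <- counts[r, b, ] / sum(counts[r, b, ])
    for (v in seq_len(V)) {
      tot <- sum(freq[, v])
      incl[r, v] <- tot >= params$f_freq_min
      if (tot > 0) w[r, v] <- sum(params$bin_weights * freq[, v]) / tot
    }
  }
  norm <- matrix(NA_real_, reps, V)
  for (r in seq_len(reps)) {
    use <- incl[r, ] & !is.na(w[r, ])
    mn <- median(w[r, use & mut_class == "nonsense"])
    ms <- median(w[r, use & mut_class == "synonymous"])
    norm[r, use] <- (w[r, use] - mn) / (ms - mn)
  }
  out <- data.frame(score = rep(NA_real_, V), sd = NA_real_, se = NA_real_,
                    n_reps = colSums(incl & !is.na(w)))
  for (v in seq_len(V)) {
    x <- norm[incl[, v] & !is.na(w[, v]), v]
    if (length(x) >= params$f_expt_min) {
      out$score[v] <- mean(x)
      out$sd[v] <- sd(x)
      out$se[v] <- sd(x) / sqrt(length(x))
    }
  }
  out
}

# random variant score table over positions 1..L
random_score_table <- function(n, L = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sample(L, n, replace = TRUE)
  wt <- sample(c(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), n,
               replace = TRUE)
  alt <- sample(c(AA, "*"), n, replace = TRUE)
  data.frame(variant = paste0(wt, pos, alt), position = pos, wt_aa = wt,
             alt_aa = alt,
             mut_class = ifelse(alt == "*", "nonsense",
                                ifelse(alt == wt, "synonymous", "missense")),
             score = rnorm(n, 0.6, 0.4), stringsAsFactors = FALSE)
}

# tiny simulated experiment shared by several test files
small_sim <- function(seed = 3) {
  cfg <- sim_config(seed = seed, n_positions = 20, first_position = 2,
                    tmd_segments = list(c(8L, 14L)), tm_flank = 1L,
                    active_site_positions = c(17L, 19L),
                    n_missense_per_position = 2, n_synonymous = 6,
                    n_nonsense = 4, cells_sorted = 5000, reads_per_bin = 2e4,
                    n_replicates = 3)
  list(cfg = cfg, sim = simulate_sortseq(cfg))
}

# write FASTQ records from parallel vectors of sequence and quality strings
write_fastq_lines <- function(path, seqs, quals) {
  stopifnot(length(seqs) == length(quals))
  rec <- rbind(paste0("@read", seq_along(seqs)), seqs, "+", quals)
  writeLines(as.vector(rec), path)
  path
}
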