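# Generative model of a binned-sort (sort-seq) deep mutational scan.
# Emulates: a site-saturation library with synonymous and nonsense controls,
# library-representation skew, per-cell fluorescence noise, quartile FACS
# gating, and per-bin sequencing-depth sampling, for both an abundance-style
# and an activity-style assay over the same variant library.

CHARGED_AAS <- c("R", "K", "H", "D", "E")
ALIPHATIC_AAS <- c("G", "A", "V", "I", "L")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the sort-seq simulator
#'
#' Defaults describe a four-transmembrane-domain membrane protein scanned
#' over residues 2-163 with roughly 550 variants, four replicates, 2e5
#' sorted cells and 1e6 reads per bin -- a desk-scale stand-in for a real
#' quartile-sort experiment.
#'
#' @param seed Integer seed; all sampling is reproducible given the seed.
#' @param n_positions Number of mutagenized residues (default 162).
#' @param first_position First mutagenized residue (default 2; position 1 is
#'   the untouched initiator methionine).
#' @param tmd_segments List of inclusive residue intervals forming
#'   transmembrane domains; default four 21-residue helices.
#' @param tm_flank Residues flanking each segment that still sit at the
#'   membrane interface; charged/proline substitutions there are penalized
#'   like in-helix ones (default 2).
#' @param active_site_positions Residues whose missense variants lose
#'   activity while retaining abundance (default eight loop residues).
#' @param n_missense_per_position Missense variants drawn per position
#'   (default 3; active-site positions are guaranteed at least
#'   `n_active_missense_min` so the downstream >=4-variants rule can apply).
#' @param n_active_missense_min Minimum missense variants at designated
#'   active-site positions (default 5).
#' @param n_synonymous,n_nonsense Number of synonymous / nonsense control
#'   variants (defaults 40 and 25).
#' @param n_barcodes_per_variant Mean of the shifted-Poisson barcode count
#'   per variant (default 3).
#' @param cells_sorted Cells sorted per replicate (default 2e5).
#' @param reads_per_bin Sequencing depth per bin (default 1e6).
#' @param cell_noise_sd SD of per-cell fluorescence about the variant's true
#'   value, on the score scale (default 0.35).
#' @param n_replicates Number of replicates (default 4).
#' @param library_skew_concentration Gamma shape of per-barcode library
#'   weights; normalized weights are Dirichlet with this concentration
#'   (default 2, a realistically skewed library).
#' @param effect_model Named list of true-effect parameters; see the methods
#'   vignette. Components: mixture `means`/`sds` and weights for loop
#'   (`weights_loop`) and transmembrane (`weights_tm`) positions,
#'   `p_tm_charged_low` (probability that a charged/proline substitution in
#'   or flanking a helix falls in the low component), `syn_sd`/`nonsense_sd`
#'   (spread of the control distributions about 1 and 0),
#'   `activity_tracking_sd` (how tightly activity follows abundance away
#'   from the active site), and `active_site_activity_mean`/`_sd`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_positions = 162L,
                       first_position = 2L,
                       tmd_segments = list(c(10L, 30L), c(58L, 78L),
                                           c(90L, 110L), c(122L, 142L)),
                       tm_flank = 2L,
                       active_site_positions = c(35L, 37L, 39L, 43L, 45L,
                                                 47L, 51L, 55L),
                       n_missense_per_position = 3L,
                       n_active_missense_min = 5L,
                       n_synonymous = 40L,
                       n_nonsense = 25L,
                       n_barcodes_per_variant = 3,
                       cells_sorted = 2e5,
                       reads_per_bin = 1e6,
                       cell_noise_sd = 0.35,
                       n_replicates = 4L,
                       library_skew_concentration = 2,
                       effect_model = list()) {
  defaults <- list(
    weights_loop = c(wt = 0.60, intermediate = 0.20, low = 0.20),
    weights_tm = c(wt = 0.30, intermediate = 0.35, low = 0.35),
    means = c(wt = 1, intermediate = 0.5, low = 0.02),
    sds = c(wt = 0.08, intermediate = 0.12, low = 0.05),
    p_tm_charged_low = 0.95,
    syn_sd = 0.08,
    nonsense_sd = 0.04,
    activity_tracking_sd = 0.08,
    active_site_activity_mean = 0.05,
    active_site_activity_sd = 0.04)
  effect_model <- utils::modifyList(defaults, effect_model)
  cfg <- list(seed = as.integer(seed), n_positions = as.integer(n_positions),
              first_position = as.integer(first_position),
              tmd_segments = lapply(tmd_segments, as.integer),
              tm_flank = as.integer(tm_flank),
              active_site_positions = as.integer(active_site_positions),
              n_missense_per_position = as.integer(n_missense_per_position),
              n_active_missense_min = as.integer(n_active_missense_min),
              n_synonymous = as.integer(n_synonymous),
              n_nonsense = as.integer(n_nonsense),
              n_barcodes_per_variant = n_barcodes_per_variant,
              cells_sorted = cells_sorted, reads_per_bin = reads_per_bin,
              cell_noise_sd = cell_noise_sd,
              n_replicates = as.integer(n_replicates),
              library_skew_concentration = library_skew_concentration,
              effect_model = effect_model)
  counts <- c(cfg$n_positions, cfg$n_missense_per_position, cfg$n_synonymous,
              cfg$n_nonsense, cfg$n_barcodes_per_variant, cfg$cells_sorted,
              cfg$reads_per_bin, cfg$n_replicates,
              cfg$library_skew_concentration)
  if (any(counts <= 0)) stop("all counts and rates must be positive")
  if (cfg$cell_noise_sd < 0) stop("cell_noise_sd must be nonnegative")
  last <- cfg$first_position + cfg$n_positions - 1L
  for (seg in cfg$tmd_segments) {
    if (length(seg) != 2L || seg[1] > seg[2] ||
        seg[1] < cfg$first_position || seg[2] > last)
      stop("tmd_segments must be valid intervals within the mutagenized range")
  }
  if (length(cfg$tmd_segments) > 1L) {
    m <- do.call(rbind, cfg$tmd_segments)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) stop("tmd_segments must be disjoint")
  }
  structure(cfg, class = "sim_config")
}

# per-position region labels: segments are TM, intervening regions alternate
# cytoplasmic / lumenal starting from a cytoplasmic N-terminus
region_labels <- function(length_protein, tmd_segments) {
  lab <- rep(NA_character_, length_protein)
  side <- "cytoplasmic"
  cursor <- 1L
  if (length(tmd_segments) > 0L) {
    segs <- do.call(rbind, tmd_segments)
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      if (cursor < segs[i, 1]) lab[cursor:(segs[i, 1] - 1L)] <- side
      lab[segs[i, 1]:segs[i, 2]] <- "TM"
      side <- if (side == "cytoplasmic") "lumenal" else "cytoplasmic"
      cursor <- segs[i, 2] + 1L
    }
  }
  if (cursor <= length_protein) lab[cursor:length_protein] <- side
  lab
}

in_any_segment <- function(positions, segments, flank = 0L) {
  hit <- rep(FALSE, length(positions))
  for (seg in segments)
    hit <- hit | (positions >= seg[1] - flank & positions <= seg[2] + flank)
  hit
}

#' Simulate the ground-truth variant library
#'
#' Draws a random coding reference, the variant library (missense at every
#' mutagenized position plus synonymous and nonsense controls), and each
#' variant's true abundance and activity on the normalized score scale.
#' Missense abundance effects come from a three-component mixture (WT-like,
#' intermediate, low); charged and proline substitutions within (or
#' immediately flanking) transmembrane segments are assigned the low
#' component with high probability; missense variants at designated
#' active-site positions lose activity but not abundance.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `reference` (a
#'   [protein_reference()]) and `variants`, a data.frame with one row per
#'   variant: `variant`, `position`, `wt_aa`, `alt_aa`, `alt_codon`,
#'   `mut_class`, `true_abundance`, `true_activity`, `region_label`,
#'   `active_site`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  em <- config$effect_model
  L <- config$first_position + config$n_positions - 1L
  code <- Biostrings::GENETIC_CODE
  sense_codons <- names(code)[code != AA_STOP]
  codons <- c("ATG", sample(sense_codons, L - 1L, replace = TRUE))
  ref <- protein_reference("synthetic", paste(codons, collapse = ""),
                           c(config$first_position, L))
  positions <- config$first_position:L
  wt <- strsplit(ref$protein_sequence, "")[[1]]

  rows <- vector("list", 3L)
  # missense
  mm <- lapply(positions, function(p) {
    n_mm <- config$n_missense_per_position
    if (p %in% config$active_site_positions)
      n_mm <- max(n_mm, config$n_active_missense_min)
    alts <- sample(setdiff(AA_ALPHABET, wt[p]), min(n_mm, 19L))
    alt_codons <- vapply(alts, function(a) {
      sample(names(code)[code == a], 1L)
    }, "")
    variant_key(p, wt[p], alts, alt_codons, "missense")
  })
  rows[[1]] <- do.call(rbind, mm)
  # synonymous: positions whose WT codon has a synonymous alternative
  syn_ok <- positions[vapply(positions, function(p) {
    sum(code == wt[p]) > 1L
  }, TRUE)]
  syn_pos <- sample(syn_ok, min(config$n_synonymous, length(syn_ok)))
  syn_codons <- vapply(syn_pos, function(p) {
    alt <- setdiff(names(code)[code == wt[p]], codons[p])
    sample(alt, 1L)
  }, "")
  rows[[2]] <- variant_key(syn_pos, wt[syn_pos], wt[syn_pos], syn_codons,
                           "synonymous")
  # nonsense
  non_pos <- sample(positions, min(config$n_nonsense, length(positions)))
  rows[[3]] <- variant_key(non_pos, wt[non_pos], AA_STOP,
                           sample(STOP_CODONS, length(non_pos), replace = TRUE),
                           "nonsense")
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL

  n <- nrow(variants)
  tm_core <- in_any_segment(variants$position, config$tmd_segments)
  tm_iface <- in_any_segment(variants$position, config$tmd_segments,
                             config$tm_flank)
  helix_breaker <- variants$alt_aa %in% c(CHARGED_AAS, "P")

  draw_mix <- function(k, weights) {
    comp <- sample(names(em$means), k, replace = TRUE, prob = weights)
    stats::rnorm(k, em$means[comp], em$sds[comp])
  }
  abundance <- numeric(n)
  is_mis <- variants$mut_class == "missense"
  is_syn <- variants$mut_class == "synonymous"
  is_non <- variants$mut_class == "nonsense"
  abundance[is_syn] <- stats::rnorm(sum(is_syn), 1, em$syn_sd)
  abundance[is_non] <- stats::rnorm(sum(is_non), 0, em$nonsense_sd)
  # missense: interfacial charged/proline -> low with p_tm_charged_low,
  # otherwise mixture with TM or loop weights
  mis_idx <- which(is_mis)
  for (i in mis_idx) {
    if (tm_iface[i] && helix_breaker[i] &&
        stats::runif(1) < em$p_tm_charged_low) {
      abundance[i] <- stats::rnorm(1, em$means["low"], em$sds["low"])
    } else if (tm_core[i]) {
      abundance[i] <- draw_mix(1L, em$weights_tm)
    } else {
      abundance[i] <- draw_mix(1L, em$weights_loop)
    }
  }
  active <- variants$position %in% config$active_site_positions & is_mis
  activity <- numeric(n)
  activity[is_syn] <- stats::rnorm(sum(is_syn), 1, em$syn_sd)
  activity[is_non] <- stats::rnorm(sum(is_non), 0, em$nonsense_sd)
  act_mis <- is_mis & !active
  activity[act_mis] <- abundance[act_mis] +
    stats::rnorm(sum(act_mis), 0, em$activity_tracking_sd)
  activity[active] <- stats::rnorm(sum(active), em$active_site_activity_mean,
                                   em$active_site_activity_sd)

  variants$true_abundance <- abundance
  variants$true_activity <- activity
  labels <- region_labels(L, config$tmd_segments)
  variants$region_label <- labels[variants$position]
  variants$active_site <- active
  structure(list(reference = ref, variants = variants), class = "sim_truth")
}

#' Simulate the barcode-to-variant map of the library
#'
#' Each variant receives a shifted-Poisson number of distinct 18-nt
#' barcodes; each barcode carries an independent Gamma library weight, so
#' that variant representation is Dirichlet-skewed.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The [sim_config()] used to generate `truth`.
#' @return A data.frame with columns `barcode`, `variant`, `position`,
#'   `wt_aa`, `alt_aa`, `alt_codon`, `mut_class` and the (latent) library
#'   `weight` of each barcode.
#' @export
simulate_barcode_map <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  v <- truth$variants
  k <- 1L + stats::rpois(nrow(v), max(config$n_barcodes_per_variant - 1, 0))
  total <- sum(k)
  bc <- random_barcodes(total, 18L)
  idx <- rep(seq_len(nrow(v)), k)
  data.frame(barcode = bc,
             variant = v$variant[idx], position = v$position[idx],
             wt_aa = v$wt_aa[idx], alt_aa = v$alt_aa[idx],
             alt_codon = v$alt_codon[idx], mut_class = v$mut_class[idx],
             weight = stats::rgamma(total, shape = config$library_skew_concentration,
                                    rate = 1),
             stringsAsFactors = FALSE)
}

random_barcodes <- function(n, width) {
  draw <- function(m) {
    apply(matrix(sample(c("A", "C", "G", "T"), m * width, replace = TRUE),
                 nrow = m), 1L, paste, collapse = "")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Simulate FACS quartile sorting of the library
#'
#' For each replicate, cells are allotted to variants by a multinomial draw
#' over the (Dirichlet-skewed) library weights; each cell's fluorescence is
#' its variant's true value plus Gaussian noise; the pooled per-replicate
#' fluorescence histogram is cut at its empirical quartiles into four equal
#' bins, mirroring how a sorter gates a library into quartile bins.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The corresponding [sim_config()].
#' @param assay `"abundance"` or `"activity"`: which true value drives the
#'   sorted fluorescence.
#' @param weights Optional per-variant library weights (e.g. aggregated from
#'   [simulate_barcode_map()]); drawn Dirichlet internally when `NULL`.
#' @return A list of class `sim_sort` with `assay`, `variant` (tokens) and
#'   `replicates`: per replicate a list with `cell_counts` (4 x V integer
#'   matrix of cells per bin and variant) and the fluorescence `gates`.
#' @export
simulate_sort <- function(truth, config, assay = c("abundance", "activity"),
                          weights = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  assay <- match.arg(assay)
  set.seed(config$seed + 303L + 1000L * (assay == "activity"))
  v <- truth$variants
  if (nrow(v) == 0L) stop("truth table is empty")
  if (config$cells_sorted < nrow(v))
    warning("cells_sorted (", config$cells_sorted,
            ") is below the number of variants (", nrow(v), ")")
  true_val <- if (assay == "abundance") v$true_abundance else v$true_activity
  if (is.null(weights))
    weights <- stats::rgamma(nrow(v), shape = config$library_skew_concentration,
                             rate = 1)
  weights <- weights / sum(weights)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    n_cells <- as.integer(stats::rmultinom(1L, config$cells_sorted, weights))
    vid <- rep(seq_len(nrow(v)), n_cells)
    fluor <- stats::rnorm(length(vid), true_val[vid], config$cell_noise_sd)
    gates <- stats::quantile(fluor, c(0.25, 0.5, 0.75), names = FALSE)
    bin <- findInterval(fluor, gates) + 1L
    counts <- matrix(tabulate(bin + 4L * (vid - 1L), nbins = 4L * nrow(v)),
                     nrow = 4L, dimnames = list(bin = as.character(1:4),
                                                variant = v$variant))
    list(cell_counts = counts, gates = gates)
  })
  names(reps) <- paste0("R", seq_along(reps))
  structure(list(assay = assay, variant = v$variant, replicates = reps),
            class = "sim_sort")
}

#' Simulate per-bin barcode sequencing of sorted cells
#'
#' Reads in each (replicate, bin) are a multinomial sample of depth
#' `reads_per_bin` over barcodes, with probabilities proportional to the
#' cells carrying each barcode (cells of a variant are spread over its
#' barcodes in proportion to their library weights).
#'
#' @param sorted A [simulate_sort()] result.
#' @param barcode_map A [simulate_barcode_map()] result.
#' @param config The corresponding [sim_config()].
#' @return A list of class `sim_reads` with `counts`, a replicate x bin x
#'   variant integer array, and `barcode_counts`, a long data.frame
#'   (`replicate`, `bin`, `barcode`, `variant`, `count`) of nonzero barcode
#'   read counts.
#' @export
simulate_reads <- function(sorted, barcode_map, config) {
  stopifnot(inherits(sorted, "sim_sort"), inherits(config, "sim_config"))
  set.seed(config$seed + 404L + 1000L * (sorted$assay == "activity"))
  variants <- sorted$variant
  if (!all(variants %in% barcode_map$variant))
    stop("every variant must carry at least one barcode")
  vidx <- match(barcode_map$variant, variants)
  share <- barcode_map$weight / stats::ave(barcode_map$weight, vidx, FUN = sum)
  reps <- names(sorted$replicates)
  counts <- array(0L, dim = c(length(reps), 4L, length(variants)),
                  dimnames = list(replicate = reps, bin = as.character(1:4),
                                  variant = variants))
  bc_rows <- list()
  for (r in reps) {
    cells <- sorted$replicates[[r]]$cell_counts
    for (b in 1:4) {
      prob <- cells[b, vidx] * share
      if (sum(prob) <= 0) next
      reads <- as.integer(stats::rmultinom(1L, config$reads_per_bin,
                                           prob / sum(prob)))
      vcount <- as.integer(rowsum(reads, vidx))  # sorted by group index
      counts[r, b, sort(unique(vidx))] <- vcount
      nz <- which(reads > 0L)
      bc_rows[[length(bc_rows) + 1L]] <- data.frame(
        replicate = r, bin = b, barcode = barcode_map$barcode[nz],
        variant = barcode_map$variant[nz], count = reads[nz],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = counts,
                 barcode_counts = do.call(rbind, bc_rows)),
            class = "sim_reads")
}

#' Write simulated reads of one replicate/bin as FASTQ
#'
#' Each barcode read becomes a 4-line Phred+33 FASTQ record with constant
#' base quality; an optional per-base error rate perturbs barcode bases to
#' exercise exact-match counting and quality filtering downstream.
#'
#' @param barcode_counts Long data.frame from [simulate_reads()]
#'   (`$barcode_counts`).
#' @param path Output FASTQ path.
#' @param replicate,bin Which (replicate, bin) cell to emit.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param quality Constant Phred base quality (default 37).
#' @param seed Seed for error placement (default 1).
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(barcode_counts, path, replicate, bin,
                            error_rate = 0, quality = 37L, seed = 1L) {
  sel <- barcode_counts[barcode_counts$replicate == replicate &
                          barcode_counts$bin == bin, , drop = FALSE]
  reads <- rep(sel$barcode, sel$count)
  if (error_rate > 0 && length(reads) > 0L) {
    set.seed(seed)
    width <- nchar(reads[1L])
    chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                    ncol = width, byrow = TRUE)
    hit <- which(stats::runif(length(chars)) < error_rate)
    if (length(hit) > 0L)
      chars[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    reads <- apply(chars, 1L, paste, collapse = "")
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read_%d", seq_along(x))
  qual <- Biostrings::BStringSet(rep(strrep(rawToChar(as.raw(33L + quality)),
                                            if (length(x)) nchar(reads[1L]) else 0L),
                                     length(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Run the full generative model
#'
#' Convenience wrapper: truth, barcode map, and quartile sort plus per-bin
#' read sampling for both the abundance and the activity assay.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_experiment` with `config`, `truth`,
#'   `barcode_map`, and per assay (`abundance`, `activity`) the
#'   [simulate_sort()] and [simulate_reads()] results.
#' @export
simulate_sortseq <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  barcode_map <- simulate_barcode_map(truth, config)
  vweights <- as.numeric(rowsum(barcode_map$weight,
                                match(barcode_map$variant,
                                      truth$variants$variant)))
  out <- list(config = config, truth = truth, barcode_map = barcode_map)
  for (assay in c("abundance", "activity")) {
    sorted <- simulate_sort(truth, config, assay, weights = vweights)
    out[[assay]] <- list(sort = sorted,
                         reads = simulate_reads(sorted, barcode_map, config))
  }
  structure(out, class = "sim_experiment")
}

#' Write simulator outputs as plain-text tables
#'
#' Emits `truth.tsv`, `barcode_map.tsv` and one `counts_rep<k>_bin<b>.tsv`
#' (`barcode  count`) per replicate and bin for each assay.
#'
#' @param sim A [simulate_sortseq()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$truth$variants, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_barcode_map(sim$barcode_map, file.path(dir, "barcode_map.tsv"))
  for (assay in c("abundance", "activity")) {
    bc <- sim[[assay]]$reads$barcode_counts
    for (r in unique(bc$replicate)) for (b in unique(bc$bin)) {
      sel <- bc[bc$replicate == r & bc$bin == b, c("barcode", "count")]
      utils::write.table(sel,
                         file.path(dir, sprintf("%s_counts_rep%s_bin%d.tsv",
                                                assay, sub("^R", "", r), b)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
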