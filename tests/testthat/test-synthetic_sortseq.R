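test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_replicates = 0), "positive")
  expect_error(sim_config(tmd_segments = list(c(10, 30), c(25, 40))),
               "disjoint")
  expect_error(sim_config(tmd_segments = list(c(1, 30))), "within")
})

test_that("simulated truth has the stated control structure", {
  cfg <- sim_config(seed = 5, n_positions = 60, first_position = 2,
                    tmd_segments = list(c(10L, 30L)),
                    active_site_positions = c(40L, 45L),
                    n_synonymous = 30, n_nonsense = 20)
  truth <- simulate_truth(cfg)
  v <- truth$variants
  expect_equal(sum(v$mut_class == "synonymous"), 30L)
  expect_equal(sum(v$mut_class == "nonsense"), 20L)
  # controls sit near their anchors by construction
  expect_lt(abs(mean(v$true_abundance[v$mut_class == "synonymous"]) - 1), 0.06)
  expect_lt(abs(mean(v$true_abundance[v$mut_class == "nonsense"])), 0.04)
  # active-site missense: low activity, abundance from the normal model
  act <- v[v$active_site, ]
  expect_true(all(act$mut_class == "missense"))
  expect_lt(max(act$true_activity), 0.3)
  # every variant decodes against the simulated reference
  for (i in sample(nrow(v), 20)) {
    res <- call_variant(edit_codon(truth$reference, v$position[i],
                                   v$alt_codon[i]), truth$reference)
    expect_equal(res$status, "accepted")
    expect_equal(res$variant$variant, v$variant[i])
  }
  # region labels alternate around the TM segment
  expect_equal(unique(v$region_label[v$position < 10]), "cytoplasmic")
  expect_equal(unique(v$region_label[v$position >= 10 & v$position <= 30]),
               "TM")
  expect_equal(unique(v$region_label[v$position > 30]), "lumenal")
})

test_that("without TM segments the low-component fraction matches the mixture weight", {
  cfg <- sim_config(seed = 9, tmd_segments = list(),
                    active_site_positions = integer(0),
                    n_missense_per_position = 6)
  v <- simulate_truth(cfg)$variants
  mis <- v$true_abundance[v$mut_class == "missense"]
  # low component: mean 0.02, sd 0.05; intermediate leakage below 0.25 is
  # pnorm((0.25-0.5)/0.12) ~ 0.019 of its 20% weight
  frac_low <- mean(mis < 0.25)
  expected <- 0.20 + 0.20 * pnorm((0.25 - 0.5) / 0.12)
  se <- sqrt(expected * (1 - expected) / length(mis))
  expect_lt(abs(frac_low - expected), 3 * se)
})

test_that("simulation is reproducible bit-for-bit given the seed", {
  cfg <- sim_config(seed = 21, n_positions = 15, n_synonymous = 4,
                    n_nonsense = 3, tmd_segments = list(c(5L, 10L)),
                    active_site_positions = integer(0),
                    cells_sorted = 2000, reads_per_bin = 5000,
                    n_replicates = 2)
  s1 <- simulate_sortseq(cfg)
  s2 <- simulate_sortseq(cfg)
  expect_identical(s1$truth$variants, s2$truth$variants)
  expect_identical(s1$barcode_map, s2$barcode_map)
  expect_identical(s1$abundance$reads$counts, s2$abundance$reads$counts)
  expect_identical(s1$activity$reads$counts, s2$activity$reads$counts)
})

test_that("quartile gates split cells as expected", {
  cfg <- sim_config(seed = 2, n_positions = 10, n_synonymous = 3,
                    n_nonsense = 2, tmd_segments = list(),
                    active_site_positions = integer(0),
                    cells_sorted = 40000, cell_noise_sd = 1e-6,
                    n_replicates = 1)
  truth <- simulate_truth(cfg)
  # all variants share one true value: every variant splits ~evenly
  truth$variants$true_abundance <- 0.5
  sorted <- simulate_sort(truth, cfg, "abundance",
                          weights = rep(1, nrow(truth$variants)))
  counts <- sorted$replicates$R1$cell_counts
  expect_equal(sum(counts), 40000)
  per_var <- sweep(counts, 2, colSums(counts), "/")
  expect_lt(max(abs(per_var - 0.25)), 0.05)
  # two well-separated groups with equal representation: low group fills
  # bins 1-2, high group bins 3-4
  truth$variants$true_abundance <-
    rep_len(c(0, 1), nrow(truth$variants))
  sorted <- simulate_sort(truth, cfg, "abundance",
                          weights = rep(1, nrow(truth$variants)))
  counts <- sorted$replicates$R1$cell_counts
  low <- which(rep_len(c(TRUE, FALSE), ncol(counts)))
  # outer gates fall strictly inside each cluster, so bins 1 and 4 are pure;
  # the median gate sits at the cluster boundary, where multinomial
  # imbalance in group sizes leaks a binomial-order fraction across
  expect_equal(sum(counts[4, low]), 0)
  expect_equal(sum(counts[1, -low]), 0)
  leaked <- sum(counts[3:4, low]) + sum(counts[1:2, -low])
  expect_lt(leaked / sum(counts), 0.02)
})

test_that("cells below the variant count warn; read depth is conserved", {
  cfg <- sim_config(seed = 4, n_positions = 30, n_synonymous = 5,
                    n_nonsense = 5, tmd_segments = list(),
                    active_site_positions = integer(0),
                    cells_sorted = 50, reads_per_bin = 1000,
                    n_replicates = 1)
  truth <- simulate_truth(cfg)
  expect_warning(simulate_sort(truth, cfg), "below the number of variants")
  cfg2 <- sim_config(seed = 4, n_positions = 30, n_synonymous = 5,
                     n_nonsense = 5, tmd_segments = list(),
                     active_site_positions = integer(0),
                     cells_sorted = 5000, reads_per_bin = 1000,
                     n_replicates = 2)
  sim <- simulate_sortseq(cfg2)
  per_bin <- apply(sim$abundance$reads$counts, c(1, 2), sum)
  expect_true(all(per_bin == 1000))
  # barcode-level and variant-level counts agree
  bc <- sim$abundance$reads$barcode_counts
  agg <- tapply(bc$count, list(bc$replicate, bc$bin, bc$variant), sum)
  for (r in dimnames(agg)[[1]]) for (b in dimnames(agg)[[2]]) {
    v <- dimnames(agg)[[3]]
    x <- agg[r, b, ]
    x[is.na(x)] <- 0
    expect_equal(unname(x), unname(sim$abundance$reads$counts[r, b, v]))
  }
})

test_that("doubling depth shrinks frequency SE by about sqrt(2)", {
  base <- sim_config(seed = 1, n_positions = 12, n_synonymous = 3,
                     n_nonsense = 2, tmd_segments = list(),
                     active_site_positions = integer(0),
                     cells_sorted = 5000, reads_per_bin = 2000,
                     n_replicates = 1)
  truth <- simulate_truth(base)
  map <- simulate_barcode_map(truth, base)
  sorted <- simulate_sort(truth, base, "abundance")
  freq_mat <- function(depth) {
    sapply(1:20, function(s) {
      cfg <- sim_config(seed = 1000 + s, n_positions = 12, n_synonymous = 3,
                        n_nonsense = 2, tmd_segments = list(),
                        active_site_positions = integer(0),
                        cells_sorted = 5000, reads_per_bin = depth,
                        n_replicates = 1)
      counts <- simulate_reads(sorted, map, cfg)$counts
      counts[1, 1, ] / sum(counts[1, 1, ])
    })
  }
  se1 <- apply(freq_mat(2000), 1, sd)
  se2 <- apply(freq_mat(4000), 1, sd)
  keep <- se2 > 0
  ratio <- median(se1[keep] / se2[keep])
  expect_lt(abs(ratio - sqrt(2)) / sqrt(2), 0.25)
})

test_that("simulator output files are written", {
  ss <- small_sim()
  dir <- tempfile()
  write_sim_outputs(ss$sim, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "barcode_map.tsv")))
  expect_gt(length(list.files(dir, pattern = "abundance_counts_rep")), 0)
  back <- read_barcode_map(file.path(dir, "barcode_map.tsv"))
  expect_equal(nrow(back), nrow(ss$sim$barcode_map))
})
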