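# small deterministic tensor builder: reps x 4 x variants
mk_tensor <- function(counts, reps, variants) {
  array(counts, dim = c(reps, 4L, length(variants)),
        dimnames = list(replicate = paste0("R", seq_len(reps)),
                        bin = as.character(1:4), variant = variants))
}

test_that("bin frequencies divide by per-bin totals", {
  tensor <- mk_tensor(0L, 1, c("A1V", "A1G", "A1T"))
  tensor[1, 1, ] <- c(2L, 2L, 0L)
  tensor[1, 2, ] <- c(10L, 30L, 60L)
  tensor[1, 3, ] <- c(0L, 0L, 5L)
  tensor[1, 4, ] <- c(1L, 1L, 2L)
  f <- bin_frequencies(tensor)
  expect_equal(unname(f[1, 1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(f[1, 2, ]), c(0.1, 0.3, 0.6))
  expect_equal(unname(f[1, 3, ]), c(0, 0, 1))
  expect_true(all(abs(apply(f, c(1, 2), sum) - 1) < 1e-12))
  tensor[1, 3, ] <- 0L
  expect_error(bin_frequencies(tensor), "bin 3")
})

test_that("frequency and replicate filters match a brute-force oracle", {
  set.seed(31)
  variants <- paste0("V", 1:12)
  tensor <- mk_tensor(0L, 3, variants)
  tensor[] <- rpois(length(tensor), 40)
  tensor[, , 1] <- 0L       # never seen
  tensor[1, , 2] <- c(1L, 0L, 0L, 0L)  # rare in R1
  params <- scoring_params(f_freq_min = 0.01, f_expt_min = 2)
  f <- bin_frequencies(tensor)
  filt <- replicate_inclusion(f, params)
  for (r in 1:3) for (v in seq_along(variants)) {
    total <- sum(tensor[r, , v] / apply(tensor[r, , ], 1, sum))
    expect_equal(unname(filt$included[r, v]), total >= params$f_freq_min)
  }
  expect_equal(unname(filt$eligible),
               unname(colSums(filt$included) >= 2))
  expect_false(filt$eligible[1])
})

test_that("weighted averages evaluate the bin-weight formula", {
  expect_equal(weighted_average(c(0, 0, 0, 1)), 1.0)
  expect_equal(weighted_average(c(0.25, 0.25, 0.25, 0.25)), 0.625)
  expect_equal(weighted_average(c(0.4, 0.3, 0.2, 0.1)), 0.5)
  expect_true(is.na(weighted_average(c(0, 0, 0, 0))))
  # matrix and array forms agree with the vector form
  f <- matrix(runif(8), nrow = 4)
  expect_equal(weighted_average(f),
               c(weighted_average(f[, 1]), weighted_average(f[, 2])))
})

test_that("weighted averages are bounded and monotone under mass shifts", {
  set.seed(7)
  for (i in 1:500) {
    f <- runif(4)
    w <- weighted_average(f)
    expect_gte(w, 0.25)
    expect_lte(w, 1.0)
    # move mass from a lower to a higher bin
    ij <- sort(sample(4, 2))
    delta <- runif(1, 0, f[ij[1]])
    f2 <- f
    f2[ij[1]] <- f2[ij[1]] - delta
    f2[ij[2]] <- f2[ij[2]] + delta
    expect_gte(weighted_average(f2), w - 1e-12)
  }
})

test_that("replicate normalization anchors the control medians", {
  w <- c(0.2, 0.3, 0.4, 0.7, 0.8, 0.9, 0.55)
  cls <- c(rep("nonsense", 3), rep("synonymous", 3), "missense")
  z <- normalize_replicate(w, cls)
  expect_equal(unname(z[2]), 0)   # w = nonsense median 0.3
  expect_equal(unname(z[5]), 1)   # w = synonymous median 0.8
  expect_equal(unname(z[7]), 0.5) # (0.55 - 0.3) / 0.5
  expect_equal(median(z[cls == "nonsense"]), 0)
  expect_equal(median(z[cls == "synonymous"]), 1)
  # affine invariance
  z2 <- normalize_replicate(3 * w + 2, cls)
  expect_equal(as.numeric(z2), as.numeric(z))
  # anchor errors
  expect_error(normalize_replicate(w, rep("missense", 7)), "anchor")
  inverted <- c(rep("synonymous", 3), rep("nonsense", 3), "missense")
  expect_error(normalize_replicate(w, inverted), "not above")
})

test_that("replicate aggregation matches closed-form arithmetic", {
  # two replicate scores 0.4 and 0.6
  x <- c(0.4, 0.6)
  expect_equal(mean(x), 0.5)
  expect_equal(sd(x), 0.1414214, tolerance = 1e-6)
  variants <- c("N1*", "S2S", "M3V", "A4V")
  tensor <- mk_tensor(0L, 2, variants)
  # nonsense all in bin 1 (w = 0.25); synonymous all in bin 4 (w = 1);
  # missense mass split between bins 1 and 4 with fraction p in bin 4 gives
  # w = 0.25 + 0.75 p, hence normalized score p. A filler variant (A4V)
  # equalizes the per-bin totals at 200 so p reads off the raw counts.
  tensor[, 1, 1] <- c(100L, 100L)
  tensor[, 4, 2] <- c(100L, 100L)
  tensor[1, 1, 3] <- 60L; tensor[1, 4, 3] <- 40L  # p=0.4 -> score 0.4
  tensor[2, 1, 3] <- 40L; tensor[2, 4, 3] <- 60L  # p=0.6 -> score 0.6
  tensor[1, , 4] <- c(40L, 200L, 200L, 60L)
  tensor[2, , 4] <- c(60L, 200L, 200L, 40L)
  info <- parse_variant_token(variants)
  sc <- score_variants(tensor, info, scoring_params(f_freq_min = 1e-6),
                       final_normalize = FALSE)
  m <- sc[sc$variant == "M3V", ]
  expect_equal(m$score, 0.5)
  expect_equal(m$sd, sd(c(0.4, 0.6)))
  expect_equal(m$se, 0.1)
  expect_equal(m$ci_lower, 0.5 - 1.96 * 0.1)
  expect_equal(m$ci_upper, 0.5 + 1.96 * 0.1)
  expect_equal(m$n_reps, 2L)
})

test_that("score_variants equals the brute-force oracle on random tensors", {
  set.seed(55)
  for (rep_i in 1:5) {
    variants <- c(paste0("A", 1:6, "V"), paste0("L", 7:9, "L"),
                  paste0("W", 10:12, "*"))
    cls <- parse_variant_token(variants)
    tensor <- mk_tensor(0L, 3, variants)
    tensor[] <- rpois(length(tensor), 30)
    tensor[tensor == 0] <- 1L
    # give the anchors real separation: nonsense skew to bin 1, synonymous
    # to bin 4 (random counts alone can invert the anchor medians)
    tensor[, 1, cls$mut_class == "nonsense"] <-
      tensor[, 1, cls$mut_class == "nonsense"] + 150L
    tensor[, 4, cls$mut_class == "synonymous"] <-
      tensor[, 4, cls$mut_class == "synonymous"] + 150L
    params <- scoring_params(f_freq_min = 1e-4)
    got <- score_variants(tensor, cls, params, final_normalize = FALSE)
    want <- oracle_scores(tensor, cls$mut_class, params)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
    expect_equal(got$n_reps, want$n_reps)
  }
})

test_that("identical replicate scores give zero-width intervals", {
  variants <- c("N1*", "S2S", "M3V", "A4V")
  tensor <- mk_tensor(0L, 3, variants)
  tensor[, 1, 1] <- 50L
  tensor[, 4, 2] <- 50L
  tensor[, 1, 3] <- 30L
  tensor[, 4, 3] <- 70L
  tensor[, 2, 4] <- 10L
  tensor[, 3, 4] <- 10L
  sc <- score_variants(tensor, parse_variant_token(variants),
                       scoring_params(f_freq_min = 1e-6),
                       final_normalize = FALSE)
  m <- sc[sc$variant == "M3V", ]
  expect_equal(m$sd, 0)
  expect_equal(m$ci_lower, m$ci_upper)
})

test_that("final renormalization pins the aggregate anchor medians", {
  ss <- small_sim()
  sc <- sim_scores(ss$sim, "abundance")
  ok <- !is.na(sc$score)
  expect_equal(median(sc$score[ok & sc$mut_class == "synonymous"]), 1)
  expect_equal(median(sc$score[ok & sc$mut_class == "nonsense"]), 0)
  # variants failing filters are retained with a reason
  expect_true(all(is.na(sc$score) == sc$excluded))
  expect_true(all(!is.na(sc$exclusion_reason[sc$excluded])))
})

test_that("score tables round trip through TSV", {
  ss <- small_sim()
  sc <- sim_scores(ss$sim, "abundance")
  path <- tempfile(fileext = ".tsv")
  write_score_table(sc, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(sc))
  expect_equal(back$score, sc$score, tolerance = 1e-6)
  expect_true(all(c("SD", "SE", "CI_lower", "CI_upper") %in% names(back)))
})
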