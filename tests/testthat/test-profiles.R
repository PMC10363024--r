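# single-cell profile helper: one genome -> one-cell profile object
one_cell_profile <- function(genome, tpl, id = "cell_0001") {
  compute_profiles(stats::setNames(list(genome), id), tpl)
}

test_that("binned ground truth matches region bookkeeping", {
  tpl <- toy_template(n_regions = 40, regions_per_bin = 10)
  g <- init_diploid_genome(tpl)
  cnp <- compute_ground_truth_cnp(g, tpl)
  expect_equal(nrow(cnp), 4L)
  expect_true(all(cnp$cn_total == 2L & cnp$cn_a == 1L & cnp$cn_b == 1L))

  # a magnitude-1 gain spanning exactly one full bin lifts only that bin
  g2 <- apply_focal_event(g, focal_ev("gain", start = 10, length = 10,
                                      magnitude = 1))
  cnp2 <- compute_ground_truth_cnp(g2, tpl)
  expect_equal(cnp2$cn_total, c(2L, 3L, 2L, 2L))
  expect_equal(cnp2$cn_a, c(1L, 2L, 1L, 1L))
})

test_that("bin values are length-weighted means rounded half away from zero", {
  # 25 regions of 10 bp, 10 regions per bin: last bin has 5 regions
  tpl <- toy_template(n_regions = 25, regions_per_bin = 10)
  g <- init_diploid_genome(tpl)
  # gain of magnitude 1 over 5 of the 10 regions of bin 1: mean 2.5 -> 3
  g2 <- apply_focal_event(g, focal_ev("gain", 10, 5, magnitude = 1))
  cnp <- compute_ground_truth_cnp(g2, tpl)
  expect_equal(cnp$cn_total[2], 3L)
  expect_equal(round_half_away(c(2.5, -2.5, 2.4)), c(3, -3, 2))
})

test_that("ground truth equals the brute-force counter oracle on random runs", {
  set.seed(20)
  for (i in 1:50) {
    tpl <- toy_template(n_chrom = 2, n_regions = 25)
    tr <- simulate_tumor_lineage(population_params(3))
    p <- event_model_params(focal_rate = 4, mean_length = 4, min_length = 1,
                            founder_event_mean = 2, p_cnloh = 0.2)
    evo <- suppressWarnings(evolve_tree(tr, tpl, p))
    states <- naive_replay(tr, tpl, evo$event_log)
    for (id in names(evo$genomes)) {
      cnp <- compute_ground_truth_cnp(evo$genomes[[id]], tpl)
      oracle <- unlist(lapply(states[[id]]$cnt, as.integer))
      expect_identical(cnp$cn_total, as.integer(oracle))
    }
  }
})

test_that("boundary noise is the identity when disabled or boundary-free", {
  tpl <- toy_template(n_regions = 20)
  g <- apply_focal_event(init_diploid_genome(tpl),
                         focal_ev("gain", 5, 5, magnitude = 1))
  prof <- one_cell_profile(g, tpl)
  expect_identical(add_boundary_noise(prof, error_model_params(0, 0.5, 0)),
                   prof)
  flat <- one_cell_profile(init_diploid_genome(tpl), tpl)
  set.seed(21)
  expect_identical(add_boundary_noise(flat, error_model_params(1, 0.5, 0)),
                   flat)
})

test_that("mean displaced bins per boundary equals p_b / p_s", {
  # single boundary in the middle of a long chromosome
  tpl <- toy_template(n_regions = 60)
  g <- apply_chromosomal_event(init_diploid_genome(tpl), tpl, "chr1", "q",
                               "gain")
  base <- one_cell_profile(g, tpl)
  truth <- base$total[1, ]
  reps <- 20000
  prof <- base
  prof$total <- matrix(rep(truth, reps), nrow = reps, byrow = TRUE)
  prof$cn_a <- matrix(rep(base$cn_a[1, ], reps), nrow = reps, byrow = TRUE)
  prof$cn_b <- matrix(rep(base$cn_b[1, ], reps), nrow = reps, byrow = TRUE)
  rownames(prof$total) <- rownames(prof$cn_a) <- rownames(prof$cn_b) <-
    sprintf("c%d", seq_len(reps))

  for (case in list(c(1, 0.5), c(0.6, 0.4))) {
    set.seed(22)
    noisy <- add_boundary_noise(prof, error_model_params(case[1], case[2], 0))
    displaced <- rowSums(noisy$total != matrix(rep(truth, reps),
                                               nrow = reps, byrow = TRUE))
    se <- sd(displaced) / sqrt(reps)
    expect_lt(abs(mean(displaced) - case[1] / case[2]), 3 * se)
  }
})

test_that("boundary noise preserves the set of copy-number states per chromosome", {
  set.seed(23)
  tpl <- toy_template(n_regions = 12)
  for (i in 1:100) {
    v <- sample(0:4, 12, replace = TRUE)
    g <- init_diploid_genome(tpl)  # container only; overwrite profile
    prof <- one_cell_profile(g, tpl)
    prof$total[1, ] <- v
    prof$cn_a[1, ] <- pmin(1, v)
    prof$cn_b[1, ] <- v - pmin(1, v)
    noisy <- add_boundary_noise(prof, error_model_params(1, 0.9, 0))
    expect_setequal(unique(noisy$total[1, ]), unique(v))
    # jitter, by contrast, may create new states (checked elsewhere)
  }
})

test_that("jitter is proportional to copy number state and spares zeros", {
  tpl <- toy_template(n_regions = 20)
  prof <- one_cell_profile(init_diploid_genome(tpl), tpl)
  expect_identical(add_jitter(prof, error_model_params(0.5, 0.5, 0)), prof)

  nbin <- 20000
  mk <- function(c_state) {
    p <- prof
    p$total <- matrix(rep(c_state, nbin), nrow = 1)
    p$cn_a <- matrix(rep(c_state %/% 2, nbin), nrow = 1)
    p$cn_b <- p$total - p$cn_a
    rownames(p$total) <- rownames(p$cn_a) <- rownames(p$cn_b) <- "c1"
    p$bins <- data.frame(chrom = "chr1", start = seq_len(nbin),
                         end = seq_len(nbin) + 1)
    p
  }
  set.seed(24)
  ep <- error_model_params(0, 0.5, 0.25)
  sd4 <- sd(add_jitter(mk(4), ep)$total[1, ] - 4)
  sd2 <- sd(add_jitter(mk(2), ep)$total[1, ] - 2)
  expect_gt(sd4 / sd2, 1.7)
  expect_lt(sd4 / sd2, 2.3)

  z <- add_jitter(mk(0), error_model_params(0, 0.5, 5))
  expect_true(all(z$total == 0))
})

test_that("jitter error grows with the jitter scale and keeps allele splits valid", {
  tpl <- toy_template(n_regions = 30)
  g <- apply_wgd(init_diploid_genome(tpl))
  prof <- one_cell_profile(g, tpl)
  big <- prof
  big$total <- matrix(rep(prof$total[1, ], 500), nrow = 500, byrow = TRUE)
  big$cn_a <- matrix(rep(prof$cn_a[1, ], 500), nrow = 500, byrow = TRUE)
  big$cn_b <- matrix(rep(prof$cn_b[1, ], 500), nrow = 500, byrow = TRUE)
  rownames(big$total) <- rownames(big$cn_a) <- rownames(big$cn_b) <-
    sprintf("c%d", 1:500)
  set.seed(25)
  j1 <- add_jitter(big, error_model_params(0, 0.5, 0.2))
  j2 <- add_jitter(big, error_model_params(0, 0.5, 0.4))
  expect_gte(mean(abs(j2$total - big$total)), mean(abs(j1$total - big$total)))
  expect_true(all(j2$cn_a + j2$cn_b == j2$total))
  expect_true(all(j2$cn_a >= 0 & j2$cn_b >= 0))
})

test_that("zero-noise profiles are bit-identical to the truth on disk", {
  tpl <- toy_template(n_chrom = 2, n_regions = 20)
  set.seed(26)
  tr <- simulate_tumor_lineage(population_params(4))
  evo <- suppressWarnings(evolve_tree(tr, tpl, event_model_params(
    focal_rate = 3, mean_length = 3, min_length = 1)))
  meta <- leaf_metadata(tr)
  genomes <- stats::setNames(evo$genomes[as.character(meta$id)], meta$leaf)
  truth <- compute_profiles(genomes, tpl)
  e0 <- error_model_params(0, 0.5, 0)
  noisy <- add_jitter(add_boundary_noise(truth, e0), e0)
  d <- withr::local_tempdir()
  ft <- write_profiles(truth, d, "truth")
  fn <- write_profiles(noisy, d, "noisy")
  for (i in seq_along(ft)) {
    expect_identical(readBin(ft[i], "raw", file.size(ft[i])),
                     readBin(fn[i], "raw", file.size(fn[i])))
  }
})

test_that("profile files round-trip losslessly", {
  tpl <- toy_template(n_chrom = 2, n_regions = 15, regions_per_bin = 5)
  set.seed(27)
  tr <- simulate_tumor_lineage(population_params(3))
  evo <- suppressWarnings(evolve_tree(tr, tpl, event_model_params(
    focal_rate = 2, mean_length = 3, min_length = 1)))
  meta <- leaf_metadata(tr)
  prof <- compute_profiles(stats::setNames(evo$genomes[as.character(meta$id)],
                                           meta$leaf), tpl)
  d <- withr::local_tempdir()
  paths <- write_profiles(prof, d, "truth")
  back <- read_profiles(paths[1])
  expect_identical(back$total, prof$total)
  expect_identical(back$cn_a, prof$cn_a)
  expect_identical(back$cn_b, prof$cn_b)
  expect_equal(back$bins$start, prof$bins$start)

  # segment export merges equal adjacent bins
  seg_path <- file.path(d, "segments.tsv")
  write_segments(prof, seg_path)
  segs <- read.table(seg_path, header = TRUE, sep = "\t")
  one <- segs[segs$cell_id == meta$leaf[1] & segs$chrom == "chr1", ]
  expect_true(all(diff(one$start) > 0))
  expect_equal(one$start[1], 0)
})
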