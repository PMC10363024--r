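toy_params <- function(...) {
  args <- list(focal_rate = 2, mean_length = 3, min_length = 1,
               p_gain = 0.5, p_cnloh = 0.2, p_mag = 0.5,
               founder_event_mean = 1, subclone_event_mean = 1,
               pseudo_normal_event_mean = 2)
  do.call(event_model_params, utils::modifyList(args, list(...)))
}

test_that("degenerate focal distributions give unit gains", {
  tpl <- toy_template(n_regions = 50)
  g <- init_diploid_genome(tpl)
  p <- event_model_params(p_gain = 1, p_cnloh = 0, p_mag = 1,
                          mean_length = 3, min_length = 1)
  set.seed(1)
  for (i in 1:20) {
    ev <- draw_focal_event(g, p)
    expect_equal(ev$type, "gain")
    expect_equal(ev$magnitude, 1L)
  }
})

test_that("focal lengths follow the truncated geometric with the stated mean", {
  tpl <- toy_template(n_regions = 10000, region_size = 10)
  g <- init_diploid_genome(tpl)
  p <- event_model_params(mean_length = 5, min_length = 1, p_cnloh = 0)
  set.seed(2)
  lens <- vapply(seq_len(30000), function(i) draw_focal_event(g, p)$length,
                 integer(1))
  expect_lt(abs(mean(lens) - 5) / 5, 0.02)
})

test_that("CNLOH falls back to gain/loss when no homolog carries the locus", {
  tpl <- toy_template(n_regions = 20)
  g <- init_diploid_genome(tpl)
  g[["chr1"]][["B"]] <- NULL  # single-allele chromosome
  p <- event_model_params(p_cnloh = 1, mean_length = 3, min_length = 1)
  set.seed(3)
  types <- vapply(1:50, function(i) draw_focal_event(g, p)$type, character(1))
  expect_true(all(types %in% c("gain", "loss")))
})

test_that("focal losses and gains splice the allele sequence as specified", {
  tpl <- toy_template(n_regions = 10)
  g <- init_diploid_genome(tpl)
  lost <- apply_focal_event(g, focal_ev("loss", start = 3, length = 2))
  expect_identical(lost$chr1$A, c(0:2, 5:9))
  gained <- apply_focal_event(g, focal_ev("gain", start = 3, length = 2,
                                          magnitude = 2))
  expect_identical(gained$chr1$A, c(0:4, 3L, 4L, 3L, 4L, 5:9))
  expect_length(gained$chr1$A, 14L)
  expect_error(apply_focal_event(g, focal_ev("loss", start = 9, length = 5)),
               "bounds")
})

test_that("random focal events match a naive splice oracle", {
  tpl <- toy_template(n_regions = 30)
  set.seed(4)
  for (i in 1:100) {
    g <- init_diploid_genome(tpl)
    naive <- g$chr1$A
    type <- sample(c("gain", "loss"), 1)
    s <- sample(0:(length(naive) - 1), 1)
    L <- sample.int(length(naive) - s, 1)
    m <- sample(1:3, 1)
    g2 <- apply_focal_event(g, focal_ev(type, s, L, magnitude = m))
    seg <- naive[(s + 1):(s + L)]
    naive <- if (type == "loss") {
      c(head(naive, s), tail(naive, length(naive) - s - L))
    } else {
      c(head(naive, s + L), rep(seg, m), tail(naive, length(naive) - s - L))
    }
    expect_identical(g2$chr1$A, as.integer(naive))
  }
})

test_that("CNLOH conserves the per-region total copy number", {
  tpl <- toy_template(n_regions = 20)
  set.seed(5)
  for (i in 1:50) {
    g <- init_diploid_genome(tpl)
    s <- sample(0:15, 1)
    L <- sample.int(20 - s, 1)
    g2 <- apply_focal_event(g, focal_ev("cnloh", s, L, allele = "A",
                                        allele2 = "B"))
    expect_identical(genome_region_cn(g2, tpl), genome_region_cn(g, tpl))
    # copies moved from the A lineage to the B lineage
    expect_equal(length(g2$chr1$A), 20L - L)
    expect_equal(length(g2$chr1$B), 20L + L)
  }
})

test_that("arm and whole-chromosome events follow the allele-lineage contract", {
  tpl <- toy_template(n_regions = 10, arm_region = 4)
  g <- init_diploid_genome(tpl)

  set.seed(6)
  ploss <- apply_chromosomal_event(g, tpl, "chr1", "p", "loss")
  lens <- sort(vapply(ploss$chr1, length, integer(1)))
  expect_equal(unname(lens), c(6L, 10L))
  hit <- ploss$chr1[[which.min(vapply(ploss$chr1, length, integer(1)))]]
  expect_identical(hit, 4:9)

  wgain <- apply_chromosomal_event(g, tpl, "chr1", "whole", "gain")
  expect_length(wgain$chr1, 3L)
  expect_true(any(grepl("\\.dup1$", names(wgain$chr1))))
  expect_true(all(genome_region_cn(wgain, tpl)[[1]] == 3L))

  # two whole-chromosome losses empty the chromosome; a third is skipped
  g2 <- apply_chromosomal_event(g, tpl, "chr1", "whole", "loss")
  g2 <- apply_chromosomal_event(g2, tpl, "chr1", "whole", "loss")
  expect_length(g2$chr1, 0L)
  expect_warning(g3 <- apply_chromosomal_event(g2, tpl, "chr1", "whole", "loss"),
                 "skipped")
  expect_identical(g3, g2)
})

test_that("WGD doubles every region and tracks new allele lineages", {
  tpl <- toy_template(n_chrom = 2, n_regions = 10)
  g <- init_diploid_genome(tpl)
  g4 <- apply_wgd(g)
  for (cn in names(g4)) {
    expect_length(g4[[cn]], 4L)
    expect_true(all(genome_region_cn(g4, tpl)[[match(cn, names(g4))]] == 4L))
  }
  expect_setequal(names(g4$chr1), c("A", "B", "A.wgd1", "B.wgd1"))
  g8 <- apply_wgd(g4)
  expect_true(all(genome_region_cn(g8, tpl)[[1]] == 8L))
  expect_length(g8$chr1, 8L)

  # a prior deletion is present in original and duplicated lineages alike
  gd <- apply_focal_event(g, focal_ev("loss", 2, 3))
  gd4 <- apply_wgd(gd)
  expect_identical(gd4$chr1$A, gd4$chr1$A.wgd1)
})

test_that("an event-free model leaves every cell diploid", {
  tpl <- toy_template(n_regions = 20)
  set.seed(7)
  tr <- attach_outgroup_cells(simulate_tumor_lineage(population_params(6)),
                              1, 1, 0.5)
  p <- event_model_params(focal_rate = 0, founder_event_mean = 0,
                          pseudo_normal_event_mean = 0)
  evo <- evolve_tree(tr, tpl, p)
  expect_equal(nrow(evo$event_log), 0L)
  ref <- init_diploid_genome(tpl)
  for (g in evo$genomes) expect_identical(g, ref)
})

test_that("WGD at tumor onset makes tumor cells CN 4 and leaves normals CN 2", {
  tpl <- toy_template(n_regions = 20)
  set.seed(8)
  tr <- attach_outgroup_cells(simulate_tumor_lineage(population_params(5)),
                              2, 0, 0.5)
  p <- event_model_params(focal_rate = 0, founder_event_mean = 0, wgd = TRUE)
  evo <- evolve_tree(tr, tpl, p)
  meta <- leaf_metadata(tr)
  for (i in seq_len(nrow(meta))) {
    cnp <- compute_ground_truth_cnp(evo$genomes[[as.character(meta$id[i])]], tpl)
    expected <- if (meta$class[i] == "tumor_leaf") 4L else 2L
    expect_true(all(cnp$cn_total == expected))
  }
})

test_that("normal leaves are bit-identical to the initialized diploid", {
  tpl <- toy_template(n_chrom = 2, n_regions = 30)
  set.seed(9)
  tr <- attach_outgroup_cells(simulate_tumor_lineage(population_params(8)),
                              2, 2, 1)
  evo <- suppressWarnings(evolve_tree(tr, tpl, toy_params(wgd = TRUE)))
  meta <- leaf_metadata(tr)
  ref <- init_diploid_genome(tpl)
  for (id in meta$id[meta$class == "normal_leaf"]) {
    expect_identical(evo$genomes[[as.character(id)]], ref)
  }
  # pseudo-normals never receive chromosomal events or WGD
  pn_ids <- meta$id[meta$class == "pseudo_normal_leaf"]
  el <- evo$event_log
  expect_true(all(el$scale[el$edge_child_id %in% pn_ids] == "focal"))
})

test_that("replaying the event log reproduces every leaf genome exactly", {
  set.seed(10)
  for (i in 1:20) {
    tpl <- toy_template(n_chrom = sample(1:2, 1), n_regions = 30)
    tr <- attach_outgroup_cells(
      simulate_tumor_lineage(population_params(sample(3:6, 1))), 1, 1, 0.5)
    evo <- suppressWarnings(evolve_tree(tr, tpl,
                                        toy_params(wgd = i %% 2 == 0)))
    replayed <- replay_event_log(tr, tpl, evo$event_log)
    expect_identical(replayed, evo$genomes[names(replayed)])
  }
})

test_that("per-region copy number agrees with the independent counter oracle", {
  set.seed(11)
  for (i in 1:50) {
    tpl <- toy_template(n_chrom = 2, n_regions = 25)
    tr <- attach_outgroup_cells(
      simulate_tumor_lineage(population_params(4)), 0, 1, 0.5)
    evo <- suppressWarnings(evolve_tree(tr, tpl,
                                        toy_params(wgd = i %% 3 == 0)))
    states <- naive_replay(tr, tpl, evo$event_log)
    for (id in names(states)) {
      pkg_cn <- genome_region_cn(evo$genomes[[id]], tpl)
      expect_identical(lapply(pkg_cn, as.integer),
                       lapply(states[[id]]$cnt, as.integer))
      expect_identical(pkg_cn, naive_seq_cn(states[[id]], tpl))
    }
  }
})

test_that("subclone edges carry unique chromosomal signatures", {
  tpl <- toy_template(n_chrom = 2, n_regions = 40)
  set.seed(12)
  tr <- select_subclones(attach_outgroup_cells(
    simulate_tumor_lineage(population_params(12)), 0, 0, 0.5), 3, 2)
  evo <- suppressWarnings(evolve_tree(tr, tpl, toy_params()))
  roots <- tr$nodes$id[!is.na(tr$nodes$subclone) &
                         tr$nodes$class == "ancestral"]
  el <- as.data.frame(evo$event_log)
  sigs <- vapply(roots, function(r) {
    rows <- el[el$edge_child_id == r & el$scale %in% c("arm", "chromosome"), ]
    paste(sort(paste(rows$chrom, rows$arm, rows$type)), collapse = ";")
  }, character(1))
  expect_equal(anyDuplicated(sigs), 0L)
  # each subclone root receives at least one chromosomal event
  expect_true(all(vapply(roots, function(r) {
    sum(el$edge_child_id == r & el$scale %in% c("arm", "chromosome")) >= 1
  }, logical(1))))
})

test_that("allele labels stay unique within each chromosome", {
  tpl <- toy_template(n_chrom = 2, n_regions = 30)
  set.seed(13)
  tr <- simulate_tumor_lineage(population_params(6))
  evo <- suppressWarnings(evolve_tree(tr, tpl, toy_params(
    wgd = TRUE, founder_event_mean = 4)))
  for (g in evo$genomes) {
    for (cn in names(g)) {
      expect_equal(anyDuplicated(names(g[[cn]])), 0L)
    }
  }
})

test_that("pseudo-normal genomes carry the right number of focal events", {
  tpl <- toy_template(n_regions = 50)
  p0 <- toy_params(pseudo_normal_event_mean = 0)
  expect_identical(make_pseudo_normal(tpl, p0)$genome,
                   init_diploid_genome(tpl))
  set.seed(14)
  p3 <- toy_params(pseudo_normal_event_mean = 3)
  counts <- vapply(seq_len(2000), function(i) {
    res <- suppressWarnings(make_pseudo_normal(tpl, p3))
    expect_true(all(vapply(res$events, function(e) e$scale, character(1)) ==
                      "focal"))
    length(res$events)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("genome evolution is deterministic under seed", {
  tpl <- toy_template(n_chrom = 2, n_regions = 30)
  run <- function() {
    set.seed(99)
    tr <- simulate_tumor_lineage(population_params(8))
    suppressWarnings(evolve_tree(tr, tpl, toy_params(wgd = TRUE)))
  }
  a <- run(); b <- run()
  expect_identical(a$event_log, b$event_log)
  expect_identical(a$genomes, b$genomes)
})
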