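# Generators are pure functions of the configuration: fixed seed, fixed
# output. Small genomes keep these checks fast.
small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, chrom_length = 4e5, n_genes = 40,
                   n_tes = 50, n_planted_enriched = 6, n_regions = 200,
                   n_planted_diff = 10,
                   planted_categories = c(I = 2, II = 3, III = 1))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("annotation generation is deterministic and non-overlapping", {
  cfg <- small_cfg(seed = 9)
  a1 <- make_annotation(cfg)
  a2 <- make_annotation(cfg)
  expect_identical(a1, a2)
  # brute-force pairwise non-overlap of gene bodies
  g <- a1$genes
  for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
    expect_equal(oracle_overlap_simple(g[i, ], g[j, ]), 0)
  }
  expect_true(all(table(a1$roles$role)[c("I", "II", "III")] ==
                    c(2, 3, 1)))
  # empty gene table
  cfg0 <- sim_config(n_genes = 0, n_planted_enriched = 0,
                     planted_categories = c(I = 0, II = 0, III = 0))
  expect_equal(nrow(make_annotation(cfg0)$genes), 0)
  # infeasible packing: more genes than 20 kb slots
  expect_error(make_annotation(sim_config(chrom_length = 1e5,
                                          n_genes = 200)),
               "infeasible")
})

test_that("bedGraph tracks have the configured background rate", {
  cfg <- small_cfg(seed = 4)
  sim <- simulate_bedgraph(cfg, make_annotation(cfg), "control", 1)
  # mean value over all bins (zeros included) ~ Poisson(background_rate)
  nbins <- cfg$n_chroms * cfg$chrom_length / cfg$bin_width
  total <- sum(sim$track$value * (sim$track$end - sim$track$start)) /
    cfg$bin_width
  # planted blocks inflate the mean slightly; allow for them explicitly
  planted_bins <- sum(sim$blocks$end - sim$blocks$start) / cfg$bin_width
  expected <- cfg$background_rate *
    (nbins + planted_bins * (cfg$enrichment_fold - 1))
  se <- sqrt(expected)
  expect_lt(abs(total - expected), 4 * se)
})

test_that("noiseless tracks contain exactly the planted blocks", {
  cfg <- small_cfg(seed = 6, background_rate = 0, enrichment_fold = 20)
  ann <- make_annotation(cfg)
  sim <- simulate_bedgraph(cfg, ann, "treated", 2)
  blocks <- segment_signal_blocks(sim$track)
  expect_equal(blocks[, c("chrom", "start", "end")],
               sim$blocks[order(sim$blocks$chrom, sim$blocks$start),
                          c("chrom", "start", "end")],
               ignore_attr = TRUE)
  # replicates share block locations
  sim2 <- simulate_bedgraph(cfg, ann, "treated", 1)
  expect_identical(sim$blocks, sim2$blocks)
  # determinism
  expect_identical(sim$track,
                   simulate_bedgraph(cfg, ann, "treated", 2)$track)
})

test_that("count simulation plants fold changes and stays near-Poisson", {
  cfg <- small_cfg(seed = 12)
  ann <- make_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  expect_identical(sim$table$counts,
                   simulate_counts(cfg, ann)$table$counts)
  # planted up-regions have elevated treated counts
  up <- sim$planted$region_index[sim$planted$direction == "up"]
  null_idx <- setdiff(seq_len(nrow(sim$table$counts)),
                      sim$planted$region_index)
  expect_gt(mean(sim$table$counts[up, 3:4]),
            4 * mean(sim$table$counts[null_idx, 3:4]))
  # null counts: variance/mean close to 1 at near-zero dispersion
  v <- as.numeric(sim$table$counts[null_idx, ])
  expect_equal(var(v) / mean(v), 1 + cfg$nb_dispersion * cfg$depth_mean,
               tolerance = 0.1)
  # library sizes are the column sums
  expect_equal(sim$table$samples$library_size,
               unname(colSums(sim$table$counts)))
})

test_that("a null count simulation stays at the type-I error rate", {
  cfg <- small_cfg(seed = 33, planted_fc = 1, n_regions = 500)
  sim <- simulate_counts(cfg, make_annotation(cfg))
  res <- exact_region_test(sim$table)
  d <- classify_differential(sim$table$regions, res)
  expect_lt(mean(d$direction != "unchanged"), 0.005)
})

test_that("the bundle writer is deterministic and self-consistent", {
  cfg <- small_cfg(seed = 14)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  md5_1 <- unname(tools::md5sum(file.path(d1, f1)))
  md5_2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(md5_1, md5_2)
  # round trips: files re-read match the in-memory objects
  genes <- read_gene_table(b1$paths$genes)
  ann <- make_annotation(cfg)
  expect_equal(genes, ann$genes, ignore_attr = TRUE)
  tab <- read_region_counts(b1$paths$counts, b1$paths$samples)
  expect_equal(unname(tab$counts),
               unname(simulate_counts(cfg, ann)$table$counts))
  tr <- read_bedgraph(b1$paths$bedgraph$control[[1]])
  expect_equal(tr, simulate_bedgraph(cfg, ann, "control", 1)$track,
               ignore_attr = TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})
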