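test_that("fragment filter keeps fragments strictly below the cutoff", {
  fr <- genomic_intervals("chr1", c(0, 0, 0, 0), c(150, 999, 1000, 1500))
  kept <- filter_fragments(fr, 1000)
  expect_equal(kept$end, c(150, 999))
  expect_equal(nrow(filter_fragments(fr[0, ], 1000)), 0)
  short <- genomic_intervals("chr1", c(5, 100), c(105, 300))
  expect_equal(filter_fragments(short, 1000), short)
})

test_that("signal blocks merge abutting records and split at gaps/zeros", {
  tr <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                   end = c(100, 200, 400), value = c(2, 3, 1))
  bl <- segment_signal_blocks(tr)
  expect_equal(bl$start, c(0, 300))
  expect_equal(bl$end, c(200, 400))
  expect_equal(bl$auc, c(2 * 100 + 3 * 100, 100))
  expect_equal(bl$max_value, c(3, 1))
  # zero-valued record separates abutting positives
  tr2 <- data.frame(chrom = "chr1", start = c(0, 100, 110),
                    end = c(100, 110, 200), value = c(2, 0, 3))
  expect_equal(nrow(segment_signal_blocks(tr2)), 2)
  zero <- data.frame(chrom = "chr1", start = 0, end = 100, value = 0)
  expect_equal(nrow(segment_signal_blocks(zero)), 0)
})

test_that("malformed bedGraph input is rejected", {
  bad_sort <- data.frame(chrom = "chr1", start = c(100, 0),
                         end = c(200, 50), value = 1)
  expect_error(segment_signal_blocks(bad_sort), "sorted")
  bad_ov <- data.frame(chrom = "chr1", start = c(0, 50),
                       end = c(100, 150), value = 1)
  expect_error(segment_signal_blocks(bad_ov), "overlap")
})

test_that("signal blocks agree with a per-base oracle and conserve auc", {
  set.seed(7)
  for (rep_i in 1:25) {
    # random sorted non-overlapping records with zero stretches
    n <- sample(10:60, 1)
    bounds <- sort(sample(0:1000, n + 1)) * 10
    tr <- data.frame(chrom = sample(c("chrA", "chrB"), 1),
                     start = bounds[-(n + 1)], end = bounds[-1],
                     value = sample(0:4, n, replace = TRUE))
    tr <- tr[tr$end > tr$start, ]
    got <- segment_signal_blocks(tr)
    want <- oracle_blocks(tr)
    expect_equal(got, want)
    expect_equal(sum(got$auc),
                 sum(tr$value * (tr$end - tr$start)))
  }
})

test_that("call_peaks keeps the ceiling(threshold*N) top-auc blocks", {
  bl <- data.frame(chrom = "chr1", start = (1:100) * 1000,
                   end = (1:100) * 1000 + 500, auc = 1:100,
                   max_value = 1)
  pk <- call_peaks(bl, 0.05)
  expect_equal(sort(pk$auc), 96:100)
  one <- call_peaks(bl[1, ], 0.05)
  expect_equal(nrow(one), 1)
  expect_equal(nrow(call_peaks(bl[0, ], 0.05)), 0)
  expect_error(call_peaks(bl, 0), "threshold")
})

test_that("call_peaks matches a sort-and-slice oracle with ties", {
  set.seed(13)
  for (rep_i in 1:20) {
    n <- sample(20:200, 1)
    bl <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = sample.int(1e6, n), auc = 0, max_value = 1)
    bl$end <- bl$start + 100
    bl$auc <- sample(1:15, n, replace = TRUE)  # many ties
    bl <- bl[order(bl$chrom, bl$start), ]
    th <- runif(1, 0.02, 0.5)
    got <- call_peaks(bl, th)
    n_keep <- ceiling(th * n)
    expect_equal(nrow(got), n_keep)
    ord <- bl[order(-bl$auc, bl$chrom, bl$start), ][seq_len(n_keep), ]
    expect_equal(got$auc[order(got$chrom, got$start)],
                 ord$auc[order(ord$chrom, ord$start)])
    expect_setequal(paste(got$chrom, got$start),
                    paste(ord$chrom, ord$start))
  }
})

test_that("half-mean filter drops peaks below half the file mean", {
  p1 <- ps("chr1", c(0, 100, 200), c(50, 150, 250), auc = c(10, 10, 1))
  expect_equal(half_mean_filter(p1)$auc, c(10, 10))
  p2 <- ps("chr1", c(0, 100), c(50, 150), auc = c(4, 4))
  expect_equal(nrow(half_mean_filter(p2)), 2)
  p3 <- ps("chr1", (0:4) * 100, (0:4) * 100 + 50,
           auc = c(100, 1, 1, 1, 1))
  expect_equal(half_mean_filter(p3)$auc, 100)
  # never removes the maximum-auc peak
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:30, 1)
    p <- ps("chr1", (1:n) * 100, (1:n) * 100 + 50,
            auc = rexp(n, 1 / 50))
    expect_true(max(p$auc) %in% half_mean_filter(p)$auc)
  }
})

test_that("replicate consensus takes union spans above the overlap floor", {
  r1 <- ps("chr1", 100, 500, auc = 10)
  r2 <- ps("chr1", 150, 480, auc = 20)
  cons <- replicate_consensus(r1, r2, 300)
  expect_equal(c(cons$start, cons$end, cons$auc), c(100, 500, 30))
  r3 <- ps("chr1", 300, 900, auc = 5)
  expect_equal(nrow(replicate_consensus(r1, r3, 300)), 0)
})

test_that("replicate consensus agrees with an all-pairs oracle", {
  set.seed(99)
  for (rep_i in 1:15) {
    mk <- function() {
      n <- sample(5:40, 1)
      s <- sort(sample(seq(0, 5e4, by = 50), n))
      w <- sample(seq(100, 1500, by = 50), n, replace = TRUE)
      # enforce non-overlap within a set
      e <- pmin(s + w, c(s[-1], Inf))
      keep <- e > s
      ps(sample(c("chr1", "chr2"), 1), s[keep], e[keep],
         auc = round(runif(sum(keep), 1, 100)))
    }
    r1 <- mk(); r2 <- mk()
    attr(r2, "chrom") <- attr(r1, "chrom")
    r2$chrom <- r1$chrom[1]
    got <- replicate_consensus(r1, r2, 300)
    want <- oracle_consensus(r1, r2, 300)
    expect_equal(as.data.frame(got)[, c("chrom", "start", "end", "auc")],
                 want)
    # consensus footprint within the union of replicate footprints
    if (nrow(got) > 0) {
      for (k in seq_len(nrow(got))) {
        cov <- sum(pmax(0, pmin(got$end[k], c(r1$end, r2$end)) -
                          pmax(got$start[k], c(r1$start, r2$start))))
        expect_true(cov >= got$end[k] - got$start[k])
      }
    }
  }
})

test_that("condition-unique peaks require strictly zero overlap", {
  a <- ps("chr1", 0, 1000, auc = 5, condition = "treated")
  expect_equal(nrow(condition_unique(a, ps("chr1", 2000, 3000))), 1)
  expect_equal(nrow(condition_unique(a, ps("chr1", 999, 3000))), 0)
  empty <- ps("chr1", 1, 2)[0, ]
  b_empty <- peak_set(as.data.frame(empty), "control", "consensus")
  expect_equal(nrow(condition_unique(a, b_empty)), 1)
})
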