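# Small fixture: three plus-strand genes 100 kb apart, TSS windows
# [tss-5000, tss+3000).
int_genes <- data.frame(
  chrom = "chr1", start = c(1e5, 2e5, 3e5), end = c(1e5, 2e5, 3e5) + 8000,
  strand = "+", gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)

atac_row <- function(gene_id, tss, direction, lfc) {
  data.frame(chrom = "chr1", start = tss - 200, end = tss + 200,
             log2fc = lfc, p_value = 1e-5, direction = direction,
             gene_id = gene_id, stringsAsFactors = FALSE)
}

test_that("joint calls follow the four-quadrant category rule", {
  atac <- rbind(atac_row("g1", 1e5, "gained-open", 3),
                atac_row("g2", 2e5, "gained-closed", -3),
                atac_row("g3", 3e5, "gained-closed", -2.5))
  ut <- ps("chr1", c(1e5 - 100, 3e5 - 100), c(1e5 + 400, 3e5 + 400),
           condition = "treated")
  uc <- ps("chr1", 2e5 - 100, 2e5 + 400, condition = "control")
  calls <- integrate_at_tss(atac, ut, uc, int_genes)
  expect_equal(calls$category[calls$gene_id == "g1"], "I")
  expect_equal(calls$category[calls$gene_id == "g2"], "II")
  expect_equal(calls$category[calls$gene_id == "g3"], "III")
  # category IV: gain accessibility, lose H3K56ac
  calls_iv <- integrate_at_tss(atac_row("g2", 2e5, "gained-open", 3),
                               NULL, uc, int_genes)
  expect_equal(calls_iv$category[calls_iv$gene_id == "g2"], "IV")
})

test_that("missing or conflicting evidence leaves genes uncalled", {
  atac <- atac_row("g1", 1e5, "gained-open", 3)
  # no CUT&RUN evidence at all -> every gene uncalled
  calls <- integrate_at_tss(atac, NULL, NULL, int_genes)
  expect_true(all(calls$category == "uncalled"))
  # H3K56ac evidence without an ATAC direction -> uncalled
  ut <- ps("chr1", 2e5 - 100, 2e5 + 400, condition = "treated")
  calls2 <- integrate_at_tss(atac, ut, NULL, int_genes)
  expect_equal(calls2$category[calls2$gene_id == "g2"], "uncalled")
  # ambiguous: both gain and loss peaks over one TSS window
  uc <- ps("chr1", 1e5 - 900, 1e5 - 300, condition = "control")
  ut1 <- ps("chr1", 1e5 - 100, 1e5 + 400, condition = "treated")
  calls3 <- integrate_at_tss(atac, ut1, uc, int_genes)
  expect_equal(calls3$k56_evidence[calls3$gene_id == "g1"], "ambiguous")
  expect_equal(calls3$category[calls3$gene_id == "g1"], "uncalled")
  # unchanged ATAC direction -> uncalled even with K56 evidence
  calls4 <- integrate_at_tss(atac_row("g1", 1e5, "unchanged", 0.2),
                             ut1, NULL, int_genes)
  expect_equal(calls4$category[calls4$gene_id == "g1"], "uncalled")
})

test_that("strongest |log2fc| region decides a gene's ATAC direction", {
  atac <- rbind(atac_row("g1", 1e5, "gained-closed", -1.2),
                atac_row("g1", 1e5, "gained-open", 3.5))
  ut <- ps("chr1", 1e5 - 100, 1e5 + 400, condition = "treated")
  calls <- integrate_at_tss(atac, ut, NULL, int_genes)
  expect_equal(calls$category[calls$gene_id == "g1"], "I")
  expect_equal(calls$log2fc[calls$gene_id == "g1"], 3.5)
})

test_that("every gene gets exactly one mutually exclusive call", {
  atac <- rbind(atac_row("g1", 1e5, "gained-open", 3),
                atac_row("g2", 2e5, "gained-closed", -3))
  ut <- ps("chr1", 1e5 - 100, 1e5 + 400, condition = "treated")
  calls <- integrate_at_tss(atac, ut, NULL, int_genes)
  expect_equal(nrow(calls), nrow(int_genes))
  expect_equal(anyDuplicated(calls$gene_id), 0)
  expect_true(all(calls$category %in% c("I", "II", "III", "IV",
                                        "uncalled")))
})

test_that("category counts tally distinct genes per category", {
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      category = c("I", "I", "II", "uncalled"))
  cc <- category_counts(calls)
  expect_equal(cc[["I"]], 2)
  expect_equal(cc[["II"]], 1)
  expect_equal(cc[["uncalled"]], 1)
  expect_equal(cc[["III"]], 0)
  empty <- category_counts(calls[0, ])
  expect_true(all(empty == 0))
})

test_that("manifest-planted categories are recovered exactly end to end", {
  cfg <- sim_config(seed = 202, chrom_length = 4e5, n_genes = 40,
                    n_tes = 40, n_planted_enriched = 6, n_regions = 300,
                    n_planted_diff = 10,
                    planted_categories = c(I = 3, II = 4, III = 2))
  ann <- make_annotation(cfg)
  cts <- simulate_counts(cfg, ann)
  diff <- classify_differential(cts$table$regions,
                                exact_region_test(cts$table))
  diff_tss <- restrict_to_tss(diff, ann$genes)
  calls <- integrate_at_tss(diff_tss,
                            manifest_unique(cfg, ann, "treated"),
                            manifest_unique(cfg, ann, "control"),
                            ann$genes)
  cc <- category_counts(calls)
  expect_equal(cc[["I"]], 3)
  expect_equal(cc[["II"]], 4)
  expect_equal(cc[["III"]], 2)
  expect_equal(cc[["IV"]], 0)
})
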