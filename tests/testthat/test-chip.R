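test_that("E-value filtering is inclusive, idempotent, and matches a naive scan", {
  peaks <- make_peaks("s1", c(10, 200, 400), c(100, 300, 500),
                      e_value = c(1e-9, 1e-8, 1e-7))
  kept <- filter_peaks_by_evalue(peaks, 1e-8)
  expect_equal(nrow(kept), 2)                       # boundary retained
  expect_identical(filter_peaks_by_evalue(kept, 1e-8), kept)  # idempotent
  expect_identical(filter_peaks_by_evalue(peaks, 1), peaks)   # all e <= 1
  expect_error(filter_peaks_by_evalue(peaks, -1), class = "h4map_config_error")

  set.seed(12)
  big <- make_peaks("s1", 1:50 * 100, 1:50 * 100 + 50,
                    e_value = 10^-sample(1:20, 50, replace = TRUE))
  thr <- 1e-10
  expect_identical(filter_peaks_by_evalue(big, thr),
                   big[vapply(big$e_value, function(e) e <= thr, logical(1)), ])
})

test_that("nearest-gene annotation carries the printed sign convention", {
  # a peak 557 bp past the 3' end of a plus-strand gene: distance -557, DOWN
  genes <- make_genes("Px013825", "ChrLG-1", 260000, 266858)
  peaks <- make_peaks("ChrLG-1", 267415, 267973)
  ann <- annotate_nearest_cds(peaks, genes)
  expect_equal(ann$nearest_gene, "Px013825")
  expect_equal(ann$signed_distance, -557)
  expect_equal(ann$locality, "DOWN")

  # the same gap on the 5' side is +557, UP
  peaks_up <- make_peaks("ChrLG-1", 260000 - 557 - 500, 260000 - 557)
  ann_up <- annotate_nearest_cds(peaks_up, genes)
  expect_equal(ann_up$signed_distance, 557)
  expect_equal(ann_up$locality, "UP")

  # strand flip reverses the labels but not the gap size
  genes_minus <- dplyr::mutate(genes, strand = "-")
  expect_equal(annotate_nearest_cds(peaks, genes_minus)$locality, "UP")
  expect_equal(annotate_nearest_cds(peaks, genes_minus)$signed_distance, 557)
  # ignore_strand restores the coordinate reading
  expect_equal(annotate_nearest_cds(peaks, genes_minus,
                                    ignore_strand = TRUE)$locality, "DOWN")

  # a peak strictly inside a gene: distance 0, GB
  inside <- annotate_nearest_cds(make_peaks("ChrLG-1", 261000, 261150), genes)
  expect_equal(inside$signed_distance, 0)
  expect_equal(inside$locality, "GB")
})

test_that("equidistant ties resolve to the lexicographically smallest gene id", {
  genes <- make_genes(c("PxB", "PxA"), "s1", c(100, 1000), c(200, 1100))
  # peak midway: gap to PxB = 300, gap to PxA = 300
  peaks <- make_peaks("s1", 500, 700)
  expect_equal(500 - 200, 1000 - 700)  # construction really is a tie
  ann <- annotate_nearest_cds(peaks, genes)
  expect_equal(ann$nearest_gene, "PxA")
  expect_equal(abs(ann$signed_distance), 300)
})

test_that("gene-less scaffolds are flagged and random annotations match GenomicRanges", {
  genes <- make_genes("Px1", "s1", 100, 200)
  peaks <- make_peaks(c("s1", "s_empty"), c(300, 10), c(400, 60))
  expect_warning(ann <- annotate_nearest_cds(peaks, genes))
  expect_false(ann$annotated[ann$scaffold == "s_empty"])
  expect_true(is.na(ann$nearest_gene[ann$scaffold == "s_empty"]))

  skip_if_not_installed("GenomicRanges")
  set.seed(31)
  for (rep in 1:5) {
    gs <- sort(sample.int(50000, 8))
    genes <- make_genes(sprintf("Px%02d", 1:8), "s1", gs, gs + 400)
    ps <- sample.int(50000, 15)
    peaks <- make_peaks("s1", ps, ps + 150)
    ann <- annotate_nearest_cds(peaks, genes)
    gr_g <- GenomicRanges::GRanges("s1", IRanges::IRanges(genes$start + 1,
                                                          genes$end))
    gr_p <- GenomicRanges::GRanges("s1", IRanges::IRanges(peaks$start + 1,
                                                          peaks$end))
    hit <- GenomicRanges::distanceToNearest(gr_p, gr_g)
    expect_equal(abs(ann$signed_distance),
                 as.numeric(S4Vectors::mcols(hit)$distance))
  }
})

test_that("control subtraction removes targets by gene identity only", {
  genes <- make_genes(c("PxA", "PxB", "PxC"), "s1",
                      c(1000, 5000, 9000), c(2000, 6000, 10000))
  treat <- annotate_nearest_cds(
    make_peaks("s1", c(500, 4500, 8500), c(650, 4650, 8650)), genes)
  expect_equal(specific_targets(treat, treat[0, ]), treat)  # empty control
  expect_equal(nrow(specific_targets(treat, treat)), 0)         # full overlap

  # control peak far from the treatment peak but nearest to the same gene
  ctrl <- annotate_nearest_cds(make_peaks("s1", 2200, 2350), genes)
  expect_equal(ctrl$nearest_gene, "PxA")
  spec <- specific_targets(treat, ctrl)
  expect_setequal(spec$nearest_gene, c("PxB", "PxC"))
  # asserted invariant: no specific target shares a control gene
  expect_length(intersect(spec$nearest_gene, ctrl$nearest_gene), 0)
})

test_that("core targets intersect screens and keep the closest site per gene", {
  genes <- make_genes(c("PxA", "PxB"), "s1", c(1000, 5000), c(2000, 6000))
  a <- annotate_nearest_cds(
    make_peaks("s1", c(500, 700, 4500), c(600, 800, 4600),
               peak_id = c("a1", "a2", "a3")), genes, screen = "parasitism")
  b <- annotate_nearest_cds(
    make_peaks("s1", c(900, 5100), c(950, 5200),
               peak_id = c("b1", "b2")), genes, screen = "viral")
  core <- core_targets(a, b)
  expect_equal(nrow(core), 2)
  expect_setequal(core$gene_id, c("PxA", "PxB"))
  # PxA has two sites in screen a; the closer one (a2, gap 200) represents it
  expect_equal(core$peak_id_a[core$gene_id == "PxA"], "a2")
  expect_true(all(core$gene_id %in% a$nearest_gene))
  expect_true(all(core$gene_id %in% b$nearest_gene))

  disjoint <- core_targets(a[a$nearest_gene == "PxA", ],
                           b[b$nearest_gene == "PxB", ])
  expect_equal(nrow(disjoint), 0)
  self <- core_targets(a, a)
  expect_equal(nrow(self), 2)  # one record per distinct gene
})

test_that("planted screens are recovered exactly from synthetic data", {
  cfg <- small_sim_config(seed = 77, n_specific_peaks = 10L,
                          n_shared_peaks = 5L, n_core_targets = 4L,
                          e_value_nonspecific = 1e-9)
  # nonspecific e-value chosen to PASS the filter so that subtraction, not
  # significance, must remove the shared sites
  gen <- generate_genome(cfg)
  pk <- generate_peak_sets(cfg, gen$genes, gen$genome)
  spec_p <- chip_screen(pk$peaks$P7, pk$peaks$NP5, gen$genes, 1e-8,
                        "parasitism")
  spec_v <- chip_screen(pk$peaks$vH4, pk$peaks$vH4T, gen$genes, 1e-8, "viral")
  truth <- pk$truth$peaks
  planted_p <- truth$target_gene[truth$role == "specific" &
                                   truth$screen == "parasitism"]
  expect_setequal(spec_p$nearest_gene, planted_p)
  expect_equal(nrow(spec_p), 10)
  expect_equal(nrow(spec_v), 10)
  core <- core_targets(spec_p, spec_v)
  expect_setequal(core$gene_id, pk$truth$core_genes)
  expect_equal(nrow(core), 4)
  # planted signed distances and localities survive the annotation
  m <- match(spec_p$peak_id, truth$peak_id)
  expect_identical(spec_p$locality, truth$locality[m])
  expect_equal(abs(spec_p$signed_distance), truth$distance[m])
})
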