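test_that("locality classification is overlap-first and strand-aware", {
  gene <- make_genes("Px1", "s1", 1000, 2000)
  expect_equal(classify_locality(999, 1001, gene), "GB")   # 1 bp overlap
  expect_equal(classify_locality(500, 1000, gene), "UP")   # adjacent, no overlap
  expect_equal(classify_locality(500, 800, gene), "UP")
  expect_equal(classify_locality(2100, 2200, gene), "DOWN")
  gene_minus <- dplyr::mutate(gene, strand = "-")
  expect_equal(classify_locality(500, 800, gene_minus), "DOWN")
  expect_equal(classify_locality(2100, 2200, gene_minus), "UP")
  expect_error(classify_locality(1, 10, gene, peak_scaffold = "s2"),
               class = "h4map_domain_error")

  set.seed(6)
  for (i in 1:50) {
    gs <- sample.int(5000, 1); ge <- gs + sample.int(2000, 1)
    ps <- sample.int(8000, 1); pe <- ps + sample.int(300, 1)
    strand <- sample(c("+", "-"), 1)
    g <- make_genes("Px1", "s1", gs, ge, strand = strand)
    expect_equal(classify_locality(ps, pe, g),
                 naive_locality(ps, pe, gs, ge, strand))
  }
})

test_that("neighborhood profiles tile the region and conserve read counts", {
  gs <- seq(10000, 70000, by = 10000)
  genes <- make_genes(sprintf("Px%02d", 1:7), "s1", gs, gs + 2000)
  focal <- "Px04"

  empty <- build_neighborhood_profile(focal, genes, make_peaks("s1",
                                                               integer(0),
                                                               integer(0)))
  expect_true(all(empty$regions$chip_count == 0))
  expect_false(empty$truncated)
  # regions tile without overlap: each next start equals the previous end
  r <- empty$regions
  expect_true(all(r$start[-1] == r$end[-nrow(r)]))
  expect_equal(sum(r$type == "gene"), 7)

  # a single peak at a gene midpoint counts fully in that gene's region
  pk <- make_peaks("s1", 40950, 41050, read_count = 7)
  prof <- build_neighborhood_profile(focal, genes, pk)
  focal_row <- which(prof$regions$gene_id == focal)
  expect_equal(prof$regions$chip_count[focal_row], 7)
  expect_equal(sum(prof$regions$chip_count), 7)

  # conservation under many random peaks assigned by midpoint
  set.seed(23)
  ps <- sample(5000:75000, 40)
  many <- make_peaks("s1", ps, ps + 150,
                     read_count = sample.int(30, 40, replace = TRUE))
  prof2 <- build_neighborhood_profile(focal, genes, many)
  mid <- floor((many$start + many$end) / 2)
  span <- range(prof2$regions$start, prof2$regions$end)
  in_span <- mid >= span[1] & mid < span[2]
  expect_equal(sum(prof2$regions$chip_count), sum(many$read_count[in_span]))

  # truncated neighborhoods at scaffold ends are flagged, not dropped
  edge <- build_neighborhood_profile("Px01", genes, pk)
  expect_true(edge$truncated)
  expect_error(build_neighborhood_profile("nope", genes, pk),
               class = "h4map_lookup_error")
})

test_that("main position calls use focal-adjacent regions with UP > GB > DOWN ties", {
  gs <- seq(10000, 70000, by = 10000)
  genes <- make_genes(sprintf("Px%02d", 1:7), "s1", gs, gs + 2000)
  peak_at <- function(start, n) make_peaks("s1", start, start + 100,
                                           read_count = n,
                                           peak_id = paste0("p", start))
  # UP=10 (just left of focal), GB=2, DOWN=1
  pk <- dplyr::bind_rows(peak_at(39000, 10), peak_at(41000, 2),
                         peak_at(43000, 1))
  call <- call_main_position(build_neighborhood_profile("Px04", genes, pk))
  expect_equal(call$main_locality, "UP")
  expect_equal(call[, c("up_count", "gb_count", "down_count")],
               tibble::tibble(up_count = 10, gb_count = 2, down_count = 1))

  # tie UP = GB resolves to UP by fixed precedence
  tie <- dplyr::bind_rows(peak_at(39000, 5), peak_at(41000, 5))
  expect_equal(call_main_position(
    build_neighborhood_profile("Px04", genes, tie))$main_locality, "UP")

  # no reads in the three focal regions -> undefined locality
  none <- call_main_position(build_neighborhood_profile("Px04", genes,
                                                        peak_at(12000, 9)))
  expect_true(is.na(none$main_locality))

  # minus-strand focal gene swaps which intergenic side is UP
  genes_m <- dplyr::mutate(genes, strand = ifelse(gene_id == "Px04", "-", "+"))
  call_m <- call_main_position(build_neighborhood_profile("Px04", genes_m, pk))
  expect_equal(call_m$main_locality, "DOWN")

  # regulation is looked up from the DEG list
  degs <- tibble::tibble(transcript_id = "Px04", direction = "down")
  expect_equal(call_main_position(build_neighborhood_profile("Px04", genes,
                                                             pk),
                                  degs)$regulation, "down")
})

test_that("planted main localities are recovered from isolated synthetic peaks", {
  cfg <- small_sim_config(seed = 41)
  gen <- generate_genome(cfg)
  pk <- generate_peak_sets(cfg, gen$genes, gen$genome)
  truth <- dplyr::filter(pk$truth$peaks, condition == "P7",
                         role == "specific")
  p7 <- pk$peaks$P7
  # restrict to focal genes whose adjacent regions hold no other planted peak
  for (i in seq_len(nrow(truth))) {
    g <- truth$target_gene[i]
    others <- p7[p7$peak_id != truth$peak_id[i], ]
    prof <- build_neighborhood_profile(g, gen$genes, p7)
    own <- build_neighborhood_profile(g, gen$genes,
                                      p7[p7$peak_id == truth$peak_id[i], ])
    isolated <- sum(prof$regions$chip_count) == sum(own$regions$chip_count)
    if (!isolated) next
    expect_equal(call_main_position(prof)$main_locality, truth$locality[i],
                 label = truth$peak_id[i])
  }
})

test_that("the positional-effect test matches the direct Pearson formula", {
  make_calls <- function(tab) {
    df <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
    tibble::tibble(
      gene_id = as.character(seq_len(sum(df$Freq))),
      main_locality = rep(df$Var1, df$Freq),
      regulation = rep(df$Var2, df$Freq))
  }
  # perfectly proportional table: statistic 0, p 1
  prop <- matrix(c(10, 20, 30, 5, 10, 15), nrow = 3,
                 dimnames = list(c("UP", "GB", "DOWN"), c("up", "down")))
  res <- positional_effect_test(make_calls(prop))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)   # full 3 x 2 layout

  set.seed(55)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 6, replace = TRUE), nrow = 3,
                  dimnames = list(c("UP", "GB", "DOWN"), c("up", "down")))
    res <- positional_effect_test(make_calls(tab))
    expect_equal(res$statistic, naive_chisq_stat(tab), tolerance = 1e-12)
    expect_equal(res$df, 2)
  }

  # an empty locality row is dropped with a warning and df reduced
  two_rows <- matrix(c(10, 0, 12, 8, 0, 4), nrow = 3,
                     dimnames = list(c("UP", "GB", "DOWN"), c("up", "down")))
  expect_warning(res2 <- positional_effect_test(make_calls(two_rows)))
  expect_equal(res2$df, 1)
  # "none" calls are excluded before testing
  calls <- make_calls(prop)
  calls$regulation[1] <- "none"
  expect_s3_class(positional_effect_test(calls), "h4_chisq")
})
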