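test_that("AT content counts unambiguous bases only", {
  expect_equal(at_content("ATAT"), 1)
  expect_equal(at_content("ACGT"), 0.5)
  expect_equal(at_content("acgt"), 0.5)
  expect_equal(at_content("ANT"), 1)        # N excluded from both sides
  expect_equal(at_content("ACGN"), 1 / 3)
  expect_error(at_content("NNNN"), class = "h4map_domain_error")
  set.seed(2)
  for (i in 1:20) {
    s <- random_dna(60, at = stats::runif(1, 0.2, 0.8))
    expect_equal(at_content(s) + gc_content(s), 1)
  }
})

test_that("the repeat finder reports maximal primitive runs", {
  hits <- find_tandem_repeats("AAGTGTGTGTCC", min_copies = c(`2` = 4))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$unit, "GT")
  expect_equal(hits$start, 2)
  expect_equal(hits$copies, 4)
  expect_false(hits$partial_tail)

  # primitivity: an AGAGAGAG run is an AG-run, never an AGAG-run
  h2 <- find_tandem_repeats("AGAGAGAG", min_copies = c(`2` = 4, `4` = 2))
  expect_equal(h2$unit, "AG")
  expect_equal(h2$copies, 4)

  # partial tails are flagged, not counted as copies
  h3 <- find_tandem_repeats("CCGTGTGTGTGTGC", min_copies = c(`2` = 5))
  expect_equal(h3$copies, 5)
  expect_true(h3$partial_tail)
  expect_equal(h3$span, 11)   # 5 complete units + 1-base tail
  h3b <- find_tandem_repeats("CCGTGTGTGTGTGC", min_copies = c(`2` = 5),
                             allow_partial_tail = FALSE)
  expect_equal(h3b$span, 10)

  expect_error(find_tandem_repeats("ACGT", min_copies = c(`2` = 1)),
               class = "h4map_config_error")
})

test_that("unit classes are rotation-canonical with complements kept apart", {
  expect_equal(unit_class("TG"), "GT")
  expect_equal(unit_class("GT"), "GT")
  expect_equal(unit_class("CA"), "AC")
  expect_equal(unit_class(c("GA", "TC")), c("AG", "CT"))
  expect_false(unit_class("GT") == unit_class("AC"))   # never merged
  expect_equal(unit_class("ATC"), "ATC")
  expect_equal(unit_class("TCA"), "ATC")
})

test_that("the finder agrees with brute-force enumeration on random and adversarial inputs", {
  set.seed(7)
  cases <- c(
    replicate(60, random_dna(150, at = 0.6)),
    replicate(20, random_dna(40, at = 0.3)),
    "GTGTGTGTGTGTGTGTGTGT",      # whole-sequence repeat
    "AAAAAAAAAAAA",              # homopolymer: k = 1 excluded entirely
    "ATATATATATATAT",            # overlapping phases of a 2-mer
    "CATCATCATCATCAT",           # 3-mer
    "TTCTGTTCTGTTCTGTTCTG",      # 5-mer
    "ACGTACGTACGTACGT")          # 4-mer, 3 copies + tail
  for (s in cases) {
    got <- find_tandem_repeats(s)
    want <- naive_find_repeats(s)
    expect_equal(nrow(got), nrow(want), label = s)
    if (nrow(want) > 0) {
      expect_equal(got$unit, want$unit, label = s)
      expect_equal(got$start, want$start, label = s)
      expect_equal(got$copies, want$copies, label = s)
    }
    # every emitted hit is non-extendable by a full unit on the left, and the
    # base after the complete copies does not start another full unit
    for (i in seq_len(nrow(got))) {
      k <- nchar(got$unit[i]); st <- got$start[i]
      if (st >= k) {
        expect_false(substr(s, st - k + 1, st) == got$unit[i])
      }
      after <- substr(s, st + k * got$copies[i] + 1,
                      st + k * (got$copies[i] + 1))
      if (nchar(after) == k) expect_false(after == got$unit[i])
    }
  }
})

test_that("reverse complement maps classes GT<->AC and CT<->AG, never merging them", {
  set.seed(15)
  for (i in 1:20) {
    s <- paste0(random_dna(30), strrep(sample(c("GT", "CT", "CAT"), 1), 8),
                random_dna(30))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd_units <- find_tandem_repeats(s)$unit
    rc_classes <- sort(unique(find_tandem_repeats(rc)$unit_class))
    expected <- sort(unique(unit_class(vapply(fwd_units, function(u) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
    }, character(1)))))
    expect_equal(rc_classes, expected)
  }
  expect_equal(classify_site_repeats(strrep("GT", 8)), "GT")
  expect_equal(classify_site_repeats(strrep("AC", 8)), "AC")
})

test_that("sites can carry several repeat classes or none", {
  two <- paste0("AAC", strrep("GT", 6), "CCA", strrep("CT", 6), "AA")
  expect_setequal(classify_site_repeats(two), c("GT", "CT"))
  # repeat-free sequence at strict minimum copies
  expect_length(classify_site_repeats("ACGTAGCTTGCAATGCCATG"), 0)
})

test_that("planted repeat classes are recovered across seeds", {
  for (s in c(3, 14, 159)) {
    cfg <- small_sim_config(seed = s, repeat_site_fraction = 0.5)
    gen <- generate_genome(cfg)
    pk <- generate_peak_sets(cfg, gen$genes, gen$genome)
    planted <- dplyr::filter(pk$truth$peaks, !is.na(planted_unit))
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      site_seq <- extract_interval_sequence(
        pk$genome, p$scaffold,
        pk$peaks[[p$condition]]$start[pk$peaks[[p$condition]]$peak_id == p$peak_id],
        pk$peaks[[p$condition]]$end[pk$peaks[[p$condition]]$peak_id == p$peak_id])
      expect_true(p$planted_unit_class %in% classify_site_repeats(site_seq),
                  label = paste(s, p$peak_id, p$planted_unit))
    }
  }
})

test_that("the repeat-by-regulation cross-tab honours planted associations", {
  sites <- tibble::tibble(
    nearest_gene = c("g1", "g2", "g3", "g4"),
    repeat_classes = list("CT", "CT", c("GT", "AC"), character(0)))
  no_degs <- tibble::tibble(transcript_id = character(),
                            direction = character())
  tab0 <- repeat_deg_crosstab(sites, no_degs)
  expect_true(all(tab0$up == 0) && all(tab0$down == 0))
  expect_equal(sum(tab0$none), 4)  # g4 has no class, contributes no row

  # all CT sites attached to up-regulated genes: CT row has zero "down"
  degs <- tibble::tibble(transcript_id = c("g1", "g2", "g3"),
                         direction = c("up", "up", "down"))
  tab <- repeat_deg_crosstab(sites, degs)
  expect_equal(tab$down[tab$unit_class == "CT"], 0)
  expect_equal(tab$up[tab$unit_class == "CT"], 2)
  expect_equal(tab$down[tab$unit_class == "GT"], 1)
  expect_equal(tab$down[tab$unit_class == "AC"], 1)

  # a nearest gene at FC -6.6 lands in the down column
  deg_one <- call_degs(tibble::tibble(transcript_id = "g1", NP5 = 6.6,
                                      P7 = 1, vH4 = 1, vH4T = 1), "P7/NP5")
  expect_equal(deg_one$signed_fc, -6.6)
  tab2 <- repeat_deg_crosstab(sites[1, ], deg_one)
  expect_equal(tab2$down[tab2$unit_class == "CT"], 1)
})
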