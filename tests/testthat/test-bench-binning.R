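gold4 <- function() {
  tibble::tibble(contig_id = c("a", "b", "c", "d"),
                 source_genome_id = c("g1", "g1", "g2", "g2"),
                 genome_superkingdom = c("eukaryote", "eukaryote",
                                         "prokaryote", "prokaryote"),
                 length_bp = c(100, 100, 100, 100))
}

test_that("strategy filters implement the FULL / EUK-only / OTHER-rem definitions", {
  m <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                      length_bp = c(2000L, 2000L, 2000L),
                      true_label = "unknown", source_genome_id = NA_character_)
  fl <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                       final_label = c("eukaryote", "noneukaryote", "unclassified"))
  expect_setequal(strategy_filter(m, fl, "EUK_only"), "c1")
  expect_setequal(strategy_filter(m, fl, "OTHER_rem"), c("c1", "c3"))
  expect_setequal(strategy_filter(m, fl, "FULL"), c("c1", "c2", "c3"))

  # degenerate labels: all three modes coincide
  fl_euk <- dplyr::mutate(fl, final_label = "eukaryote")
  expect_setequal(strategy_filter(m, fl_euk, "FULL"),
                  strategy_filter(m, fl_euk, "EUK_only"))
  expect_error(strategy_filter(m, fl, "BOGUS"))
})

test_that("strategy filters nest and match a brute-force filter on random labels", {
  for (seed in c(3, 4)) {
    m <- random_manifest(200, seed)
    set.seed(seed)
    fl <- tibble::tibble(contig_id = m$contig_id,
                         final_label = sample(norm_labels, 200, replace = TRUE))
    euk <- strategy_filter(m, fl, "EUK_only", min_len = 1500)
    oth <- strategy_filter(m, fl, "OTHER_rem", min_len = 1500)
    ful <- strategy_filter(m, fl, "FULL", min_len = 1500)
    expect_true(all(euk %in% oth))
    expect_true(all(oth %in% ful))
    lab <- fl$final_label[match(m$contig_id, fl$contig_id)]
    expect_setequal(ful, m$contig_id[m$length_bp >= 1500])
    expect_setequal(euk, m$contig_id[m$length_bp >= 1500 & lab == "eukaryote"])
    expect_setequal(oth, m$contig_id[m$length_bp >= 1500 & lab != "noneukaryote"])
  }
})

test_that("eukaryotic bins need a strict bp majority", {
  gold <- tibble::tibble(contig_id = c("e1", "p1"),
                         source_genome_id = c("ge", "gp"),
                         genome_superkingdom = c("eukaryote", "prokaryote"),
                         length_bp = c(49, 51))
  one_bin <- tibble::tibble(contig_id = c("e1", "p1"), bin_id = "B")
  expect_length(euk_bins(one_bin, gold), 0)  # 49% eukaryote
  solo <- tibble::tibble(contig_id = "e1", bin_id = "B")
  expect_equal(euk_bins(solo, gold[1, ]), "B")
})

test_that("fraction of eukaryotic bp binned matches a direct tally", {
  g <- gold4()
  all_binned <- tibble::tibble(contig_id = g$contig_id, bin_id = "B1")
  expect_equal(pct_euk_bp_binned(all_binned, g), 1)
  none <- tibble::tibble(contig_id = g$contig_id, bin_id = NA_character_)
  expect_equal(pct_euk_bp_binned(none, g), 0)

  set.seed(5)
  g2 <- g
  g2$length_bp <- sample(50:150, 4)
  bm <- tibble::tibble(contig_id = g$contig_id,
                       bin_id = c("B1", NA, "B1", NA))
  is_euk <- g2$genome_superkingdom == "eukaryote"
  want <- sum(g2$length_bp[is_euk & !is.na(bm$bin_id)]) / sum(g2$length_bp[is_euk])
  expect_equal(pct_euk_bp_binned(bm, g2), want)

  prok_only <- g[3:4, ]
  expect_warning(out <- pct_euk_bp_binned(bm[3:4, ], prok_only), "undefined")
  expect_true(is.na(out))
})

test_that("purity/completeness/F1 closed forms", {
  g <- gold4()
  # bins identical to genomes: everything is 1
  ident <- tibble::tibble(contig_id = g$contig_id,
                          bin_id = c("B1", "B1", "B2", "B2"))
  res <- purity_completeness_f1(ident, g)
  expect_equal(res$scores$purity, 1)
  expect_equal(res$scores$completeness, 1)
  expect_equal(res$scores$f1, 1)

  # one genome split into two equal bins: most-complete-bin F1 = 2/3
  split <- tibble::tibble(contig_id = c("a", "b"), bin_id = c("B1", "B2"))
  res <- purity_completeness_f1(split, g[1:2, ], variant = "most_complete_bin")
  expect_equal(res$scores$f1, 2 / 3)
  expect_equal(res$summary$f1, 2 / 3)

  # two equal-size eukaryotic genomes merged into one bin: purity 0.5
  g_two_euk <- dplyr::mutate(g, genome_superkingdom = "eukaryote")
  merged <- tibble::tibble(contig_id = g$contig_id, bin_id = "B1")
  res <- purity_completeness_f1(merged, g_two_euk, variant = "all_bins")
  expect_equal(res$scores$purity, 0.5)

  # no eukaryotic bins at all
  prok <- dplyr::mutate(g, genome_superkingdom = "prokaryote")
  expect_warning(res <- purity_completeness_f1(merged, prok), "no eukaryotic bins")
  expect_equal(nrow(res$scores), 0)
})

test_that("completeness denominators cover unbinned contigs of the filtered assembly", {
  g <- gold4()[1:2, ]
  half <- tibble::tibble(contig_id = c("a", "b"), bin_id = c("B1", NA))
  res <- purity_completeness_f1(half, g)
  expect_equal(res$scores$completeness, 0.5)  # genome bp in assembly, not in bins
})

test_that("ARI is 1 on identity, 0 on the one-bin partition, and matches pair counting", {
  g <- gold4()
  ident <- tibble::tibble(contig_id = g$contig_id,
                          bin_id = c("B1", "B1", "B2", "B2"))
  expect_equal(as.numeric(bin_ari(ident, g)), 1)
  one <- tibble::tibble(contig_id = g$contig_id, bin_id = "B")
  expect_equal(as.numeric(bin_ari(one, g)), 0)

  # single genome in a single bin is flagged degenerate with value 1
  solo <- bin_ari(tibble::tibble(contig_id = c("a", "b"), bin_id = "B"), g[1:2, ])
  expect_equal(as.numeric(solo), 1)
  expect_true(attr(solo, "degenerate"))

  set.seed(8)
  for (i in 1:20) {
    gr <- tibble::tibble(contig_id = sprintf("c%d", 1:8),
                         source_genome_id = sample(c("g1", "g2", "g3"), 8, TRUE),
                         genome_superkingdom = "eukaryote",
                         length_bp = sample(1:5, 8, TRUE))
    bm <- tibble::tibble(contig_id = gr$contig_id,
                         bin_id = sample(c("b1", "b2", NA), 8, TRUE))
    if (all(is.na(bm$bin_id))) next
    got <- as.numeric(bin_ari(bm, gr))
    expect_equal(got, oracle_ari_pairs(bm, gr), tolerance = 1e-12, info = i)
  }
})

test_that("ARI is invariant to bin relabeling and bounded above by 1", {
  set.seed(12)
  g <- tibble::tibble(contig_id = sprintf("c%d", 1:10),
                      source_genome_id = sample(c("g1", "g2"), 10, TRUE),
                      genome_superkingdom = "eukaryote",
                      length_bp = sample(10:50, 10))
  bm <- tibble::tibble(contig_id = g$contig_id,
                       bin_id = sample(c("x", "y", "z"), 10, TRUE))
  a1 <- as.numeric(bin_ari(bm, g))
  relab <- dplyr::mutate(bm, bin_id = c(x = "q", y = "r", z = "s")[bin_id])
  expect_equal(as.numeric(bin_ari(relab, g)), a1)
  expect_lte(a1, 1)
})

test_that("evaluate_binning bundles the metrics with tidy/glance methods", {
  g <- gold4()
  ident <- tibble::tibble(contig_id = g$contig_id,
                          bin_id = c("B1", "B1", "B2", "B2"))
  bq <- evaluate_binning(ident, g)
  expect_equal(bq$ari, 1)
  expect_equal(bq$pct_euk_bp_binned, 1)
  gl <- glance(bq)
  expect_equal(gl$mean_f1, 1)
  expect_equal(gl$n_euk_bins, 1)
  expect_equal(nrow(tidy(bq)), 1)
  expect_s3_class(autoplot(bq), "ggplot")
})
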