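cov_table <- function(breadths, depths = NULL) {
  n <- length(breadths)
  tibble::tibble(sample_id = rep("s1", n),
                 contig_id = sprintf("c%d", seq_len(n)),
                 mean_depth = if (is.null(depths)) rep(1, n) else depths,
                 breadth = breadths)
}

test_that("presence threshold is inclusive at 25% breadth", {
  cov <- cov_table(c(0.25, 0.249, 0, 1))
  p <- presence_calls(cov, prune = FALSE)
  expect_equal(p$s1, c(TRUE, FALSE, FALSE, TRUE))

  # elementwise oracle on a random table
  set.seed(2)
  cov2 <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                             contig_id = paste0("c", 1:30))
  cov2$mean_depth <- runif(nrow(cov2), 0.1, 5)
  cov2$breadth <- runif(nrow(cov2))
  p2 <- presence_calls(cov2, prune = FALSE)
  m <- as.matrix(p2[-1])
  for (i in seq_len(nrow(cov2))) {
    expect_identical(unname(m[match(cov2$contig_id[i], p2$taxon_id),
                              cov2$sample_id[i]]),
                     cov2$breadth[i] >= 0.25)
  }
  # pruning drops taxa present nowhere
  cov3 <- cov_table(c(0, 0.5))
  p3 <- presence_calls(cov3)
  expect_equal(p3$taxon_id, "c2")
})

test_that("bp fractions are coverage-weighted and sum to one", {
  cov <- tibble::tibble(sample_id = "s1", contig_id = c("c1", "c2"),
                        mean_depth = c(2, 2), breadth = c(0.9, 0.9),
                        length_bp = c(1000, 1000))
  labs <- tibble::tibble(contig_id = c("c1", "c2"),
                         label = c("eukaryote", "prokaryote"))
  fr <- bp_fractions(cov, labs)
  expect_equal(sort(fr$fraction), c(0.5, 0.5))

  solo <- bp_fractions(cov[1, ], labs[1, ])
  expect_equal(solo$fraction, 1)

  set.seed(3)
  cov2 <- tidyr::expand_grid(sample_id = paste0("s", 1:4),
                             contig_id = paste0("c", 1:25))
  cov2$mean_depth <- runif(nrow(cov2), 0, 10)
  cov2$breadth <- runif(nrow(cov2))
  cov2$length_bp <- rep(sample(1000:9000, 25), times = 4)
  labs2 <- tibble::tibble(contig_id = paste0("c", 1:25),
                          label = sample(c("eukaryote", "prokaryote", "virus",
                                           "unclassified"), 25, replace = TRUE))
  fr2 <- bp_fractions(cov2, labs2)
  sums <- tapply(fr2$fraction, fr2$sample_id, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  # weighted tally oracle for one sample/group
  w <- cov2$mean_depth * cov2$length_bp
  pres <- cov2$breadth >= 0.25
  lab <- labs2$label[match(cov2$contig_id, labs2$contig_id)]
  in_s2 <- cov2$sample_id == "s2" & pres
  want <- sum(w[in_s2 & lab == "eukaryote"]) / sum(w[in_s2])
  got <- fr2$fraction[fr2$sample_id == "s2" & fr2$label == "eukaryote"]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("samples with nothing present are dropped with a warning", {
  cov <- tibble::tibble(sample_id = c("s1", "s2"), contig_id = "c1",
                        mean_depth = c(1, 1), breadth = c(0.9, 0.01),
                        length_bp = 1000)
  labs <- tibble::tibble(contig_id = "c1", label = "eukaryote")
  expect_warning(fr <- bp_fractions(cov, labs), "s2")
  expect_equal(fr$sample_id, "s1")
})

test_that("well-separated sample groups are recovered and named by eukaryotic fraction", {
  set.seed(4)
  n <- 30
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:(2 * n)),
    nonpareil_coverage = c(rnorm(n, 0.45, 0.02), rnorm(n, 0.92, 0.02)),
    euk_fraction = c(abs(rnorm(n, 0.005, 0.002)), rnorm(n, 0.25, 0.04)))
  cl <- cluster_samples(samples, seed = 9)
  expect_equal(cl$cluster[1:n], rep("eukaryotic-deficient", n))
  expect_equal(cl$cluster[(n + 1):(2 * n)], rep("eukaryotic-increasing", n))

  # invariant to sample order
  perm <- sample(nrow(samples))
  cl2 <- cluster_samples(samples[perm, ], seed = 9)
  expect_equal(cl2$cluster[match(cl$sample_id, cl2$sample_id)], cl$cluster)

  # invariant to affine rescaling of the coverage variable (z-scored away)
  resc <- dplyr::mutate(samples, nonpareil_coverage =
                          (nonpareil_coverage - 0.2) / 3)
  cl3 <- cluster_samples(resc, seed = 9)
  expect_equal(cl3$cluster, cl$cluster)
})

test_that("degenerate clustering input is flagged", {
  samples <- tibble::tibble(sample_id = paste0("s", 1:5),
                            nonpareil_coverage = 0.5, euk_fraction = 0.1)
  expect_warning(cl <- cluster_samples(samples), "degenerate")
  expect_true(attr(cl, "degenerate"))
  expect_error(cluster_samples(samples[0, ]), "at least")
})

test_that("zero fractions enter the logit via the half-minimum rule", {
  samples <- tibble::tibble(sample_id = paste0("s", 1:6),
                            nonpareil_coverage = c(0.2, 0.21, 0.22, 0.8, 0.81, 0.82),
                            euk_fraction = c(0, 0.001, 0.002, 0.3, 0.31, 0.32))
  cl <- cluster_samples(samples, seed = 1)
  expect_equal(cl$cluster, rep(c("eukaryotic-deficient", "eukaryotic-increasing"),
                               each = 3))
})

test_that("co-occurrence p-values match exhaustive enumeration", {
  # 3-of-5 vs 3-of-5 with full co-presence: p = 0.1, no edge at 0.05
  m <- rbind(A = c(TRUE, TRUE, TRUE, FALSE, FALSE),
             B = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  colnames(m) <- paste0("s", 1:5)
  e <- cooccurrence_edges(m)
  expect_equal(e$p_value, 0.1, tolerance = 1e-12)
  expect_false(e$significant)
  expect_equal(nrow(e), 1)  # no self-edges

  set.seed(6)
  for (i in 1:15) {
    N <- sample(3:6, 1)
    nt <- sample(2:4, 1)
    mm <- matrix(runif(nt * N) < 0.5, nt, N,
                 dimnames = list(paste0("t", 1:nt), paste0("s", 1:N)))
    mm[rowSums(mm) == 0, 1] <- TRUE  # taxa present somewhere
    ee <- cooccurrence_edges(mm, alpha = 0.05)
    expect_true(all(ee$p_value > 0 & ee$p_value <= 1))
    for (r in seq_len(nrow(ee))) {
      set_a <- which(mm[ee$taxon_a[r], ])
      want <- oracle_hyper_enum(set_a, ee$prevalence_b[r], N, ee$co_count[r])
      expect_equal(ee$p_value[r], want, tolerance = 1e-12,
                   info = sprintf("draw %d pair %s-%s", i, ee$taxon_a[r], ee$taxon_b[r]))
    }
  }
})

test_that("adding a co-absent sample cannot make a pair less significant", {
  # enumerate small configurations; appending a sample where neither taxon
  # occurs raises N while keeping prevalences, which can only shrink p
  for (N in 3:5) for (ka in 1:N) for (kb in 1:N) for (x in 0:min(ka, kb)) {
    p_n <- phyper(x - 1, ka, N - ka, kb, lower.tail = FALSE)
    p_n1 <- phyper(x - 1, ka, N + 1 - ka, kb, lower.tail = FALSE)
    expect_lte(p_n1, p_n + 1e-12)
  }
})

test_that("BH adjustment flags on adjusted p-values", {
  set.seed(7)
  mm <- matrix(runif(60) < 0.5, 10, 6,
               dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  e_raw <- cooccurrence_edges(mm, adjust = "none")
  e_bh <- cooccurrence_edges(mm, adjust = "BH")
  expect_equal(e_bh$p_adjusted,
               stats::p.adjust(e_raw$p_value, method = "BH"))
  expect_true(sum(e_bh$significant) <= sum(e_raw$significant))
})

test_that("module detection reports only modules with more than 10 taxa", {
  two <- dplyr::bind_rows(clique_edges(12, "x"), clique_edges(12, "y"))
  mod <- detect_modules(two, seed = 1)
  expect_equal(nrow(mod), 2)
  expect_true(all(mod$reported))
  expect_equal(mod$n_nodes, c(12, 12))
  expect_equal(mod$n_edges, c(66, 66))

  expect_true(detect_modules(clique_edges(11, "z"), seed = 1)$reported)
  expect_false(detect_modules(clique_edges(10, "z"), seed = 1)$reported)

  empty <- tibble::tibble(taxon_a = character(), taxon_b = character())
  expect_equal(nrow(detect_modules(empty)), 0)
})

test_that("modules partition the nodes and recover planted communities", {
  set.seed(10)
  groups <- rep(1:3, each = 15)
  nodes <- sprintf("n%02d", 1:45)
  pairs <- t(utils::combn(45, 2))
  p_edge <- ifelse(groups[pairs[, 1]] == groups[pairs[, 2]], 0.9, 0.05)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(taxon_a = nodes[pairs[keep, 1]],
                          taxon_b = nodes[pairs[keep, 2]])
  mod <- detect_modules(edges, seed = 3)
  memb <- attr(mod, "membership")
  expect_setequal(names(memb), nodes)  # a full partition
  expect_equal(sum(mod$n_nodes), 45)
  # best-match accuracy against the planted grouping
  tab <- table(memb[nodes], groups)
  acc <- sum(apply(tab, 2, max)) / 45
  expect_gte(acc, 0.95)
})

test_that("network autoplot renders", {
  mod <- detect_modules(dplyr::bind_rows(clique_edges(5, "a"), clique_edges(4, "b")),
                        seed = 1)
  expect_s3_class(autoplot(mod), "ggplot")
})
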