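test_that("Kosambi map function matches the closed form and inverts exactly", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))   # 27.46531 cM
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(kosambi_r(-1), ">= 0")
  for (r in c(0.01, 0.1, 0.25, 0.4, 0.49))
    expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-12)
})

test_that("simulated genomes conserve length and are seed-deterministic", {
  sim <- simulate_genome(2, 1e6, 10, min_scaffold_len = 2e4, seed = 5)
  expect_equal(sum(sim$scaffolds$length), 2e6)
  expect_equal(nrow(sim$truth$scaffold_truth), 10L)
  expect_equal(nchar(sim$scaffolds$sequence), sim$scaffolds$length)
  # scaffolds tile each chromosome without overlap
  st <- sim$truth$scaffold_truth
  for (c_i in 1:2) {
    s <- st[st$chrom == c_i, ]
    s <- s[order(s$start), ]
    expect_equal(s$start, cumsum(c(1, head(s$length, -1))), ignore_attr = TRUE)
    expect_equal(sum(s$length), 1e6)
  }

  again <- simulate_genome(2, 1e6, 10, min_scaffold_len = 2e4, seed = 5)
  expect_identical(sim, again)

  one_per <- simulate_genome(3, 1e5, 3, min_scaffold_len = 1e4, seed = 5)
  expect_equal(one_per$truth$scaffold_truth$length, rep(1e5L, 3))
  expect_error(simulate_genome(2, 1e4, 10, min_scaffold_len = 2e4, seed = 5),
               "too small")
  expect_error(simulate_genome(3, 1e6, 2, seed = 1), "n_scaffolds")
})

test_that("cross simulation follows CP class semantics", {
  sim <- place_markers(simulate_genome(1, 1e6, 2, min_scaffold_len = 1e5,
                                       with_sequence = FALSE, seed = 8),
                       n_per_chrom = 30, seed = 8)
  gm <- simulate_cross(sim$truth, n_offspring = 400, missing_rate = 0, seed = 8)
  expect_false(any(gm$calls == "--"))
  # calls respect the class alphabet
  for (i in seq_len(nrow(gm$markers))) {
    alpha <- switch(gm$markers$seg_class[i],
                    lmxll = c("lm", "ll"), nnxnp = c("nn", "np"),
                    hkxhk = c("hh", "hk", "kk"))
    expect_true(all(gm$calls[i, ] %in% alpha))
  }
  # markers at zero genetic distance cosegregate within parental meioses:
  # two lmxll markers at identical cM give identical or fully mirrored calls
  mt <- sim$truth$marker_truth
  mt2 <- rbind(mt[1, ], mt[1, ])
  mt2$marker_id <- c("dupA", "dupB")
  mt2$seg_class <- "lmxll"
  truth2 <- sim$truth
  truth2$marker_truth <- mt2
  gm2 <- simulate_cross(truth2, n_offspring = 50, missing_rate = 0, seed = 9)
  agree <- mean(gm2$calls[1, ] == gm2$calls[2, ])
  expect_true(agree %in% c(0, 1))
})

test_that("testcross segregation is 1:1 within binomial error at n = 10000", {
  sim <- place_markers(simulate_genome(1, 1e6, 2, min_scaffold_len = 1e5,
                                       with_sequence = FALSE, seed = 2),
                       n_per_chrom = 6,
                       class_mix = c(lmxll = 1, nnxnp = 0, hkxhk = 0), seed = 2)
  gm <- simulate_cross(sim$truth, n_offspring = 10000, missing_rate = 0,
                       seed = 2)
  frac_lm <- rowMeans(gm$calls == "lm")
  sigma <- sqrt(0.25 / 10000)
  expect_true(all(abs(frac_lm - 0.5) < 3 * sigma + 1e-9))
})

test_that("adjacent-marker recombinant fraction tracks kosambi_r", {
  # two lmxll markers 10 cM apart, n = 5000: recombinants within 3 sigma
  truth <- structure(list(
    chromosomes = data.frame(chrom = 1L, length = 1e6L),
    scaffold_truth = data.frame(scaffold_id = "s1", chrom = 1L, start = 1L,
                                length = 1e6L, orientation = "+"),
    marker_truth = data.frame(
      marker_id = c("mA", "mB"), chrom = 1L,
      genome_pos = c(1e5L, 5e5L), true_cm = c(0, 10),
      seg_class = "lmxll", phase1 = 1L, phase2 = 0L,
      scaffold = "s1", scaffold_pos = c(1e5L, 5e5L),
      stringsAsFactors = FALSE),
    causal_locus = NULL), class = "truth_layout")
  gm <- simulate_cross(truth, n_offspring = 5000, missing_rate = 0, seed = 4)
  rec <- mean(gm$calls[1, ] != gm$calls[2, ])
  r_exp <- kosambi_r(10)
  expect_lt(abs(rec - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 5000))
})

test_that("map perturbation is identity at zero rates and respects knobs", {
  # ~0.9 cM marker spacing (100 markers over a 92 cM chromosome), so mild
  # jitter cannot scramble ranks
  sim <- place_markers(simulate_genome(2, 2e7, 8, min_scaffold_len = 5e5,
                                       with_sequence = FALSE, seed = 6),
                       n_per_chrom = 100, seed = 6)
  tm <- true_genetic_map(sim$truth, "T", 2)
  expect_equal(perturb_map(tm, 0, 0, 0, seed = 1)$placements, tm$placements)
  expect_equal(nrow(perturb_map(tm, drop_rate = 1, seed = 1)$placements), 0L)
  # mild jitter keeps per-LG rank order nearly intact (rank-correlation oracle)
  pj <- perturb_map(tm, jitter_cm = 0.5, seed = 1)
  for (lg in 1:2) {
    a <- tm$placements[tm$placements$lg == lg, ]
    b <- pj$placements[match(a$marker_id, pj$placements$marker_id), ]
    expect_gt(oracle_spearman(a$cm, b$cm), 0.99)
  }
})

test_that("bulk simulation yields the linkage-determined Delta(SNP-index)", {
  sim <- place_markers(simulate_genome(2, 10e6, 4, min_scaffold_len = 1e5,
                                       with_sequence = FALSE, seed = 12),
                       n_per_chrom = 5, causal_chrom = 1, causal_frac = 0.1,
                       seed = 12)
  pools <- simulate_bulks(sim$truth, n_snps_per_chrom = 8000, mean_depth = 400,
                          seed = 12)
  d <- abs_delta(pools)
  causal <- sim$truth$causal_locus
  # near the causal locus (r ~ 0): carrier index ~ 0.5, non-carrier ~ 0
  near <- d[d$chrom == "chr1" & abs(d$pos - causal$genome_pos) < 5e4, ]
  expect_gt(nrow(near), 10)
  expect_equal(mean(near$index1), 0.5, tolerance = 0.05)
  expect_lt(mean(near$index2), 0.02)
  expect_equal(mean(near$abs_delta), 0.5, tolerance = 0.05)
  # r = 0.25 at 25 ln 3 cM from the locus: expected |Delta| = 0.25
  d_cm <- 25 * log(3)
  target <- causal$genome_pos + d_cm / 4.6 * 1e6
  at25 <- d[d$chrom == "chr1" & abs(d$pos - target) < 5e4, ]
  expect_gt(nrow(at25), 10)
  expect_equal(mean(at25$abs_delta), 0.25, tolerance = 0.06)
  # unlinked chromosome: expected Delta 0, only sampling noise remains
  off <- d[d$chrom == "chr2", ]
  expect_lt(abs(mean(off$index1 - off$index2)), 0.01)
  expect_error(simulate_bulks(sim$truth, mean_depth = 0), "mean_depth")
})
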