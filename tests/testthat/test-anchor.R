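test_that("spearman_rho matches the rank-formula values", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 12/60
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1, 2), "length")
})

test_that("chromosome assignment follows the weighted marker majority", {
  mk <- function(id, lg, cm, scaf, pos)
    data.frame(marker_id = id, lg = lg, cm = cm, scaffold = scaf, pos = pos)
  mapA <- genetic_map("A", 2, rbind(mk("x1", 5, 1, "s", 10), mk("x2", 5, 2, "s", 20),
                                    mk("x3", 5, 3, "s", 30)))
  mapC <- genetic_map("C", 1, rbind(mk("y1", 11, 1, "s", 10), mk("y2", 11, 2, "s", 20)))
  expect_equal(assign_chromosome(maps = list(mapA, mapC), scaffold = "s"), 5L)
  # 1 marker at weight 1 vs 2 markers at weight 2 on the same LG
  mapD <- genetic_map("D", 1, mk("z1", 1, 1, "t", 10))
  mapE <- genetic_map("E", 2, rbind(mk("z2", 1, 1, "t", 10), mk("z3", 1, 2, "t", 20)))
  expect_equal(assign_chromosome(maps = list(mapD, mapE), scaffold = "t"), 1L)
  # an exact weighted tie is unplaced
  mapF <- genetic_map("F", 1, rbind(mk("w1", 1, 1, "u", 10), mk("w2", 2, 1, "u", 20)))
  expect_equal(assign_chromosome(maps = list(mapF), scaffold = "u"), 0L)
})

test_that("consensus positions are weighted means of normalised map positions", {
  mk <- function(id, lg, cm, scaf, pos)
    data.frame(marker_id = id, lg = lg, cm = cm, scaffold = scaf, pos = pos)
  # map LG spans 0..10 cM; scaffold at 2 cM -> 0.2 in both maps
  span <- function(pref) rbind(mk(paste0(pref, "lo"), 1, 0, "zz_lo", 1),
                               mk(paste0(pref, "hi"), 1, 10, "zz_hi", 1))
  m1 <- genetic_map("M1", 2, rbind(span("a"), mk("a1", 1, 2, "sc", 10)))
  m2 <- genetic_map("M2", 2, rbind(span("b"), mk("b1", 1, 2, "sc", 10)))
  expect_equal(consensus_position("sc", 1, list(m1, m2)), 0.2)
  # 0.1 at weight 2 and 0.4 at weight 1 -> (0.2 + 0.4) / 3 = 0.2
  m3 <- genetic_map("M3", 2, rbind(span("c"), mk("c1", 1, 1, "sc", 10)))
  m4 <- genetic_map("M4", 1, rbind(span("d"), mk("d1", 1, 4, "sc", 10)))
  expect_equal(consensus_position("sc", 1, list(m3, m4)), 0.2)
  # present in one map only: that map's position
  expect_equal(consensus_position("sc", 1, list(m3)), 0.1)
})

test_that("ordering equals the enumeration oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    n_scaf <- sample(3:6, 1)
    n_maps <- sample(1:3, 1)
    scafs <- sprintf("s%02d", seq_len(n_scaf))
    maps <- lapply(seq_len(n_maps), function(k) {
      n_mark <- sample(n_scaf:(3 * n_scaf), 1)
      genetic_map(paste0("m", k), sample(c(1, 2, 2), 1),
                  data.frame(marker_id = sprintf("k%d_%d", k, seq_len(n_mark)),
                             lg = 1L, cm = round(runif(n_mark, 0, 50), 2),
                             scaffold = sample(scafs, n_mark, replace = TRUE),
                             pos = sample.int(1e5, n_mark)))
    })
    res <- order_scaffolds(scafs, 1L, maps)
    expect_equal(res$J, oracle_best_ordering(scafs, 1L, maps), tolerance = 1e-9,
                 label = sprintf("instance %d", i))
  }
})

test_that("hill-climb branch attains the enumerated optimum too", {
  set.seed(7)
  for (i in 1:10) {
    scafs <- sprintf("h%d", 1:5)
    maps <- list(genetic_map("m", 2, data.frame(
      marker_id = sprintf("q%d", 1:12), lg = 1L,
      cm = round(runif(12, 0, 40), 1),
      scaffold = sample(scafs, 12, replace = TRUE),
      pos = sample.int(1e5, 12))))
    hc <- order_scaffolds(scafs, 1L, maps, exact_limit = 2L)
    ex <- order_scaffolds(scafs, 1L, maps, exact_limit = 8L)
    expect_gte(hc$J, ex$J - 1e-9)
  }
})

test_that("monotone single-map groups sort by position with J = w", {
  maps <- list(genetic_map("solo", 2, data.frame(
    marker_id = sprintf("p%d", 1:3), lg = 1L, cm = c(1, 5, 9),
    scaffold = c("sA", "sB", "sC"), pos = 100L)))
  res <- order_scaffolds(c("sC", "sA", "sB"), 1L, maps)
  expect_equal(res$order, c("sA", "sB", "sC"))
  expect_equal(res$J, 2)
})

test_that("orientation follows the within-scaffold bp ~ cM trend", {
  mk <- function(id, cm, pos)
    data.frame(marker_id = id, lg = 1L, cm = cm, scaffold = "sc", pos = pos)
  up <- genetic_map("up", 1, rbind(mk("u1", 5.0, 100e3), mk("u2", 5.8, 500e3)))
  expect_equal(orient_scaffold("sc", 1L, list(up)), "+")
  dn <- genetic_map("dn", 1, rbind(mk("d1", 5.8, 100e3), mk("d2", 5.0, 500e3)))
  expect_equal(orient_scaffold("sc", 1L, list(dn)), "-")
  # two markers at identical cM carry no orientation signal
  flat <- genetic_map("flat", 1, rbind(mk("f1", 5.0, 100e3), mk("f2", 5.0, 500e3)))
  expect_equal(orient_scaffold("sc", 1L, list(flat)), "?")
  single <- genetic_map("one", 1, mk("s1", 5.0, 100e3))
  expect_equal(orient_scaffold("sc", 1L, list(single)), "?")
})

test_that("plans cover every scaffold once and concordance is 1 for a self-map", {
  maps <- fixture_maps()
  scafs <- fixture_scaffolds()
  plan <- build_anchor_plan(maps, scafs)
  expect_setequal(plan$scaffold_id, scafs$scaffold_id)
  expect_equal(anyDuplicated(plan$scaffold_id), 0L)
  # order_index contiguous within each chromosome
  for (c_i in unique(plan$chrom[plan$chrom > 0])) {
    oi <- sort(plan$order_index[plan$chrom == c_i])
    expect_equal(oi, seq_along(oi))
  }
  expect_true(all(is.na(plan$order_index[plan$chrom == 0])))
  # s7 has no markers -> unplaced
  expect_equal(plan$chrom[plan$scaffold_id == "s7"], 0L)
  # single-marker scaffolds anchored but unoriented
  expect_equal(plan$orientation[plan$scaffold_id == "s3"], "?")
  expect_gt(plan$chrom[plan$scaffold_id == "s3"], 0L)
  # consensus built from one map alone agrees with itself perfectly
  solo_plan <- build_anchor_plan(maps[1])
  cc <- compare_maps(solo_plan, maps[1])
  expect_equal(cc$rho, rep(1, nrow(cc)))
  # a map with one LG reversed shows rho = -1 on that LG
  rev_p <- maps[[1]]$placements
  rev_p$cm[rev_p$lg == 2] <- max(rev_p$cm[rev_p$lg == 2]) - rev_p$cm[rev_p$lg == 2]
  rev_map <- genetic_map("R", 2, rev_p, n_lg = 2)
  cc2 <- compare_maps(solo_plan, list(rev_map))
  expect_equal(cc2$rho[cc2$chrom == 2], -1, tolerance = 1e-12)
})

test_that("weight monotonicity: raising a map's weight never hurts its rho", {
  set.seed(31)
  for (i in 1:10) {
    scafs <- sprintf("w%d", 1:5)
    mk_map <- function(name, w, seed) {
      set.seed(seed)
      n <- 10L
      genetic_map(name, w, data.frame(
        marker_id = sprintf("%s_%d", name, 1:n), lg = 1L,
        cm = round(runif(n, 0, 30), 1),
        scaffold = sample(scafs, n, replace = TRUE),
        pos = sample.int(1e5, n)))
    }
    m1 <- mk_map("m1", 1, 1000 + i)
    m2 <- mk_map("m2", 1, 2000 + i)
    rho_of <- function(maps) {
      res <- order_scaffolds(scafs, 1L, maps)
      pos <- match(scafs, res$order)
      pl <- maps[[1]]$placements
      y <- pos[match(pl$scaffold, scafs)]
      if (length(unique(pl$cm)) < 2 || length(unique(y)) < 2) return(0)
      oracle_spearman(pl$cm, y)
    }
    m1_heavy <- m1
    m1_heavy$weight <- 2
    expect_gte(rho_of(list(m1_heavy, m2)) + 1e-9, rho_of(list(m1, m2)))
  }
})

test_that("synthetic recovery: zero-noise maps reproduce the true layout", {
  sim <- place_markers(simulate_genome(2, 3e6, 24, min_scaffold_len = 5e4,
                                       with_sequence = FALSE, seed = 11),
                       n_per_chrom = 120, seed = 11)
  maps <- list(true_genetic_map(sim$truth, "MH", 2),
               true_genetic_map(sim$truth, "YM", 2))
  plan <- build_anchor_plan(maps)
  st <- sim$truth$scaffold_truth
  for (c_i in 1:2) {
    truth_order <- st$scaffold_id[st$chrom == c_i][order(st$start[st$chrom == c_i])]
    got <- plan[plan$chrom == c_i, ]
    got <- got$scaffold_id[order(got$order_index)]
    expect_equal(got, intersect(truth_order, got))
    multi <- plan$scaffold_id[plan$chrom == c_i & plan$n_markers >= 2 &
                                plan$orientation != "?"]
    expect_equal(plan$orientation[match(multi, plan$scaffold_id)],
                 st$orientation[match(multi, st$scaffold_id)])
  }
})
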