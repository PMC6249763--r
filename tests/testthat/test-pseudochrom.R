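length_only_plan <- function(n, chrom = 1L) {
  structure(data.frame(
    scaffold_id = sprintf("c%dsc%03d", chrom, seq_len(n)),
    chrom = chrom, order_index = seq_len(n), orientation = "+",
    n_markers = 2L, consensus_pos = seq_len(n) / n,
    stringsAsFactors = FALSE), class = c("anchor_plan", "data.frame"))
}

split_lengths <- function(total, n) {
  base <- total %/% n
  lens <- rep(base, n)
  lens[n] <- lens[n] + total - base * n
  lens
}

test_that("pseudo-chromosome length = scaffold bases + 100 bp spacers", {
  # 38 scaffolds of 17,741,026 bp -> chromosome of 17,744,726 bp
  plan <- length_only_plan(38)
  lens <- split_lengths(17741026, 38)
  scafs <- scaffold_set(plan$scaffold_id, lens)
  bundle <- build_pseudochromosomes(plan, scafs)
  expect_equal(bundle$chromosomes$length, 17744726)
  expect_equal(max(bundle$agp$object_end), 17744726L)
  # a one-scaffold chromosome has no gaps
  solo <- build_pseudochromosomes(length_only_plan(1), scaffold_set("c1sc001", 5000L))
  expect_equal(solo$chromosomes$length, 5000)
  expect_equal(nrow(solo$agp), 1L)
  # plan scaffold absent from the set is an error
  expect_error(build_pseudochromosomes(plan, scaffold_set("other", 10L)),
               "missing from scaffold set")
})

test_that("sequence builds conserve bases, round-trip through AGP, and invert", {
  maps <- fixture_maps()
  scafs <- fixture_scaffolds()
  plan <- build_anchor_plan(maps, scafs)
  bundle <- build_pseudochromosomes(plan, scafs, gap_len = 100L, maps = maps)
  # conservation: non-gap bases (chromosomes + unplaced) = input bases
  placed <- plan$chrom > 0
  n_gaps <- sum(table(plan$chrom[placed]) - 1L)
  expect_equal(sum(bundle$chromosomes$length) - 100L * n_gaps +
                 sum(scafs$length[scafs$scaffold_id %in% bundle$unplaced]),
               sum(scafs$length))
  expect_equal(sum(nchar(gsub("[^N]", "", unlist(
    lapply(bundle$chromosomes$chrom, function(c_i)
      bundle$sequences[paste0("chr", c_i)]))))) >= 100L * n_gaps, TRUE)
  # AGP <-> FASTA cross-validation is byte-identical
  rebuilt <- sequences_from_agp(bundle$agp, scafs)
  for (obj in names(rebuilt))
    expect_identical(rebuilt[[obj]], unname(bundle$sequences[obj]))
  # building with every orientation flipped gives chromosomes whose reverse
  # complement restores the original scaffold content; revcomp is an involution
  flip <- function(p) { p$orientation <- chartr("+-", "-+", p$orientation); p }
  flipped <- build_pseudochromosomes(flip(plan), scafs, gap_len = 100L)
  for (obj in names(bundle$sequences)[startsWith(names(bundle$sequences), "chr")]) {
    expect_identical(revcomp(revcomp(bundle$sequences[[obj]])),
                     bundle$sequences[[obj]])
    expect_false(identical(flipped$sequences[[obj]], bundle$sequences[[obj]]))
  }
  # revcomp agrees with the Biostrings implementation on DNA input
  dna <- scafs$sequence[1]
  expect_identical(revcomp(dna),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(dna))))
  # reversed scaffold really is the reverse complement
  minus <- plan$scaffold_id[plan$orientation == "-"][1]
  expect_false(is.na(minus))
  w <- bundle$agp[bundle$agp$component_type == "W" &
                    bundle$agp$component_id == minus, ]
  chrom_seq <- bundle$sequences[[w$object_id]]
  expect_identical(substr(chrom_seq, w$object_beg, w$object_end),
                   revcomp(scafs$sequence[scafs$scaffold_id == minus]))
})

test_that("marker projections land on the projected scaffold bases", {
  maps <- fixture_maps()
  scafs <- fixture_scaffolds()
  plan <- build_anchor_plan(maps, scafs)
  bundle <- build_pseudochromosomes(plan, scafs, maps = maps)
  pr <- bundle$projections
  expect_gt(nrow(pr), 0)
  mt <- do.call(rbind, lapply(maps, function(m) m$placements))
  for (i in seq_len(nrow(pr))) {
    m <- mt[mt$marker_id == pr$marker_id[i], ][1, ]
    piece <- agp_pieces(bundle$agp, pr$chrom[i], pr$chrom_pos[i], pr$chrom_pos[i])
    expect_equal(piece$scaffold_id, m$scaffold)
    expect_equal(piece$piece_start, m$pos)
  }
})

test_that("N50/L50 match the cumulative-sum definition", {
  expect_equal(n50_stats(c(10, 10, 10)), list(n50 = 10, l50 = 2L))
  expect_equal(n50_stats(c(100, 10, 10)), list(n50 = 100, l50 = 1L))
  expect_equal(n50_stats(c(5, 4, 3, 2, 1)), list(n50 = 4, l50 = 2L))
  expect_equal(n50_stats(7), list(n50 = 7, l50 = 1L))
})

test_that("assembly statistics partition counts, bases and densities", {
  plan <- rbind(length_only_plan(3, 1L), length_only_plan(2, 2L))
  plan$n_markers <- c(1L, 2L, 4L, 3L, 2L)
  plan$orientation <- c("?", "+", "-", "+", "?")
  unpl <- data.frame(scaffold_id = "loose", chrom = 0L, order_index = NA_integer_,
                     orientation = "?", n_markers = 0L, consensus_pos = NA_real_)
  plan <- rbind(as.data.frame(plan), unpl)
  class(plan) <- c("anchor_plan", "data.frame")
  scafs <- scaffold_set(plan$scaffold_id, c(10L, 10L, 10L, 20L, 20L, 30L))
  st <- assembly_stats(plan, scafs, genome_total_bp = 100)
  anch <- st[st$partition == "anchored", ]
  expect_equal(anch$n_scaffolds, 5L)
  expect_equal(anch$total_bases, 70)
  expect_equal(anch$pct_of_genome, 70)
  expect_equal(anch$n_markers, 12L)
  expect_equal(anch$with_1_marker, 1L)
  expect_equal(anch$with_4plus_markers, 1L)
  orient <- st[st$partition == "oriented", ]
  expect_equal(orient$n_scaffolds, 3L)
  expect_equal(orient$total_bases, 40)
  unp <- st[st$partition == "unanchored", ]
  expect_equal(unp$total_bases, 30)
  expect_error(assembly_stats(plan, scafs, genome_total_bp = 50), "smaller")
})

test_that("map statistics reproduce hand-counted per-LG values", {
  p <- data.frame(marker_id = sprintf("g%d", 1:5),
                  lg = c(1L, 1L, 1L, 2L, 3L),
                  cm = c(0, 5, 20, 7, 3),
                  scaffold = "s", pos = 1:5)
  st <- map_stats(genetic_map("toy", 1, p, n_lg = 3))
  lg1 <- st[st$lg == "1", ]
  expect_equal(lg1$length_cm, 20)
  expect_equal(lg1$max_gap_cm, 15)
  expect_equal(lg1$gaps_over_10, 1L)
  expect_equal(lg1$gaps_over_5, 1L)
  # single-marker LG: zero length and gap
  lg3 <- st[st$lg == "3", ]
  expect_equal(c(lg3$length_cm, lg3$max_gap_cm), c(0, 0))
  expect_equal(st$n_markers[st$lg == "all"], 5L)
})
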