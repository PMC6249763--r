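# Fixtures built in code, shared across test files.

# A tiny hand-written two-map fixture: 4 scaffolds on LG1, 2 on LG2,
# with within-scaffold bp~cM trends for orientation.
fixture_maps <- function() {
  mk <- function(id, lg, cm, scaf, pos)
    data.frame(marker_id = id, lg = lg, cm = cm, scaffold = scaf, pos = pos,
               stringsAsFactors = FALSE)
  a <- rbind(
    mk("a1", 1, 0.0, "s1", 100), mk("a2", 1, 1.0, "s1", 900),
    mk("a3", 1, 2.0, "s2", 200), mk("a4", 1, 3.0, "s2", 800),
    mk("a5", 1, 4.0, "s3", 500),
    mk("a6", 1, 5.0, "s4", 900), mk("a7", 1, 6.0, "s4", 100),
    mk("a8", 2, 0.0, "s5", 100), mk("a9", 2, 2.0, "s5", 700),
    mk("a10", 2, 4.0, "s6", 400))
  b <- rbind(
    mk("b1", 1, 0.0, "s1", 200), mk("b2", 1, 1.2, "s1", 950),
    mk("b3", 1, 2.1, "s2", 300),
    mk("b4", 1, 5.2, "s4", 800), mk("b5", 1, 6.1, "s4", 200),
    mk("b6", 2, 0.5, "s5", 150), mk("b7", 2, 3.5, "s6", 350))
  list(genetic_map("A", 2, a, n_lg = 2),
       genetic_map("B", 1, b, n_lg = 2))
}

fixture_scaffolds <- function(seed = 1L) {
  set.seed(seed)
  ids <- paste0("s", 1:7)
  lens <- c(1000L, 1000L, 600L, 1000L, 800L, 500L, 400L)
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  scaffold_set(ids, lens, seqs)
}

# Length-only anchor plan + scaffold set shaped like the published
# chromosome build: per-chromosome scaffold counts and base totals, and
# partition marker-class counts, taken from the summary tables shipped in
# extdata. Individual scaffold lengths are an even split (they are not
# published); every reported statistic depends only on counts and totals.
ds_reference_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "scafmap")
  chroms <- read.delim(ext("ds_v11_chromosomes.tsv"))
  parts <- read.delim(ext("ds_v11_partitions.tsv"))
  split_even <- function(total, n) {
    base <- total %/% n
    lens <- rep(base, n)
    lens[n] <- lens[n] + total - base * n
    lens
  }
  plan <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    n <- chroms$n_scaffolds[i]
    data.frame(scaffold_id = sprintf("c%02dsc%03d", chroms$chrom[i], seq_len(n)),
               chrom = chroms$chrom[i], order_index = seq_len(n),
               orientation = "+", n_markers = 0L, consensus_pos = seq_len(n) / n,
               length = split_even(chroms$scaffold_bases[i], n),
               stringsAsFactors = FALSE)
  }))
  # distribute marker-class and orientation counts over the anchored scaffolds
  anch <- parts[parts$partition == "anchored", ]
  ori <- parts[parts$partition == "oriented", ]
  classes <- rep(c(1L, 2L, 3L, 4L),
                 c(anch$with_1_marker, anch$with_2_markers,
                   anch$with_3_markers, anch$with_4plus_markers))
  n4 <- anch$with_4plus_markers
  left <- anch$n_markers - sum(classes[classes < 4L]) - 4L * n4
  extra4 <- rep(0L, n4)
  if (left > 0) {
    per <- left %/% n4
    extra4 <- rep(per, n4)
    extra4[seq_len(left - per * n4)] <- per + 1L
  }
  classes[classes == 4L] <- 4L + extra4
  unoriented <- c(rep(TRUE, anch$with_1_marker - ori$with_1_marker),
                  rep(FALSE, ori$with_1_marker),
                  rep(TRUE, anch$with_2_markers - ori$with_2_markers),
                  rep(FALSE, ori$with_2_markers),
                  rep(TRUE, anch$with_3_markers - ori$with_3_markers),
                  rep(FALSE, ori$with_3_markers),
                  rep(TRUE, anch$with_4plus_markers - ori$with_4plus_markers),
                  rep(FALSE, ori$with_4plus_markers))
  plan$n_markers <- classes
  plan$orientation[unoriented] <- "?"
  # unanchored scaffolds: counts and base total from the partition table
  un <- parts[parts$partition == "unanchored", ]
  un_markers <- rep(0L, un$n_scaffolds)
  un_markers[seq_len(un$with_1_marker)] <- 1L
  un_markers[un$with_1_marker + seq_len(un$with_2_markers)] <- 2L
  un_markers[un$with_1_marker + un$with_2_markers + seq_len(un$with_3_markers)] <- 3L
  i4 <- un$with_1_marker + un$with_2_markers + un$with_3_markers +
    seq_len(un$with_4plus_markers)
  left_un <- un$n_markers - sum(un_markers)
  base4 <- left_un %/% un$with_4plus_markers
  un_markers[i4] <- base4
  un_markers[i4[seq_len(left_un - base4 * un$with_4plus_markers)]] <- base4 + 1L
  unpl <- data.frame(scaffold_id = sprintf("unpl%04d", seq_len(un$n_scaffolds)),
                     chrom = 0L, order_index = NA_integer_, orientation = "?",
                     n_markers = un_markers, consensus_pos = NA_real_,
                     length = split_even(un$total_bases, un$n_scaffolds),
                     stringsAsFactors = FALSE)
  plan <- rbind(plan, unpl)
  scafs <- scaffold_set(plan$scaffold_id, plan$length)
  plan$length <- NULL
  class(plan) <- c("anchor_plan", "data.frame")
  list(plan = plan, scaffolds = scafs, chroms = chroms, partitions = parts)
}

# Independent Spearman: Pearson product-moment on average ranks, written out.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Independent ordering objective + exhaustive maximiser used as oracle.
oracle_best_ordering <- function(scaffolds, chrom, maps) {
  scaffolds <- sort(scaffolds)
  n <- length(scaffolds)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    pos <- integer(n); pos[p] <- seq_len(n)
    j <- 0
    for (m in maps) {
      pl <- m$placements
      pl <- pl[pl$lg == chrom & pl$scaffold %in% scaffolds, , drop = FALSE]
      if (nrow(pl) < 2L) next
      y <- pos[match(pl$scaffold, scaffolds)]
      if (length(unique(pl$cm)) < 2L || length(unique(y)) < 2L) next
      r <- oracle_spearman(pl$cm, y)
      if (!is.na(r)) j <- j + m$weight * r
    }
    if (j > best) best <- j
  }
  best
}
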