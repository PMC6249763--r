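# Synthetic data emulating the statistical structure of a GBS-genotyped F1
# outcross study: a fragmented genome with a known scaffold layout, markers of
# the three CP segregation classes, per-population genetic maps with
# estimation noise, and two phenotype-pooled bulks segregating at one causal
# locus. Ground truth is retained so downstream stages can be scored.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Kosambi mapping function ---------------------------------------------------

#' Kosambi map distance from recombination fraction (and back)
#'
#' `kosambi_cm` converts a recombination fraction r in [0, 0.5) to map
#' distance d = 25 ln((1 + 2r) / (1 - 2r)) centimorgans; `kosambi_r` is the
#' exact inverse, r = tanh(d / 50) / 2.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @param d map distance(s) in cM, >= 0.
#' @return numeric vector.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop_format("recombination fraction must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop_format("map distance must be >= 0")
  tanh(d / 50) / 2
}

# Genome layout --------------------------------------------------------------

#' Simulate a fragmented genome with known scaffold layout
#'
#' Chromosomes are cut at random breakpoints into scaffolds; each scaffold is
#' given a random true orientation on its chromosome (the assembler does not
#' know strands), and optionally a random i.i.d. nucleotide sequence.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length(s) in bp (scalar recycled).
#' @param n_scaffolds total scaffold count (>= `n_chrom`).
#' @param min_scaffold_len smallest allowed scaffold (bp).
#' @param with_sequence generate sequences (FALSE gives a length-only set).
#' @param seed RNG seed.
#' @return list with `truth` (a `truth_layout`: `chromosomes`,
#'   `scaffold_truth`, later `marker_truth`/`causal_locus`) and `scaffolds`
#'   (a [scaffold_set()]).
#' @export
simulate_genome <- function(n_chrom = 17L, chrom_len = 2e6, n_scaffolds = 170L,
                            min_scaffold_len = 10e3, with_sequence = TRUE,
                            seed = 42L) {
  if (n_scaffolds < n_chrom) stop_format("n_scaffolds must be >= n_chrom")
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  with_seed(seed, {
    # distribute scaffold counts over chromosomes proportionally to length
    per_chrom <- rep(1L, n_chrom)
    extra <- n_scaffolds - n_chrom
    if (extra > 0L) {
      add <- sample(rep(seq_len(n_chrom), times = pmax(1L, round(chrom_len / sum(chrom_len) * 4 * extra))),
                    extra, replace = TRUE)
      per_chrom <- per_chrom + tabulate(add, nbins = n_chrom)
    }
    if (any(chrom_len < per_chrom * min_scaffold_len))
      stop_format("chrom_len too small to host %d scaffolds of >= %d bp",
                  max(per_chrom), min_scaffold_len)
    scaf <- vector("list", n_chrom)
    idx0 <- 0L
    for (c_i in seq_len(n_chrom)) {
      k <- per_chrom[c_i]
      len <- chrom_len[c_i]
      if (k == 1L) {
        starts <- 1L
        lens <- len
      } else {
        cand <- seq_len(len - 1L)[seq_len(len - 1L) %% min_scaffold_len == 0L]
        cuts <- sort(cand[sample.int(length(cand), k - 1L)])
        starts <- c(1L, cuts + 1L)
        lens <- diff(c(0L, cuts, len))
      }
      scaf[[c_i]] <- data.frame(
        scaffold_id = sprintf("scaf%04d", idx0 + seq_len(k)),
        chrom = c_i, start = as.integer(starts), length = as.integer(lens),
        orientation = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
      idx0 <- idx0 + k
    }
    scaffold_truth <- do.call(rbind, scaf)
    seqs <- NULL
    if (with_sequence)
      seqs <- vapply(scaffold_truth$length, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
        character(1))
    truth <- structure(list(
      chromosomes = data.frame(chrom = seq_len(n_chrom), length = chrom_len),
      scaffold_truth = scaffold_truth,
      marker_truth = NULL, causal_locus = NULL),
      class = "truth_layout")
    list(truth = truth,
         scaffolds = scaffold_set(scaffold_truth$scaffold_id,
                                  scaffold_truth$length, seqs))
  })
}

#' Place markers (and a causal locus) on a simulated genome
#'
#' Marker genome positions are uniform per chromosome; true genetic positions
#' follow a linear cM/Mb rate, so true order equals physical order. Each
#' marker gets a CP segregation class and a random linkage phase in each
#' parent.
#'
#' @param sim result of [simulate_genome()].
#' @param n_per_chrom markers per chromosome.
#' @param class_mix named proportions for lmxll / nnxnp / hkxhk (sum 1).
#' @param cm_per_mb genetic:physical rate (default 4.6 cM/Mb, the
#'   genome-wide average implied by a ~1850 cM map over ~400 Mb).
#' @param causal_chrom,causal_frac chromosome and fractional position of the
#'   causal locus used by [simulate_bulks()].
#' @param seed RNG seed.
#' @return `sim` with `truth$marker_truth` and `truth$causal_locus` filled.
#' @export
place_markers <- function(sim, n_per_chrom = 100L,
                          class_mix = c(lmxll = 0.4, nnxnp = 0.4, hkxhk = 0.2),
                          cm_per_mb = 4.6, causal_chrom = 1L,
                          causal_frac = 0.5, seed = 42L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  truth <- sim$truth
  with_seed(seed, {
    chroms <- truth$chromosomes
    mk <- vector("list", nrow(chroms))
    for (c_i in seq_len(nrow(chroms))) {
      pos <- sort(sample.int(chroms$length[c_i], n_per_chrom))
      mk[[c_i]] <- data.frame(
        marker_id = sprintf("m%02d_%04d", c_i, seq_len(n_per_chrom)),
        chrom = c_i, genome_pos = pos, true_cm = pos / 1e6 * cm_per_mb,
        seg_class = sample(names(class_mix), n_per_chrom, replace = TRUE,
                           prob = class_mix),
        phase1 = sample(0:1, n_per_chrom, replace = TRUE),
        phase2 = sample(0:1, n_per_chrom, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    marker_truth <- do.call(rbind, mk)
    # scaffold coordinates from the truth tiling
    st <- truth$scaffold_truth
    idx <- vapply(seq_len(nrow(marker_truth)), function(i) {
      which(st$chrom == marker_truth$chrom[i] &
              st$start <= marker_truth$genome_pos[i] &
              st$start + st$length > marker_truth$genome_pos[i])[1L]
    }, integer(1))
    off <- marker_truth$genome_pos - st$start[idx] + 1L
    marker_truth$scaffold <- st$scaffold_id[idx]
    marker_truth$scaffold_pos <- ifelse(st$orientation[idx] == "+", off,
                                        st$length[idx] - off + 1L)
    truth$marker_truth <- marker_truth
    cpos <- round(chroms$length[causal_chrom] * causal_frac)
    truth$causal_locus <- data.frame(chrom = causal_chrom, genome_pos = cpos,
                                     true_cm = cpos / 1e6 * cm_per_mb)
    sim$truth <- truth
    sim
  })
}

# Population simulation ------------------------------------------------------

#' Simulate F1 outcross genotypes with GBS-style depths and missingness
#'
#' For every offspring one gamete per parent is generated along each
#' chromosome: a random starting haplotype, then recombination between
#' adjacent markers independently with probability `kosambi_r` of the
#' true-cM interval (no crossover interference). Calls follow the CP class
#' semantics (lm x ll offspring lm/ll 1:1, nn x np offspring nn/np 1:1,
#' hk x hk offspring hh/hk/kk 1:2:1). Depths are overdispersed
#' (negative-binomial, variance mu + disp mu^2); calls are masked to `"--"`
#' at `missing_rate`, and miscalled uniformly within the class alphabet at
#' `error_rate`.
#'
#' @param truth a `truth_layout` with markers placed.
#' @param n_offspring population size.
#' @param missing_rate per-call missing probability.
#' @param depth_mean,depth_disp depth distribution (mean 30, dispersion 0.3
#'   by default; dispersion 0 gives Poisson).
#' @param error_rate genotyping error probability (default 0).
#' @param seed RNG seed.
#' @return a [genotype_matrix()].
#' @export
simulate_cross <- function(truth, n_offspring = 200L, missing_rate = 0.05,
                           depth_mean = 30, depth_disp = 0.3, error_rate = 0,
                           seed = 42L) {
  mt <- truth$marker_truth
  if (is.null(mt)) stop_format("truth has no markers; call place_markers() first")
  assert_scalar_number(depth_mean, "depth_mean", min = 1e-9)
  with_seed(seed, {
    mt <- mt[order(mt$chrom, mt$true_cm, mt$marker_id), , drop = FALSE]
    n_mark <- nrow(mt)
    gam <- function() {
      g <- matrix(0L, n_mark, n_offspring)
      for (c_i in unique(mt$chrom)) {
        rows <- which(mt$chrom == c_i)
        r <- kosambi_r(diff(mt$true_cm[rows]))
        h <- matrix(0L, length(rows), n_offspring)
        h[1L, ] <- sample(0:1, n_offspring, replace = TRUE)
        if (length(rows) > 1L) {
          flip <- matrix(rbinom((length(rows) - 1L) * n_offspring, 1L,
                                rep(r, n_offspring)),
                         length(rows) - 1L, n_offspring)
          for (j in 2L:length(rows)) h[j, ] <- (h[j - 1L, ] + flip[j - 1L, ]) %% 2L
        }
        g[rows, ] <- h
      }
      g
    }
    g1 <- gam()
    g2 <- gam()
    calls <- matrix(MISSING_CALL, n_mark, n_offspring,
                    dimnames = list(mt$marker_id,
                                    sprintf("off%04d", seq_len(n_offspring))))
    for (i in seq_len(n_mark)) {
      cls <- mt$seg_class[i]
      if (cls == "lmxll") {
        calls[i, ] <- ifelse(g1[i, ] == mt$phase1[i], "lm", "ll")
      } else if (cls == "nnxnp") {
        calls[i, ] <- ifelse(g2[i, ] == mt$phase2[i], "np", "nn")
      } else {
        a1 <- ifelse(g1[i, ] == mt$phase1[i], "k", "h")
        a2 <- ifelse(g2[i, ] == mt$phase2[i], "k", "h")
        calls[i, ] <- paste0(pmin(a1, a2), pmax(a1, a2))
      }
    }
    if (error_rate > 0) {
      err <- matrix(runif(n_mark * n_offspring) < error_rate, n_mark, n_offspring)
      for (i in which(rowSums(err) > 0L)) {
        alphabet <- SEG_ALPHABET[[mt$seg_class[i]]]
        k <- sum(err[i, ])
        calls[i, err[i, ]] <- sample(alphabet, k, replace = TRUE)
      }
    }
    n_calls <- n_mark * n_offspring
    depths <- if (depth_disp > 0) {
      matrix(rnbinom(n_calls, mu = depth_mean, size = 1 / depth_disp), n_mark)
    } else {
      matrix(stats::rpois(n_calls, depth_mean), n_mark)
    }
    if (missing_rate > 0)
      calls[matrix(runif(n_calls) < missing_rate, n_mark)] <- MISSING_CALL
    genotype_matrix(
      data.frame(marker_id = mt$marker_id, seg_class = mt$seg_class,
                 scaffold = mt$scaffold, pos = mt$scaffold_pos,
                 stringsAsFactors = FALSE),
      calls, depths)
  })
}

# Map estimates --------------------------------------------------------------

#' Exact genetic map implied by the truth layout
#'
#' @param truth a `truth_layout` with markers placed.
#' @param name,weight map label and merge weight.
#' @param keep_fraction fraction of markers retained (simulates maps built
#'   from population-specific marker subsets).
#' @param seed RNG seed for the subset draw.
#' @return a [genetic_map()] with lg = chromosome and cm = true cM.
#' @export
true_genetic_map <- function(truth, name, weight = 1, keep_fraction = 1,
                             seed = 42L) {
  mt <- truth$marker_truth
  if (is.null(mt)) stop_format("truth has no markers; call place_markers() first")
  with_seed(seed, {
    if (keep_fraction < 1) {
      keep <- sort(sample.int(nrow(mt), max(2L, round(keep_fraction * nrow(mt)))))
      mt <- mt[keep, , drop = FALSE]
    }
    genetic_map(name, weight,
                data.frame(marker_id = mt$marker_id, lg = mt$chrom,
                           cm = mt$true_cm, scaffold = mt$scaffold,
                           pos = mt$scaffold_pos, stringsAsFactors = FALSE),
                n_lg = max(truth$chromosomes$chrom))
  })
}

#' Perturb a genetic map to emulate estimation error
#'
#' Adds Gaussian cM jitter, swaps the cM of random adjacent marker pairs,
#' drops random markers, and (optionally) misassigns markers to a random
#' other LG — the error modes that make multi-map consensus non-trivial.
#'
#' @param map a [genetic_map()].
#' @param jitter_cm standard deviation of the positional jitter (cM).
#' @param swap_rate probability an adjacent pair exchanges positions.
#' @param drop_rate probability a marker is dropped.
#' @param lg_misassign_rate probability a marker moves to a random wrong LG.
#' @param seed RNG seed.
#' @return a [genetic_map()] (same name/weight).
#' @export
perturb_map <- function(map, jitter_cm = 0, swap_rate = 0, drop_rate = 0,
                        lg_misassign_rate = 0, seed = 42L) {
  stopifnot(swap_rate >= 0, swap_rate <= 1, drop_rate >= 0, drop_rate <= 1)
  p <- map$placements
  with_seed(seed, {
    if (drop_rate > 0) {
      p <- p[runif(nrow(p)) >= drop_rate, , drop = FALSE]
      if (nrow(p) == 0L)
        return(genetic_map(map$name, map$weight,
                           p[0, , drop = FALSE], n_lg = map$n_lg))
    }
    if (jitter_cm > 0)
      p$cm <- pmax(0, p$cm + stats::rnorm(nrow(p), 0, jitter_cm))
    if (swap_rate > 0) {
      p <- p[order(p$lg, p$cm, p$marker_id), , drop = FALSE]
      for (lg in unique(p$lg)) {
        rows <- which(p$lg == lg)
        j <- 1L
        while (j < length(rows)) {
          if (runif(1) < swap_rate) {
            a <- rows[j]; b <- rows[j + 1L]
            p$cm[c(a, b)] <- p$cm[c(b, a)]
            j <- j + 2L  # a marker takes part in at most one swap
          } else j <- j + 1L
        }
      }
    }
    if (lg_misassign_rate > 0) {
      move <- runif(nrow(p)) < lg_misassign_rate
      if (any(move))
        p$lg[move] <- vapply(p$lg[move], function(l)
          sample(setdiff(seq_len(map$n_lg), l), 1L), integer(1))
    }
    genetic_map(map$name, map$weight, p, n_lg = map$n_lg)
  })
}

# Bulked segregants -----------------------------------------------------------

#' Simulate pooled allele depths for two phenotype bulks
#'
#' A dominant causal model: pool 1 holds carrier offspring, pool 2
#' non-carriers. For a SNP at recombination fraction r from the causal locus
#' (via `kosambi_r` of the true cM distance; r = 0.5 on other chromosomes)
#' the expected alternate-allele frequency is (1 - r)/2 in the carrier pool
#' and r/2 in the non-carrier pool, so the expected Delta(SNP-index) is
#' (1 - 2r)/2. Per-SNP pool depths are Poisson around `mean_depth` with
#' binomial alternate counts.
#'
#' @param truth a `truth_layout` with a causal locus.
#' @param n_snps_per_chrom SNPs per chromosome (uniform positions).
#' @param mean_depth mean pool depth (> 0).
#' @param cm_per_mb genetic:physical rate used for SNP-to-locus distances.
#' @param seed RNG seed.
#' @return a [pool_depth_table()] with chrom names `chr<i>`.
#' @export
simulate_bulks <- function(truth, n_snps_per_chrom = 1000L, mean_depth = 20,
                           cm_per_mb = 4.6, seed = 42L) {
  if (is.null(truth$causal_locus))
    stop_format("truth has no causal locus; call place_markers() first")
  if (mean_depth <= 0) stop_format("mean_depth must be > 0")
  cl <- truth$causal_locus
  with_seed(seed, {
    rows <- vector("list", nrow(truth$chromosomes))
    for (c_i in truth$chromosomes$chrom) {
      len <- truth$chromosomes$length[truth$chromosomes$chrom == c_i]
      pos <- sort(sample.int(len, n_snps_per_chrom))
      r <- if (c_i == cl$chrom) {
        kosambi_r(abs(pos / 1e6 * cm_per_mb - cl$true_cm))
      } else rep(0.5, n_snps_per_chrom)
      p_carrier <- (1 - r) / 2
      p_noncar <- r / 2
      d1 <- stats::rpois(n_snps_per_chrom, mean_depth)
      d2 <- stats::rpois(n_snps_per_chrom, mean_depth)
      alt1 <- rbinom(n_snps_per_chrom, d1, p_carrier)
      alt2 <- rbinom(n_snps_per_chrom, d2, p_noncar)
      rows[[c_i]] <- data.frame(chrom = sprintf("chr%d", c_i), pos = pos,
                                ref1 = d1 - alt1, alt1 = alt1,
                                ref2 = d2 - alt2, alt2 = alt2,
                                stringsAsFactors = FALSE)
    }
    pool_depth_table(do.call(rbind, rows))
  })
}
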